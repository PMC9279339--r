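#' Annotate off-target sites with gene-feature context
#'
#' Places each site (the 20-nt protospacer interval, 0-based half-open
#' coordinates) into exactly one genomic category by interval overlap
#' against a GFF3 gene model, with precedence
#' 5'UTR/3'UTR > exon > intron (gene body) > upstream2kb/downstream2kb >
#' IGR. Up/downstream windows are strand-aware relative to the gene. When
#' several genes compete at the same precedence level the alphabetically
#' first gene id wins, making the assignment deterministic. Sites on
#' chromosomes absent from the model are IGR (with a warning).
#'
#' @param sites data.frame with `site_id`, `chrom`, `start` (0-based),
#'   `end`, or a manifest from [design_library()].
#' @param gff Path to a GFF3 file or an imported `GRanges`.
#' @param gene_list Optional character vector (or one-symbol-per-line file)
#'   of gene ids of interest; matched sites get `in_user_list = TRUE`.
#' @param flank Up/downstream window size in bp (default 2000).
#' @return data.frame: `site_id`, `category`, `gene_id`, `in_user_list`.
#' @export
annotate_sites <- function(sites, gff, gene_list = NULL, flank = 2000L) {
  if (is.character(gff)) gff <- rtracklayer::import(gff)
  if (!is.null(gene_list) && length(gene_list) == 1L && file.exists(gene_list))
    gene_list <- readLines(gene_list)

  id_col <- function(gr) {
    mc <- S4Vectors::mcols(gr)
    ids <- if ("gene_id" %in% names(mc)) mc$gene_id
    else if ("Name" %in% names(mc)) mc$Name
    else if ("ID" %in% names(mc)) mc$ID
    else if ("Parent" %in% names(mc)) as.character(unlist(mc$Parent))
    else rep(NA_character_, length(gr))
    as.character(ids)
  }
  ty <- tolower(as.character(gff$type))
  pick <- function(types) {
    gr <- gff[ty %in% types]
    names(gr) <- NULL
    gr
  }
  genes <- pick("gene")
  if (length(genes) == 0L) genes <- pick(c("mrna", "transcript"))
  gene_ids <- id_col(genes)
  # exon/UTR records name their transcript; map to the owning gene where possible
  feature_gene <- function(gr) {
    ids <- id_col(gr)
    hit <- GenomicRanges::findOverlaps(gr, genes, select = "first")
    ifelse(!is.na(hit), gene_ids[hit], ids)
  }

  layers <- list(
    `5'UTR` = pick("five_prime_utr"),
    `3'UTR` = pick("three_prime_utr"),
    exon = pick("exon"),
    intron = genes,
    upstream2kb = GenomicRanges::flank(genes, flank, start = TRUE),
    downstream2kb = GenomicRanges::flank(genes, flank, start = FALSE))
  layer_gene <- list(
    feature_gene(layers[["5'UTR"]]), feature_gene(layers[["3'UTR"]]),
    feature_gene(layers$exon), gene_ids, gene_ids, gene_ids)

  model_chroms <- unique(as.character(GenomicRanges::seqnames(gff)))
  missing_chrom <- setdiff(unique(sites$chrom), model_chroms)
  if (length(missing_chrom))
    warning("chromosomes absent from gene model, sites set to IGR: ",
            paste(missing_chrom, collapse = ", "))

  n <- nrow(sites)
  known <- which(sites$chrom %in% model_chroms)
  q <- GenomicRanges::GRanges(sites$chrom[known],
                              IRanges::IRanges(sites$start[known] + 1L,
                                               sites$end[known]))
  category <- rep("IGR", n)
  gene <- rep(NA_character_, n)
  for (li in seq_along(layers)) {
    gr <- layers[[li]]
    if (length(gr) == 0L) next
    hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
    if (length(hits) == 0L) next
    hq <- known[S4Vectors::queryHits(hits)]
    hg <- layer_gene[[li]][S4Vectors::subjectHits(hits)]
    # alphabetically first gene per site at this precedence level
    first <- tapply(hg, hq, function(g) sort(g)[1L])
    idx <- as.integer(names(first))
    open <- idx[category[idx] == "IGR" & is.na(gene[idx])]
    sel <- match(open, idx)
    category[open] <- names(layers)[li]
    gene[open] <- unname(first[sel])
  }
  data.frame(site_id = sites$site_id, category = category, gene_id = gene,
             in_user_list = !is.na(gene) & gene %in% (gene_list %||% character()),
             stringsAsFactors = FALSE)
}
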