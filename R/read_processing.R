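#' Read a FASTQ file into sequences and Phred qualities
#'
#' @param path FASTQ path (gzip-aware).
#' @return List with `id` (character), `seq` (character), `qual` (list of
#'   integer Phred vectors).
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  q <- methods::as(Biostrings::quality(x), "IntegerList")
  list(id = sub("\\s.*$", "", names(x)),
       seq = as.character(x),
       qual = as.list(q))
}

write_fastq <- function(id, seq, qual, path) {
  if (length(seq) == 0L) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    close(con)
    return(invisible(path))
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seq),
    Biostrings::PhredQuality(methods::as(qual, "IntegerList")))
  names(x) <- id
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Merge paired-end mates into single amplicon reads
#'
#' For each pair, the reverse mate is reverse-complemented and the best
#' suffix/prefix overlap of at least `min_overlap` bases with mismatch
#' fraction at most `max_mismatch_frac` is chosen (fewest mismatches; ties
#' broken toward the longest overlap). Disagreeing overlap bases are
#' resolved toward the higher-quality base call. Pairs with no admissible
#' overlap are dropped and counted.
#'
#' @param r1,r2 FASTQ paths or `read_fastq()` lists, mates in sync.
#' @param min_overlap Minimum overlap length (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.25).
#' @return List with `id`, `seq`, `mean_quality` for merged reads and
#'   `n_unmerged` for dropped pairs.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.25) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  n <- length(r1$seq)
  if (length(r2$seq) != n)
    stop("desynchronized mates: ", n, " forward vs ", length(r2$seq),
         " reverse reads")
  strip <- function(id) sub("(/[12]| [12]:.*)$", "", id)
  if (!identical(strip(r1$id), strip(r2$id)))
    stop("desynchronized mates: read ids do not pair up")

  seqs <- character(n)
  mq <- numeric(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    m <- .merge_pair(r1$seq[i], r1$qual[[i]], r2$seq[i], r2$qual[[i]],
                     as.integer(min_overlap), max_mismatch_frac)
    if (!is.null(m$merged)) {
      seqs[i] <- m$merged
      mq[i] <- mean(m$qual)
      ok[i] <- TRUE
    }
  }
  list(id = strip(r1$id)[ok], seq = seqs[ok], mean_quality = mq[ok],
       n_unmerged = sum(!ok))
}

#' Assign merged reads to library constructs by barcode
#'
#' Locates the constant scaffold tail anchor in each read (testing the
#' reverse complement when the forward orientation fails), reads the 10-nt
#' barcode immediately downstream, and exact-matches it against the
#' manifest. Reads with no anchor or an unknown barcode are `unassigned`.
#'
#' @param seqs Character vector of merged read sequences.
#' @param manifest Constructs data.frame (see [read_manifest()]).
#' @param scaffold The 82-nt scaffold whose 3' tail is the anchor.
#' @param anchor_len Length of the scaffold tail used as anchor (default 20).
#' @return data.frame with `construct_id` (NA when unassigned), `barcode`,
#'   `oriented_seq` (read in construct orientation); attribute
#'   `n_unassigned`.
#' @export
demultiplex <- function(seqs, manifest, scaffold = surro_scaffold(),
                        anchor_len = 20L) {
  anchor <- substr(scaffold, nchar(scaffold) - anchor_len + 1L, nchar(scaffold))
  pos <- regexpr(anchor, seqs, fixed = TRUE)
  flip <- pos < 0L
  if (any(flip)) {
    rc <- revcomp(seqs[flip])
    prc <- regexpr(anchor, rc, fixed = TRUE)
    seqs[flip] <- ifelse(prc > 0L, rc, seqs[flip])
    pos[flip] <- prc
  }
  bc_at <- as.integer(pos) + anchor_len
  barcode <- ifelse(pos > 0L, substr(seqs, bc_at, bc_at + 9L), NA_character_)
  idx <- match(barcode, manifest$barcode)
  out <- data.frame(construct_id = manifest$construct_id[idx],
                    barcode = barcode, oriented_seq = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- sum(is.na(out$construct_id))
  out
}

#' Structural filter and surrogate-region extraction
#'
#' A read passes the first filtering step iff the invariant construct
#' backbone -- `g` + spacer (20) + scaffold (82) + barcode (10) at the
#' start of the cassette and the `GTTT` linker anchor at its end -- matches
#' the reference exactly. On pass, the read segment between the barcode and
#' the linker (the observed surrogate region, possibly length-shifted by
#' indels) is returned.
#'
#' @param seqs Reads (construct orientation) assigned to `construct`.
#' @param construct One-row manifest entry (`spacer`, `barcode`).
#' @param scaffold 82-nt scaffold.
#' @return data.frame with `pass` (logical), `segment` (NA on fail),
#'   `reason` ("" or "structure").
#' @export
structural_filter <- function(seqs, construct, scaffold = surro_scaffold()) {
  prefix <- paste0(OLIGO_G, construct$spacer, toupper(scaffold),
                   construct$barcode)
  # the linker + downstream BsmBI site; CGTCTC cannot occur inside the
  # surrogate region (excluded at design time), making the anchor unique
  tail_anchor <- paste0(OLIGO_LINKER3, BSMBI_SITE)

  p1 <- regexpr(prefix, seqs, fixed = TRUE)
  seg_from <- as.integer(p1) + nchar(prefix)
  rest <- ifelse(p1 > 0L, substr(seqs, seg_from, nchar(seqs)), NA_character_)
  p2 <- ifelse(is.na(rest), -1L, regexpr(tail_anchor, rest, fixed = TRUE))
  pass <- p1 > 0L & p2 > 0L
  segment <- ifelse(pass, substr(rest, 1L, as.integer(p2) - 1L), NA_character_)
  data.frame(pass = pass, segment = segment,
             reason = ifelse(pass, "", "structure"), stringsAsFactors = FALSE)
}

#' Call indels in an observed surrogate region
#'
#' Globally aligns the observed segment to the 27-nt reference with affine
#' gap scoring (defaults: match +2, mismatch -4, gap open -6, gap extend -1
#' per base; a length-k gap scores `open + k * ext`). Tied optima take the
#' leftmost gap placement. Gaps are reported in reference coordinates
#' N1..N27; an insertion at Nk follows reference base k (k = 0 before N1).
#' Substitutions are not indels.
#'
#' @param observed Observed segment (non-empty).
#' @param reference Reference surrogate region (non-empty, normally 27 nt).
#' @param match,mismatch,gap_open,gap_ext Alignment scores.
#' @param max_len_dev Maximum tolerated deviation of the observed length
#'   from the reference length (default 24); beyond it the read fails with
#'   reason "length".
#' @return data.frame of indel events (`op` in ins/del, `start`, `end`,
#'   `length`, `seq`) -- zero rows when the alignment has no gaps -- or
#'   `NULL` with attribute-free failure signalled by class "length_fail".
#' @export
call_indel <- function(observed, reference, match = 2, mismatch = -4,
                       gap_open = -6, gap_ext = -1, max_len_dev = 24L) {
  if (!nzchar(observed) || !nzchar(reference))
    stop("observed and reference must be non-empty")
  if (abs(nchar(observed) - nchar(reference)) > max_len_dev) {
    out <- structure(list(), class = "length_fail")
    return(out)
  }
  r <- .nw_indels(observed, reference, match, mismatch, gap_open, gap_ext)
  data.frame(op = as.character(r$op), start = r$start, end = r$end,
             length = r$length, seq = as.character(r$seq),
             stringsAsFactors = FALSE)
}

#' Positional 1-bp indel filter
#'
#' Third filtering step: a read whose only indel content is 1-bp events
#' lying entirely within N1-N14 or N22-N27 of the 27-nt surrogate region is
#' background (PCR/sequencing) rather than nuclease editing. By default
#' such reads are reclassified as non-indel but kept in the clean total;
#' `full_removal = TRUE` discards them. Indels of length >= 2 and any indel
#' overlapping N15-N21 (deletion interval overlap; insertion anchor within
#' 15..21) are retained as edits. At the N14/N15 and N21/N22 boundaries the
#' position of the deleted base (or insertion anchor) of the leftmost-
#' aligned representation decides.
#'
#' @param calls Indel call data.frame from [call_indel()].
#' @param window Retained edit window (default `c(15L, 21L)`).
#' @return One of `"indel"`, `"non_indel"`, `"reclassified"` (non-indel via
#'   the positional rule).
#' @export
classify_indel_call <- function(calls, window = c(15L, 21L)) {
  if (inherits(calls, "length_fail")) stop("length-failed read has no class")
  if (nrow(calls) == 0L) return("non_indel")
  is_edit <- vapply(seq_len(nrow(calls)), function(i) {
    len <- calls$length[i]
    if (len >= 2L) return(TRUE)
    if (calls$op[i] == "del")
      calls$start[i] <= window[2L] && calls$end[i] >= window[1L]
    else
      calls$start[i] >= window[1L] && calls$start[i] <= window[2L]
  }, logical(1))
  if (any(is_edit)) "indel" else "reclassified"
}

#' Subtract wild-type pseudo-editing alleles
#'
#' Second filtering step: every non-reference allele sequence observed in
#' the MOCK (wild-type) sample of a construct is a synthesis/PCR artefact;
#' its reads are removed from the SpCas9 allele table (subtracted from both
#' indel and total counts downstream).
#'
#' @param cas9_alleles Named integer vector (allele sequence -> read count)
#'   for the SpCas9 sample of one construct.
#' @param mock_alleles Same for the MOCK sample.
#' @param reference The construct's reference surrogate region.
#' @return List with `alleles` (corrected SpCas9 table) and `n_removed`
#'   (reads removed as "wt_pseudoedit").
#' @export
subtract_wt_pseudoedits <- function(cas9_alleles, mock_alleles, reference) {
  pseudo <- setdiff(names(mock_alleles), reference)
  drop <- names(cas9_alleles) %in% pseudo
  list(alleles = cas9_alleles[!drop], n_removed = sum(cas9_alleles[drop]))
}
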