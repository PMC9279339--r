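# composition of the read-processing steps into per-construct count tables

process_sample <- function(fq1, fq2 = NULL, manifest,
                           min_overlap = 10L, max_mismatch_frac = 0.25,
                           min_mean_quality = NULL,
                           scaffold = surro_scaffold(),
                           align = list(match = 2, mismatch = -4,
                                        gap_open = -6, gap_ext = -1),
                           max_len_dev = 24L, window = c(15L, 21L)) {
  n_unmerged <- 0L
  if (is.null(fq2)) {
    rd <- if (is.character(fq1)) read_fastq(fq1) else fq1
    seqs <- rd$seq
    mq <- vapply(rd$qual, mean, numeric(1))
  } else {
    m <- merge_pairs(fq1, fq2, min_overlap, max_mismatch_frac)
    seqs <- m$seq
    mq <- m$mean_quality
    n_unmerged <- m$n_unmerged
  }
  n_lowq <- 0L
  if (!is.null(min_mean_quality)) {
    keep <- mq >= min_mean_quality
    n_lowq <- sum(!keep)
    seqs <- seqs[keep]
  }
  dm <- demultiplex(seqs, manifest, scaffold)
  n_unassigned <- attr(dm, "n_unassigned")

  per <- stats::setNames(vector("list", nrow(manifest)), manifest$construct_id)
  groups <- split(dm$oriented_seq, dm$construct_id)
  for (cid in names(groups)) {
    cons <- manifest[manifest$construct_id == cid, ]
    sf <- structural_filter(groups[[cid]], cons, scaffold)
    segs <- sf$segment[sf$pass]
    tab <- table(segs)
    alleles <- stats::setNames(as.integer(tab), names(tab))
    cls <- character(length(alleles))
    lenfail <- logical(length(alleles))
    for (k in seq_along(alleles)) {
      a <- names(alleles)[k]
      if (a == cons$surrogate27) { cls[k] <- "non_indel"; next }
      calls <- call_indel(a, cons$surrogate27, align$match, align$mismatch,
                          align$gap_open, align$gap_ext, max_len_dev)
      if (inherits(calls, "length_fail")) { lenfail[k] <- TRUE; next }
      cls[k] <- classify_indel_call(calls, window)
    }
    per[[cid]] <- list(alleles = alleles[!lenfail],
                       class = stats::setNames(cls[!lenfail],
                                               names(alleles)[!lenfail]),
                       n_structure = sum(!sf$pass),
                       n_length = sum(alleles[lenfail]))
  }
  empty <- list(alleles = stats::setNames(integer(), character()),
                class = stats::setNames(character(), character()),
                n_structure = 0L, n_length = 0L)
  per[vapply(per, is.null, logical(1))] <- list(empty)
  list(per_construct = per, n_unmerged = n_unmerged,
       n_unassigned = n_unassigned, n_low_quality = n_lowq)
}

count_from_alleles <- function(alleles, class, full_removal = FALSE) {
  indel <- sum(alleles[class == "indel"])
  recl <- sum(alleles[class == "reclassified"])
  total <- sum(alleles)
  if (full_removal) total <- total - recl
  list(total_clean = total, indel = indel, n_reclassified = recl)
}

#' Tabulate per-construct, per-sample indel counts
#'
#' Runs the complete read-processing chain for the MOCK and SpCas9 samples
#' of one library: pair merging (skipped for pre-merged input), barcode
#' demultiplexing, the structural filter, global-alignment indel calling
#' with the positional 1-bp filter, and wild-type pseudo-edit subtraction
#' of MOCK artefact alleles from the SpCas9 table. Counts are deterministic
#' and invariant to read input order.
#'
#' @param manifest Constructs data.frame ([read_manifest()]).
#' @param mock,cas9 Each a list `list(r1 =, r2 =)` of FASTQ paths (`r2 =
#'   NULL` for pre-merged reads).
#' @param full_removal Discard positionally-reclassified reads instead of
#'   keeping them as non-indel (default `FALSE`).
#' @param wt_subtract Apply MOCK pseudo-edit subtraction (default `TRUE`).
#' @param ... Further arguments passed to the processing steps
#'   (`min_overlap`, `max_mismatch_frac`, `min_mean_quality`, `scaffold`,
#'   `align`, `max_len_dev`, `window`).
#' @return List: `counts` (data.frame with one row per construct x sample:
#'   `construct_id`, `sample`, `total_clean`, `indel`, `n_structure`,
#'   `n_length`, `n_wt_pseudoedit`, `n_reclassified`), `alleles` (per
#'   construct, per sample named count vectors), `log` (unmerged/unassigned
#'   tallies per sample).
#' @export
tabulate_counts <- function(manifest, mock, cas9, full_removal = FALSE,
                            wt_subtract = TRUE, ...) {
  ps_mock <- process_sample(mock$r1, mock$r2, manifest, ...)
  ps_cas9 <- process_sample(cas9$r1, cas9$r2, manifest, ...)

  assigned <- sum(vapply(ps_mock$per_construct,
                         function(x) sum(x$alleles) + x$n_structure + x$n_length,
                         numeric(1))) +
    sum(vapply(ps_cas9$per_construct,
               function(x) sum(x$alleles) + x$n_structure + x$n_length,
               numeric(1)))
  if (assigned == 0L)
    warning("no reads matched any manifest barcode; count table is empty")

  rows <- vector("list", 2L * nrow(manifest))
  alleles_out <- list()
  for (i in seq_len(nrow(manifest))) {
    cid <- manifest$construct_id[i]
    refseq <- manifest$surrogate27[i]
    mk <- ps_mock$per_construct[[cid]]
    cs <- ps_cas9$per_construct[[cid]]

    n_wt <- 0L
    if (wt_subtract) {
      sub <- subtract_wt_pseudoedits(cs$alleles, mk$alleles, refseq)
      n_wt <- sub$n_removed
      cs$class <- cs$class[names(sub$alleles)]
      cs$alleles <- sub$alleles
    }
    cm <- count_from_alleles(mk$alleles, mk$class, full_removal)
    cc <- count_from_alleles(cs$alleles, cs$class, full_removal)
    rows[[2L * i - 1L]] <- data.frame(
      construct_id = cid, sample = "MOCK", total_clean = cm$total_clean,
      indel = cm$indel, n_structure = mk$n_structure, n_length = mk$n_length,
      n_wt_pseudoedit = 0L, n_reclassified = cm$n_reclassified,
      stringsAsFactors = FALSE)
    rows[[2L * i]] <- data.frame(
      construct_id = cid, sample = "SpCas9", total_clean = cc$total_clean,
      indel = cc$indel, n_structure = cs$n_structure, n_length = cs$n_length,
      n_wt_pseudoedit = n_wt, n_reclassified = cc$n_reclassified,
      stringsAsFactors = FALSE)
    alleles_out[[cid]] <- list(MOCK = mk$alleles, SpCas9 = cs$alleles)
  }
  list(counts = do.call(rbind, rows), alleles = alleles_out,
       log = list(mock = ps_mock[c("n_unmerged", "n_unassigned", "n_low_quality")],
                  cas9 = ps_cas9[c("n_unmerged", "n_unassigned", "n_low_quality")]))
}
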