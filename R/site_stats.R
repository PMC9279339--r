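#' Indel frequency in percent
#'
#' `IF% = indel reads / total reads * 100`. A zero total yields `NA`
#' (the site cannot be quantified and is filtered downstream).
#'
#' @param indel,total Non-negative read counts (vectorized).
#' @return Numeric percent in `[0, 100]`, `NA` where `total == 0`.
#' @export
indel_frequency <- function(indel, total) {
  if (any(total < 0) || any(indel < 0)) stop("counts must be non-negative")
  if (any(indel > total)) stop("indel count exceeds total count")
  ifelse(total == 0, NA_real_, indel / total * 100)
}

#' Two-sided Fisher exact p-value for a 2x2 indel table
#'
#' Tests association between sample (SpCas9 vs MOCK) and read class (indel
#' vs no indel). With margins fixed, the two-sided p-value sums the
#' hypergeometric probabilities of every table whose probability does not
#' exceed the observed table's (ties compared within a relative tolerance
#' of 1e-12). The all-zero table gives p = 1.
#'
#' @param indel_cas9,nonindel_cas9,indel_mock,nonindel_mock Non-negative
#'   integer counts.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
fisher_exact_p <- function(indel_cas9, nonindel_cas9, indel_mock, nonindel_mock) {
  cnt <- c(indel_cas9, nonindel_cas9, indel_mock, nonindel_mock)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  m <- indel_cas9 + indel_mock          # indel reads
  n <- nonindel_cas9 + nonindel_mock    # non-indel reads
  k <- indel_cas9 + nonindel_cas9       # SpCas9 margin
  if (m + n == 0) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(indel_cas9, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `adj_(i) = min_{j >= i} min(1, m/j * p_(j))` over
#' the ranked p-values; invariant under permutation of the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

pivot_counts <- function(counts) {
  mk <- counts[counts$sample == "MOCK", ]
  cs <- counts[counts$sample == "SpCas9", ]
  ids <- unique(counts$construct_id)
  data.frame(construct_id = ids,
             total_mock = mk$total_clean[match(ids, mk$construct_id)],
             indel_mock = mk$indel[match(ids, mk$construct_id)],
             total_cas9 = cs$total_clean[match(ids, cs$construct_id)],
             indel_cas9 = cs$indel[match(ids, cs$construct_id)],
             stringsAsFactors = FALSE)
}

#' Call off-target sites from paired counts
#'
#' Applies the full statistical recipe to paired MOCK/SpCas9 counts:
#' quality filters (clean total >= `min_total` in each sample; MOCK indel
#' frequency <= `max_wt_if` as a bias filter and <= `max_mock_if` as a
#' synthesis-quality filter), a paired two-sided Fisher exact test per
#' site, BH adjustment jointly across all non-filtered sites, and the
#' significance rule `adj_p < alpha` and `FC >= min_fc` with
#' `FC = IF(SpCas9) / IF(MOCK)`. Significant sites split into LIOT
#' (`IF(SpCas9) < hiot_if`) and HIOT (`>= hiot_if`); sites with fewer than
#' `min_indel` SpCas9 indel reads are demoted to NSOT (still tested and
#' part of the BH family). When the MOCK indel count is zero, FC uses a
#' 0.5-read continuity correction on the MOCK numerator
#' (`fc_mode = "raw"` reports infinite FC instead).
#'
#' @param counts Long count table from [tabulate_counts()] (columns
#'   `construct_id`, `sample`, `total_clean`, `indel`).
#' @param thresholds Named list as from [surro_thresholds()].
#' @param fc_mode `"continuity"` (default) or `"raw"`.
#' @param apply_wt_if,apply_mock_if Independent switches for the two MOCK
#'   indel-frequency filters (both default `TRUE`).
#' @return data.frame with one row per construct: counts, `if_mock`,
#'   `if_cas9`, `fisher_p`, `adj_p`, `fold_change`, `call` (NSOT / LIOT /
#'   HIOT / FILTERED), `filter_reasons`. Thresholds are echoed in the
#'   `"thresholds"` attribute.
#' @export
call_sites <- function(counts, thresholds = surro_thresholds(),
                       fc_mode = c("continuity", "raw"),
                       apply_wt_if = TRUE, apply_mock_if = TRUE) {
  fc_mode <- match.arg(fc_mode)
  th <- utils::modifyList(surro_thresholds(), thresholds)
  w <- pivot_counts(counts)
  n <- nrow(w)

  unpaired <- is.na(w$total_mock) | is.na(w$total_cas9)
  w$if_mock <- ifelse(unpaired, NA_real_,
                      indel_frequency(ifelse(unpaired, 0, w$indel_mock),
                                      ifelse(unpaired, 0, w$total_mock)))
  w$if_cas9 <- ifelse(unpaired, NA_real_,
                      indel_frequency(ifelse(unpaired, 0, w$indel_cas9),
                                      ifelse(unpaired, 0, w$total_cas9)))

  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character()
    if (unpaired[i]) r <- "unpaired"
    else {
      if (w$total_mock[i] < th$min_total || w$total_cas9[i] < th$min_total)
        r <- c(r, "read_quality")
      if (!is.na(w$if_mock[i])) {
        if (apply_wt_if && w$if_mock[i] > th$max_wt_if) r <- c(r, "wt_if")
        if (apply_mock_if && w$if_mock[i] > th$max_mock_if) r <- c(r, "synthesis")
      } else r <- c(r, "read_quality")
    }
    reasons[[i]] <- r
  }
  filtered <- lengths(reasons) > 0L

  w$fisher_p <- NA_real_
  tested <- which(!filtered)
  for (i in tested)
    w$fisher_p[i] <- fisher_exact_p(w$indel_cas9[i], w$total_cas9[i] - w$indel_cas9[i],
                                    w$indel_mock[i], w$total_mock[i] - w$indel_mock[i])
  w$adj_p <- NA_real_
  if (length(tested)) w$adj_p[tested] <- bh_adjust(w$fisher_p[tested])

  w$fold_change <- NA_real_
  for (i in tested) {
    ifm <- w$if_mock[i]
    if (w$indel_mock[i] == 0) {
      ifm <- if (fc_mode == "continuity") 0.5 / w$total_mock[i] * 100 else 0
    }
    w$fold_change[i] <- if (ifm == 0) {
      if (w$if_cas9[i] == 0) NaN else Inf
    } else w$if_cas9[i] / ifm
  }

  w$call <- "FILTERED"
  low_support <- !filtered & w$indel_cas9 < th$min_indel
  sig <- !filtered & !low_support &
    !is.na(w$adj_p) & w$adj_p < th$alpha &
    !is.nan(w$fold_change) & w$fold_change >= th$min_fc
  w$call[!filtered] <- "NSOT"
  w$call[sig & w$if_cas9 < th$hiot_if] <- "LIOT"
  w$call[sig & w$if_cas9 >= th$hiot_if] <- "HIOT"
  for (i in which(low_support))
    reasons[[i]] <- c(reasons[[i]], "low_indel_support")
  w$filter_reasons <- vapply(reasons, paste, character(1), collapse = ";")

  attr(w, "thresholds") <- th
  w
}

#' Flag enriched or depleted constructs
#'
#' Normalizes clean totals to reads-per-million within each sample and
#' flags constructs whose normalized abundance ratio between samples is at
#' least `min_ratio` in either direction: depleted constructs may report
#' off-targets affecting cell growth and are excluded from downstream
#' sequence-context analyses.
#'
#' @param counts Long count table (as for [call_sites()]).
#' @param min_ratio Flagging ratio (default 2).
#' @return data.frame `construct_id`, `rpm_mock`, `rpm_cas9`, `ratio`
#'   (SpCas9 / MOCK), `enrichment_flag` in none/enriched/depleted.
#' @export
enrichment_depletion <- function(counts, min_ratio = 2) {
  w <- pivot_counts(counts)
  lib_mock <- sum(w$total_mock, na.rm = TRUE)
  lib_cas9 <- sum(w$total_cas9, na.rm = TRUE)
  if (lib_mock == 0 || lib_cas9 == 0) stop("zero library size in one sample")
  w$rpm_mock <- w$total_mock / lib_mock * 1e6
  w$rpm_cas9 <- w$total_cas9 / lib_cas9 * 1e6
  w$ratio <- ifelse(w$rpm_mock == 0,
                    ifelse(w$rpm_cas9 == 0, NaN, Inf),
                    w$rpm_cas9 / w$rpm_mock)
  flag <- rep("none", nrow(w))
  flag[!is.na(w$ratio) & !is.nan(w$ratio) & w$ratio >= min_ratio] <- "enriched"
  flag[!is.na(w$ratio) & !is.nan(w$ratio) & w$ratio <= 1 / min_ratio] <- "depleted"
  w$enrichment_flag <- flag
  w[, c("construct_id", "rpm_mock", "rpm_cas9", "ratio", "enrichment_flag")]
}

#' Write a calls table with threshold metadata
#'
#' @param calls Result of [call_sites()].
#' @param path Output TSV path; thresholds are echoed as `#` header lines.
#' @export
write_calls <- function(calls, path) {
  th <- attr(calls, "thresholds")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(th))
    writeLines(sprintf("# %s = %s", names(th), unlist(th)), con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
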