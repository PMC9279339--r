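MISMATCH_TYPES <- c("AC", "AG", "AT", "CA", "CG", "CT",
                    "GA", "GC", "GT", "TA", "TC", "TG")

#' Tabulate mismatch positions and types for a site group
#'
#' Counts, over the selected group of off-target sites, how often a
#' spacer/protospacer mismatch falls on each spacer position N1 (PAM-distal)
#' .. N20 (PAM-proximal) and how often each of the 12 ordered mismatch
#' types occurs. A type is named by (spacer base, protospacer base on the
#' non-target strand): e.g. `GA` is a spacer G opposite a protospacer A,
#' which leaves an rG:dT wobble pair with the target strand.
#'
#' @param manifest Constructs data.frame carrying `mismatches` annotations.
#' @param calls Optional calls data.frame from [call_sites()]; required for
#'   groups other than `"ALL"`.
#' @param group One of `"ALL"`, `"NSOT"`, `"Sig"`, `"LIOT"`, `"HIOT"`.
#' @param mm_range Optional length-2 vector restricting sites by mismatch
#'   count, e.g. `c(3, 4)`.
#' @return Object of class `"mismatch_profile"`: list with `group`,
#'   `position_counts` (N1..N20), `type_counts`, `n_sites`,
#'   `n_mismatches_total`, `position_frac`, `type_frac` (NA when the group
#'   holds no mismatches).
#' @export
profile_mismatches <- function(manifest, calls = NULL, group = "ALL",
                               mm_range = NULL) {
  group <- match.arg(group, c("ALL", "NSOT", "Sig", "LIOT", "HIOT"))
  sites <- manifest
  if (group != "ALL") {
    if (is.null(calls)) stop("calls are required for group ", group)
    keep <- switch(group,
                   NSOT = calls$call == "NSOT",
                   Sig = calls$call %in% c("LIOT", "HIOT"),
                   LIOT = calls$call == "LIOT",
                   HIOT = calls$call == "HIOT")
    ids <- calls$construct_id[keep]
    sites <- sites[sites$construct_id %in% ids, , drop = FALSE]
  }
  if (!is.null(mm_range))
    sites <- sites[sites$n_mismatches >= mm_range[1L] &
                     sites$n_mismatches <= mm_range[2L], , drop = FALSE]

  pos <- stats::setNames(integer(20L), paste0("N", 1:20))
  typ <- stats::setNames(integer(12L), MISMATCH_TYPES)
  for (mm in sites$mismatches) {
    d <- parse_mismatches(mm)
    if (nrow(d) == 0L) next
    for (k in seq_len(nrow(d))) {
      pos[d$position[k]] <- pos[d$position[k]] + 1L
      t <- paste0(d$grna_base[k], d$proto_base[k])
      typ[t] <- typ[t] + 1L
    }
  }
  tot <- sum(pos)
  stopifnot(tot == sum(typ))
  structure(list(group = group, position_counts = pos, type_counts = typ,
                 n_sites = nrow(sites), n_mismatches_total = tot,
                 position_frac = if (tot > 0) pos / tot else pos * NA_real_,
                 type_frac = if (tot > 0) typ / tot else typ * NA_real_),
            class = "mismatch_profile")
}

#' @export
print.mismatch_profile <- function(x, ...) {
  cat("Mismatch profile [", x$group, "]: ", x$n_sites, " sites, ",
      x$n_mismatches_total, " mismatches\n", sep = "")
  cat("positions:\n")
  print(x$position_counts)
  cat("types:\n")
  print(x$type_counts)
  invisible(x)
}

#' Hypergeometric enrichment of mismatch positions and types
#'
#' For each spacer position and mismatch type, tests whether mismatches of
#' the significant group are over- or under-represented relative to a
#' background profile. Sampling model: draw `n_mismatches_total(sig)`
#' mismatches from the background population; successes are the background
#' mismatches in the tested category. Over-representation p is the upper
#' hypergeometric tail at the observed count, under-representation the
#' lower tail.
#'
#' @param sig [profile_mismatches()] result for the foreground group.
#' @param background Profile for the background group (`ALL` or `NSOT`).
#' @return data.frame: `category` (position/type), `name`, `sig_count`,
#'   `bg_count`, `over_p`, `under_p`.
#' @export
hypergeom_enrichment <- function(sig, background) {
  stopifnot(inherits(sig, "mismatch_profile"),
            inherits(background, "mismatch_profile"))
  if (background$group == "ALL" &&
      (any(sig$position_counts > background$position_counts) ||
       any(sig$type_counts > background$type_counts)))
    stop("significant profile is not a subset of the ALL background")

  one <- function(category, names_, q, m_all) {
    N <- background$n_mismatches_total
    k <- sig$n_mismatches_total
    over <- stats::phyper(q - 1L, m_all, N - m_all, k, lower.tail = FALSE)
    under <- stats::phyper(q, m_all, N - m_all, k, lower.tail = TRUE)
    data.frame(category = category, name = names_, sig_count = as.integer(q),
               bg_count = as.integer(m_all), over_p = over, under_p = under,
               stringsAsFactors = FALSE)
  }
  rbind(one("position", names(sig$position_counts), sig$position_counts,
            background$position_counts),
        one("type", names(sig$type_counts), sig$type_counts,
            background$type_counts))
}

#' Spacer GC content vs on-target efficiency
#'
#' Computes the GC percentage of each spacer, splits guides at an on-target
#' indel-frequency threshold (default 80%), and compares the two groups'
#' GC content with a two-sided Wilcoxon rank-sum test.
#'
#' @param guides data.frame with `guide_id`, `spacer`, `on_target_if`
#'   (percent).
#' @param threshold Efficiency split, percent (default 80).
#' @return List: `guides` (with `gc` and `group` columns), `mean_gc` per
#'   group, `p_value` (NA when a group is empty or GC is constant).
#' @export
gc_content_compare <- function(guides, threshold = 80) {
  gc <- vapply(guides$spacer, function(s) {
    b <- strsplit(toupper(s), "")[[1L]]
    mean(b %in% c("G", "C")) * 100
  }, numeric(1), USE.NAMES = FALSE)
  group <- ifelse(guides$on_target_if >= threshold, "high", "low")
  out <- cbind(guides, gc = gc, group = group, stringsAsFactors = FALSE)
  means <- tapply(gc, group, mean)
  p <- NA_real_
  if (all(c("high", "low") %in% group) &&
      stats::var(gc) > 0) {
    wt <- try(stats::wilcox.test(gc ~ group, data = out, exact = FALSE),
              silent = TRUE)
    if (!inherits(wt, "try-error")) p <- wt$p.value
  }
  list(guides = out,
       mean_gc = c(high = unname(means["high"]), low = unname(means["low"])),
       p_value = p)
}
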