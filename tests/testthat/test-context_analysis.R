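fake_manifest <- function(mm_strings, ids = NULL, n_mm = NULL) {
  n <- length(mm_strings)
  data.frame(construct_id = ids %||% sprintf("c%03d", seq_len(n)),
             mismatches = mm_strings,
             n_mismatches = n_mm %||% vapply(mm_strings, function(x)
               if (x == "") 0L else length(strsplit(x, ";")[[1]]),
               integer(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mismatch profiles count positions and types exactly", {
  m <- fake_manifest(c("1:G>A;17:C>T", "2:A>C", ""))
  p <- profile_mismatches(m)
  expect_equal(p$n_sites, 3L)
  expect_equal(p$n_mismatches_total, 3L)
  expect_equal(unname(p$position_counts[c("N1", "N2", "N17")]), c(1L, 1L, 1L))
  expect_equal(sum(p$position_counts), 3L)
  expect_equal(unname(p$type_counts[c("GA", "CT", "AC")]), c(1L, 1L, 1L))
  expect_equal(sum(p$type_counts), sum(p$position_counts))
  # empty group: zero counts, NA fractions
  p0 <- profile_mismatches(m[m$n_mismatches > 5, ])
  expect_equal(p0$n_mismatches_total, 0L)
  expect_true(all(is.na(p0$position_frac)))
})

test_that("profiles are order-invariant and group selection follows calls", {
  m <- fake_manifest(c("3:A>G", "7:T>C", "12:G>T", "19:C>A"))
  calls <- data.frame(construct_id = m$construct_id,
                      call = c("HIOT", "LIOT", "NSOT", "NSOT"),
                      stringsAsFactors = FALSE)
  sig <- profile_mismatches(m, calls, "Sig")
  expect_equal(sig$n_sites, 2L)
  expect_equal(unname(sig$position_counts[c("N3", "N7")]), c(1L, 1L))
  shuf <- profile_mismatches(m[c(3, 1, 4, 2), ], calls, "Sig")
  expect_identical(sig$position_counts, shuf$position_counts)
  expect_error(profile_mismatches(m, NULL, "Sig"), "calls")
})

test_that("uniformly planted mismatch positions come out uniform", {
  set.seed(12)
  pos <- sample(1:20, 4000, replace = TRUE)
  base <- sample(c("A", "C", "G", "T"), 4000, TRUE)
  other <- vapply(base, function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
  mm <- sprintf("%d:%s>%s", pos, base, other)
  p <- profile_mismatches(fake_manifest(mm))
  expect_equal(unname(p$position_counts), unname(table(factor(pos, 1:20))),
               ignore_attr = TRUE)
  # multinomial sampling error around 1/20
  expect_true(all(abs(p$position_frac - 0.05) < 4 * sqrt(0.05 * 0.95 / 4000)))
})

test_that("hypergeometric tails equal the summation oracle to 1e-12", {
  set.seed(6)
  for (i in 1:40) {
    N <- sample(20:200, 1)       # background mismatches
    m <- sample(0:N, 1)          # background in category
    k <- sample(1:N, 1)          # significant draw
    q <- max(0, k - (N - m)):min(k, m)
    q <- sample(q, 1)
    sigp <- structure(list(group = "Sig",
                           position_counts = c(N1 = q, N2 = k - q),
                           type_counts = c(AC = q, AG = k - q),
                           n_sites = k, n_mismatches_total = k),
                      class = "mismatch_profile")
    bgp <- structure(list(group = "NSOT",
                          position_counts = c(N1 = m, N2 = N - m),
                          type_counts = c(AC = m, AG = N - m),
                          n_sites = N, n_mismatches_total = N),
                     class = "mismatch_profile")
    enr <- hypergeom_enrichment(sigp, bgp)
    want <- hyper_tails_oracle(q, m, N - m, k)
    row <- enr[enr$category == "position" & enr$name == "N1", ]
    expect_lt(abs(row$over_p - want["over"]), 1e-12)
    expect_lt(abs(row$under_p - want["under"]), 1e-12)
    # tail identity: over + under = 1 + P(X == q)
    pq <- exp(lchoose(m, q) + lchoose(N - m, k - q) - lchoose(N, k))
    expect_lt(abs(row$over_p + row$under_p - 1 - pq), 1e-9)
  }
})

test_that("a profile matching the background composition is never significant", {
  bg_pos <- stats::setNames(rep(50L, 20), paste0("N", 1:20))
  bg_typ <- stats::setNames(c(rep(84L, 4), rep(83L, 8)), surroseq:::MISMATCH_TYPES)
  sig_pos <- stats::setNames(rep(5L, 20), paste0("N", 1:20))
  sig_typ <- stats::setNames(c(rep(9L, 4), rep(8L, 8)), surroseq:::MISMATCH_TYPES)
  mk <- function(g, pos, typ) structure(
    list(group = g, position_counts = pos, type_counts = typ,
         n_sites = NA, n_mismatches_total = sum(pos)),
    class = "mismatch_profile")
  enr <- hypergeom_enrichment(mk("Sig", sig_pos, sig_typ),
                              mk("ALL", bg_pos, bg_typ))
  expect_true(all(enr$over_p > 0.05))
  expect_true(all(enr$under_p > 0.05))
  # subset precondition enforced against the ALL background
  bad <- mk("Sig", bg_pos + 1L, bg_typ)
  expect_error(hypergeom_enrichment(bad, mk("ALL", bg_pos, bg_typ)),
               "subset")
})

test_that("a planted 3x GA-type excess among edited sites is detected", {
  set.seed(23)
  n_bg <- 600; n_sig <- 150
  draw_mm <- function(n, ga_weight) {
    types <- sample(surroseq:::MISMATCH_TYPES, n, TRUE,
                    prob = ifelse(surroseq:::MISMATCH_TYPES == "GA",
                                  ga_weight, 1))
    pos <- sample(1:20, n, TRUE)
    sprintf("%d:%s>%s", pos, substr(types, 1, 1), substr(types, 2, 2))
  }
  m_bg <- fake_manifest(draw_mm(n_bg, 1), ids = sprintf("b%04d", 1:n_bg))
  m_sig <- fake_manifest(draw_mm(n_sig, 3), ids = sprintf("s%04d", 1:n_sig))
  sig <- profile_mismatches(m_sig)
  bg <- profile_mismatches(m_bg)
  bg$group <- "NSOT"
  enr <- hypergeom_enrichment(sig, bg)
  ga <- enr[enr$category == "type" & enr$name == "GA", ]
  expect_lt(ga$over_p, 0.05)
})

test_that("GC comparison splits guides at the efficiency threshold", {
  expect_equal(gc_content_compare(
    data.frame(guide_id = "g", spacer = "ATATATATATATATATATAT",
               on_target_if = 90))$guides$gc, 0)
  all_g <- data.frame(guide_id = c("a", "b"),
                      spacer = strrep("G", 20),
                      on_target_if = c(90, 50))
  res <- gc_content_compare(all_g)
  expect_equal(unname(res$mean_gc), c(100, 100))
  expect_true(is.na(res$p_value))
})

test_that("a true GC difference between efficiency groups is detected", {
  set.seed(41)
  draw_spacer <- function(gc) paste(sample(c("G", "C", "A", "T"), 20, TRUE,
                                           prob = c(gc/2, gc/2, (1-gc)/2, (1-gc)/2)),
                                    collapse = "")
  g <- data.frame(
    guide_id = sprintf("g%02d", 1:50),
    spacer = c(vapply(1:25, function(i) draw_spacer(0.55), ""),
               vapply(1:25, function(i) draw_spacer(0.35), "")),
    on_target_if = c(runif(25, 85, 99), runif(25, 20, 75)),
    stringsAsFactors = FALSE)
  res <- gc_content_compare(g)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$mean_gc["high"], res$mean_gc["low"])
})
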