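# independent oracles and shared fixtures for the test suite

# internal helpers used by fixtures
random_dna <- surroseq:::random_dna
read_tsv <- surroseq:::read_tsv

# exhaustive window scan: every 20-mer on both strands followed by NGG,
# Hamming distance to the spacer <= max_mm; windows with non-ACGT context
# or truncated PAM+4nt context skipped. Character-matrix implementation,
# independent of the Biostrings-based scanner.
scan_oracle <- function(genome_seq, spacer, max_mm, chrom = "chr") {
  g <- strsplit(toupper(genome_seq), "")[[1L]]
  sp <- strsplit(spacer, "")[[1L]]
  L <- length(g)
  rc1 <- function(x) chartr("ACGT", "TGCA", x)
  hits <- list()
  for (strand in c("+", "-")) {
    for (start0 in 0:(L - 20L)) {
      if (strand == "+") {
        ctx_to <- start0 + 27L
        if (ctx_to > L) next
        ctx <- g[(start0 + 1L):ctx_to]
      } else {
        ctx_from <- start0 - 6L
        if (ctx_from < 1L) next
        ctx <- rev(rc1(g[ctx_from:(start0 + 20L)]))
      }
      if (any(!ctx %in% c("A", "C", "G", "T"))) next
      if (ctx[22L] != "G" || ctx[23L] != "G") next
      nmm <- sum(ctx[1:20] != sp)
      if (nmm > max_mm) next
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = start0, strand = strand,
        protospacer = paste(ctx[1:20], collapse = ""),
        pam = paste(ctx[21:23], collapse = ""),
        downstream4 = paste(ctx[24:27], collapse = ""),
        n_mismatches = nmm, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(), start = integer(), strand = character(),
               protospacer = character(), pam = character(),
               downstream4 = character(), n_mismatches = integer())
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# vectorized brute force over every window of larger genomes: tests all
# 20-mer starts on both strands directly against the spacer characters
brute_scan_oracle <- function(genome_seq, spacer, max_mm) {
  g <- strsplit(toupper(genome_seq), "")[[1L]]
  L <- length(g)
  sp <- strsplit(spacer, "")[[1L]]
  rc_sp <- strsplit(revcomp(spacer), "")[[1L]]
  acgt_ok <- g %in% c("A", "C", "G", "T")
  bad_cum <- cumsum(!acgt_ok)
  ctx_clean <- function(from, to) {   # all of g[from..to] are ACGT
    bad_cum[to] - c(0, bad_cum)[from] == 0
  }
  starts <- seq_len(L - 19L)          # 1-based window starts

  mm_plus <- integer(length(starts))
  mm_minus <- integer(length(starts))
  for (off in 0:19) {
    seg <- g[starts + off]
    mm_plus <- mm_plus + (seg != sp[off + 1L])
    mm_minus <- mm_minus + (seg != rc_sp[off + 1L])
  }
  res <- list()
  # + strand: PAM at w+20..w+22 (NGG), downstream w+23..w+26
  okp <- starts + 26L <= L
  wp <- starts[okp]
  keep <- mm_plus[okp] <= max_mm & g[wp + 21L] == "G" & g[wp + 22L] == "G" &
    ctx_clean(wp, wp + 26L)
  wp <- wp[keep]
  if (length(wp))
    res$p <- data.frame(start = wp - 1L, strand = "+",
                        n_mismatches = mm_plus[okp][keep])
  # - strand: genome CCN at w-3..w-1, context w-7..w+19
  okm <- starts - 7L >= 1L
  wm <- starts[okm]
  keep <- mm_minus[okm] <= max_mm & g[wm - 3L] == "C" & g[wm - 2L] == "C" &
    ctx_clean(wm - 7L, wm + 19L)
  wm <- wm[keep]
  if (length(wm))
    res$m <- data.frame(start = wm - 1L, strand = "-",
                        n_mismatches = mm_minus[okm][keep])
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(start = integer(), strand = character(),
                                      n_mismatches = integer())
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# plant n variant protospacers (with NGG PAM) of a spacer in a genome string
plant_variants <- function(genome, spacer, mm_counts, slot = 600L) {
  g <- strsplit(genome, "")[[1L]]
  for (i in seq_along(mm_counts)) {
    b <- strsplit(spacer, "")[[1L]]
    for (p in sample(20, mm_counts[i]))
      b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    site <- c(b, sample(c("A", "C", "G", "T"), 1), "G", "G",
              sample(c("A", "C", "G", "T"), 4, TRUE))
    at <- slot * i
    if (sample(c(TRUE, FALSE), 1)) {
      g[at:(at + 26)] <- site
    } else {
      g[at:(at + 26)] <- strsplit(revcomp(paste(site, collapse = "")), "")[[1L]]
    }
  }
  paste(g, collapse = "")
}

# two-sided Fisher p by direct summation over all tables with fixed
# margins, probabilities from lchoose (independent of dhyper)
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m + n == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- p[match(a, xs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# definitional BH step-up formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# hypergeometric upper/lower tails by direct summation
hyper_tails_oracle <- function(q, m, n, k) {
  xs <- max(0, k - n):min(k, m)
  p <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  c(over = sum(p[xs >= q]), under = sum(p[xs <= q]))
}

# all single-indel alignments of obs vs ref, leftmost-optimal placement;
# returns list(op, pos) or NULL when obs is not a single-indel mutant
single_indel_oracle <- function(obs, ref) {
  no <- nchar(obs); nr <- nchar(ref)
  oc <- strsplit(obs, "")[[1L]]; rc <- strsplit(ref, "")[[1L]]
  if (no == nr - 1L) {          # deletion of one ref base
    for (p in seq_len(nr)) {
      cand <- rc[-p]
      if (identical(cand, oc)) return(list(op = "del", pos = p))
    }
  } else if (no == nr + 1L) {   # insertion after ref base k (k = 0..nr)
    for (k in 0:nr) {
      cand <- append(rc, oc[k + 1L], after = k)
      if (identical(cand, oc)) return(list(op = "ins", pos = k))
    }
  }
  NULL
}

# a 27-nt surrogate region with no two adjacent equal bases, so every
# single-base deletion has a unique leftmost placement
surro27_distinct <- function() paste(rep(c("A", "C", "G", "T"), 7)[1:27],
                                     collapse = "")

# small designed library shared across files (built once per test run)
.fixture_env <- new.env()
fixture_library <- function() {
  if (is.null(.fixture_env$lib)) {
    cfg <- sim_config(seed = 42, genome_length = 6000, n_guides = 2,
                      planted = c("0" = 1, "2" = 2, "3" = 1))
    gg <- simulate_genome_and_guides(cfg)
    lib <- design_library(gg$genome, gg$guides, seed = 42)
    .fixture_env$lib <- list(cfg = cfg, gg = gg, lib = lib)
  }
  .fixture_env$lib
}

# make read pairs that tile an amplicon exactly, constant quality
tile_pair <- function(amplicon, read_len = 150L, qual = 37L) {
  L <- nchar(amplicon)
  r1 <- substr(amplicon, 1L, min(read_len, L))
  r2 <- revcomp(substr(amplicon, max(1L, L - read_len + 1L), L))
  list(r1 = list(id = "p1", seq = r1, qual = list(rep(qual, nchar(r1)))),
       r2 = list(id = "p1", seq = r2, qual = list(rep(qual, nchar(r2)))))
}
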