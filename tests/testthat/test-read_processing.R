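test_that("overlapping mates reconstruct the amplicon; zero-overlap pairs drop", {
  set.seed(2)
  amp <- random_dna(1, 180)
  pr <- tile_pair(amp, read_len = 150)   # 120-nt overlap
  m <- merge_pairs(pr$r1, pr$r2)
  expect_equal(m$n_unmerged, 0L)
  expect_identical(m$seq, amp)

  # disjoint mates: no admissible overlap
  r1 <- list(id = "q", seq = random_dna(1, 50), qual = list(rep(30L, 50)))
  r2 <- list(id = "q", seq = random_dna(1, 50), qual = list(rep(30L, 50)))
  m2 <- merge_pairs(r1, r2, min_overlap = 30)
  expect_equal(m2$n_unmerged, 1L)
  expect_length(m2$seq, 0L)

  expect_error(merge_pairs(r1, list(id = "other", seq = "ACGT",
                                    qual = list(rep(30L, 4)))),
               "desynchronized")
})

test_that("overlap disagreements resolve toward the higher-quality base", {
  set.seed(4)
  amp <- random_dna(1, 120)
  r1seq <- substr(amp, 1, 80)
  r2seq <- revcomp(substr(amp, 41, 120))
  # corrupt base 60 of R1 (inside the 40-nt overlap) at low quality
  substr(r1seq, 60, 60) <- "T"
  r1 <- list(id = "p", seq = r1seq, qual = list(c(rep(37L, 59), 5L, rep(37L, 20))))
  r2 <- list(id = "p", seq = r2seq, qual = list(rep(37L, 80)))
  m <- merge_pairs(r1, r2)
  expect_identical(m$seq, amp)
})

test_that("simulated pairs merge at >= 99% with truth-matching lengths", {
  fx <- fixture_library()
  cfg <- sim_config(seed = 9, depth = 60, true_if = 0, sub_rate = 0.01,
                    indel1_rate = 0)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(fx$lib$manifest, cfg, dir)
  m <- merge_pairs(rd$mock_r1, rd$mock_r2)
  n_pairs <- nrow(fx$lib$manifest) * cfg$depth
  expect_gte(length(m$seq) / n_pairs, 0.99)
  amp_len <- 170 + 2 * cfg$flank_len
  expect_true(all(nchar(m$seq) == amp_len))
})

test_that("demultiplexing assigns exact barcodes and rejects mutated ones", {
  fx <- fixture_library()
  m <- fx$lib$manifest
  amp <- paste0("AAAAA", m$oligo[1], "TTTTT")
  dm <- demultiplex(amp, m)
  expect_equal(dm$construct_id, m$construct_id[1])
  # reverse-complement orientation auto-detected
  dm_rc <- demultiplex(revcomp(amp), m)
  expect_equal(dm_rc$construct_id, m$construct_id[1])
  # one substitution inside the barcode -> unassigned
  bc_at <- 5 + 118 + 1
  mut <- amp
  substr(mut, bc_at + 2, bc_at + 2) <- if (substr(mut, bc_at + 2, bc_at + 2) == "A") "C" else "A"
  dm2 <- demultiplex(mut, m)
  expect_true(is.na(dm2$construct_id))
  expect_equal(attr(dm2, "n_unassigned"), 1L)
})

test_that("demultiplexing is >= 99% accurate with zero cross-assignments on simulated reads", {
  fx <- fixture_library()
  # ~10,000 reads with a 0.3% per-barcode error rate (0.03% per base)
  cfg <- sim_config(seed = 13, depth = 800, true_if = 10, sub_rate = 0.0003,
                    indel1_rate = 0)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(fx$lib$manifest, cfg, dir)
  mg <- merge_pairs(rd$cas9_r1, rd$cas9_r2)
  truth_cid <- sub("_spcas9_.*$", "", mg$id)
  dm <- demultiplex(mg$seq, fx$lib$manifest)
  assigned <- !is.na(dm$construct_id)
  expect_gte(mean(assigned & dm$construct_id == truth_cid), 0.99)
  expect_equal(sum(assigned & dm$construct_id != truth_cid), 0L)
})

test_that("structural filter demands intact backbone and extracts the surrogate segment", {
  fx <- fixture_library()
  cons <- fx$lib$manifest[1, ]
  amp <- paste0("GGGGG", cons$oligo, "CCCCC")
  sf <- structural_filter(amp, cons)
  expect_true(sf$pass)
  expect_identical(sf$segment, cons$surrogate27)

  # 2-nt deletion inside the protospacer: still passes, segment length 25
  surro_at <- 5 + 128 + 1
  del2 <- paste0(substr(amp, 1, surro_at + 4), substr(amp, surro_at + 7, nchar(amp)))
  sf2 <- structural_filter(del2, cons)
  expect_true(sf2$pass)
  expect_equal(nchar(sf2$segment), 25L)

  # substitution in the scaffold: structure failure
  scaf_at <- 5 + 36 + 10
  bad <- amp
  substr(bad, scaf_at, scaf_at) <- if (substr(bad, scaf_at, scaf_at) == "A") "G" else "A"
  sf3 <- structural_filter(bad, cons)
  expect_false(sf3$pass)
  expect_equal(sf3$reason, "structure")
})

test_that("indel caller: identity, single deletions, and exhaustive single-indel oracle", {
  ref <- surro27_distinct()
  expect_equal(nrow(call_indel(ref, ref)), 0L)

  d17 <- paste0(substr(ref, 1, 16), substr(ref, 18, 27))
  call <- call_indel(d17, ref)
  expect_equal(call$op, "del")
  expect_equal(call$start, 17L)
  expect_equal(call$end, 17L)
  expect_equal(call$length, 1L)

  set.seed(31)
  for (i in 1:200) {
    realref <- random_dna(1, 27)
    if (runif(1) < 0.5) {
      p <- sample(27, 1)
      obs <- paste0(substr(realref, 1, p - 1), substr(realref, p + 1, 27))
    } else {
      k <- sample(0:27, 1)
      obs <- paste0(substr(realref, 1, k), sample(c("A","C","G","T"), 1),
                    substr(realref, k + 1, 27))
    }
    want <- single_indel_oracle(obs, realref)
    got <- call_indel(obs, realref)
    expect_equal(nrow(got), 1L)
    expect_equal(got$op, want$op)
    expect_equal(got$start, want$pos)
    expect_equal(got$length, 1L)
  }
})

test_that("caller attains the optimal affine score (independent DP oracle) within edit distance 3", {
  # independent Gotoh DP in R returning only the optimal score
  score_oracle <- function(obs, ref, ma = 2, mi = -4, go = -6, ge = -1) {
    n <- nchar(ref); m <- nchar(obs)
    rc <- strsplit(ref, "")[[1L]]; oc <- strsplit(obs, "")[[1L]]
    NEG <- -1e18
    D <- matrix(NEG, n + 1, m + 1); P <- D; Q <- D
    D[1, 1] <- 0
    for (i in seq_len(n)) P[i + 1, 1] <- go + i * ge
    for (j in seq_len(m)) Q[1, j + 1] <- go + j * ge
    for (i in seq_len(n)) for (j in seq_len(m)) {
      s <- if (rc[i] == oc[j]) ma else mi
      D[i + 1, j + 1] <- max(D[i, j], P[i, j], Q[i, j]) + s
      P[i + 1, j + 1] <- max(D[i, j + 1] + go + ge, Q[i, j + 1] + go + ge,
                             P[i, j + 1] + ge)
      Q[i + 1, j + 1] <- max(D[i + 1, j] + go + ge, P[i + 1, j] + go + ge,
                             Q[i + 1, j] + ge)
    }
    max(D[n + 1, m + 1], P[n + 1, m + 1], Q[n + 1, m + 1])
  }
  ref <- surro27_distinct()
  set.seed(77)
  for (i in 1:40) {
    b <- strsplit(ref, "")[[1L]]
    for (e in seq_len(sample(1:3, 1))) {
      kind <- sample(c("del", "ins", "sub"), 1)
      p <- sample(length(b), 1)
      if (kind == "del") b <- b[-p]
      else if (kind == "ins") b <- append(b, sample(c("A","C","G","T"), 1), p)
      else b[p] <- sample(setdiff(c("A","C","G","T"), b[p]), 1)
    }
    obs <- paste(b, collapse = "")
    got <- surroseq:::.nw_indels(obs, ref, 2, -4, -6, -1)
    expect_equal(got$score, score_oracle(obs, ref))
    # reported ops account exactly for the length difference
    dlen <- sum(ifelse(got$op == "ins", got$length, -got$length))
    expect_equal(nchar(ref) + dlen, nchar(obs))
  }
})

test_that("positional filter keeps only 1-bp indels in N15-N21 as edits", {
  ref <- surro27_distinct()
  # deletions at every position
  for (p in 1:27) {
    obs <- paste0(substr(ref, 1, p - 1), substr(ref, p + 1, 27))
    cls <- classify_indel_call(call_indel(obs, ref))
    if (p >= 15 && p <= 21) expect_equal(cls, "indel")
    else expect_equal(cls, "reclassified")
  }
  # a 2-bp deletion at N3 is retained as an edit
  obs2 <- paste0(substr(ref, 1, 2), substr(ref, 5, 27))
  expect_equal(classify_indel_call(call_indel(obs2, ref)), "indel")
  # insertion anchors at the window boundaries
  ins_after <- function(k) paste0(substr(ref, 1, k), "A",
                                  substr(ref, k + 1, 27))
  expect_equal(classify_indel_call(call_indel(ins_after(14), ref)), "reclassified")
  expect_equal(classify_indel_call(call_indel(ins_after(21), ref)), "indel")
})

test_that("length-deviant segments fail with reason length", {
  ref <- surro27_distinct()
  short <- substr(ref, 1, 2)
  expect_s3_class(call_indel(short, ref), "length_fail")
  expect_error(call_indel("", ref), "non-empty")
})

test_that("wild-type pseudo-edit alleles are subtracted from the SpCas9 table", {
  ref <- surro27_distinct()
  bad <- paste0(substr(ref, 1, 16), substr(ref, 18, 27))  # synthesis artefact
  cas9 <- c(700L, 7L, 12L)
  names(cas9) <- c(ref, bad, paste0(substr(ref, 1, 10), substr(ref, 14, 27)))
  mock <- c(980L, 15L)
  names(mock) <- c(ref, bad)
  out <- subtract_wt_pseudoedits(cas9, mock, ref)
  expect_equal(out$n_removed, 7L)
  expect_false(bad %in% names(out$alleles))
  expect_equal(unname(out$alleles[ref]), 700L)

  # disjoint allele sets leave the SpCas9 table unchanged
  out2 <- subtract_wt_pseudoedits(cas9, c(stats::setNames(10L, ref)), ref)
  expect_equal(out2$n_removed, 0L)
  expect_identical(out2$alleles, cas9)
})

test_that("tabulation bookkeeping is exact and order-invariant on simulated reads", {
  fx <- fixture_library()
  man <- fx$lib$manifest[1:3, ]
  cfg <- sim_config(seed = 21, depth = 80, true_if = c(0, 15, 40),
                    sub_rate = 0.002, indel1_rate = 0.01, synth_rate = 0)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(man, cfg, dir)
  tc <- tabulate_counts(man, mock = list(r1 = rd$mock_r1, r2 = rd$mock_r2),
                        cas9 = list(r1 = rd$cas9_r1, r2 = rd$cas9_r2))
  cnt <- tc$counts
  expect_true(all(cnt$indel <= cnt$total_clean))
  # per construct and sample: clean + filtered == assigned reads
  n_assigned_total <- sum(cnt$total_clean + cnt$n_structure + cnt$n_length +
                            cnt$n_wt_pseudoedit)
  n_reads <- 2 * nrow(man) * cfg$depth
  n_lost <- tc$log$mock$n_unmerged + tc$log$mock$n_unassigned +
    tc$log$cas9$n_unmerged + tc$log$cas9$n_unassigned
  expect_equal(n_assigned_total, n_reads - n_lost)

  # shuffling read order leaves the counts unchanged
  shuffle_fq <- function(p1, p2, dir, tag) {
    a <- read_fastq(p1); b <- read_fastq(p2)
    set.seed(99); o <- sample(length(a$seq))
    q1 <- file.path(dir, paste0(tag, "_s1.fastq")); q2 <- file.path(dir, paste0(tag, "_s2.fastq"))
    surroseq:::write_fastq(a$id[o], a$seq[o], a$qual[o], q1)
    surroseq:::write_fastq(b$id[o], b$seq[o], b$qual[o], q2)
    list(r1 = q1, r2 = q2)
  }
  mo <- shuffle_fq(rd$mock_r1, rd$mock_r2, dir, "m")
  ca <- shuffle_fq(rd$cas9_r1, rd$cas9_r2, dir, "c")
  tc2 <- tabulate_counts(man, mock = mo, cas9 = ca)
  expect_equal(tc2$counts, tc$counts)
})

test_that("estimated indel frequency tracks simulator truth within binomial error", {
  fx <- fixture_library()
  man <- fx$lib$manifest[1:2, ]
  cfg <- sim_config(seed = 33, depth = 400, true_if = c(30, 60),
                    sub_rate = 0, indel1_rate = 0, synth_rate = 0)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(man, cfg, dir)
  tc <- tabulate_counts(man, mock = list(r1 = rd$mock_r1, r2 = rd$mock_r2),
                        cas9 = list(r1 = rd$cas9_r1, r2 = rd$cas9_r2))
  cs <- tc$counts[tc$counts$sample == "SpCas9", ]
  est <- indel_frequency(cs$indel, cs$total_clean)
  truth <- rd$truth$n_detectable_reads / rd$truth$depth_cas9 * 100
  expect_equal(est, truth[match(cs$construct_id, rd$truth$construct_id)],
               tolerance = 0.02)
})
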