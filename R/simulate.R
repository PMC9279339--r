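#' Simulation configuration
#'
#' Assembles and validates the configuration for the synthetic-data
#' generators. Defaults emulate the measurement conditions the pipeline is
#' designed for: 150-bp paired-end reads over a 170-nt oligo cassette with
#' short constant primer flanks, a per-read background of 1% spurious 1-bp
#' indels (the PCR/deep-sequencing indel background observed in unedited
#' cells), a 0.1% per-base substitution error rate, and nuclease indels
#' centred on the blunt cut between N17 and N18 of the 27-nt surrogate
#' region (3 bp upstream of the PAM).
#'
#' @param seed Integer master seed; every random draw flows from it.
#' @param genome_length Synthetic genome length in bp.
#' @param n_guides Number of guides to draw.
#' @param planted Named integer vector: planted site count per mismatch
#'   class per guide, e.g. `c("0" = 1, "2" = 3, "4" = 5)`.
#' @param depth Reads per construct per sample.
#' @param true_if Per-construct true editing rates in percent (recycled),
#'   or `NULL` to draw from `runif(0, 80)`.
#' @param read_len Read length (150).
#' @param flank_len Constant flank length either side of the oligo (25).
#' @param del_geom_p Geometric parameter for deletion lengths
#'   (`length = 1 + rgeom(p)`, default 0.45, mean ~2.2 bp).
#' @param ins_frac Fraction of nuclease indels that are insertions (0.15).
#' @param sub_rate Per-base sequencing substitution rate (0.001).
#' @param indel1_rate Per-read spurious 1-bp indel rate (0.01).
#' @param synth_rate Fraction of constructs carrying a synthesis-error
#'   allele (0.02).
#' @param synth_frac Fraction of a synthesis-error construct's molecules
#'   carrying the erroneous allele (0.10).
#' @param dropout_rate Fraction of constructs depleted in the SpCas9
#'   sample (0), `dropout_factor`-fold (4).
#' @param dropout_factor Depletion factor for dropout constructs.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, genome_length = 10000L, n_guides = 1L,
                       planted = c("0" = 1L, "2" = 2L, "3" = 2L, "4" = 2L),
                       depth = 500L, true_if = NULL,
                       read_len = 150L, flank_len = 25L,
                       del_geom_p = 0.45, ins_frac = 0.15,
                       sub_rate = 0.001, indel1_rate = 0.01,
                       synth_rate = 0.02, synth_frac = 0.10,
                       dropout_rate = 0, dropout_factor = 4) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_guides = as.integer(n_guides), planted = planted,
              depth = as.integer(depth), true_if = true_if,
              read_len = as.integer(read_len), flank_len = as.integer(flank_len),
              del_geom_p = del_geom_p, ins_frac = ins_frac,
              sub_rate = sub_rate, indel1_rate = indel1_rate,
              synth_rate = synth_rate, synth_frac = synth_frac,
              dropout_rate = dropout_rate, dropout_factor = dropout_factor)
  rates <- c(cfg$del_geom_p, cfg$ins_frac, cfg$sub_rate, cfg$indel1_rate,
             cfg$synth_rate, cfg$synth_frac, cfg$dropout_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$depth < 0) stop("depth must be >= 0")
  structure(cfg, class = "sim_config")
}

mutate_spacer <- function(spacer, n_mm) {
  b <- strsplit(spacer, "")[[1L]]
  pos <- sort(sample(20L, n_mm))
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  list(seq = paste(b, collapse = ""), positions = pos)
}

#' Simulate a genome with planted guide target sites
#'
#' Draws a random genome and `n_guides` random 20-nt spacers, then plants,
#' for each guide, the configured number of protospacer variants per
#' mismatch class at recorded non-overlapping positions (random strand),
#' each followed by an NGG PAM and 4 downstream bases. The truth table
#' lists every planted site; the genome may additionally contain incidental
#' near-matches, which a scan will legitimately report.
#'
#' @param cfg A [sim_config()].
#' @return List: `genome` (named character vector, one chromosome),
#'   `guides` (data.frame `guide_id`, `spacer`), `truth` (data.frame with
#'   planted coordinates, strand, mismatch class and positions).
#' @export
simulate_genome_and_guides <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$genome_length
  genome <- random_dna(1L, L)
  guides <- data.frame(guide_id = sprintf("G%02d", seq_len(cfg$n_guides)),
                       spacer = random_dna(cfg$n_guides, 20L),
                       stringsAsFactors = FALSE)

  n_per_guide <- sum(cfg$planted)
  slot_len <- 40L
  n_slots <- (L - slot_len) %/% slot_len
  need <- n_per_guide * cfg$n_guides
  if (need > n_slots) stop("planting infeasible: genome too short for ",
                           need, " sites")
  slots <- sample(n_slots, need) # 1-based slot index

  truth <- list()
  si <- 0L
  gchars <- strsplit(genome, "")[[1L]]
  for (gi in seq_len(cfg$n_guides)) {
    for (cls in names(cfg$planted)) {
      for (r in seq_len(cfg$planted[[cls]])) {
        si <- si + 1L
        mut <- mutate_spacer(guides$spacer[gi], as.integer(cls))
        pam <- paste0(sample(c("A", "C", "G", "T"), 1L), "GG")
        down <- random_dna(1L, 4L)
        ctx <- paste0(mut$seq, pam, down)                 # 27 nt
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") ctx else revcomp(ctx)
        at <- (slots[si] - 1L) * slot_len + 5L            # 1-based
        gchars[at:(at + 26L)] <- strsplit(ins, "")[[1L]]
        start0 <- if (strand == "+") at - 1L else at - 1L + 7L
        truth[[si]] <- data.frame(
          guide_id = guides$guide_id[gi], chrom = "chrSim",
          start = start0, end = start0 + 20L, strand = strand,
          n_mismatches = as.integer(cls),
          mismatch_positions = paste(mut$positions, collapse = ";"),
          protospacer = mut$seq, pam = pam, downstream4 = down,
          stringsAsFactors = FALSE)
      }
    }
  }
  genome <- paste(gchars, collapse = "")
  list(genome = c(chrSim = genome), guides = guides,
       truth = do.call(rbind, truth))
}

add_seq_errors <- function(seq, sub_rate, indel1_rate) {
  b <- strsplit(seq, "")[[1L]]
  n <- length(b)
  nsub <- stats::rbinom(1L, n, sub_rate)
  if (nsub > 0L) {
    at <- sample(n, nsub)
    for (p in at) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  }
  if (stats::runif(1L) < indel1_rate) {
    p <- sample(length(b), 1L)
    if (stats::runif(1L) < 0.5) b <- b[-p]
    else b <- append(b, sample(c("A", "C", "G", "T"), 1L), after = p)
  }
  paste(b, collapse = "")
}

nuclease_indel <- function(surro, del_geom_p, ins_frac, cut_after = 17L) {
  len <- 1L + stats::rgeom(1L, del_geom_p)
  if (stats::runif(1L) < ins_frac) {
    ins <- random_dna(1L, len)
    list(allele = paste0(substr(surro, 1L, cut_after), ins,
                         substr(surro, cut_after + 1L, nchar(surro))),
         op = "ins", pos = cut_after, len = len, seq = ins)
  } else {
    len <- min(len, 10L)
    s <- sample(max(1L, cut_after + 1L - len):(cut_after + 1L), 1L)
    list(allele = paste0(substr(surro, 1L, s - 1L),
                         substr(surro, s + len, nchar(surro))),
         op = "del", pos = s, len = len, seq = substr(surro, s, s + len - 1L))
  }
}

# does an indel survive the positional 1-bp filter once left-aligned?
# (independent run-shift computation, not the alignment engine)
edit_detectable <- function(ref, op, pos, len, seq, window = c(15L, 21L)) {
  if (len >= 2L) return(TRUE)
  b <- strsplit(ref, "")[[1L]]
  if (op == "del") {
    s <- pos
    while (s > 1L && b[s - 1L] == b[s]) s <- s - 1L
    s >= window[1L] && s <= window[2L]
  } else {
    k <- pos
    while (k >= 1L && b[k] == seq) k <- k - 1L
    k >= window[1L] && k <= window[2L]
  }
}

#' Simulate paired-end reads for a designed library
#'
#' Emits MOCK and SpCas9 FASTQ pairs for every manifest construct together
#' with a per-construct truth table. Per construct: the true editing rate
#' is taken from `cfg$true_if` (MOCK true editing is always zero); edited
#' SpCas9 molecules carry a nuclease indel at the cut between N17 and N18;
#' synthesis-error constructs emit a fixed erroneous allele in both
#' samples; all reads pass through the same sequencing substitution and
#' spurious-1-bp-indel error processes; dropout constructs emit
#' `dropout_factor`-fold fewer SpCas9 reads.
#'
#' @param manifest Constructs data.frame from [design_library()].
#' @param cfg A [sim_config()].
#' @param dir Output directory for FASTQ and truth files.
#' @return List with FASTQ paths (`mock_r1`, `mock_r2`, `cas9_r1`,
#'   `cas9_r2`), `truth` data.frame (also written to `truth.tsv`), and the
#'   constant `flank5`/`flank3` sequences.
#' @export
simulate_reads <- function(manifest, cfg, dir) {
  set.seed(cfg$seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flank5 <- random_dna(1L, cfg$flank_len)
  flank3 <- random_dna(1L, cfg$flank_len)
  n <- nrow(manifest)
  true_if <- if (is.null(cfg$true_if)) stats::runif(n, 0, 80)
             else rep_len(cfg$true_if, n)
  synth <- stats::runif(n) < cfg$synth_rate
  dropout <- stats::runif(n) < cfg$dropout_rate

  out <- list(MOCK = list(id = character(), seq = character()),
              SpCas9 = list(id = character(), seq = character()))
  truth <- vector("list", n)
  surro_at <- cfg$flank_len + 128L      # 0-based offset of surrogate27 start

  for (i in seq_len(n)) {
    oligo <- manifest$oligo[i]
    surro <- manifest$surrogate27[i]
    amp_ref <- paste0(flank5, oligo, flank3)
    pre <- substr(amp_ref, 1L, surro_at)
    post <- substr(amp_ref, surro_at + 28L, nchar(amp_ref))
    synth_allele <- if (synth[i]) {
      # 2-bp deletion in the PAM-distal half: counted as an indel by the
      # positional filter, but disjoint from the cut-centred alleles the
      # nuclease produces
      p <- sample(2L:8L, 1L)
      paste0(substr(surro, 1L, p - 1L), substr(surro, p + 2L, 27L))
    } else NA_character_

    n_edit <- 0L
    n_synth_cas9 <- 0L
    n_detect <- 0L
    for (smp in c("MOCK", "SpCas9")) {
      depth <- cfg$depth
      if (smp == "SpCas9" && dropout[i])
        depth <- as.integer(round(depth / cfg$dropout_factor))
      if (depth == 0L) next
      p_edit <- if (smp == "SpCas9") true_if[i] / 100 else 0
      edited <- stats::runif(depth) < p_edit
      synthed <- !edited & stats::runif(depth) < (if (synth[i]) cfg$synth_frac else 0)
      seqs <- character(depth)
      for (r in seq_len(depth)) {
        if (edited[r]) {
          ed <- nuclease_indel(surro, cfg$del_geom_p, cfg$ins_frac)
          s27 <- ed$allele
          if (edit_detectable(surro, ed$op, ed$pos, ed$len, ed$seq))
            n_detect <- n_detect + 1L
        } else {
          s27 <- if (synthed[r]) synth_allele else surro
        }
        seqs[r] <- add_seq_errors(paste0(pre, s27, post),
                                  cfg$sub_rate, cfg$indel1_rate)
      }
      ids <- sprintf("%s_%s_%05d_e%d", manifest$construct_id[i],
                     tolower(smp), seq_len(depth), as.integer(edited))
      out[[smp]]$id <- c(out[[smp]]$id, ids)
      out[[smp]]$seq <- c(out[[smp]]$seq, seqs)
      if (smp == "SpCas9") {
        n_edit <- sum(edited)
        n_synth_cas9 <- sum(synthed)
      }
    }
    truth[[i]] <- data.frame(
      construct_id = manifest$construct_id[i], true_if = true_if[i],
      n_edited_reads = n_edit,
      n_detectable_reads = n_detect,
      n_synth_reads_cas9 = n_synth_cas9,
      synthesis_error = synth[i], dropout = dropout[i],
      depth_mock = cfg$depth,
      depth_cas9 = if (dropout[i]) as.integer(round(cfg$depth / cfg$dropout_factor))
                   else cfg$depth,
      stringsAsFactors = FALSE)
  }

  paths <- list()
  for (smp in c("MOCK", "SpCas9")) {
    tag <- if (smp == "MOCK") "mock" else "cas9"
    seqs <- out[[smp]]$seq
    ids <- out[[smp]]$id
    lens <- nchar(seqs)
    r1 <- substr(seqs, 1L, pmin(cfg$read_len, lens))
    r2 <- revcomp(substr(seqs, pmax(1L, lens - cfg$read_len + 1L), lens))
    q <- lapply(nchar(r1), function(k) rep(37L, k))
    q2 <- lapply(nchar(r2), function(k) rep(37L, k))
    p1 <- file.path(dir, paste0(tag, "_R1.fastq.gz"))
    p2 <- file.path(dir, paste0(tag, "_R2.fastq.gz"))
    write_fastq(ids, r1, q, p1)
    write_fastq(ids, r2, q2, p2)
    paths[[paste0(tag, "_r1")]] <- p1
    paths[[paste0(tag, "_r2")]] <- p2
  }
  truth <- do.call(rbind, truth)
  write_tsv(truth, file.path(dir, "truth.tsv"))
  c(paths, list(truth = truth, flank5 = flank5, flank3 = flank3))
}

#' Simulate paired count tables directly
#'
#' Counts-level companion to [simulate_reads()] for statistical
#' calibration at scale: per site, MOCK indel reads are
#' `Binomial(depth, bg_rate)` and SpCas9 indel reads
#' `Binomial(depth, t + (1 - t) * bg_rate)` where `t` is the site's true
#' editing rate; both samples share the background process.
#'
#' @param n_sites Number of sites.
#' @param depth Reads per site per sample.
#' @param true_if True editing rates in percent (recycled; 0 = null).
#' @param bg_rate Shared background indel rate (default 0.01).
#' @param seed Integer seed.
#' @return Long count data.frame as produced by [tabulate_counts()].
#' @export
simulate_site_counts <- function(n_sites, depth, true_if = 0, bg_rate = 0.01,
                                 seed = 1L) {
  set.seed(seed)
  t <- rep_len(true_if, n_sites) / 100
  ids <- sprintf("S%05d", seq_len(n_sites))
  im <- stats::rbinom(n_sites, depth, bg_rate)
  ic <- stats::rbinom(n_sites, depth, t + (1 - t) * bg_rate)
  rbind(data.frame(construct_id = ids, sample = "MOCK", total_clean = depth,
                   indel = im, stringsAsFactors = FALSE),
        data.frame(construct_id = ids, sample = "SpCas9", total_clean = depth,
                   indel = ic, stringsAsFactors = FALSE))
}
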