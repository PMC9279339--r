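#' Read a guide table
#'
#' Reads a tab-separated guide list with columns `guide_id` and `spacer`
#' (20-nt, ACGT, written 5'->3' with position N1 the most PAM-distal base
#' and N20 adjacent to the PAM).
#'
#' @param path Path to a TSV file (header required).
#' @return data.frame with columns `guide_id`, `spacer`.
#' @export
read_guides <- function(path) {
  g <- read_tsv(path)
  if (!all(c("guide_id", "spacer") %in% names(g)))
    stop("guide table must have columns guide_id and spacer: ", path)
  g$spacer <- vapply(g$spacer, check_spacer, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(g$guide_id)) stop("duplicate guide_id in ", path)
  g[, c("guide_id", "spacer")]
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a FASTA path, named character vector, or DNAStringSet")
  if (is.null(names(genome)) || any(names(genome) == ""))
    stop("genome sequences must be named")
  # FASTA headers may carry descriptions; use the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Enumerate candidate off-target sites for one guide
#'
#' Scans every 20-nt window on both strands of a genome for windows followed
#' by an NGG PAM whose Hamming distance to the guide spacer does not exceed
#' `max_mismatches`, capturing the PAM and the 4 nt downstream of it.
#' Windows too close to a sequence end to supply PAM + 4 nt, and windows
#' whose protospacer/PAM/downstream context contains a non-ACGT base, are
#' skipped (the latter tallied in the `n_skipped_ambiguous` attribute).
#'
#' Coordinates are 0-based half-open on the forward strand of the reference;
#' `protospacer`, `pam` and `downstream4` are reported on the protospacer
#' strand (reverse-complemented for `-` strand sites). Mismatch positions
#' use the spacer numbering N1 (PAM-distal) .. N20 (PAM-proximal).
#'
#' @param genome FASTA path, named character vector, or `DNAStringSet`.
#' @param guide List or one-row data.frame with `guide_id` and `spacer`, or a
#'   bare 20-nt spacer string.
#' @param max_mismatches Maximum Hamming distance, 0..6 (default 4).
#' @return data.frame of sites ordered by (chrom, start, strand) with columns
#'   `site_id`, `guide_id`, `chrom`, `start`, `end`, `strand`, `protospacer`,
#'   `pam`, `downstream4`, `n_mismatches`, `mismatches`.
#' @export
enumerate_offtargets <- function(genome, guide, max_mismatches = 4L) {
  if (is.character(guide)) guide <- list(guide_id = "guide1", spacer = guide)
  spacer <- check_spacer(guide$spacer)
  if (max_mismatches < 0L || max_mismatches > 6L)
    stop("max_mismatches must be in 0..6")
  genome <- load_genome(genome)

  spacer_chars <- strsplit(spacer, "")[[1L]]
  n_ambig <- 0L
  rows <- list()

  for (chr in names(genome)) {
    subj <- genome[[chr]]
    L <- length(subj)
    if (L < 27L) next
    sstr <- as.character(subj)

    # + strand: spacer match at s (1-based), PAM at s+20..s+22, down at s+23..s+26
    hits <- Biostrings::start(Biostrings::matchPattern(
      spacer, subj, max.mismatch = max_mismatches, fixed = TRUE))
    for (s in hits) {
      if (s + 26L > L) next
      ctx <- substr(sstr, s, s + 26L)
      if (!is_acgt(ctx)) { n_ambig <- n_ambig + 1L; next }
      pam <- substr(ctx, 21L, 23L)
      if (substr(pam, 2L, 3L) != "GG") next
      proto <- substr(ctx, 1L, 20L)
      rows[[length(rows) + 1L]] <- site_row(guide$guide_id, chr, s - 1L, "+",
                                            proto, pam, substr(ctx, 24L, 27L),
                                            spacer_chars)
    }

    # - strand: revcomp(spacer) at s..s+19; PAM context at s-7..s-1
    hits <- Biostrings::start(Biostrings::matchPattern(
      revcomp(spacer), subj, max.mismatch = max_mismatches, fixed = TRUE))
    for (s in hits) {
      if (s - 7L < 1L) next
      ctx_fwd <- substr(sstr, s - 7L, s + 19L)
      if (!is_acgt(ctx_fwd)) { n_ambig <- n_ambig + 1L; next }
      ctx <- revcomp(ctx_fwd)                       # protospacer-strand context
      pam <- substr(ctx, 21L, 23L)
      if (substr(pam, 2L, 3L) != "GG") next
      rows[[length(rows) + 1L]] <- site_row(guide$guide_id, chr, s - 1L, "-",
                                            substr(ctx, 1L, 20L), pam,
                                            substr(ctx, 24L, 27L), spacer_chars)
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else empty_sites()
  out <- out[out$n_mismatches <= max_mismatches, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out))
    out$site_id <- sprintf("%s_OT%03d", out$guide_id, seq_len(nrow(out)))
  attr(out, "n_skipped_ambiguous") <- n_ambig
  out
}

site_row <- function(guide_id, chrom, start0, strand, proto, pam, down4,
                     spacer_chars) {
  pc <- strsplit(proto, "")[[1L]]
  mmpos <- which(pc != spacer_chars)
  data.frame(site_id = NA_character_, guide_id = guide_id, chrom = chrom,
             start = start0, end = start0 + 20L, strand = strand,
             protospacer = proto, pam = pam, downstream4 = down4,
             n_mismatches = length(mmpos),
             mismatches = format_mismatches(mmpos, spacer_chars[mmpos], pc[mmpos]),
             stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(site_id = character(), guide_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             protospacer = character(), pam = character(),
             downstream4 = character(), n_mismatches = integer(),
             mismatches = character(), stringsAsFactors = FALSE)
}

#' Assign construct barcodes
#'
#' Draws one 10-nt barcode per site: fixed `"AC"` followed by 8 random ACGT
#' bases. Barcodes are pairwise distinct (optionally at a minimum pairwise
#' Hamming distance) and are redrawn if, placed between the scaffold tail
#' and the site's surrogate region, they would create a BsmBI recognition
#' site in context.
#'
#' @param sites Site data.frame from [enumerate_offtargets()] (needs
#'   `site_id`, `protospacer`, `pam`, `downstream4`).
#' @param seed Integer seed; the assignment is reproducible under it.
#' @param min_hamming Minimum pairwise Hamming distance between barcodes
#'   (default 1 = exact-match uniqueness only).
#' @param scaffold Scaffold whose 3' tail forms the upstream barcode context.
#' @param max_tries Redraw budget per barcode before giving up.
#' @return Named character vector: `site_id -> barcode`.
#' @export
assign_barcodes <- function(sites, seed, min_hamming = 1L,
                            scaffold = surro_scaffold(), max_tries = 10000L) {
  n <- nrow(sites)
  if (n == 0L) return(stats::setNames(character(), character()))
  if (n > 4^8) stop("barcode space exhausted: more than 4^8 sites requested")
  set.seed(seed)
  tail5 <- substr(scaffold, nchar(scaffold) - 4L, nchar(scaffold))
  surro27 <- paste0(sites$protospacer, sites$pam, sites$downstream4)

  accepted <- character(n)
  accepted_mat <- matrix(NA_character_, nrow = 8L, ncol = n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      tail8 <- sample(c("A", "C", "G", "T"), 8L, replace = TRUE)
      bc <- paste0("AC", paste(tail8, collapse = ""))
      if (has_bsmbi(paste0(tail5, bc, substr(surro27[i], 1L, 5L)))) next
      if (i > 1L) {
        if (min_hamming <= 1L) {
          if (bc %in% accepted[seq_len(i - 1L)]) next
        } else {
          d <- colSums(accepted_mat[, seq_len(i - 1L), drop = FALSE] != tail8)
          if (any(d < min_hamming)) next
        }
      }
      accepted[i] <- bc
      accepted_mat[, i] <- tail8
      ok <- TRUE
      break
    }
    if (!ok)
      stop("barcode assignment exhausted after ", max_tries,
           " tries at site ", sites$site_id[i],
           " (constraint: uniqueness/min Hamming distance ", min_hamming,
           " and no BsmBI site in context)")
  }
  stats::setNames(accepted, sites$site_id)
}

#' Assemble one surrogate oligo
#'
#' Builds the 170-nt oligo for a (guide, site, barcode) triple:
#' `ACCA + CGTCTC + ACACC + G + spacer(20) + scaffold(82) + surrogate37(37)
#' + GTTTG + CGTCTC + ACGG`, where `surrogate37 = barcode(10) +
#' protospacer(20) + PAM(3) + downstream(4)`. Constructs whose internal
#' region (spacer, scaffold or surrogate37, including junctions) contains a
#' BsmBI recognition site are rejected, since Golden Gate assembly requires
#' exactly the two flanking sites.
#'
#' @param guide List/row with `guide_id` and 20-nt `spacer`.
#' @param site One-row site data.frame (or list) with `site_id`,
#'   `protospacer`, `pam`, `downstream4` (and optionally coordinates).
#' @param barcode 10-nt barcode starting `"AC"`.
#' @param scaffold 82-nt gRNA scaffold (default [surro_scaffold()]).
#' @return One-row data.frame describing the construct (`construct_id`,
#'   ids, coordinates if present, `barcode`, `surrogate27`, `surrogate37`,
#'   `spacer`, `oligo`).
#' @export
assemble_oligo <- function(guide, site, barcode, scaffold = surro_scaffold()) {
  spacer <- check_spacer(guide$spacer)
  barcode <- toupper(barcode)
  if (nchar(barcode) != 10L || substr(barcode, 1L, 2L) != "AC" ||
      !is_acgt(barcode))
    stop("barcode must be a 10-nt ACGT string starting with 'AC'")
  if (nchar(scaffold) != 82L)
    stop("scaffold must be 82 nt to preserve the 170-nt oligo layout, got ",
         nchar(scaffold))
  surrogate27 <- toupper(paste0(site$protospacer, site$pam, site$downstream4))
  if (nchar(surrogate27) != 27L)
    stop("surrogate region must be 27 nt (20 protospacer + 3 PAM + 4 downstream)")
  surrogate37 <- paste0(barcode, surrogate27)

  internal <- paste0(OLIGO_LINKER5, OLIGO_G, spacer, toupper(scaffold),
                     surrogate37, OLIGO_LINKER3)
  if (has_bsmbi(internal))
    stop("construct rejected (BsmBI): internal BsmBI recognition site in ",
         "spacer/scaffold/surrogate37 for site ", site$site_id)

  oligo <- paste0(OLIGO_FLANK5, BSMBI_SITE, internal, BSMBI_SITE, OLIGO_FLANK3)
  stopifnot(nchar(oligo) == 170L)

  data.frame(construct_id = paste0("C_", site$site_id),
             guide_id = guide$guide_id, site_id = site$site_id,
             chrom = site$chrom %||% NA_character_,
             start = site$start %||% NA_integer_,
             end = site$end %||% NA_integer_,
             strand = site$strand %||% NA_character_,
             n_mismatches = site$n_mismatches %||% NA_integer_,
             mismatches = site$mismatches %||% "",
             spacer = spacer, barcode = barcode,
             surrogate27 = surrogate27, surrogate37 = surrogate37,
             oligo = oligo, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Design a full surrogate library
#'
#' For each guide: enumerate candidate off-target sites, optionally add the
#' guide's perfect-match sites, assign library-wide unique barcodes, and
#' assemble oligos. Sites whose sequence would introduce an internal BsmBI
#' site are dropped and tallied.
#'
#' @param genome FASTA path / named character vector / DNAStringSet.
#' @param guides data.frame with `guide_id`, `spacer` (see [read_guides()]).
#' @param max_mismatches Maximum mismatches for off-target enumeration.
#' @param seed Integer seed for barcode assignment.
#' @param min_hamming Barcode distance mode (see [assign_barcodes()]).
#' @param scaffold 82-nt scaffold.
#' @return List with `manifest` (constructs data.frame), `n_rejected_bsmbi`,
#'   `n_skipped_ambiguous`.
#' @export
design_library <- function(genome, guides, max_mismatches = 4L, seed = 1L,
                           min_hamming = 1L, scaffold = surro_scaffold()) {
  all_sites <- list()
  n_ambig <- 0L
  for (i in seq_len(nrow(guides))) {
    s <- enumerate_offtargets(genome, guides[i, ], max_mismatches)
    n_ambig <- n_ambig + attr(s, "n_skipped_ambiguous")
    all_sites[[i]] <- s
  }
  sites <- do.call(rbind, all_sites)
  if (is.null(sites) || nrow(sites) == 0L)
    stop("no candidate sites found for any guide")

  bsmbi_bad <- has_bsmbi(paste0(sites$protospacer, sites$pam, sites$downstream4))
  n_rej <- sum(bsmbi_bad)
  sites <- sites[!bsmbi_bad, , drop = FALSE]

  barcodes <- assign_barcodes(sites, seed, min_hamming, scaffold)
  spmap <- stats::setNames(guides$spacer, guides$guide_id)
  rows <- vector("list", nrow(sites))
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    g <- list(guide_id = sites$guide_id[i], spacer = spmap[[sites$guide_id[i]]])
    r <- try(assemble_oligo(g, sites[i, ], barcodes[[sites$site_id[i]]],
                            scaffold), silent = TRUE)
    if (inherits(r, "try-error")) { n_rej <- n_rej + 1L; next }
    rows[[i]] <- r
    keep[i] <- TRUE
  }
  manifest <- do.call(rbind, rows[keep])
  rownames(manifest) <- NULL
  list(manifest = manifest, n_rejected_bsmbi = n_rej,
       n_skipped_ambiguous = n_ambig)
}

#' Export a designed library
#'
#' Writes the oligo FASTA, the construct manifest TSV (coordinates 0-based
#' half-open) and a per-guide mismatch-count spectrum TSV.
#'
#' @param lib Result of [design_library()], or a bare manifest data.frame.
#' @param dir Output directory (created if missing).
#' @return Invisibly, named paths of the three files.
#' @export
export_library <- function(lib, dir) {
  manifest <- if (is.data.frame(lib)) lib else lib$manifest
  if (is.null(manifest) || nrow(manifest) == 0L) stop("empty library")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  fa <- file.path(dir, "oligos.fasta")
  seqs <- Biostrings::DNAStringSet(manifest$oligo)
  names(seqs) <- manifest$construct_id
  Biostrings::writeXStringSet(seqs, fa)

  mf <- file.path(dir, "manifest.tsv")
  write_tsv(manifest, mf)

  spectrum <- as.data.frame(table(guide_id = manifest$guide_id,
                                  n_mismatches = manifest$n_mismatches),
                            stringsAsFactors = FALSE)
  spectrum <- spectrum[spectrum$Freq > 0L, ]
  names(spectrum)[3L] <- "n_sites"
  sp <- file.path(dir, "mismatch_spectrum.tsv")
  write_tsv(spectrum[order(spectrum$guide_id, spectrum$n_mismatches), ], sp)

  invisible(c(fasta = fa, manifest = mf, spectrum = sp))
}

#' Read a library manifest
#'
#' @param path Manifest TSV written by [export_library()].
#' @return Constructs data.frame.
#' @export
read_manifest <- function(path) {
  m <- read_tsv(path)
  need <- c("construct_id", "guide_id", "barcode", "surrogate27", "spacer")
  if (!all(need %in% names(m)))
    stop("manifest missing columns: ",
         paste(setdiff(need, names(m)), collapse = ", "))
  if (anyDuplicated(m$barcode)) stop("manifest barcodes are not unique")
  m
}
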