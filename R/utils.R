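# sequence helpers shared across modules

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings (ACGTN and IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_acgt <- function(x) !grepl("[^ACGT]", x)

check_spacer <- function(spacer) {
  if (length(spacer) != 1L || is.na(spacer))
    stop("spacer must be a single DNA string")
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L)
    stop("spacer must be exactly 20 nt, got ", nchar(spacer))
  if (!is_acgt(spacer))
    stop("spacer contains non-ACGT base: ", spacer)
  spacer
}

has_bsmbi <- function(x) {
  grepl(BSMBI_SITE, x, fixed = TRUE) | grepl(BSMBI_SITE_RC, x, fixed = TRUE)
}

# mismatch annotation string "pos:grna>proto;..." used in manifests
format_mismatches <- function(positions, grna_bases, proto_bases) {
  if (length(positions) == 0L) return("")
  paste(sprintf("%d:%s>%s", positions, grna_bases, proto_bases), collapse = ";")
}

#' Parse a manifest mismatch string into a data.frame
#'
#' @param mm Single mismatch string, e.g. `"3:G>A;17:C>T"` (empty for a
#'   perfect match).
#' @return data.frame with columns `position`, `grna_base`, `proto_base`.
#' @export
parse_mismatches <- function(mm) {
  if (is.na(mm) || mm == "") {
    return(data.frame(position = integer(), grna_base = character(),
                      proto_base = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(mm, ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^(\\d+):([ACGT])>([ACGT])$", parts))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("malformed mismatch token: ", parts[bad][1L])
  data.frame(position = as.integer(vapply(m, `[`, "", 2L)),
             grna_base = vapply(m, `[`, "", 3L),
             proto_base = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write ", path, ": ", attr(ok, "condition")$message)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA, comment.char = "#")
}

# draw n random DNA bases as one string each
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
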