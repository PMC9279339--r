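#' Construct layout constants
#'
#' The surrogate oligo is a fixed 170-nt cassette:
#' `acca` (4) + BsmBI site `cgtctc` (6) + Golden-Gate linker `aCACC` (5) +
#' transcription-initiating `g` (1) + spacer (20) + gRNA scaffold (82) +
#' surrogate37 (37 = 10-nt barcode + 20-nt protospacer + 3-nt PAM + 4-nt
#' downstream) + linker `GTTTg` (5) + BsmBI site (6) + `acgg` (4).
#' All sequences are stored uppercase; the lowercase in the layout notation
#' above is cosmetic (synthesis-order casing).
#'
#' @name oligo-layout
#' @keywords internal
NULL

# BsmBI recognition site and its reverse complement
BSMBI_SITE <- "CGTCTC"
BSMBI_SITE_RC <- "GAGACG"

OLIGO_FLANK5 <- "ACCA"
OLIGO_LINKER5 <- "ACACC"
OLIGO_G <- "G"
OLIGO_LINKER3 <- "GTTTG"
OLIGO_FLANK3 <- "ACGG"

# canonical SpCas9 sgRNA scaffold (76 nt) + Pol III terminator T6 = 82 nt.
# The published cassette arithmetic requires an 82-nt scaffold; the exact
# sequence is configurable everywhere it is used.
SCAFFOLD_SPCAS9_82 <- paste0(
  "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC",
  "TTTTTT"
)

#' Default SpCas9 gRNA scaffold used in oligo assembly
#'
#' Returns the 82-nt scaffold placed between the spacer and the barcoded
#' surrogate region. Any replacement must keep the total oligo length at
#' 170 nt, i.e. must itself be 82 nt.
#'
#' @return A single uppercase DNA string of length 82.
#' @export
surro_scaffold <- function() SCAFFOLD_SPCAS9_82

#' Default statistical thresholds for site calling
#'
#' Thresholds of the site-calling recipe: BH-adjusted significance level,
#' minimum fold change, the indel-frequency split between low- and
#' high-indel significant sites, minimum clean reads per sample, minimum
#' supporting indel reads in the edited sample, the maximum tolerated
#' background indel frequency in the unedited (MOCK) sample used as a
#' bias filter, and the synthesis-quality cap on MOCK indel frequency.
#'
#' @return Named list: `alpha` (0.05), `min_fc` (2), `hiot_if` (3, percent),
#'   `min_total` (32 reads), `min_indel` (5 reads), `max_wt_if` (25, percent),
#'   `max_mock_if` (4, percent).
#' @export
surro_thresholds <- function() {
  list(alpha = 0.05, min_fc = 2, hiot_if = 3,
       min_total = 32, min_indel = 5, max_wt_if = 25, max_mock_if = 4)
}
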