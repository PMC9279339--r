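---
title: "Methods: design, counting and statistics behind surroseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, counting and statistics behind surroseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surroseq)
```

# The measurement model

A surrogate off-target library turns off-target (OT) validation into a
counting experiment. Each candidate OT of a guide is synthesised as a
27-nt surrogate region (20-nt protospacer + 3-nt NGG PAM + 4 nt
downstream) carried on a lentiviral construct together with the guide
itself, so that a cell receiving the construct expresses the gRNA and
exposes a private copy of the OT sequence to Cas9. Two cell populations
are sequenced: one expressing SpCas9 and an otherwise identical MOCK
population. For a construct with clean read total $T$ and indel reads
$I$, the indel frequency is

$$\mathrm{IF}\% = \frac{I}{T} \times 100,$$

and a site shows significantly detectable indels when a two-sided Fisher
exact test on the table

|          | indel | no indel |
|----------|-------|----------|
| SpCas9   | $I_C$ | $T_C - I_C$ |
| MOCK     | $I_M$ | $T_M - I_M$ |

gives a Benjamini–Hochberg-adjusted $p < 0.05$ together with a fold
change $\mathrm{FC} = \mathrm{IF}_C / \mathrm{IF}_M \ge 2$. The paired
design is the point: PCR and sequencing introduce spurious indels at the
percent level, and only the MOCK contrast separates nuclease editing from
that background. Significant sites are reported as LIOT
($\mathrm{IF}_C < 3\%$) or HIOT ($\ge 3\%$).

## Why each filter exists

Counting is preceded by three read-level filters, applied identically to
both samples:

1. **Structural filter.** The invariant backbone — `g` + spacer(20) +
   scaffold(82) + barcode(10) at the front, the `GTTT` linker at the back
   — must match exactly. Reads damaged by synthesis, PCR or sequencing
   anywhere outside the surrogate region are removed before they can
   distort either the numerator or the denominator. The segment between
   barcode and linker is the observed surrogate region; its length may
   legitimately differ from 27 by the indel being measured.

2. **Pseudo-edit subtraction.** Any non-reference allele sequence seen in
   the MOCK sample of a construct is a synthesis/PCR artefact carried by
   the oligo pool itself (both samples derive from the same pool), so its
   reads are removed from the SpCas9 allele table — from indel and total
   counts alike. After removal the denominator is the valid molecules of
   the construct, which is also the denominator the editing-rate estimate
   refers to. The subtraction is by whole allele class; an artefact whose
   sequence coincides with a genuine nuclease product would remove real
   edits too, which is an accepted cost of the rule (see Limitations).

3. **Positional 1-bp filter.** Spurious sequencing/PCR indels are
   overwhelmingly 1 bp and occur anywhere, whereas Cas9 cuts bluntly
   between N17 and N18 (3 bp upstream of the PAM) and its indels cluster
   there. A read whose only indel content is 1-bp events lying entirely
   within N1–N14 or N22–N27 is therefore reclassified as non-indel (kept
   in the clean total, so denominators stay stable; `full_removal = TRUE`
   discards such reads instead). Events of length ≥ 2, and any event
   overlapping N15–N21, count as edits.

# Numerical and convention choices

**Alignment.** Observed surrogate segments are aligned to the 27-nt
reference by global Needleman–Wunsch with affine gaps (match +2, mismatch
−4, gap open −6, gap extend −1 per base; a length-$k$ gap scores
$-6 - k$). The scores are package defaults, chosen so one longer gap beats
several scattered 1-bp gaps — the shape nuclease indels actually take —
and are configurable. Tied optima take the **leftmost** gap placement,
which makes calls deterministic and defines behaviour at the window
boundaries: a 1-bp deletion inside a homopolymer is attributed to the
run's first position, and an insertion "at Nk" follows reference base $k$.
A 1-bp event exactly at the N14/N15 or N21/N22 boundary is decided by the
position of the deleted base (or insertion anchor) of that canonical
representation. The consequence — a 1-bp insertion at the cut that
left-aligns through a homopolymer crossing N14/N15 is classified as
background — is a property of the filter definition, not an
implementation accident, and the simulator's truth bookkeeping accounts
for it (`n_detectable_reads`).

**Fisher test.** The two-sided p-value sums hypergeometric probabilities
of all tables (margins fixed) whose probability does not exceed the
observed table's, with ties compared at a relative tolerance of
$10^{-12}$. Degenerate all-zero tables give $p = 1$. The implementation
is the direct summation; `stats::fisher.test` serves as an independent
cross-check in the test suite.

**BH family.** Adjustment is applied jointly across all sites of a run
that pass the read-quality and synthesis filters. Sites demoted for
having fewer than 5 supporting indel reads are still tested and remain in
the family (they appear as NSOT); this matches the use of the indel-read
threshold as a significance gate rather than an exclusion.

**Fold change at zero MOCK indels.** $\mathrm{IF}_M = 0$ makes FC
undefined; the default applies a 0.5-read continuity correction to the
MOCK numerator only ($\mathrm{FC} = \mathrm{IF}_C / (0.5/T_M \times 100)$),
which preserves the FC ≥ 2 decision while avoiding infinities.
`fc_mode = "raw"` reports infinite FC instead.

**Read-quality interpretation.** The low-coverage filter requires
total ≥ 32 clean reads in *each* sample — the stricter reading, chosen
because a site unquantifiable in either sample supports no paired
contrast. The MOCK-IF bias filter (≤ 25%) and the synthesis-quality
filter (≤ 4%) are independent switches; both default on, in which case
the 4% cap binds.

**Scaffold constant.** The 170-nt oligo arithmetic requires an 82-nt
scaffold between spacer and surrogate cassette. The package ships the
canonical 76-nt SpCas9 sgRNA scaffold extended by the `TTTTTT` Pol III
terminator as its default and treats the sequence as configurable; all
length checks reference the configured value.

**Barcodes.** `AC` + 8 random bases, exact-match unique by default.
Because the structural filter requires a byte-perfect barcode, exact
matching in demultiplexing loses no reads that could ever be counted — a
read with a mutated barcode could not pass filtering anyway. An optional
minimum-pairwise-Hamming mode (`min_hamming`) is provided for users who
want error-robust codes; barcodes that would create a BsmBI site in
context are redrawn.

**Coordinates.** Genomic coordinates are 0-based half-open everywhere
(internally and in manifests); spacer positions are the field's N1
(PAM-distal) … N20 (PAM-proximal) convention, surrogate positions
N1…N27. Mismatch types are ordered (spacer base, protospacer base on the
non-target strand), so `GA` denotes the rG:dT wobble-forming mismatch.

**Annotation precedence.** 5'UTR/3'UTR > exon > intron > upstream2kb /
downstream2kb > IGR, with alphabetical gene id as the deterministic
tie-break. UTRs outrank the generic exon because they are the more
specific label; a site is its 20-nt protospacer interval and any base of
overlap suffices. Whether the assay's cut point or the whole protospacer
should anchor annotation is not observable from the data; the interval
choice is the more conservative.

**PAM policy.** NGG only. Alternative PAMs (NAG etc.) are cleavable at
lower rates but are not part of the library design this package targets;
the scanner is the single place a different policy would plug in.

# What the simulator emulates — and what it does not

`simulate_reads()` draws, per construct: edited molecules at the
construct's true rate (deletions with geometric lengths and insertions at
the N17/N18 cut), a fixed synthesis-artefact allele present in *both*
samples for a configurable fraction of constructs (a 2-bp deletion in the
PAM-distal half — an indel-like artefact that does not coincide with the
nuclease's cut-centred allele space), per-base substitution errors
(default 0.1%), a per-read spurious 1-bp indel process (default 1%, the
PCR/deep-sequencing background level the paired design exists to cancel),
and optional fold-dropout of constructs in the SpCas9 sample. Reads are
150-bp pairs over the 170-nt cassette plus 25-nt constant flanks, so
mates overlap by ≈ 80 bp. All randomness flows from one seed; identical
configurations produce byte-identical outputs.

Deliberately **not** modelled: chromatin and epigenetic position effects
on the integrated reporter (a known limitation of surrogate assays
generally), guide-sequence-dependent indel spectra, quality-score decay
along reads, DNA/RNA-bulge off-targets, and lentiviral copy-number
variation beyond the dropout flag. Passing tests therefore demonstrate
that the pipeline recovers what the reporter measures — indels at the
surrogate sequence — not that surrogate measurements equal endogenous
editing rates.

`simulate_site_counts()` is the counts-level companion used for
statistical calibration at scale: MOCK indels are
$\mathrm{Bin}(d, b)$ and SpCas9 indels $\mathrm{Bin}(d, t + (1-t)b)$ with
shared background $b$, skipping read-level processing entirely.

# Validation strategy and problem sizes

The test suite checks each stage against an independent oracle: the
scanner against an exhaustive window-by-window brute force (genomes up to
50 kb, planted variants, both strands), the Fisher p-value against direct
summation over all 2x2 tables with margins ≤ 30 and against
`fisher.test`, BH against the definitional step-up formula, the aligner
against enumeration of single-indel placements and an independent R
implementation of the affine DP score, and hypergeometric tails against
direct summation. Statistical behaviour is checked under the study
conditions: null calibration at 500 sites x depth 1000 x 20 seeds
(counts level; significant fraction ≈ 0 because significance requires
both FC ≥ 2 and adjusted p < 0.05 against a matched background), and
read-level parameter recovery at depth 2000 over true rates
{0.5, 3, 10, 50, 95}%, judged against the simulator's realized,
filter-visible truth since at that depth the binomial draw alone moves
the nominal rate by about a point at intermediate frequencies. These
sizes keep the full suite near a minute on one core while leaving every
statistical check comfortably powered.

# Known limitations

* Whole-allele pseudo-edit subtraction can remove genuine nuclease
  alleles whose sequence happens to coincide with a MOCK artefact or a
  MOCK sequencing-indel allele (most likely for 1-bp deletions at the
  cut when sequencing depth makes rare background alleles visible). This
  biases IF slightly downward at high editing rates; it is the stated
  rule and is kept.
* The positional filter cannot see real 1-bp insertions that left-align
  out of N15–N21 through homopolymers; such edits are counted as
  background by definition.
* The scanner enumerates substitution-only neighbours; bulge off-targets
  are out of scope.
* Barcode collision pressure rises with library size; the default
  exact-uniqueness mode supports up to $4^8$ constructs but provides no
  error correction.
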