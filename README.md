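# surroseq

Targeted, high-throughput evaluation of CRISPR-Cas9 off-target activity
with pooled barcoded surrogate reporter libraries.

## The problem

Therapeutic use of SpCas9 requires knowing whether a guide RNA (gRNA) cuts
not only its intended target but also similar genomic sites. Genome-wide
screens (GUIDE-seq, CIRCLE-seq) nominate candidate off-targets (OTs);
validating hundreds to thousands of them in cells, each at deep coverage,
is the bottleneck. A surrogate-library assay solves this: every candidate
OT is synthesised as a short reporter cassette on a lentiviral construct,
integrated into cells with and without Cas9, and the indels introduced at
each surrogate site are read out by amplicon sequencing. Because deletions
can erase the few bases that distinguish one OT from another, each
construct carries a 10-nt barcode that assigns reads to constructs
unambiguously.

`surroseq` implements the complete computational workflow around such
libraries:

* **Library design** — enumerate every genomic 20-mer + NGG window within
  a mismatch budget of each spacer, assign `AC`-prefixed barcodes, and
  assemble the 170-nt synthesis oligo:

  ```
  ACCA + CGTCTC + ACACC + g + spacer(20) + scaffold(82)
       + [barcode(10) + protospacer(20) + PAM(3) + downstream(4)] = surrogate37
       + GTTTG + CGTCTC + ACGG                                   = 170 nt
  ```

  Constructs with internal BsmBI sites (`CGTCTC`/`GAGACG`) are rejected
  (Golden Gate assembly requires exactly the two flanking sites).

* **Read processing** — merge read pairs by overlap consensus, demultiplex
  by exact barcode behind the constant scaffold anchor, require an intact
  backbone (`g` + spacer + scaffold + barcode ... `GTTT`), call indels in
  the 27-nt surrogate region by affine-gap global alignment (leftmost tie
  placement), reclassify background 1-bp indels outside N15–N21, and
  subtract pseudo-editing alleles observed in the unedited (MOCK) sample.

* **Site calling** — per site, indel frequency
  `IF% = indel reads / total reads x 100` in each sample; a two-sided
  Fisher exact test on the 2x2 (indel / no-indel) x (SpCas9 / MOCK) table;
  Benjamini–Hochberg correction across sites; significance requires
  `adj. p < 0.05` and fold change `FC = IF(SpCas9)/IF(MOCK) >= 2`.
  Significant sites split into LIOT (`IF < 3%`) and HIOT (`IF >= 3%`);
  quality filters (total reads >= 32 per sample, >= 5 supporting indel
  reads, MOCK IF <= 25% bias filter, MOCK IF <= 4% synthesis filter) and
  reads-per-million enrichment/depletion flags (ratio >= 2) are applied.

* **Context analysis** — mismatch position (N1 PAM-distal … N20
  PAM-proximal) and mismatch type (12 ordered spacer→protospacer types,
  e.g. the rG:dT wobble-producing GA type) frequency profiles, with
  hypergeometric over/under-representation tests against an ALL or NSOT
  background, and spacer GC% versus on-target efficiency.

* **Annotation** — one deterministic category per site
  (5'UTR/3'UTR > exon > intron > upstream2kb/downstream2kb > IGR) from a
  GFF3 gene model, with optional user gene-list intersection.

* **Simulation** — fully ground-truthed synthetic genomes, libraries and
  paired-end FASTQ (nuclease indels at the cut between N17/N18, synthesis
  artefact alleles shared by both samples, sequencing substitution and
  spurious 1-bp indel errors, construct dropout), so every stage can be
  scored against known truth.

## Worked example

Simulate a small two-guide experiment, design its library, process the
reads and call sites:

```r
library(surroseq)

cfg <- sim_config(seed = 42, genome_length = 6000, n_guides = 2,
                  planted = c("0" = 1, "2" = 2, "3" = 1),
                  depth = 400, true_if = c(0, 1, 8, 45))
gg  <- simulate_genome_and_guides(cfg)
lib <- design_library(gg$genome, gg$guides, max_mismatches = 4, seed = 42)
rd  <- simulate_reads(lib$manifest, cfg, "example_run")
tc  <- tabulate_counts(lib$manifest,
                       mock = list(r1 = rd$mock_r1, r2 = rd$mock_r2),
                       cas9 = list(r1 = rd$cas9_r1, r2 = rd$cas9_r2))
calls <- call_sites(tc$counts)
calls[, c("construct_id", "if_mock", "if_cas9", "adj_p", "fold_change", "call")]
```

```
  construct_id if_mock if_cas9    adj_p fold_change call
1  C_G01_OT001   0.000   0.000 1.00e+00        0.00 NSOT
2  C_G01_OT002   0.000   1.130 1.99e-01        7.71 NSOT
3  C_G01_OT003   0.000   7.692 1.20e-08       54.77 HIOT
4  C_G01_OT004   0.000  44.444 1.31e-57      320.89 HIOT
5  C_G02_OT001   0.000   0.000 1.00e+00        0.00 NSOT
6  C_G02_OT002   0.000   0.829 3.32e-01        5.82 NSOT
7  C_G02_OT003   0.288   8.696 1.53e-08       30.17 HIOT
8  C_G02_OT004   0.000  40.058 1.65e-49        279.61 HIOT
```

Per guide, the four constructs were simulated at true editing rates 0, 1,
8 and 45%. The unedited constructs and the 1%-edited constructs (whose
400-read depth leaves too few indel reads for significance) come out NSOT;
the 8% and 45% constructs are significant with high indel frequency
(HIOT), with estimated `if_cas9` close to the simulated rates and MOCK
background near zero.

The same stages are available from the shell:

```sh
Rscript exec/surroseq.R simulate --seed 5 --out sim/
Rscript exec/surroseq.R count --manifest sim/manifest.tsv \
    --mock_r1 sim/mock_R1.fastq.gz --mock_r2 sim/mock_R2.fastq.gz \
    --cas9_r1 sim/cas9_R1.fastq.gz --cas9_r2 sim/cas9_R2.fastq.gz --out cnt/
Rscript exec/surroseq.R call --counts cnt/counts.tsv --out calls/
```

Every stage writes a `run_<stage>.yaml` manifest (package version,
effective configuration, input checksums) next to its outputs.

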