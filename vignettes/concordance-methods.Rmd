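---
title: "Scoring genomic concordance between tumours and patient-derived models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genomic concordance between tumours and patient-derived models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxconcord)
```

## The problem

Patient-derived xenografts (PDX) and organoids (PDO) are only useful as
preclinical avatars if they genuinely recapitulate the genome of the donor
tumour. `pdxconcord` quantifies that fidelity at three levels of genomic
complexity — simple somatic mutations (SSM), structural variants (SV) and
copy-number (CN) states — producing scores on a common 0–1 scale where 0
means no aberration of the tumour is recovered in the model and 1 means all
of them are. A trio (tumour + PDX + PDO) is always analysed as three
pairwise comparisons, tumour–PDX, tumour–PDO and PDX–PDO, so that the three
levels and the three relationships can be inspected independently.

## Mutation concordance

Two calls denote the same variant iff they share chromosome, 1-based
position, reference and alternate allele. The annotation category (e.g.
`Missense_Mutation`, `lincRNA`) and the read depths are deliberately *not*
part of identity: a relabelled or re-covered variant is still the same
substitution. Indels match on their exact ref/alt strings — the strictest
reading of "same substitution", stated once here and enforced by tests.

For each category $M$ present in either sample,

$$J_M = \frac{C_M}{T_M + P_M - C_M}$$

with $T_M$, $P_M$ the distinct variant counts in tumour and model and
$C_M$ the identical variants annotated $M$ in both. Duplicated keys within
one sample collapse before counting — the Jaccard index is a set statistic.
An "All Mutations" row pools every category. A category absent from both
samples has an empty denominator: it is reported `NA`, never 0, because the
absence of a mutation class is not evidence of discordance. Variant-allele
fractions (`alt/(alt+ref)` depths) are extracted for descriptive plots only
and feed no score.

## Structural-variant concordance

Events are breakpoint pairs in one of four categories: DEL, DUP, INV
(intra-chromosomal, size = distance between breakpoints) and TRA
(inter-chromosomal, size fixed at 1 base). Two events are identical iff
both breakpoints' chromosomes and positions and the category agree;
a `tolerance` argument (default 0 bp, i.e. exact) can relax positional
equality for jittery caller output, with greedy first-match-in-position
order consumption so no event matches twice.

Per chromosome $V$, the size-weighted Jaccard is
$J_V = C_V / (T_V + P_V - C_V)$ over the summed event sizes, and the
overall score is $S^c = P/(P+N)$ where $P$ counts chromosomes with
$J_V \ge 0.6$ (inclusive) and $N$ those below; chromosomes with no event
in either sample enter neither. Per-category scores $J_K$ use the same
base-sum formula restricted to one category, genome-wide or per
chromosome.

Weighted event counts give each intra-chromosomal event 1 on its
chromosome and each translocation 0.5 on each side; a chromosome is
flagged *elevated* when both samples carry ≥ 5 weighted events (clustered
rearrangements, suggestive of chromothripsis) and *count-discordant* when
the counts differ by ≥ 10. The flags use weighted counts because that is
the only counting rule defined; the thresholds are configuration values.

Two conventions were genuinely open and are therefore explicit, tested
decisions:

* **TRA size attribution per chromosome.** The unit size of a
  translocation is credited to *both* involved chromosomes' base sums,
  consistent in spirit with the 0.5/0.5 count rule while preserving
  "size = 1" within each chromosome's ledger.
* **Flag counts.** The ≥5/≥10 flags evaluate weighted (0.5-granular)
  counts, so `t = 4.5` does not reach the elevated threshold.

## Copy-number concordance

Segments carry `imean`, an average integer copy number; each sample also
has a genome-average ploidy. Before comparison every defined `imean` is
divided by its sample's ploidy, so whole-genome doubling (a tetraploid
PDX over a diploid tumour) does not masquerade as global discordance.
The two segmentations are partitioned into maximal constant-value blocks
(IRanges `disjoin` + overlap lookup, the in-memory equivalent of a
bedtools intersection), and over blocks:
$T$ = bases where the tumour has a defined rescaled state, $X$ likewise
for the model, $C$ = bases where either does, and $I$ = bases where both
do and the states differ by at most 0.25. The score is

$$G = \frac{I}{T + X - C}.$$

Because $T + X - C$ is exactly the co-defined footprint, $G$ is the
fraction of co-defined bases in agreement; this literal reading of the
formula is the default, and bases covered by only one sample dilute
nothing (they are still reported in $T$, $X$, $C$ for transparency). A
`denominator = "union"` option scores $I/C$ instead for users who want
single-sample bases to count against the pair. The 0.25 tolerance applies
to rescaled values — the rescaling step precedes the identity rule — and
both the tolerance and the order are configurable. The genome-wide score
aggregates numerators and denominators across chromosomes; it is not the
mean of per-chromosome scores. Pairs whose ploidies are neither
comparable nor a clean doubling (10% relative tolerance on the ratio) are
flagged `ambiguous` rather than silently scored away — mirroring studies
that exclude samples whose ploidy cannot be fixed unambiguously — but
scoring still proceeds on rescaled values so the user sees both the flag
and the number.

Degenerate inputs are resolved deterministically: overlapping segments
within one sample are an input defect and are truncated at the later
segment's start (warned, never averaged); segments with missing `imean`
stay in the file but contribute no defined bases.

## What the synthetic generator emulates

The matched call sets this package was validated on are simulated, with
ground truth written at generation time by straight-line arithmetic kept
independent of the scoring code. The default scenario — the package's
reference study conditions — is one patient trio:

* **SSM:** 700 shared, 300 tumour-only, 300 model-only variants at
  distinct sites, categories drawn from a 12-label vocabulary of
  annotator-style classes (missense, nonsense, silent, splice-site,
  intron, UTRs, flank, intergenic, lincRNA, RNA, frameshift). The
  vocabulary is a package default chosen to span functional and
  non-functional classes; real annotators emit more labels. The overall
  tumour–PDX Jaccard is 700/1300 ≈ 0.538 by construction.
* **SV:** five chromosomes with mixed shared/private events of 50 kb–1 Mb
  plus a few translocations; chr8 carries six shared events confined to a
  5 Mb window, so both samples show the elevated flag and the chromosome
  scores $J_V = 1$ — a chromothripsis-like cluster transmitted intact.
* **CN:** ~20 Mb segments over a 24-chromosome, ~3.1 Gb genome; the PDX
  is whole-genome doubled (ploidy factor 2) with rescaled states equal to
  the tumour's up to a jitter bounded by half the tolerance on 70% of
  segments and offset by twice the tolerance on the remaining 30%, so the
  expected ploidy-corrected agreement is ≈ 0.7 and the raw (uncorrected)
  profiles disagree everywhere.
* **Trio:** the organoid is derived by perturbing the *PDX* (drop 10% of
  its mutations, add 10% new; drop 15% / add 10% of SV events; re-jitter
  the CN profile with a 10% discordant fraction at equal ploidy). This
  reproduces the expected ordering — PDX–PDO concordance exceeds
  tumour–PDO concordance — without hand-setting any score.
* **Hypermutator:** an optional mismatch-repair-deficient-like flag
  multiplies all mutation counts by 10 while leaving SV and CN behaviour
  untouched; the Jaccard ratios are unchanged because both samples scale
  together.

What the generator does *not* emulate: sequencing reads and coverage,
mutational signatures, subclonal structure and clonal selection across
passages, caller-specific breakpoint jitter (shared events have exactly
equal breakpoints, which is why the default match tolerance of 0 recovers
them), and segmentation disagreement between samples (both samples share
one segment grid, so CN truth is exact at segment resolution). Passing
tests therefore demonstrate that the statistics are computed correctly
and recover known structure, not that any particular biological cohort
will score well.

## Numerical choices

* All Jaccard/agreement scores return `NA` on an empty denominator —
  absence of evidence is reported as missing, never as 0 or 1.
* Score thresholds are inclusive (`>= 0.6` is concordant; a difference of
  exactly 0.25 agrees), matching each rule's definition.
* Event sizes, base sums and block lengths are integer-valued doubles, so
  sums and ratios are exact and the test suite can assert exact equality
  against brute-force oracles rather than approximate closeness.
* Problem sizes used in validation: 200 random mutation pairs (≤ 100
  calls), 200 random SV pairs (≤ 30 events), 50 random segmentations over
  a 10 kb two-chromosome toy genome scanned per base, and the full
  default trio (1,300 distinct variants, ~20 SV events, ~150 CN segments
  over 3.1 Gb). These sizes keep the whole suite and the validation
  script to a few minutes on one CPU while exercising every rule,
  including the TRA and flag edge cases.

## A worked example

```{r example, eval = FALSE}
library(pdxconcord)

dir <- tempfile()
trio <- simulate_trio(pair_scenario(seed = 1), out_dir = dir)
report <- run_patient(read_manifest(file.path(dir, "manifest.yaml"))[[1]])

report$pair_results$TvsX$ssm$overall$jaccard   # 0.5384615 = 700/1300
report$pair_results$TvsX$sv$overall$score      # fraction of chromosomes >= 0.6
subset(report$pair_results$TvsX$cn$table, scope == "genome")$score
report$pair_results$TvsX$cn$ploidy_qc          # "doubled"
write_report_tables(report, file.path(dir, "report"))
```

## Known limitations

* Breakpoint matching at tolerance 0 is exact; real caller output needs a
  small tolerance, and the greedy matcher is order-deterministic but not
  globally optimal when tolerant matching creates ambiguity.
* Copy-number concordance is allele-agnostic (total copy state only) and
  applies no sex-chromosome-aware ploidy adjustment.
* The clustered-rearrangement flag is a count heuristic, not a formal
  chromothripsis test.
* Scores on real cohorts depend on the upstream callers and filters;
  this package consumes calls, it does not make them.
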