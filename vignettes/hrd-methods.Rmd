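---
title: "Methods: three routes to a homologous-recombination-deficiency call"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three routes to a homologous-recombination-deficiency call}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdkit)
library(dplyr)
```

Tumors that have lost homologous recombination repair (HRD) respond
preferentially to platinum and PARP inhibitors. hrdkit implements three
complementary ways of calling HRD from routine tumor material, plus the
statistics needed to compare such assays against a reference test and to
relate the calls to clinical outcome. Everything runs on tabular inputs
(tibbles in, tibbles out) and every simulated input carries known ground
truth, so each engine can be validated in a closed loop.

## Genomic-scar scoring

Defective homologous recombination leaves permanent copy-number "scars".
The genomic-instability (GI) score is the unweighted sum of three counts
computed from an allele-specific segment profile (`total_cn`, `minor_cn`
per segment, purity/ploidy-adjusted upstream):

* **LOH** — runs of segments with minor allele copy number 0 (and total
  ≥ 1) longer than 15 Mb that do not span a whole chromosome;
* **TAI** — runs of allelic imbalance (minor ≠ total − minor) that touch
  a chromosome end, do not cross the centromere, and exceed 11 Mb;
* **LST** — junctions between ≥ 10 Mb segments with different
  allele-specific states, per chromosome arm, after smoothing away
  segments shorter than 3 Mb.

The source study does not restate these three definitions (it cites the
established scar literature), so the lengths above are the conventional
published values and every one of them is a `scar_config()` field;
alternative published variants can be configured rather than forked.
Three further conventions are ours and deliberately explicit:

* allele copy numbers are integerized by rounding half away from zero
  before any state comparison (adjusted inputs are rarely exact
  integers);
* segments separated by an assembly-style gap shorter than `gap_tol`
  (default 1 Mb) belong to the same run — real profiles have small holes
  at unmappable regions;
* run length is the sum of covered bases, not the end-to-start span, so
  gap-merging can never inflate a run past its threshold.

A sample is called HRD when its GI score strictly exceeds 42. The study
phrases the rule as ">42 deficient, <42 proficient", leaving 42 itself
undefined; we implement the strict inequality (so 42 is HRP) and emit a
warning whenever a score lands exactly on the threshold, rather than
guess the intent. A proficient-by-score sample carrying a pathogenic
BRCA1/2 variant is overridden to HRD (`rationale = "brca_override"`).
Whether the study's score was the plain unweighted sum of the three
components is also not disclosed; the unweighted sum is implemented. The
threshold itself can be re-derived with `calibrate_threshold()`, the
nearest-rank fifth percentile of GI scores in a BRCA-deficient reference
set (at least 20 scores, or the percentile is too unstable to use).

Sex chromosomes are excluded by default simply by using the autosome-only
`default_build()`; minor-allele semantics differ on X/Y and the scar
literature is autosomal.

**Validation.** The engine is checked against an oracle that materializes
per-base state vectors at 0.1 Mb resolution and applies the definitions
literally (`tests/testthat/helper-oracle.R`), on hundreds of random
profiles; and `gen_profile()` constructs profiles whose scar counts equal
requested targets exactly, which the engine must recover 50/50. The
oracle comparisons run on a build whose coordinates are rounded to the
0.1 Mb grid so the per-base discretization is exact.

## Shallow-WGS LGA scoring

The second route needs only low-coverage (0.4–0.8×) whole-genome
sequencing. Binned read counts are converted to log2 ratios against the
sample median, segmented, and scanned for large-scale genomic
alterations (LGAs): junctions between ≥ 10 Mb segments whose log2 ratios
differ by ≥ 0.2, per arm, after 3 Mb smoothing.

The study ran this on six "integrated models encompassing variable
sliding windows spanning 5–1000 kb" and called HRD by the agreement of
the six segmentation profiles — but published neither the exact window
sizes, nor the agreement statistic, nor the cutoff, delegating the
computation to external scripts. Our implementation therefore makes
every piece explicit and recalibratable, as declared stand-ins:

* windows default to the geometric ladder {5, 10, 50, 100, 500, 1000} kb;
* segmentation is exact penalized least-squares changepoint detection.
  Two compiled kernels compute the identical optimum: classic PELT and a
  functional-pruning variant (FPOP) that stays fast when chromosomes
  contain few changepoints; the package uses FPOP and the test suite
  proves them equal. The per-changepoint penalty is
  `penalty_factor · σ² · log n` (default factor 3) with σ estimated
  robustly from the median absolute first difference of the log2
  ratios — so the fit is scale-invariant and deterministic;
* each window's model votes HRD when its LGA count reaches the cutoff
  (default 20); the consensus is the majority label if at least 4 of 6
  models agree, otherwise Inconclusive. BRCA status is never consulted.
* `calibrate_lga_cutoff()` re-derives the cutoff from a labeled
  development set (the study used 30 HRD + 30 HRP samples) by maximizing
  Youden's J over integer thresholds, ties broken toward specificity.

A 0.5 pseudo-count guards `log2` against empty bins; samples whose bins
cover less than 80% of the genome fail with `insufficient coverage`
rather than risk arm-scale blind spots.

**Validation and problem sizes.** `gen_lga_profile()` packs alternating
≥ 12 Mb copy-2/copy-3 segments into arms so that exactly G qualifying
junctions exist; `gen_coverage()` overlays negative-binomial counting
noise (FFPE shallow WGS is overdispersed; `sigma = 0` degenerates to
Poisson). The recovery study segments 100 such genomes (G ∈ {0, 5, 15,
25}, 5 kb base bins genome-wide, ≈ 576,000 bins per genome) and requires
the per-model LGA count to equal G in ≥ 95% of models at windows ≤ 100
kb, and the ensemble consensus to match the G-vs-cutoff truth in ≥ 95%
of genomes. These sizes were chosen as the smallest study that exercises
every window of the ladder on full-genome input while keeping the suite
comfortably reproducible on a laptop.

## RAD51 functional scoring

Genomic scars are history; RAD51 foci are a live functional readout.
The RAD51 score of a slide is the percentage of geminin-positive
(S/G2-phase) tumor cells showing ≥ 5 RAD51 nuclear foci; ≤ 10% calls
HRD, above calls HRP. Two QC gates precede scoring, in this order:
fewer than 40 geminin-positive cells fails as `fail_few_cells` (too
little cycling tumor), and less than 25% of geminin-positive cells with
γH2AX foci fails as `fail_low_gh2ax` (no endogenous double-strand-break
damage, so an empty RAD51 stain would be uninterpretable). Both failure
comparisons are strict, exactly as the study states them, so a slide
with exactly 40 cells and exactly 25% γH2AX passes; a slide with no
cells at all is `fail_no_tumor`.

Focus counting itself (image → integer per cell) is upstream microscopy;
the computable artifact starts at the per-cell count table, and γH2AX
positivity arrives as a per-cell boolean (the study does not state a
per-cell focus threshold for it). The study scored "100 geminin-positive
cells from at least three representative areas"; whether that is a hard
cap or a minimum is ambiguous, so `subsample_cells()` implements the cap
(a seeded, area-stratified draw of exactly 100 cells, warning when fewer
than three areas exist) and `classify_lab3()` scores all cells by
default.

## Concordance statistics

Assay-vs-reference comparison uses complete cases only: pairs where
either assay is missing or inconclusive are excluded and counted. From
the 2×2 table the package computes the agreement rate (a+d)/n, Cohen's
κ = (p~o~ − p~e~)/(1 − p~e~), sensitivity and specificity, all with
exact Clopper–Pearson intervals for the proportions via the
beta-quantile equivalence. κ's interval is Wald on the
Fleiss–Cohen–Everitt asymptotic SE — the study does not name its SE
formula, so κ point estimates, not κ intervals, are what the tests
assert. κ is banded by the conventional six intervals (≤ 0.20 slight,
…, 0.81–1.00 almost perfect). `kappa_sample_size()` inverts the Wald
width: n = ⌈(z·sd/(width/2))²⌉, which reproduces the study's planning
figure of 89 subjects for width 0.25 and sd 0.60.

One published inconsistency is handled by documentation rather than
assertion: reconstructing the second genomic assay's complete-case
statistics from its published contingency table gives agreement 0.88
and κ 0.75, while the study prints 0.87 and 0.74. The 0.01 gap cannot
be resolved from the printed counts (a different complete-case set or a
different rounding chain are both possible), so those two printed values
are documented here and excluded from the assertions; the same assay's
sensitivity and specificity, which do reconcile with the table, are
asserted.

## Outcome analysis

Survival machinery wraps the standard survival package behind a tidy
surface: Kaplan–Meier with log–log intervals (medians reported as NA
when the curve never reaches 0.5, mirroring "NE" in trial tables), the
two-group log-rank test, and Cox regression with Efron tie handling
(month-resolution times tie constantly; Efron is the more accurate
standard choice). `cox_fit()` warns below 10 events per term — the study
makes the same caveat for overall survival — and converts monotone
likelihood (separation) into an error instead of returning a diverged
coefficient. Response rate is (complete + partial)/evaluable with exact
intervals; non-evaluable subjects leave the denominator.

The trial's patient-level data are not public, so the outcome tables of
the study are structural templates only: the synthetic cohort generator
reproduces their shape (exponential progression times with a designed
hazard ratio between true HRD/HRP strata, uniform censoring, per-assay
misclassification and missingness), and the tests assert parameter
recovery — e.g. the designed multivariable hazard ratio 0.53 is
recovered within 3 SE at n = 2000 — not the unpublishable patient-level
values.

## The synthetic cohort as a study stand-in

`gen_cohort()` draws a latent true HRD status per sample
(prevalence 0.56, matching the reference assay's deficient fraction) and
passes it through each assay's designed sensitivity/specificity/
missingness filter. Because misclassification is parameterized this way,
expected contingency tables are closed-form (`expected_contingency()`)
and can be moment-matched to published margins; the default assay
designs echo the printed performance of the four tests, including the
30% failure rate of the functional assay. What the generator does not
emulate: correlated errors between assays (each assay errs
independently given truth), batch effects, intratumoral heterogeneity,
or any association between assay failure and outcome. Passing tests
therefore demonstrate the correctness of the statistical machinery and
the internal consistency of the pipeline, not the clinical performance
of any assay on real tumors.

The fixed published tables live in `fixture_table2()` /
`fixture_calls_table2()`, which expand the printed margins into
per-sample call tables; these are inputs, reproduced digit-for-digit,
and immutable.

## Numerical choices, degenerate inputs, limitations

* SEG input is 1-based inclusive and converted to 0-based half-open on
  read; all internal arithmetic is half-open, which keeps length sums
  free of off-by-one errors. Readers reject malformed rows (naming the
  row) rather than repairing them.
* An empty segment profile is an error ("insufficient data"), never a
  GI score of 0 — silence here would fabricate a proficient call.
* Percentile and threshold scans are nearest-rank/integer, so calibrated
  cutoffs are always achievable values, not interpolations.
* Display rounding is half-away-from-zero at printed precision; machine
  output keeps full precision.
* The scar definitions are faithful to the cited literature but the
  study's exact in-house variants are unpublished; likewise the shallow
  pipeline's windows/cutoff/agreement rule. All are configuration, and
  the defaults are documented stand-ins, not inferred facts.
* Purity/ploidy estimation, variant calling, image analysis and database
  classification are upstream of every module by design.
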