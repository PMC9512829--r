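# hrdkit

Tumors that have lost homologous recombination repair (HRD) are the ones
most likely to respond to platinum chemotherapy and PARP inhibitors, so
calling HRD status reliably — and knowing how well different assays agree —
matters for treatment selection in ovarian cancer. hrdkit implements three
complementary HRD-calling routes the way academic laboratories run them,
plus the diagnostic-concordance and outcome statistics used to compare them
against a commercial reference test:

1. **Genomic-scar scoring** from allele-specific copy-number segments.
   The genomic-instability score is the unweighted sum of three counts,
   GI = LOH + TAI + LST, where LOH counts loss-of-heterozygosity runs
   > 15 Mb not spanning a whole chromosome, TAI counts telomeric
   allelic-imbalance runs > 11 Mb avoiding the centromere, and LST counts
   junctions between ≥ 10 Mb copy states after 3 Mb smoothing, per arm.
   GI > 42 calls HRD; a below-threshold sample with a pathogenic BRCA1/2
   variant is overridden to HRD.
2. **Shallow-WGS LGA scoring** from 0.4–0.8× binned coverage: exact
   penalized least-squares segmentation (PELT/FPOP, compiled) at six
   window sizes from 5 to 1000 kb, counting large-scale genomic
   alterations (≥ 10 Mb flanks, |Δlog2| ≥ 0.2) per window, with an HRD
   consensus when at least 4 of the 6 window models agree.
3. **RAD51 functional scoring** from per-cell immunofluorescence counts:
   the RAD51 score is the percentage of geminin-positive cells with ≥ 5
   RAD51 nuclear foci (≤ 10% ⇒ HRD), gated by slide QC (≥ 40
   geminin-positive cells, ≥ 25% γH2AX-positive among them).

Around these sit the comparison statistics — complete-case 2×2 tables,
agreement rate, Cohen's κ (with Fleiss–Cohen–Everitt SE and the
conventional interpretation bands), sensitivity/specificity with exact
Clopper–Pearson intervals, κ-precision sample-size planning — survival
analysis of biomarker strata (Kaplan–Meier, log-rank, Cox with Efron
ties), and a synthetic-data generator that produces every input format
with known ground truth: segment profiles with exact scar counts,
negative-binomial shallow coverage over designed LGA profiles, per-cell
foci tables with designed positivity, and trial-like cohorts with
designed hazard ratios and per-assay misclassification.

## Worked example

Simulate a tumor whose scar counts are known by construction, score and
call it, then reproduce the published assay-vs-reference concordance
analysis from the fixed contingency fixtures:

```r
library(hrdkit)

build   <- default_build()                       # 22 autosomes + centromeres
profile <- gen_profile(c(loh = 18, tai = 12, lst = 15), build, seed = 42)
scores  <- compute_gi_score(profile, build)
classify_lab1(scores, brca_status = "wild_type")
#> # A tibble: 1 × 8
#>   sample loh_count tai_count lst_count gi_score brca_status label rationale
#>   <chr>      <int>     <int>     <int>    <int> <chr>       <chr> <chr>
#> 1 S1            18        12        15       45 wild_type   HRD   score
```

The engine recovers the designed counts exactly (18 + 12 + 15 = 45 > 42,
hence HRD by score — no BRCA override needed). Concordance of the first
academic assay against the reference, from the published table expanded
to per-sample calls:

```r
fx  <- fixture_calls_table2("LAB1")
rep <- concordance_report(fx$index, fx$ref)
rep
#> 2x2 assay contingency table (complete cases, n = 92)
#>      reference
#> index HRD HRP
#>   HRD  53   6
#>   HRP   1  32
#> excluded as missing: 8
#> agreement 0.92 (0.85-0.97)  kappa 0.84 (0.73-0.95, almost perfect)
#> sensitivity 98.1%  specificity 84.2%

tidy(rep)
#> # A tibble: 4 × 4
#>   statistic      estimate conf_low conf_high
#>   <chr>             <dbl>    <dbl>     <dbl>
#> 1 agreement_rate    0.924    0.849     0.969
#> 2 kappa             0.840    0.727     0.953
#> 3 sensitivity       0.981    0.901     1.000
#> 4 specificity       0.842    0.687     0.940
```

92 of 100 samples had definitive calls from both assays; the index assay
found 53 of the 54 reference-deficient tumors (sensitivity 98.1%) and
agreed on 85 of 92 calls overall, κ = 0.84 — chance-corrected agreement
in the "almost perfect" band.

Fitted survival and segmentation objects follow broom/ggplot2
conventions: `tidy()`, `glance()` and `autoplot()` work on Cox fits,
Kaplan–Meier estimates and shallow-WGS segmentations.

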