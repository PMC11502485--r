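# stratmr — biologically stratified two-sample Mendelian randomization

`stratmr` is an R package for two-sample Mendelian randomization (MR) from
GWAS summary statistics when the exposure is a circulating biomarker whose
genetic instruments are biologically heterogeneous. A variant that raises
measured fasting insulin may mark greater insulin *bioaction* or greater
insulin *resistance*; pooling both kinds of variants estimates the effect of
"higher measured concentration", which is not a single biological exposure.
The package implements the stratified design for this situation: instruments
are split by the **sign of their effect on a downstream indicator trait**
whose response to the biomarker is established (glucose for insulin,
childhood height for IGF-1), and each stratum is analyzed as its own
instrument set.

It is aimed at genetic epidemiologists who already have harmonizable
summary statistics (exposure, indicator, outcome) and pre-resolved
independent signals, and at methodologists who want a fully simulatable
test bed for the design.

## What it computes

For oriented records (effect allele = exposure-increasing allele,
β<sub>X</sub> ≥ 0) with per-variant associations
(β<sub>Xj</sub>, β<sub>Zj</sub>, β<sub>Yj</sub>) and outcome standard errors
σ<sub>Yj</sub>, the package provides:

- **Harmonization** — instrument selection at P &lt; 5×10⁻⁸ (strict), allele
  alignment with strand-complement and palindrome handling, orientation to
  the exposure-increasing allele, and LD-proxy substitution (r² &gt; 0.7
  within 1 Mb, deterministic tie-breaks) for variants missing from a table.
- **Filters** — Steiger directionality (remove a variant when its variance
  explained in the outcome, r² = z²/(z²+n−2), exceeds that in the exposure)
  and sign stratification on β<sub>Z</sub> into positive / negative /
  unclassified strata that always partition the input.
- **Estimators** — inverse-variance weighted
  (β̂ = Σw<sub>j</sub>β<sub>Xj</sub>β<sub>Yj</sub> / Σw<sub>j</sub>β<sub>Xj</sub>²,
  w<sub>j</sub> = 1/σ<sub>Yj</sub>², random-effects scale
  max{1, √(Q/(L−1))}), MR-Egger (free intercept, t<sub>L−2</sub> inference),
  weighted median and penalized weighted median (bootstrap standard
  errors), with Cochran's Q, I², and the Egger-intercept test.
- **Reporting** — the Egger-intercept validity rule (intercept P &lt; 0.05
  invalidates IVW), the family-wise Bonferroni threshold
  α/(n<sub>exposures</sub>·n<sub>outcomes</sub>), funnel and dosage
  diagnostic datasets, and TSV reports with full provenance (selected =
  kept + dropped at every stage).
- **A seeded simulator** of linked exposure/indicator/outcome tables with
  latent variant classes, directional pleiotropy, reverse-causal variants
  and LD blocks, with ground truth for every variant.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `05_report.R`). Stage 1 simulates a study with two
latent instrument classes — true causal effects −0.5 and +0.3 with opposite
indicator-effect signs — plus 10% reverse-causal variants and three outcome
variants withheld to force the proxy path. Running the stages from the
repository root prints:

```
$ Rscript analysis/01_simulate.R
simulated 60 variants (A: 23, B: 34, reverse: 3)
withheld 3 outcome variants to exercise the proxy path

$ Rscript analysis/02_harmonize.R
selected 34, kept 34 (proxied 1), dropped 0

$ Rscript analysis/03_filter.R
Steiger removed 1 of 34 instruments (1 of them truly reverse-causal)
<stratified_groups> 14 classA (+), 19 classB (-), 0 unclassified

$ Rscript analysis/04_estimate.R
IVW [all, L=33]:    beta = -0.127 (95% CI -0.270 to +0.016), p = 0.083
IVW [classA, L=14]: beta = -0.490 (95% CI -0.553 to -0.427), p = 7.4e-53
IVW [classB, L=19]: beta = +0.313 (95% CI +0.266 to +0.360), p = 1.5e-38
truth: classA = -0.5, classB = +0.3
```

The pooled ("all") estimate is a non-significant average of two opposite
effects — and stage 5 additionally flags it as invalid because the
class mixture shows up as a significant Egger intercept — while each
stratum recovers its own truth. That contrast is the quantitative argument
for stratifying before estimating. The same chain is available as one call:

```r
library(stratmr)
report <- run_analysis(analysis_config(
  exposure = "results/data/exposure.tsv",
  indicator = "results/data/indicator.tsv",
  outcome = "results/data/outcome.tsv",
  ld = c("results/data/ld_pairs.tsv", "results/data/ld_positions.tsv"),
  labels = c(positive = "classA", negative = "classB"),
  n_exposures = 2, n_outcomes = 2, seed = 20260305))
print(report)
write_report(report, "results/report")
```

## Scope

The package assumes pre-resolved independent signals (no LD clumping or
conditional analysis), consumes LD as a precomputed pairwise r² table (no
genotype handling), and implements no multivariable, mode-based or
non-linear MR. See `vignettes/stratified-mr-methods.Rmd` for the model,
design decisions and limitations.
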