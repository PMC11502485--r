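---
title: "Biologically stratified two-sample Mendelian randomization: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biologically stratified two-sample Mendelian randomization: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratmr)
```

## The problem

Circulating biomarkers such as fasting insulin or IGF-1 pose a particular
difficulty for Mendelian randomization: a variant that *raises* the measured
hormone concentration can do so for two biologically opposite reasons. It may
increase the hormone's secretion and downstream action ("bioaction"), or it
may impair the tissue response so that concentrations rise compensatorily
("resistance"). Pooling both kinds of variants into one instrument set
estimates a causal effect of a quantity — "higher measured concentration" —
that is not one biological exposure, and the pooled estimate can be an
uninterpretable average of two effects with opposite signs.

`stratmr` implements the stratified design that addresses this: instruments
for the biomarker are split by the *sign* of their effect on a third,
downstream indicator trait whose response to the biomarker is established
(glucose for insulin, which insulin lowers; childhood height for IGF-1,
which IGF-1 raises). Hormone-raising alleles whose indicator effect is
concordant with the hormone's known action index bioaction; discordant
alleles index resistance. Each stratum is then analyzed as its own
instrument set.

## Model and estimators

For variant $j$, let $\hat\beta_{Xj}, \hat\beta_{Zj}, \hat\beta_{Yj}$ be the
estimated per-allele associations with exposure, indicator and outcome, with
standard errors $\sigma_{Xj}, \sigma_{Zj}, \sigma_{Yj}$, all expressed on a
common effect allele and oriented so the effect allele increases the
exposure ($\hat\beta_{Xj} \ge 0$). The per-variant Wald ratio is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order
delta-method standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$.

* **IVW** — weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  through the origin with weights $w_j = 1/\sigma_{Yj}^2$:
  $\hat\theta = \sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj} \big/ \sum_j w_j
  \hat\beta_{Xj}^2$, fixed-effect standard error
  $(\sum_j w_j \hat\beta_{Xj}^2)^{-1/2}$. The random-effects form (the
  default) multiplies the standard error by
  $\max\{1, \sqrt{Q/(L-1)}\}$, a multiplicative over-dispersion scale
  floored at 1 so reported uncertainty is never smaller than the
  fixed-effect value. P-values are normal. A single instrument degenerates
  to its Wald ratio.
* **MR-Egger** — the same regression with a free intercept. The slope is
  the causal estimate under InSIDE (pleiotropy independent of instrument
  strength); the intercept estimates average directional pleiotropy.
  Standard errors are scaled by $\max\{1, \sqrt{Q_E/(L-2)}\}$ and p-values
  use the $t_{L-2}$ distribution. At least three instruments are required.
* **Weighted median (WM)** — order the Wald ratios, form standardized
  cumulative weights $s_j = (\sum_{k\le j} w_k - w_j/2)/\sum_k w_k$ with
  $w_j = 1/\mathrm{se}(\hat\theta_j)^2$, and interpolate linearly at
  $s = 0.5$. Consistent when at least half the weight comes from valid
  instruments.
* **Penalized weighted median (PWM)** — after a first WM estimate $b$,
  each variant's heterogeneity contribution $q_j = w_j(\hat\theta_j - b)^2$
  is scored against the $\chi^2_1$ upper tail $p_j$ and its weight is
  rescaled to $w_j \min(1, 20\,p_j)$; the median is recomputed. Concordant
  variants keep their weight ($20 p_j \ge 1$); gross outliers are driven
  towards zero.

WM and PWM standard errors come from a seeded parametric bootstrap (1000
draws by default): each ratio is resampled from
$\mathrm{Normal}(\hat\theta_j, \mathrm{se}_j^2)$ and the (penalized)
median recomputed. Heterogeneity is summarized by Cochran's
$Q = \sum_j w_j(\hat\beta_{Yj} - \widehat{\beta}_{Yj})^2$ against
$\chi^2_{L-1}$ (IVW) or $\chi^2_{L-2}$ (Egger), and
$I^2 = \max\{0, (Q - \mathrm{df})/Q\} \times 100$. We report the Higgins
heterogeneity $I^2$; the Egger instrument-strength statistic
$I^2_{GX}$ is a different quantity and is not computed.

## Filters

**Steiger directionality.** A variant used as an instrument should affect
the exposure first. Each record's variance explained is approximated from
summary statistics as $r^2 = z^2/(z^2 + n - 2)$, $z = \hat\beta/\sigma$,
and a record is removed when $r^2_{\text{outcome}} \ge r^2_{\text{exposure}}$.
The default rule compares point estimates with no significance gate — a
deterministic, binary decision per variant; records lacking a sample size
are dropped (configurable to keep).

**Biological-effect stratification.** Oriented records are partitioned by
$\mathrm{sign}(\hat\beta_{Zj})$: positive, negative, or unclassified
(missing indicator association, or exactly zero). The sign alone is used —
no p-value threshold on the indicator association — because the stratifying
notion is the *direction* of the downstream effect; gating on indicator
significance would discard most of each stratum and make stratum membership
depend on indicator sample size. The strata always partition the input set,
and group sizes are reported alongside every analysis. Steiger runs before
stratification; both orders are possible in principle, but filtering first
means each stratum's size reflects instruments that are actually usable.

## Harmonization

Instruments are the exposure records with $P < 5\times10^{-8}$ (strict
inequality), assumed to be pre-resolved independent signals — no LD
clumping is performed. Alleles are aligned across tables by label
comparison with strand-complement resolution; palindromic variants (A/T,
G/C) are aligned by allele-frequency concordance and dropped as ambiguous
when either frequency is missing or within $0.5 \pm 0.08$ (the window is
configurable; 0.08 is the conventional conservative choice). Variants
absent from the outcome or indicator table are replaced by an LD proxy
within 1 Mb with known $r^2 > 0.7$ (strict), ranked by $r^2$, then
distance, then identifier — a deterministic total order. A proxy
contributes its own outcome/indicator association while the index variant
keeps its exposure association; when allele labels differ the proxy's sign
is set by frequency concordance. Missing outcome association with no proxy
drops the instrument; missing indicator association leaves it usable but
unclassified. Every selected instrument ends in exactly one of
kept/proxied/dropped, so selected = kept + dropped at each stage.

## The synthetic study generator

Because the real summary statistics behind the motivating analyses (UK
Biobank, MoBa, EGG, large insulin and IGF-1 meta-analyses) cannot be
redistributed, every claim the package makes about itself is validated on
a generative model that mirrors the stratified design:

* variants are independent signals with MAF uniform on $(0.05, 0.5)$,
  placed 200 kb apart on one chromosome so proxy search within 1 Mb is
  meaningful; traits are standardized, so the per-allele sampling standard
  error is the closed form $1/\sqrt{2\,\mathrm{eaf}(1-\mathrm{eaf})\,n}$;
* forward variants draw a true exposure effect
  $\gamma_j \sim N(0, 0.05^2)$ and belong to latent class A or B; the
  indicator effect is $\pm\gamma_j$ by class and the outcome effect is
  $\theta_{\text{class}}\gamma_j$;
* directional pleiotropy adds $\alpha_j$ to the outcome effect *in the
  exposure-increasing-allele frame* (i.e. the added term is
  $\mathrm{sign}(\gamma_j)\,\alpha_j$ on the stored allele). Drawing
  per-allele pleiotropy instead would average to zero after orientation
  and make every directional-pleiotropy diagnostic vacuous; $\alpha_j$ is
  drawn independently of $\gamma_j$, so InSIDE holds unless the
  correlated-pleiotropy switch is set;
* reverse-causal variants draw a direct outcome effect
  $\delta_j \sim N(0, 0.15^2)$ — the scale of strong primary outcome
  loci — and an induced exposure effect $\delta_j/3$, a 3-fold effect
  ratio and hence a 9-fold variance-explained ratio that Steiger should
  detect;
* observed coefficients add independent noise per study (distinct
  sub-seeds: the two-sample design), and a configurable fraction of
  indicator/outcome rows is stored on swapped allele labels to keep the
  harmonization honest.

Default sample sizes are 100,000 per study with 50 variants, the scale at
which genome-wide-significant instruments for a well-powered biomarker GWAS
are strong ($|z| \approx 10$). The Steiger validation uses 200,000 per
study and 600 variants: a design-stage power calculation over these effect
distributions puts expected removal near 98% of reverse-causal and 5% of
forward variants there, comfortably away from the 95%/10% acceptance
margins, while 50,000 would put the forward rate near its margin because of
the weak tail of $N(0, 0.05^2)$ effects.

What the generator does **not** emulate: LD-correlated instruments (blocks
exist only to exercise proxy lookup; effects are independent), binary
outcomes and their logistic effect scales, sample overlap between studies,
population stratification, and winner's-curse from discovery-and-use of the
same exposure scan. Passing tests therefore demonstrate the estimators'
and filters' correctness under the stated model, not robustness to those
real-data phenomena.

## Validation design and problem sizes

The test suite recomputes every statistical property from scratch at desk
scale: 200 replicates for parameter recovery (mean IVW within 3 Monte Carlo
standard errors of the truth; 95% CI coverage within [92%, 98%]), 1000
replicates for type-I error against the exact binomial 99% interval, 200
replicates for stratified recovery of opposite-sign class effects
($\theta_A = -0.5$, $\theta_B = +0.3$) and Egger-intercept recovery
($\mu_\alpha = 0.02$), and 100 replicates for the robustness ordering under
40% invalid instruments. IVW and Egger point estimates are additionally
checked against a generic weighted-least-squares solver to $10^{-10}$
relative error on random instances.

Recovery suites that depend on orientation (notably the Egger intercept)
select instruments at the genome-wide threshold, exactly as the pipeline
does: a sub-significant variant's exposure sign is dominated by noise, and
orienting on a noisy sign flips its pleiotropy term, biasing the mean
intercept towards zero. This is a property of the design being emulated —
instruments *are* genome-wide-significant variants — not a numerical
convenience.

## Numerical choices and degenerate inputs

* P-values are clamped to the smallest positive double rather than
  underflowing to 0, keeping them in $(0, 1]$; the PWM penalty tail is
  clamped the same way so penalized weights stay positive.
* Summary statistics serialize with `%.17g`, so write-then-read
  round-trips are bit-exact.
* Zero instruments yield structured `"no-instruments"` results; fewer than
  three yield an Egger refusal, never an error. An exposure effect of
  exactly zero cannot define an increasing allele; such records are
  dropped with reason `"zero-exposure-effect"` and retained in provenance.
* Proxy ties are broken by $r^2$, then distance, then identifier, making
  every pipeline run deterministic; estimator bootstraps take explicit
  seeds, and `run_analysis()` derives per-stratum sub-seeds from the
  config seed, so identical configs give byte-identical reports.
* Unknown LD is `NA`, never 0: absence of evidence about a pair is not
  evidence of linkage equilibrium.

## Limitations

The pipeline assumes pre-resolved independent instruments and performs no
clumping or conditional analysis; it consumes LD as a precomputed pairwise
table and performs no genotype handling; and it implements no
multivariable, mode-based or outlier-removal (MR-PRESSO-style) estimators.
Stratification by an observed indicator sign misclassifies variants whose
indicator association is weak relative to its standard error; with
realistic indicator power this is rare, but strata built from
under-powered indicator scans should be read with that in mind. The
dosage-style diagnostic is the per-variant effect-effect scatter with
fitted model lines; funnel asymmetry and the Egger intercept remain the
primary pleiotropy diagnostics.
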