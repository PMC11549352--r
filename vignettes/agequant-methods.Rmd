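---
title: "Methods and design notes for agequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for agequant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agequant)
```

# Scope

`agequant` implements the statistical procedures used in quantitative
studies of microbial chronological ageing: lifespan curves from
colony-forming-unit (CFU) assays, parametric growth kinetics, genome-wide
genetic-interaction scoring from arrayed colony sizes, polysome-profile
quantification, enrichment calling for RNA-pulldown proteomics, relative
qPCR quantification, and survival comparison for animal lifespan cohorts.
Every input type has a seeded generator with a ground-truth sidecar, so the
whole pipeline is testable end to end without external data. This vignette
records the models, their assumptions, and the design decisions taken where
the underlying procedures are conventionally under-specified.

# Chronological lifespan: Poisson CFU estimation

A culture's viable-cell density is measured by plating a dilution series
and counting colonies. With counts $y_j$ on plates of dilution $d_j$ and
plated volume $v_j$ (mL), we model
$y_j \sim \mathrm{Poisson}(\lambda v_j / d_j)$ independently, where
$\lambda$ is the CFU concentration per mL. The MLE has the closed form

$$\hat\lambda = \frac{\sum_j y_j}{\sum_j v_j / d_j},$$

which the tests verify against a dense grid-search maximizer of the Poisson
log-likelihood. The confidence interval is the exact (Garwood) interval on
the Poisson total $\sum_j y_j$, scaled by the total exposure — chosen over
a Wald interval because late lifespan timepoints produce very low counts
where normal approximations fail. Plates above 400 colonies (configurable)
are treated as uncountable lawns and excluded: merged colonies violate the
count model. Viability curves normalise each biological replicate to its
own Day 0 estimate (Day 0 = the day the culture reaches stable maximal
density, 100 % survival by definition) and report the cross-replicate mean
and standard error.

Assumptions: colonies arise from single cells (no clumping), plates are
independent, and the dilution factors are exact. Clumping in real
stationary-phase cultures would make counts underdispersed relative to
Poisson; the estimator stays consistent for the mean but the exact CI
would be conservative.

# Growth kinetics

Biomass curves are fitted by nonlinear least squares to the three classical
reparameterized forms in which capacity $A$, maximal rate $\mu$ (the slope
at the inflection) and lag $\lambda$ (the intercept of the inflection
tangent with the baseline) appear directly as parameters:

- logistic: $y = A/(1+\exp(4\mu(\lambda-t)/A+2))$
- Gompertz: $y = A\exp(-\exp(\mu e(\lambda-t)/A+1))$
- Richards: $y = A(1+\nu e^{1+\nu}\exp(\mu(1+\nu)^{1+1/\nu}(\lambda-t)/A))^{-1/\nu}$

Initialisation is deterministic so fits are reproducible: $A_0$ = maximum
biomass, $\mu_0$ = maximum finite-difference slope, $\lambda_0$ = the
tangent-intercept estimate. The Richards shape $\nu$ is bounded in
$[0.1, 10]$ for identifiability. The primary solver is `nls` (port
algorithm with box constraints); when it fails to converge, the same model
is refitted by direct RSS minimisation (`optim`, Nelder–Mead, positive
parameters on the log scale). A fit that still fails is reported with
`converged = FALSE` and the solver message — never silently replaced by
another model. Note that substituting $t=\lambda$ into the Gompertz form
gives $A e^{-e} \approx 0.066A$; the value $A/e$ is attained at the
inflection $t = \lambda + A/(\mu e)$.

Model selection minimises the Gaussian-likelihood AIC among converged
fits, breaking ties toward fewer parameters so the 4-parameter Richards
form never wins on equal footing. Group comparisons use one-way ANOVA
(equal variances by default, mirroring the conventional analysis; Welch is
available) followed by Tukey HSD for all pairs or a Dunnett-style
many-to-one comparison. The environment provides no multivariate-$t$
machinery, so the many-to-one adjustment is Bonferroni over the control
contrasts — conservative, and flagged as `dunnett_bonferroni` in the
output so no reader mistakes it for the exact Dunnett test.

# SGA interaction scoring

Arrayed colony sizes proxy double-mutant fitness. The pipeline:

1. **Artefact filter.** Positions whose *control* colony is absent or
   below 100 px in any control plate are excluded screen-wide — such
   positions reflect absent library mutants or pinning failures. Small
   *query* colonies are never filtered: they are the aggravating-
   interaction signal itself.
2. **Spatial normalization.** A 2D moving-median surface (reflect-padded,
   missing positions ignored) is divided out and recentred on the plate
   median, then residual row and column effects are removed by row/column
   median normalization. The default window is 5×5: on a 16×24 grid a 7×7
   window under-tracks a 30 % radial gradient (4.6-fold CV reduction in a
   constructed test, versus 6.9-fold for 5×5), while a 5×5 median still
   cannot absorb an isolated outlier colony. The window is configurable.
3. **Linkage exclusion.** Genes on the same chromosome within 250 kb
   (inclusive) of the query or control marker locus are excluded: their
   double mutants are depleted by linkage, not interaction.
4. **Scoring.** The genetic interaction score is
   $\mathrm{GIS} = \log_{10}(\tilde q/\tilde c)$, the log ratio of median
   normalized query and control sizes per gene and repeat, clipped to
   $[-2, +2]$. A control median of zero yields $+2$ when the query median
   is positive.
5. **Consensus.** Per repeat, $|\mathrm{GIS}| \ge 0.1$ calls a signed hit;
   the consensus requires the same sign in at least 2 repeats. Genes where
   both signs independently reach the threshold are flagged ambiguous and
   called `none` rather than dropped silently — sign consistency is the
   conservative reading of "supported by at least two repeats".

Row/column normalization is applied after surface smoothing (the order is
not conventionally fixed; this order removes large-scale structure first so
row/column medians estimate residual line effects, and it is documented
here as the package's choice).

# Polysome quantification

A polysome profile is an A254 absorbance trace along a sucrose gradient:
free subunits (40S/60S), the 80S monosome, then polysome peaks. Automatic
segmentation smooths the trace (moving average), finds local maxima, and
merges maxima not separated by a valley at least the prominence threshold
below the lower peak — so a noise bump on a shoulder never becomes a
region. The first peak (or first two, when 40S/60S are resolved) is the
free-subunit cluster, the next is the monosome, later peaks are
`polysome_k`; boundaries sit at inter-peak minima.

The baseline is a single scalar at the monosome trailing valley (the
conventional alignment point). A single raw sample there is noise-limited,
so the implementation estimates the valley *level*: the median of all raw
samples whose smoothed value lies within 1 % of the dynamic range of the
valley level. This pools the valley bottom with any signal-free stretches
at the same level; stretches at other levels are excluded, so a valley
riding above the tails still defines its own baseline. The outermost
region limits are trimmed by walking from the outermost peaks to the
baseline crossing, because open-ended regions would otherwise integrate
clipped noise over long signal-free stretches.

Region areas are trapezoidal integrals of the baseline-subtracted trace,
clipped below at zero. P/M is the summed polysome area over the monosome
area; ribosome content is P+M; the free-subunit region is excluded from
both. Relative ribosome content between a sample and a control is the
ratio of their P+M values, assuming equal lysate loading (enforced
upstream by OD260 normalization; no residual loading correction is
applied).

The per-fraction mRNA distribution from qPCR follows the
$2^{\Delta C_T}$ convention: $\Delta C_{T,f} = C_{T,\max} - C_{T,f}$ over
detected fractions, undetected fractions contribute zero (no imputed Ct
cap — zero signal is the conservative reading of "undetected"), and
quantities are normalised to percentages summing to 100. $C_{T,\max}$ is
the global maximum over detected fractions, not hard-coded to fractions
1–2.

# RNA-pulldown (ChIRP-MS) enrichment calling

Proteins recovered from an RNA pulldown include abundant RNA-independent
background; the deletion-control strain (which lacks the RNA) anchors the
contrast. The caller:

1. **Presence filter:** keep proteins detected in ≥ 2 of 3 replicates of
   at least one strain.
2. **Imputation:** remaining missing intensities are set to 1 (exactly 0
   after log2) and participate in statistics as ordinary values.
3. **Normalization:** log2, then per-sample robust affine calibration
   (centre on the sample median, scale by the sample MAD, rescale to the
   across-sample median location and spread). This is a deterministic
   stand-in for a variance-stabilizing transform — it equalizes per-sample
   location/scale while keeping values on the log2-intensity scale so the
   fold-change threshold stays interpretable. Calibration parameters are
   reported.
4. **Moderated t:** per contrast, the pooled two-sample variance $s^2$
   (df $d$) is shrunk toward a prior,
   $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0+d)$, with $(d_0, s_0^2)$
   estimated by closed-form moment matching on the squared coefficient of
   variation of $s^2$ across proteins (under the scaled-F hierarchical
   model, $\mathrm{CV}^2 = 2(d+d_0-2)/(d(d_0-4))$); underdispersion gives
   $d_0 = \infty$ (complete shrinkage). The statistic has $d_0 + d$ df;
   setting $d_0 = 0$ reproduces the ordinary pooled t exactly, which the
   tests verify. FDR is Benjamini–Hochberg within each contrast.
5. **Calling:** bound if FDR ≤ 0.005 **and** log2FC ≥ 6.5 (inclusive) in
   either the wild-type or the overexpression contrast against the
   deletion control (OR rule).

The thresholds are deliberately stringent: on simulated null matrices the
expected number of bound calls is below one per run.

# qPCR relative quantification

The Livak $\Delta\Delta C_T$ method with a reference gene: technical
replicates are averaged on the Ct scale,
$\Delta C_T = \bar C_{T,\mathrm{target}} - \bar C_{T,\mathrm{ref}}$,
$\Delta\Delta C_T$ subtracts the control condition, and the fold change is
$2^{-\Delta\Delta C_T}$. Amplification efficiency is assumed to be 100 %
(primers are conventionally pre-screened to 90–110 % efficiency;
efficiency-corrected quantification is out of scope). The log2-fold SE is
propagated in quadrature from the four technical-replicate SEs entering
the double difference; biological replicates should be aggregated on the
log2-fold scale.

# Survival comparison

Fly-cohort survival uses the standard two-group log-rank test
(hypergeometric variance at tied event times; censored records leave the
risk set after their time) and the Kaplan–Meier median (smallest time with
survival ≤ 0.5; `NA` when never reached). Both are backed by the
`survival` package and verified in the tests against independent
brute-force implementations.

# The synthetic-data generators: what they emulate, and what not

All generators draw from a single explicit seed through a local RNG state
and emit ground truth as a separate record, never embedded in the data.
Defaults, with rationale where neither convention nor the procedures fix a
value:

- **Dilution plating:** Poisson counts, 10-fold dilution series, duplicate
  plates of 0.1 mL — the standard robotics-based CFU design.
- **Colony screens:** 384-format (16×24) plates; lognormal size noise with
  sdlog 0.12 (~12 % CV, typical of replicate colony sizes after imaging);
  four scattered positions per gene (quadruplicate pinning); a smooth
  multiplicative surface (radial bowl + linear ramp, relative amplitude
  0.3 by default); failed library positions fixed across repeats so the
  excluded fraction matches the nominal failure rate.
- **Polysome traces:** Gaussian bumps with peak SD 0.18 at spacing 1.4
  (≈3.9 SD separation), so overlap is well under 1 % and valleys reach the
  baseline, as in a well-resolved gradient run.
- **Protein matrices:** Gaussian log2 intensities (baseline mean 10, SD 2;
  replicate noise SD 0.5); bound proteins shifted +8 log2 units outside
  the deletion control; missing-not-at-random dropout with probability
  $\mathrm{logit}^{-1}(3 - 0.8x)$ of the latent log2 intensity $x$.
- **Growth curves:** a parametric mean curve plus heteroscedastic noise,
  SD $= \sigma(0.2 + 0.8y/A)$, emulating optical readings every 10 min.
- **Lifespans:** Gompertz hazard $h(t) = ae^{bt}$ with $a = 10^{-4}$/day,
  $b = 0.1$/day (median ≈ 65 days, a realistic fly cohort); independent
  censoring at 5 %.

What the generators do **not** emulate: colony-image segmentation error,
plate-edge drying effects beyond the smooth surface, gradient-maker drift
or fraction-volume jitter, peptide-level missingness structure
(missingness is protein-level), primer-efficiency deviations, and
cohort-level frailty in survival. A green test therefore establishes that
the estimators recover the stated statistical structure at realistic noise
— not that they are robust to every laboratory artefact.

# Numerical choices and degenerate inputs

- Clipping of GIS at ±2 never changes sign; a zero control median maps to
  +2 (query present) or missing (query absent).
- A flat absorbance trace, an all-undetected fraction table, an
  all-uncountable plating record, or a single-group survival table raise
  informative errors; an undefined Kaplan–Meier median and an undefined
  P/M (monosome area 0) return `NA` as signals, distinct from errors.
- AIC ties in model selection are broken deterministically
  (parameter count, then AIC order).
- All tolerance-sensitive tests use fixed seeds; generator determinism is
  itself under test.

# Known limitations

- The Dunnett-style comparison is Bonferroni-adjusted (conservative), not
  the exact multivariate-t adjustment.
- The variance-stabilizing normalization is a robust affine per-sample
  calibration, not a fitted mean–variance transform; counts of proteins
  passing fixed fold-change thresholds are therefore method-sensitive at
  the margin.
- Automatic trace segmentation assumes peaks are resolved at the chosen
  prominence; heavily merged polysome shoulders require manual
  boundaries, for which an input path is provided.
- The CFU model ignores cell clumping and pipetting error in the dilution
  factors.
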