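---
title: "Models and methods behind pubgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pubgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pubgrowth` analyses pubertal height growth in admixed cohorts: it fits
a shape-invariant growth model to longitudinal heights, derives the
pubertal landmarks PV, APV and HAPV per child, and tests genetic and
ancestry effects on those landmarks with interaction regressions. This
vignette documents the models, the estimation choices, the simulator's
assumptions and the package's known limitations.

## The shape-invariant growth model

Each sex is modelled by a single mean curve `h` (a natural cubic
spline) that every child realizes through three random effects:

    y_it = alpha_i + h((t - beta_i) / exp(gamma_i)) + e_it

`alpha_i` shifts height (cm), `beta_i` shifts timing (years) and
`gamma_i` scales developmental speed (log scale). The transform yields
closed-form landmark identities, used throughout the tests: if the mean
curve peaks with velocity `PV0` at age `APV0` and height `HAPV0`, then
child *i* peaks at

    PV_i   = PV0 * exp(-gamma_i)
    APV_i  = beta_i + exp(gamma_i) * APV0
    HAPV_i = alpha_i + HAPV0

### Estimation

The fit alternates two least-squares problems until the relative change
in residual sum of squares drops below `tol` (default `1e-6`, at most
`max_iter` sweeps):

1. given the effects, the spline coefficients solve an ordinary
   least-squares problem on the transformed ages;
2. given the spline, each child's `(alpha, beta, gamma)` minimizes its
   residual sum of squares plus ridge penalties
   `sigma^2_resid / sigma^2_effect`, the effect variances re-estimated
   each sweep from the current spread of the effects.

After each sweep the effects are recentred to mean zero and the shift
is absorbed by the next spline refit; without this the flat direction
(a constant added to all `beta_i` against an opposite shift of `h`)
wanders and convergence stalls. `gamma` is box-constrained to
`[-1.5, 1.5]` to exclude degenerate time scalings. This alternating
scheme is a deterministic, dependency-light approximation of the full
marginal-likelihood nonlinear mixed model that the shape-invariant
literature fits; for landmark recovery it is adequate (see the
recovery tests), and it makes every stage reproducible to the bit.

The residual sum of squares is non-increasing across sweeps up to a
small plateau jitter (relative order `1e-5`) introduced by the
recentring and knot updates; the test suite asserts monotonicity with a
`1e-4` relative tolerance.

### Spline resolution

Knots sit at quantiles of the *transformed* ages, re-placed each sweep,
with boundary knots padded beyond the observed range (the spline is
linear outside them, as natural boundary conditions require). The
default is 10 interior knots. This was chosen by measuring the
approximation error of the fitted spline against the generator's known
mean curve on the 6-monthly schedule: 5 interior knots leave a 0.4 cm
RMSE and bias the curve's peak velocity by -1.6 cm/year — enough to
corrupt every downstream landmark — while 10 knots reduce the RMSE to
0.015 cm and the landmark biases to under 0.05 units. With 24
measurements per child and cohorts of hundreds, 10 knots poses no
overfitting risk.

The fitted spline is stored as its values at the knot nodes: a natural
cubic spline is uniquely determined by those values, so the regression
fit is re-expressed exactly through `stats::splinefun(method =
"natural")`, giving analytic first derivatives for velocity curves.

### Landmark extraction

APV is the argmax of the analytic velocity on a 0.01-year grid over a
pubertal search window (9–16 years for boys, 8–14 for girls), refined
by quadratic interpolation around the grid maximum; ties break to the
earliest age. A maximum attained at the window boundary is flagged
`censored`: such children (late developers whose spurt falls beyond
follow-up) have no estimable landmark, and downstream summaries exclude
them. With the default effect spreads roughly 3–7% of simulated
children are censored; this truncation slightly attenuates
ancestry-effect slopes estimated from fitted landmarks, which is
visible as a small conservative bias in the recovery experiments.

## The simulator

The generator is the package's stand-in for a real admixed cohort, with
every condition fixed by the cohort design it emulates:

* **Reference panels** — Balding–Nichols: ancestral frequency
  `p ~ U(0.05, 0.95)` per variant; each population draws
  `Beta(p(1-F)/F, (1-p)(1-F)/F)`. Defaults use divergence `F = 0.12`
  for Mapuche and Aymara and `0.05` for European and African panels —
  Native American populations are the more drifted relative to a shared
  ancestral pool. Variants sit on one chromosome at even spacing under
  a uniform 1 cM/Mb map; ref/alt pairs are strand-unambiguous, so the
  ambiguity filter is exercised with constructed fixtures instead.
* **Global ancestry** — Dirichlet with concentration
  `20 * (0.438, 0.026, 0.521, 0.015)`, matching the cohort's mean
  Mapuche / Aymara / European / African proportions with homogeneous
  admixture (few children beyond 80–90% of one ancestry).
* **Local ancestry** — per haplotype, a Markov chain along the genome:
  between adjacent variants at genetic distance `d` a recombination
  re-draw occurs with probability `1 - exp(-g d)` (`g` = 15
  generations since admixture by default, a typical depth for Chilean
  admixture), landing on ancestry `k` with probability `q_k`, so the
  child's global proportions are the stationary law. Mapuche and Aymara
  tracts are simulated separately but collapse into one Native American
  dosage, matching how local ancestry enters the association model.
* **Genotypes** — per-haplotype Bernoulli draws from the tract
  ancestry's panel frequency; missingness is sprinkled uniformly.
* **Heights** — the mean curve is a double logistic (childhood +
  pubertal component) whose parameters were solved numerically so the
  landmarks equal the cohort means: boys 9.1 cm/year at 12.7 years and
  156.4 cm, girls 7.7 at 10.8 and 145.1. Random effect SDs default to
  4 cm, 0.6 years and 0.1 (log scale) with 0.5 cm measurement noise;
  the `gamma` SD is the one parameter that cannot reproduce both the
  cohort's PV SD (0.9 cm/year) and APV SD (0.8 years) simultaneously,
  because the transform ties APV dispersion to `APV0 * sd(gamma)`;
  0.1 prioritizes the PV dispersion of the headline phenotype. The
  visit schedule is 6-monthly from 5.0 to 16.5 years.
* **Causal effects** — ancestry shifts timing by `theta_APV = -0.73`
  years and height by `theta_HAPV = -4.3` cm per unit Mapuche
  proportion. A causal PV variant scales the velocity transform and
  carries a compensating tempo shift so that a carrier's APV stays at
  baseline — the allele changes how fast the spurt is, not when it
  happens; without the compensation a -2.5 cm/year PV effect would
  push carriers' spurts years past the end of follow-up, which is
  neither biological nor detectable. Effects are sex-specific; the
  default planted variant affects boys only.

What the simulator does **not** emulate: linkage disequilibrium beyond
ancestry tracts, multi-chromosome structure, genotyping batch effects,
secular height trends, or dropout/irregular visit patterns. Passing
recovery tests therefore demonstrate the estimators' correctness under
the model's own assumptions, not robustness to all features of real
cohort data.

## Quality control

Filters run in a fixed order (the order is this package's choice):
variant missingness > 5%, duplicated physical positions (first kept),
A/T–C/G strand-ambiguous pairs, exact Hardy–Weinberg `P < 1e-6`; then
sample call rate < 0.98 and heterozygosity beyond ±3 SD; then
relatedness pruning at `PI_HAT > 0.2` (one member of each pair removed
at random, seeded), and the exclusion of boys whose last measurement
precedes age 12 (retained at exactly 12.0). The Hardy–Weinberg test is
the exact conditional test (all heterozygote counts compatible with the
observed allele counts enumerated in log space). Relatedness uses the
PLINK-style method-of-moments estimator from identity-by-state counts
and sample allele frequencies, with IBD-state probabilities clipped to
`[0, 1]` and renormalized; relatedness cut-offs are variously quoted as
IBD/IBS ratios in cohort reports, and PI_HAT is the standard statistic
behind them.
Gender-mismatch and ancestry-outlier checks are accepted as boolean
input flags, not computed (sex chromosomes are out of scope).

## Global ancestry

The supervised estimator maximizes the binomial likelihood of each
child's genotypes under a mixture `fbar_m = sum_k q_k f_km` of known
panel frequencies (clipped to `[1e-4, 1 - 1e-4]`), by EM on the simplex
started from uniform proportions, with SQUAREM-style extrapolation for
speed; any extrapolated step that would lower the likelihood falls back
to the plain EM step, so the per-iteration likelihood is monotone (and
asserted to be). The function default stops when the log-likelihood
gains less than `1e-7`; the pipeline uses `1e-4`, the conventional
stopping rule for admixture estimation — between those tolerances the
estimates move by less than `1e-3`, far below their statistical error.
With two closely related Native panels the Mapuche/Aymara split is
weakly identified at small variant counts (a likelihood ridge); the
Native *total* and the European/African components are well determined,
and cohort means converge to the truth as variants grow. An
exchangeable-panel edge case (identical frequency rows) leaves the
estimate at the uniform point of the flat direction by symmetry.

## Association models

Per SNP, ordinary least squares of the phenotype on intercept, sex,
global Mapuche proportion, local Native dosage, genotype, sex×genotype
and genotype×local-ancestry, with Wald t tests on `n - p` degrees of
freedom (at n near 900 the t/normal distinction is negligible). The
female genotype effect is the contrast `b4 + b5`, whose equality with a
sex-recoded refit is asserted to `1e-10`. Two conventions circulate for
the sixth term; the default tests genotype×local-ancestry — the
admixture-mapping interaction asking whether an allele's effect depends
on the ancestral background it sits on — and a `literal_equation`
switch substitutes sex×local-ancestry instead. Missing genotypes are handled per SNP by complete cases; no
genomic control or mixed-model correction is applied — ancestry
covariates are the confounding control, and the calibration test
verifies nominal type-I error when allele frequency tracks local
ancestry. Monomorphic or otherwise rank-deficient designs return
flagged `NA` rows. The minor-allele-count floor defaults to 1 because
the associations of interest have single-digit carrier counts.
Significance labels use strict thresholds `5e-8` (genome-wide) and
`1e-6` (nominal); Manhattan exports drop `-log10(P) < 2`.

The ancestry-effect regression (phenotype on intercept, sex, Mapuche
proportion) reports the Mapuche coefficient: the expected difference
between a fully European and a fully Mapuche child. Sex adjustment is
on by default and can be disabled for a strictly pooled regression.

## Problem sizes and determinism

All simulation-backed checks run at desk scale, chosen so the full
suite completes in minutes on one CPU while keeping Monte Carlo error
well inside the asserted tolerances: recovery cohorts of 400–900
children with 100–300 variants, admixture recovery at 5,000–20,000
variants, calibration over 1,000 null SNPs, and a 20-seed experiment of
the end-to-end pipeline at 300 children × 2,000 variants with one
planted male-specific variant. Every stochastic step takes an explicit
integer seed and the pipeline writes an MD5 manifest; re-running a
configuration reproduces artifacts bit-for-bit.

## Known limitations

* The alternating fit is not a marginal-likelihood mixed model: effect
  shrinkage depends on the ridge weights, and standard errors for the
  random effects are not produced.
* Landmarks for late developers are censored rather than extrapolated;
  cohort summaries on fitted landmarks carry the resulting selection
  effects.
* The double-logistic mean curve is calibrated for ages 5+; it is not
  meant to describe infancy, and its childhood height level is a few
  cm above reference growth charts at age 5 — immaterial for pubertal
  landmarks, which depend on the curve's shape after age 9.
* HAPV is the model-predicted height at APV, not an observed height.
* Local ancestry is taken as known (simulated or supplied); inferring
  it from genotypes is out of scope.
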