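---
title: "Latent g and brain structure: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent g and brain structure: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gsembrain re-implements, as a tested and reusable package, the
latent-variable analysis pipeline of a large population brain-imaging study
of general cognitive ability: a general factor *g* is measured by four
diverse cognitive tests, associated with global and regional MRI measures
in structural-equation models estimated by full-information maximum
likelihood (FIML), probed for age and sex measurement invariance and
moderation, and used for out-of-sample prediction from weighted regional
composites. Because the real cohort data are access-restricted, the package
ships a synthetic cohort generator whose defaults encode the published
estimates; every stage of the pipeline is exercised and validated on those
cohorts.

## The measurement model

The four tests are Matrix Reasoning (0–15), Symbol-Digit Substitution
(non-negative count), Verbal-Numerical Reasoning (0–13), and Trail-Making
part B completion time in deci-seconds. A one-factor confirmatory model

$$y_{ij} = \tau_j + \lambda_j g_i + \boldsymbol{c}_j'\boldsymbol{z}_i + \varepsilon_{ij}, \qquad g_i \sim N(0, 1)$$

identifies the latent scale by fixing the latent variance to 1, so the
loadings $\lambda_j$ are directly interpretable on the standardized metric.
Trail-Making time loads negatively (longer time, worse performance).
Covariates $\boldsymbol{z}$ (age, sex; scanner head position x/y/z for MRI
variables) are applied to the manifest variables *inside* the model, not by
pre-residualising the data. Modification indices — univariate score tests
over the residual covariances fixed at zero — drive the respecification
loop in `fit_g_cfa()`: while any preregistered index fails (CFI or TLI
$\le 0.95$, RMSEA or SRMR $\ge 0.05$), the top candidate is freed and the
model refitted, up to a cap of 3 additions (flagged, not chased, beyond
that). On default synthetic cohorts exactly one pair is added, the Matrix
Reasoning–Verbal-Numerical Reasoning residual covariance, mirroring the
generating structure.

The proportion of test-score variance explained by *g* is the mean squared
standardized loading (`variance_explained()`); the published solutions give
40% uncorrected and 32% age/sex-corrected, which the package reproduces by
direct arithmetic and, approximately, by refitting on synthetic cohorts.

## The FIML engine

No SEM library is used: the covariance-structure engine is part of the
package. Models are parsed from a small `=~`/`~`/`~~` syntax into a
reticular-action (RAM) parameterisation over $v = (\text{observed},
\text{latent})$: directed paths $A$, symmetric (co)variances $S$, means
$m$, with implied moments

$$\Sigma = F(I-A)^{-1}S(I-A)^{-T}F', \qquad \mu = F(I-A)^{-1}m.$$

The FIML log-likelihood sums each subject's multivariate-normal log-density
over their observed subvector. Subjects are grouped by missingness pattern
and each pattern is summarised by its count, mean and (ML-denominator)
covariance, so the likelihood — and its analytic gradient, assembled from
two $O(p^2)$ contractions per group — costs the same at $n = 29{,}004$ as
at $n = 300$. Optimisation uses a quasi-Newton solver (`nlminb`) with the
analytic gradient; convergence requires a relative objective change below
$10^{-10}$, and fits with a gradient max-norm above $10^{-3}$ are flagged.
Start values are 0.5 loadings, 0.5 residual variances, and sample moments
for the exogenous block. All observed variables are z-scored internally
(pooled across groups) for conditioning; the standardized solutions are
scale-free and tested to be invariant under indicator rescaling.

The saturated log-likelihood needed for the model chi-square,
$\chi^2 = 2(\ell_{sat} - \ell_{model})$, is obtained by an EM algorithm for
the unstructured multivariate-normal with missing data, run on the same
pattern summaries. The independence baseline for CFI/TLI retains covariate
regressions when covariates are attached (this choice affects the
incremental indices and is deliberate: the baseline should not be penalised
for covariate structure the model takes for granted). Conventions recorded
in each fit's metadata because software differs: RMSEA uses the $N$
divisor; saBIC uses $k\log((N+2)/24)$; SRMR is the covariance-only
(off-diagonal) variant. Standard errors come from the observed information
(central finite differences of the analytic gradient); standardized-metric
standard errors by the delta method. Heywood cases (negative residual
variances) are permitted with a warning, matching common SEM practice.

**Standardization metric.** Reported standardized estimates (`std`) are on
the covariate-adjusted metric: endogenous variables are scaled by their
model-implied standard deviation *net of* the declared exogenous
covariates. This is the metric on which "age- and sex-corrected"
associations are correlations, and it makes the generator's parameters the
exact estimands of the fitted models. The total-variance metric is also
computed (`std_all`). With no covariates the two coincide.

**Modification indices** are univariate score tests: the score of each
fixed-at-zero residual covariance comes directly from the analytic
gradient; the curvature term uses the observed information of the extended
parameter vector, computed once for all candidates. The index approximates
the chi-square drop from freeing the parameter; the approximation is
accurate for local (small) misfit and, like any score test, overstates the
drop for large omitted parameters — the package therefore uses it only to
*rank* candidates, refitting after each addition.

## Multi-group models: invariance and moderation

`invariance_test()` compares a configural multi-group CFA with a
constrained one. Weak invariance equates the loadings and frees the group-2
latent variance, giving $\Delta df = 3$ with four indicators; strong
invariance additionally equates intercepts and frees the group-2 latent
mean ($\Delta df = 6$). Tucker's congruence coefficient between the freely
estimated group loading vectors supplements the likelihood-ratio test. For
moderation (`moderation_test()`), group loadings are set to equality and
the brain-*g* path(s) are compared free vs constrained: $\Delta df$ equals
the number of constrained brain paths (1 for the TBV model, 5 for the
multi-measure model). The grouping covariate is dropped from the covariate
set whenever it is the grouping term. The age split halves the
cognitive-MRI overlap set (subjects with grey-matter volume and at least
one cognitive test), with boundary ties assigned to the middle-aged group;
an ambiguity in the published split rule (the printed group sizes match the
GM-volume N rather than the MRI-overlap N) is resolved in favour of the
GM + any-test overlap, and the `eligible` argument lets users impose either
reading.

## Global and regional associations

Each global measure (TBV, GM, NAWM, WMH, and the general factors gFA/gMD
derived from 27 tract-averaged FA/MD values) gets a bivariate SEM in which
the measure predicts *g* (MIMIC orientation; for a single standardized
predictor the path equals the latent correlation, so the published
$r$/$\beta$ interchangeability holds). The simultaneous (MIMIC) model
regresses *g* on GM, NAWM, WMH, gFA and gMD at once — TBV is excluded to
avoid part-whole overlap — with correlated residuals among the predictors
added from modification indices until the preregistered thresholds are met
(capped at 10). gFA/gMD are one-factor models over all 27 tracts with
regression (Thomson) factor scores, whose shrinkage explains the
published below-1 SDs; a Bartlett-style alternative was considered and
rejected as the published SDs indicate the regression method.

The regional scan fits one bivariate SEM per region — 96 cortical volumes,
27 FA tracts, 27 MD tracts, 14 subcortical volumes — with
Benjamini–Hochberg FDR applied strictly within family (the FDR families
follow the published analysis exactly: 6 global tests; the MIMIC path set;
96; 27; 27; 14). Stored effect signs are never flipped; MD valence
flipping is presentation-only. Tract-class summaries average standardized
paths within thalamic radiations, association fibres (incl. forceps minor)
and projection fibres (incl. forceps major); the mapping ships as an
editable table (`tract_classes()`) because the published class footnote is
not fully reproducible.

## Out-of-sample prediction

`train_composite()` fits a MIMIC over bilateral-averaged ROIs of one
family on the training site (left/right are averaged first for parsimony;
a lone observed side is used as-is), with MI-driven residual covariances up
to a cap of 10; the composite weights are the training standardized paths.
`evaluate_composite()` z-scores test-site ROIs with *training-sample*
means/SDs (the standard out-of-sample contract; the source is silent on
this), forms $\sum_j w_j z_j$, and fits one two-group SEM with the g
loadings and the MR–VNR residual covariance equated across sites — only
the stated constraints are imposed, residual variances stay free. TBV
correction comes in two variants: adjusting each ROI for TBV inside the
training model, or entering TBV as a covariate in the evaluation
regression; `tbv_attenuation()` reports the percent attenuation.

## The synthetic cohort

The generator (`default_population_spec()`, `generate_cohort()`) encodes
the study conditions: n = 29,004; age 44–81 (mean 63.13, SD 7.48,
truncated normal); three sites at the published proportions; the corrected
loading vector (0.505, 0.479, 0.592, −0.666) with the 0.170 MR–VNR
residual covariance; the printed global paths (TBV 0.276, GM 0.281, NAWM
0.246, WMH −0.106); regional rosters anchored to the printed values
(thalamus 0.251/0.256, insula 0.194/0.205, tract-class means) and
interpolated where only ranges were printed. All structural parameters are
defined on the covariate-adjusted unit-variance metric, so they are the
exact estimands of the fitted standardized solutions. Residual dependence
among brain measures comes from a global anatomy factor (loadings 0.90 on
TBV down to 0.45 on regional volumes), FA/MD white-matter factors
(mutually correlated −0.5), and left/right pair factors; covariate
confounding defaults to −0.15 SD per age-SD on cognitive and volumetric
variables (+0.25 for WMH and MD, whose burden grows with age), 0.25
SD sex effects on volumes, 0.05 on head position — values chosen once to
make covariate adjustment consequential, since the source reports no
generative values.

Missingness is assigned in hierarchical MCAR blocks (MRI processing,
VNR, enhanced cognitive battery, diffusion MRI, WM segmentation) whose
rates reproduce the published margins simultaneously: an expected 20,330
with MRI, 26,983 with VNR, 27,100 with at least one cognitive test, and
18,426 in the MRI-cognitive overlap. Independent blocks cannot reproduce
those margins — they imply that everyone lacking MRI had at least one
cognitive test — so VNR and the enhanced battery rates are conditioned on
MRI availability. Blocks are independent of all generated values, so
missingness is ignorable and FIML estimates are consistent, which the
recovery tests verify.

Two marginal-distribution features of real data are only partially
emulated. Trail-Making time is log-normal (σ = 0.348, matching the
published median/IQR of 496/236 deci-seconds) and the SEM consumes the raw
time; exponentiation attenuates its loading by the analytic factor
$b/\sqrt{e^{b^2}-1} \approx 0.97$, and recovery tests compare against that
oracle. WMH volume is log-normal with σ = 0.35 — milder than the
published IQR suggests — so that the linear association estimand stays
interpretable; real WMH distributions are heavier-tailed, and analysts of
real data may prefer a log transform. Integer cognitive scores are binned
after the correlation targets are set; the resulting attenuation is below
1% at the published score ranges and is accepted. Passing tests on these
cohorts therefore demonstrate correct estimation under the published
dependence structure and block missingness, not robustness to every
marginal feature of real imaging data (site effects on means, non-ignorable
dropout, and health-condition exclusions are out of scope by design; the
generator's `continuous` mode, with binning off and normal-scale time/WMH,
is used for the distributional calibration checks, which condition on a
correctly specified model).

## Problem sizes and numerical choices

The calibration studies run 500 replicates at n = 2,000 (null
invariance rejection rates; chi-square centring), a size at which each
replicate costs well under a second thanks to the pattern-based
likelihood; the end-to-end pipeline check runs at scale 0.1 (n ≈ 2,900).
Degenerate inputs are handled explicitly: a singular sample covariance
ridges the saturated reference with a warning; non-positive-definite trial
points during optimisation return a finite penalty; the latent sign
indeterminacy is resolved by flipping each factor so its loading sum is
positive; boundary Heywood solutions are kept but flagged. Known
limitations: no robust (sandwich) standard errors or weighted
least-squares estimation, ordinal indicators are treated as continuous,
and the score-test modification indices overstate the improvement for
large omitted parameters (they are used only for ranking).
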