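---
title: "Models and methods in aslmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in aslmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslmediate)
```

## The scientific question

Cerebral blood flow (CBF) declines with age, and aerobic fitness is one of
the few modifiable factors associated with better cerebrovascular health in
older adults. The statistical question the package is built around is a
mediation question: is the apparent effect of age on gray-matter CBF
transmitted through (estimated) cardiorespiratory fitness? Formally, with
age $X$, fitness $M$, and regional CBF $Y$:

$$M = a X + \varepsilon_M, \qquad
  Y = b M + c' X + \varepsilon_Y,$$

with total effect $c = c' + ab$ (an exact OLS identity, checked to
$10^{-10}$ in the tests). *Full* mediation is the pattern where $c$, $a$
and $b$ are significant while the direct effect $c'$ is not, and the
bootstrap confidence interval for $ab$ excludes zero.

The package implements every stage needed to pose that question from raw
ASL data — perfusion GLM, CBF quantification, fitness scoring, the
mediation suite — plus a forward simulator with known ground truth, so the
whole chain is testable without human data.

## The perfusion signal model and GLM

An ASL acquisition alternates *tag* frames (arterial blood magnetically
labeled) and *control* frames. The unsubtracted series is modeled with four
regressors: a canonical double-gamma BOLD response convolved with the task
blocks, a baseline-perfusion waveform coded $+0.5$ on control and $-0.5$ on
tag frames, the same waveform gated to task-on frames (activation
perfusion), and a constant.

Two conventions matter and are deliberate:

* **±0.5 perfusion coding.** The baseline-perfusion coefficient is then
  *directly* the control-minus-tag difference signal $\Delta M$, with no
  rescaling before quantification.
* **$M_0$ is the control-image signal.** With tag frames reduced by
  $\Delta M$, the GLM intercept estimates the tag/control mid-point, so the
  static tissue signal is reconstructed as intercept $+\,\Delta M/2$. This
  makes the noise-free simulate→fit→quantify round trip exact (relative
  error below $10^{-6}$ in the acceptance tests, in practice $10^{-14}$).

An empty task produces all-zero BOLD/activation columns; the fitters drop
zero columns internally (reporting zero coefficients) so the design shape is
stable while the solve stays full rank.

**Robust weighted least squares.** Motion-corrupted volumes inflate the
residual variance of their frame. Each frame's variance is estimated by
pooling squared residuals over all in-brain voxels of that volume, and the
frame is weighted by the reciprocal — a *soft* exclusion, in preference to
deleting frames. Two weighted passes are the default; the procedure is
invariant to a global rescaling of the weights. Frames with near-zero
residual variance (possible only for degenerate, noise-free input) have
their variance floored at $10^{-20}\,\overline{S^2}$ (mean squared signal),
i.e. the weights are capped at the reciprocal floor, with a warning; when
every frame hits the cap the fit reduces exactly to OLS.

## CBF quantification

The single-compartment model (no blood–tissue water exchange) maps the
fitted coefficients to perfusion in mL/100 g/min:

$$\mathrm{CBF} = \frac{\Delta M}{M_0}\,
  \frac{6000}{\lambda_{blood}\,T_{1,blood}}
  \exp\!\Big(\frac{w + T_{slc}(n-1)}{T_{1,blood}}\Big)
  \exp\!\Big(\frac{TE}{T_{2,blood}}\Big)$$

| parameter | meaning | default | units |
|---|---|---|---|
| $\lambda_{blood}$ | water content of blood | 0.9 | — |
| $w$ | post-labeling delay | 0.5 | s |
| $T_{1,blood}$ | longitudinal relaxation of blood at 3 T | 1.68 | s |
| $T_{2,blood}$ | transverse relaxation of blood at 3 T | 0.275 | s |
| $TE$ | echo time | 0.044 | s |
| $T_{slc}$ | acquisition time of one slice | 0.06 | s |
| $n$ | acquisition index of the slice (1-based) | ascending | — |

All times are held in **seconds** internally (`ms_to_s()` converts
scanner-card values); the 6000 factor assumes exactly that, and mixed units
are the most likely implementation bug, so conversion happens only at the
boundary. $T_{slc}$ is rarely reported on scanner cards; the default spreads
a typical readout evenly over six slices and is exposed in the
configuration. Voxels with $|M_0|$ below 5% of the in-mask median are set to
`NA` rather than divided through; regional means skip them and report the
voxel count actually averaged. No partial-volume correction and no
multi-delay kinetic modeling are attempted.

## Fitness and covariate indices

Estimated cardiorespiratory fitness, in metabolic equivalents:

$$\mathrm{eCRF} = 2.77\,G - 0.10\,\mathrm{age} - 0.17\,\mathrm{BMI}
  - 0.03\,\mathrm{RHR} + \mathrm{activity} + 18.07$$

The equation is exactly linear; the tests pin the constant (18.07 at
all-zero inputs), the gender contrast (2.77) and the per-year slope
magnitude (0.10) to machine precision. The source equation does not state
which sex is coded 1; the package default codes male = 1 (the sign of the
offset matches the known male–female VO₂max gap), and because every
downstream analysis residualizes gender, results do not depend on the
choice. The activity score is accepted as a real number. Pulse pressure is
systolic − diastolic blood pressure.

## The mediation suite

* **Residualization first.** Gender is regressed out of every variable and
  the residuals are analyzed; partial correlations computed this way are
  verified in the tests against the closed-form first-order partial
  correlation formula.
* **Tails.** One-tailed tests are used only for the simple partial
  correlations, where the direction (CBF falls with age, rises with
  fitness) is hypothesized in advance; two-tailed tests are used throughout
  the mediation regressions.
* **Sobel test.** $z = ab / \sqrt{b^2 se_a^2 + a^2 se_b^2}$, with the
  convention $z = 0, p = 1$ when $a = b = 0$.
* **Percentile bootstrap.** Case resampling of subjects, $ab$ re-estimated
  per resample via closed-form centered-moment OLS (vectorized over
  resamples), percentile interval at the stated confidence. The percentile
  variant (not BCa) is the default because it is the simplest member of the
  family and the classification consumes only "does the CI exclude 0".
  Zero-variance resamples are redrawn (counted and reported); a resample
  whose mediator is exactly collinear with the predictor keeps `lm()`'s
  aliasing convention (the unidentifiable coefficient is zero). Everything
  honors an explicit seed.
* **Classification.** `"full"`/`"partial"` require both the causal-steps
  pattern *and* a bootstrap CI excluding zero; anything less is `"none"`.
  P-values in $(0.05, 0.10]$ are labeled "marginal" in printed output but
  never affect classification.
* **Reverse check.** The same machinery with predictor and mediator
  exchanged; a forward CI excluding zero alongside a reverse CI spanning
  zero supports the forward directionality.
* **Ancillaries.** ICV normalization subtracts the volume-on-ICV regression
  slope (covariance approach), leaving adjusted volumes uncorrelated with
  head size. Outlier screening removes subjects with any designated measure
  more than 3 SD from the mean, in a single pass with full-sample moments.
  The stratified sensitivity analysis splits by gender, then by median age
  within gender, removes stratum means from every measure, and correlates
  pooled residuals — a nonparametric guard against gender/age confounding.

## What the synthetic generator emulates — and what it does not

`cohort_config()` defaults describe a cohort of 41 community-dwelling older
adults: ages from a truncated normal (mean 69.15, SD 8.31, range 55–85,
drawn by rejection so the range is exact), 22 of 41 female, fitness mean
6.80 with SD 2.25 metabolic equivalents.

The path magnitudes are calibrated from the reference correlation
structure for such cohorts rather than from raw slopes: with the truncated
age SD of ≈6.92 years, $\mathrm{corr}(\mathrm{age}, \mathrm{eCRF}) = -0.42$
gives $|a| = 0.42 \cdot 2.25 / 6.92 = 0.137$ eCRF units per year (residual
SD 2.04 keeps the total eCRF SD at 2.25); $b = 2.24$ mL/100 g/min per eCRF
unit with CBF residual SD 4.8 gives $\mathrm{corr}(\mathrm{eCRF},
\mathrm{CBF}) \approx 0.73$; the direct path defaults to $c' = 0$ (full
mediation), implying a total age–CBF correlation of ≈ −0.31. Calibrating on
correlations was a deliberate choice: the mediation *pattern* — which the
package's acceptance checks exercise — is a function of the correlation
structure, and reported slopes and correlations from small studies are not
always mutually consistent. Tissue baselines default to gray ≈ 50 and
white ≈ 20 mL/100 g/min, typical older-adult values.

BMI, resting heart rate and blood pressures are drawn from plausible
truncated-normal marginals, and the activity score is **back-solved** from
the fitness equation so that `compute_ecrf()` reproduces the generative
fitness exactly. Back-solved scores are continuous, unlike the ordinal
self-report scale they stand in for.

The image simulator inverts the quantification equation per voxel and slice
to obtain $\Delta M$, so the GLM + quantification stages recover the
generating CBF exactly in the noise-free limit. Control frames carry
$M_0(1 + \mathrm{drift}\cdot t + \mathrm{bold}\cdot HRF(t))$; tag frames
are reduced by $\Delta M$; thermal noise is i.i.d. Gaussian; designated
spike frames receive extra noise. The four fine regions
(frontal/parietal × gray/white) partition an elliptical brain phantom;
global gray/white masks are their unions, so global regional means are
voxel-weighted mixtures of the fine-region ground truths.

Deliberate simplifications (hence what passing tests do *not* establish
about real data): no pulse-sequence physics or k-space sampling, no arterial
transit-time variation (the constant-offset $\Delta M$ is the steady-state,
tag-close-to-slice assumption), no rigid-body head motion (spikes model only
motion's variance effect, which is what rWLS addresses), no partial-volume
mixing, no physiological noise structure (cardiac/respiratory), and the same
path coefficients apply to every region of one cohort — regional contrasts
(e.g., mediated gray vs. null white matter) are produced by running
scenario-specific configurations. The BOLD amplitude defaults to zero: the
analysis is baseline perfusion, with the activation regressor retained
purely as a nuisance column.

## Reproducibility and problem sizes

A single study seed fans out to per-stage child seeds (cohort, one per
subject's acquisition, one per bootstrap analysis) drawn once from the
seeded master stream, so stages can be re-run independently and a report is
bit-identical under the same configuration and seed.

The validation suite runs at deliberately chosen scales: exactness checks
(round trip, OLS identities) on one 32×32×6×72 series or 100 random small
datasets; bootstrap calibration under a null indirect effect on 500 cohorts
of n = 41 with 1000 resamples each (CI-excludes-zero rate within 3 binomial
SE of the nominal 5%); the qualitative mediation pattern (gray "full",
white "none") on 100 cohorts of n = 200; spike down-weighting on 100 small
simulated series. With the default full-mediation effect sizes, per-cohort
power for the total effect at n = 200 is ≈0.99, and the direct effect stays
(correctly) non-significant 95% of the time — so the expected "full" rate
is ≈94%, which is why the pattern check demands 90%, not 100%.

## Known limitations

* The forward model is the single-compartment steady state; data with
  meaningful transit-time dispersion would need a multi-delay model the
  package deliberately does not provide.
* Frame variance is pooled over the volume, so rWLS cannot distinguish a
  spatially localized artifact from global corruption.
* The outlier rule is single-pass by design; it will not iterate after
  removals shift the moments.
* No multiple-testing correction is applied anywhere, matching the
  analysis style the package reproduces; users scanning many regions should
  bring their own correction.
* Mediation here is a regression decomposition on observational structure:
  no unmeasured-confounding sensitivity analysis or counterfactual
  machinery is included.
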