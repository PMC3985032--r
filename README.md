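# aslmediate

Does cardiorespiratory fitness explain why cerebral blood flow (CBF) declines
with age? `aslmediate` is an R package for researchers who want to answer that
kind of question with arterial spin labeling (ASL) perfusion MRI: it
implements the full computational chain from raw tag/control ASL signal to
quantified CBF, and from subject covariates to a formal mediation test of the
path **age → fitness → CBF** — together with a synthetic-data generator with
known ground truth, so every stage of the pipeline can be validated end to
end without access to human data.

## What it computes

**Perfusion estimation.** The unsubtracted tag/control time series is fit
voxelwise with a four-regressor GLM (task BOLD response, baseline perfusion
as a ±0.5 alternating waveform, task-gated activation perfusion, constant
baseline). The baseline-perfusion coefficient is the control−tag difference
signal ΔM; the static tissue signal M₀ is the control-image signal. Motion
corruption is handled by robust weighted least squares (rWLS): each frame is
weighted by the inverse of its pooled residual variance, so bad volumes are
soft-excluded rather than deleted.

**CBF quantification.** ΔM and M₀ maps are converted to mL/100 g/min with
the single-compartment model

    CBF = (ΔM / M0) · 6000 / (λ_blood · T1_blood)
          · exp((w + T_slc·(n−1)) / T1_blood) · exp(TE / T2_blood)

with λ_blood = 0.9, T1_blood = 1.68 s, T2_blood = 0.275 s, post-labeling
delay w = 0.5 s, TE = 0.044 s, and n the acquisition index of the voxel's
slice. CBF is then averaged over gray/white and frontal/parietal region
masks.

**Fitness.** Estimated cardiorespiratory fitness (eCRF, a non-exercise
VO₂max proxy in metabolic equivalents):

    eCRF = 2.77·gender − 0.10·age − 0.17·BMI − 0.03·RHR + activity + 18.07

plus pulse pressure (systolic − diastolic).

**Mediation statistics.** Gender residualization, partial correlations,
the Baron–Kenny causal-steps regressions (with the exact OLS identity
c = c′ + a·b), the Sobel z test, a percentile-bootstrap confidence interval
for the indirect effect a·b (case resampling, 10,000 resamples by default),
reverse-mediation checks, ICV covariance normalization of regional volumes,
3-SD outlier screening, and a gender×age stratified residual sensitivity
analysis.

## Worked example

Simulate and analyze a complete 41-subject study (ASL series simulated at
32×32×6 voxels × 72 frames per subject, rWLS fit, quantification, mediation
suite):

```r
library(aslmediate)
cfg <- study_config(cohort = cohort_config(n_subjects = 41),
                    n_resamples = 2000, seed = 42)
rep <- run_study(cfg)
print(rep)
#> ASL mediation study report
#>   40 subjects retained (1 excluded), seed 42
#>   gray vs white CBF: mean diff 28.7 mL/100g/min, t(39) = 37.44, p = 3.5e-32
#>   global_gray     indirect = -0.300, CI [-0.491, -0.133] -> full
#>   parietal_gray   indirect = -0.345, CI [-0.623, -0.152] -> full
#>   parietal_white  indirect = -0.250, CI [-0.475, -0.095] -> full

print(rep$mediation$global_gray)
#> Mediation analysis (n = 40 )
#>   a (X->M)     b =  -0.1624  SE =  0.0412  t =  -3.943  p = 0.0003 (significant)
#>   b (M->Y|X)   b =   1.8466  SE =  0.2753  t =   6.708  p = 0.0000 (significant)
#>   c (X->Y)     b =  -0.4373  SE =  0.1026  t =  -4.260  p = 0.0001 (significant)
#>   c' (X->Y|M)  b =  -0.1374  SE =  0.0829  t =  -1.657  p = 0.1060 (ns)
#>   indirect ab = -0.2998; Sobel z = -3.400, p = 0.0007
#>   95% percentile bootstrap CI (2000 resamples): [-0.4908, -0.1326]
#>   classification: full
```

Reading the output: one simulated subject was screened out by the 3-SD rule;
gray-matter perfusion exceeds white-matter perfusion by ~29 mL/100 g/min
(the standard tissue contrast); for global gray matter the age effect on CBF
(total effect c = −0.44 mL/100 g/min per year) collapses to a non-significant
direct effect c′ = −0.14 once fitness enters the model, while the indirect
path a·b = −0.30 has a bootstrap CI excluding zero — i.e., fitness *fully
mediates* the age effect, which is exactly the structure this cohort was
generated with (direct path c′ = 0). The reverse check (age as mediator of
the fitness effect) yields a CI spanning zero, `[-0.073, 0.658]`, supporting
the forward directionality.

All default generator settings (cohort size 41, ages 55–85 with mean 69.15,
path magnitudes, noise levels, 36 tag + 36 control frames at TR 4.5 s) are
documented in `?cohort_config`, `?acquisition_config`, and the methods
vignette (`vignettes/aslmediate-methods.Rmd`).

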