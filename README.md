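# refmapr

Quantitative analysis of four-quadrant cardiac-gated renal diffusion-weighted
MRI: IVIM and diffusion-tensor parameter estimation with directional
pseudodiffusion (the REFMAP — REnal Flow and Microstructure AnisotroPy —
parameter set), per-kidney cortex/medulla aggregation with
parenchymal-volume weighting and split-renal-function arithmetic, and the
statistical machinery to relate those imaging biomarkers to measured and
estimated glomerular filtration rate (GFR) and proteinuria status.

## Who this is for

Renal MRI researchers evaluating diffusion-derived surrogates of kidney
function. eGFR from serum creatinine is biased by muscle mass and
inflammation and cannot lateralize function; tracer-based measured GFR
(mGFR) lateralizes via split renal function (SRF) but needs radioactivity
and long clearance times. Diffusion MRI probes tissue water microstructure
and microcirculation noninvasively; acquiring it with two gradient
waveforms (bipolar, retaining slow coherent-flow attenuation, and
flow-compensated, nulling it) at two cardiac phases (systole and diastole)
separates tubular from vascular flow contributions. No patient data ship
with the package: a synthetic phantom and virtual-cohort generator emulate
the acquisition and the cohort-level statistical structure, so every stage
is testable end to end.

## The model

The diffusion-weighted signal per voxel follows the intravoxel incoherent
motion (IVIM) biexponential

```
S(b) / S0 = fp exp(-b Dp) + (1 - fp) exp(-b Dt)
```

with tissue diffusivity `Dt` (um^2/ms), perfusion fraction `fp`, and
pseudodiffusivity `Dp` (b is used internally in ms/um^2, so b = 800 s/mm^2
enters as 0.8). Fitting is segmented: a log-linear fit to b > 200 s/mm^2
gives `Dt` and a first `fp` estimate; a second bounded fit on all b-values
with `Dt` frozen gives `(fp, Dp)`.

Directionally, the per-direction tissue diffusivities `Dt_j` are fit to a
diffusion tensor, giving MD, FA, axial (`Dtax`, the principal eigenvalue)
and radial (`Dtrad`, mean of the minor eigenvalues) diffusivity. The
per-direction pseudodiffusivities `Dp_j` are then projected onto that
structural eigenframe by a nonnegative least-squares fit of amplitudes
`(a1, a2, a3)` in `Dp_j ~ sum_i a_i (g_j . e_i)^2`, giving `Dp,ax = a1`,
`Dp,rad = (a2 + a3)/2`, and mean `Dp` — so `Dp = (Dp,ax + 2 Dp,rad)/3` and
`MD = (Dtax + 2 Dtrad)/3` hold exactly.

Statistics: per-kidney ROI means (excluded labels — lesion, cyst, pelvis,
vessels — never contribute), volume weighting `V*metric = V x mean(metric)`,
split kidney function `split GFR = SRF x total GFR`, bilateral correlations
via a bivariate random-intercept mixed model (both kidneys per subject,
within-subject correlation modelled explicitly), Benjamini-Hochberg
adjustment across each 36-test family, mixed-effects LASSO with
subject-grouped K-fold cross-validation, eGFR-augmented regressions, and
Welch two-sample tests for proteinuria contrasts.

## Worked example

```r
library(refmapr)

# generate a phantom kidney and one quadrant of its DWI protocol
ph  <- make_phantom(phantom_config(grid = c(36, 36, 12), seed = 1))
ser <- synthesize_dwi(ph, study_scheme("bipolar", "diastole"), sigma = 20)

# direction-averaged segmented IVIM fit over the cortex
maps <- fit_ivim(ser, ph$masks$cortex)
rec  <- summarize_roi(maps, ph$masks, "cortex")
print(rec, digits = 3)
#>   metric     mean n_valid
#> 1     S0 1001.703    3040
#> 2     Dt    1.917    3040
#> 3     fp    0.167    3040
#> 4     Dp   26.973    3018
```

The cortex ROI means recover the generator's bipolar/diastole cortex
ground truth (Dt 1.95 um^2/ms, fp 0.16, Dp 25.4 um^2/ms) from noisy data at
SNR(b0) = 50; `n_valid` for Dp is smaller because voxels with fp below 0.01
carry no pseudodiffusion information and are excluded from Dp means only.

```r
volume_weight(rec, 150)[2, ]          # V*Dt for a 150 ml kidney
#>   metric  mean n_valid v_weighted
#> 2     Dt 1.917    3040      287.6

# bilateral correlation on a 27-subject virtual cohort
ch  <- make_cohort(cohort_config(n_subjects = 27, seed = 1))
s   <- ch$subjects
km  <- ch$kidney_metrics
drv <- km[km$tissue == "medulla" & km$waveform == "bipolar" &
          km$phase == "diastole", ]
drv <- drv[match(paste(s$subject_id, s$side),
                 paste(drv$subject_id, drv$side)), ]
mixed_corr(s$volume_ml * drv$Dtax, s$mGFRt * s$SRF, s$subject_id)
#> <mixed_corr> r = 0.727 (SE 0.065), 95% CI [0.574, 0.831], p = 1.77e-11
#>   (ml; 27 subjects, 54 kidneys)
```

At a study-sized n = 27 the volume-weighted axial diffusivity correlates
with split kidney function near its configured population value of 0.8
(here 0.727 with a CI reflecting the bilateral design).

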