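---
title: "Methods: renal flow and microstructure anisotropy from cardiac-gated DWI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: renal flow and microstructure anisotropy from cardiac-gated DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refmapr)
```

## The measurement problem

Glomerular filtration rate is the central index of kidney function, but its
two clinical routes are imperfect: creatinine-based eGFR is confounded by
muscle mass and inflammation and describes only global function, while
tracer-based measured GFR (mGFR) lateralizes function via split renal
function (SRF) at the cost of radioactivity and long clearance protocols.
Diffusion-weighted MRI offers a noninvasive window on the two tissue
processes that drive filtration — microstructural integrity (tubules,
interstitium) and microcirculation (vascular and tubular flow). This
package implements the full quantitative chain from raw four-quadrant
diffusion acquisitions to kidney-level biomarkers and their statistical
relation to kidney function, together with a synthetic generator that
stands in for patient data.

The four quadrants cross two diffusion gradient waveforms with two cardiac
trigger phases. A bipolar waveform retains signal attenuation from slow
coherent flow (tubular transport); a flow-compensated waveform nulls
first-order flow phase, suppressing that contribution. Systolic triggering
samples peak renal arterial inflow, diastolic triggering minimal inflow.
The bipolar/diastole and flow-compensated/systole quadrants are therefore
expected to carry complementary tubular and vascular information, which is
why all eight tissue/waveform/phase contexts are kept separate throughout.

## Signal model and fitting

Each voxel's signal follows the IVIM biexponential

$$S(b) = S_0\left[f_p e^{-b D_p} + (1-f_p) e^{-b D_t}\right],$$

with diffusivities in um^2/ms and b converted internally to ms/um^2 so that
$bD$ is dimensionless (b = 800 s/mm^2 enters as 0.8). The acquisition uses
b in {0, 10, 30, 50, 70, 80, 100, 120, 200, 400, 600, 800} s/mm^2 along 12
directions, one b = 0 volume per series (133 volumes per quadrant).

**Segmented fit.** Stage 1 regresses log-signal on b over the shells above
200 s/mm^2 ({400, 600, 800}), giving $D_t$ from the slope and
$f_{p,\mathrm{init}} = 1 - e^{\mathrm{intercept}}/S_0^{\mathrm{meas}}$ from
the intercept extrapolated to b = 0. Stage 2 is a bounded nonlinear least
squares over $(f_p, D_p)$ on all b-values with $D_t$ frozen and $S_0$ fixed
to the measured b = 0 mean — fixing $S_0$ avoids the three-parameter
degeneracy at small perfusion fractions. Stage 2 uses three
pseudodiffusivity starts (5, 10, 50 times $D_t$), bounds $f_p \in [0,1]$
and $D_p \in [D_t, 500]$ um^2/ms (covering the renal range with headroom),
best SSE winning and ties going to the smaller $D_p$. Voxels with fitted
$f_p < 0.01$ are flagged `dp_undefined`: their pseudodiffusivity is
unidentifiable and they are excluded from ROI means of the $D_p$ family
only. The stage-1 regression is unweighted on log-signal; a
variance-weighted alternative would down-weight the noisier high-b points
but is deliberately left out to keep the two-stage contract simple.

**Accuracy domain.** The segmented algorithm is exact only in the limit of
well-separated compartments. Freezing the stage-1 $D_t$ bakes in a
deterministic perfusion-leakage bias of order
$\frac{f_p}{1-f_p}\,e^{-(D_p-D_t)b_{\min}}$ at the smallest high-b shell
($b_{\min}$ = 0.4 ms/um^2). With this b-menu the bias stays below 0.1%
relative only once $D_p - D_t \gtrsim 28$ um^2/ms at $f_p \approx 0.16$
(roughly $D_p \gtrsim 10\,D_t$ at renal diffusivities); at $D_p = 5 D_t$ it
reaches the percent range. Typical renal parameter magnitudes
($D_t \approx 1.9$, $D_p \approx 25$--$57$) sit comfortably inside the
accurate regime, but users fitting low-$D_p$ tissues should treat
segmented-fit $D_t$ as upper-biased. This is a property of the segmented
two-stage design itself, not of its implementation.

## Directional stage

Per direction $j$, the same segmented fit applied to that direction's 11
nonzero shells (plus the shared b = 0) yields $D_{t,j}$, $f_{p,j}$,
$D_{p,j}$. The $D_{t,j}$ are fit by linear least squares to a symmetric
tensor via the design rows $(g_x^2, g_y^2, g_z^2, 2g_xg_y, 2g_xg_z,
2g_yg_z)$; eigendecomposition gives MD, FA, axial ($D_{t,ax} = \lambda_1$)
and radial ($D_{t,rad} = (\lambda_2+\lambda_3)/2$) diffusivity. Negative
eigenvalues are clamped to zero and flagged; clamped voxels stay in MD/FA
maps but are counted in the QC summary.

The pseudodiffusivities are then projected onto the structural eigenframe:
nonnegative amplitudes $(a_1,a_2,a_3)$ are fit in
$D_{p,j} \approx \sum_i a_i (g_j \cdot e_i)^2$, giving $D_{p,ax} = a_1$,
$D_{p,rad} = (a_2+a_3)/2$ and mean $D_p = (a_1+a_2+a_3)/3$. This
constrained least-squares reading of "projection along the derived
eigenvectors" uses all 12 directions and reduces exactly to a direct
axial/radial read-out when the $D_{p,j}$ are tensor-consistent; the
alternative — evaluating $D_p$ along two single directions — discards 10 of
12 measurements and was rejected for noise robustness. The scalar $f$ is
the median of the per-direction $f_{p,j}$, which survives single-direction
failures; a mean would be pulled by any corrupted direction.

The 12-direction set is a fixed electrostatic-repulsion design (antipodally
symmetric energy, frozen as `refmap_directions`), with tensor-design
condition number 1.60.

## Aggregation

ROI means are arithmetic means over valid voxels of a cortex or medulla
mask; voxels labelled excluded (lesion, cyst, renal pelvis, vessels) never
contribute. Left and right kidneys are processed independently. Masks are
voxel-aligned to the DWI grid — the higher-resolution anatomical
segmentation and its resampling are outside this package's scope, and the
"central section" sampling of typical protocols is expressed naturally by
supplying single-slice masks. Volume weighting multiplies each ROI mean by
the kidney's parenchymal volume; split kidney function multiplies subject
totals by the kidney's SRF, so bilateral splits conserve totals exactly.

## Synthetic phantom and virtual cohort

The phantom is an ellipsoidal kidney on a regular grid: an outer cortical
strip (default 22% of the radius), medullary pyramids whose principal axis
points radially at a central pelvis (default 6 pyramids, 28 degree
half-width), the pelvis itself labelled excluded, and an optional excluded
lesion. Tissue tensors are axially symmetric with eigenvalues derived from
(MD, FA) draws via $\lambda_1 = \mathrm{MD}(1+2\delta)$,
$\lambda_{2,3} = \mathrm{MD}(1-\delta)$,
$\delta = \mathrm{FA}/\sqrt{3-2\mathrm{FA}^2}$ — parameterising by (MD, FA)
rather than by independent axial/radial draws makes the generated tissue
means hit the configured targets by construction. Per-tissue, per-quadrant
means and SDs default to published renal magnitudes for
proteinuria-negative patients (e.g. bipolar/diastole cortex: MD 1.95, FA
0.19, fp 0.16, Dp 25.4; medulla: MD 1.88, FA 0.28, fp 0.20, Dp 50.9), with
the quadrant contrast carried entirely by those distributions:
flow compensation lowers fp (0.08--0.11 vs 0.16--0.21), systole raises the
fast-flow terms. Pseudodiffusion eigenvalues share the structural
eigenvectors with an axial:radial ratio of 2 in the medulla (tubular flow
alignment) and 1 in the cortex, clipped to exceed the largest structural
eigenvalue. Those between-patient SDs double as voxel-level spread — a
deliberate simplification.

Noise is Rician (magnitude MRI): $\sqrt{(S+\sigma N_1)^2 + (\sigma N_2)^2}$;
the fitters assume Gaussian residuals, as standard. The phantom does not
emulate organ anatomy, respiratory/cardiac motion, or EPI distortion, so
passing tests demonstrate estimator correctness and noise behaviour, not
robustness to motion or susceptibility artifacts in real data.

The virtual cohort draws per-kidney ground-truth metrics for all eight
contexts around the same tissue means, with a latent kidney-function score
shared between a subject's kidneys (default 50% subject-level variance)
loading 0.6 on every metric. Split kidney function follows the link
$\mathrm{mGFRt}_{\mathrm{split}} = 5 + 0.1\,(V \times D_{t,ax}) +
\varepsilon$, with the driver metric taken from the medulla/bipolar/
diastole context (where volume-weighted axial diffusivity correlates most
strongly with split function) and the residual SD calibrated so the
population correlation hits a configured target (default 0.8, the upper end
of the published volume-weighted axial-diffusivity range). SRF is defined
as each kidney's share of the total, so SRF pairs sum to one identically.
BSA (mean 1.9 m^2) converts true mGFRt (ml/min) to BSA-normalised mGFR;
eGFR adds noise calibrated to a target eGFR-mGFR correlation (default
0.735). Proteinuria (default prevalence 4/26) multiplies positive subjects'
diffusivities by 0.932, perfusion fractions by 0.614, pseudodiffusivities
by 0.532 and FA by 0.823 — the published relative group contrasts. Volumes
default to N(160, 35) ml, a realistic adult parenchymal range. Intercept
and slope of the link are arbitrary scale choices placing split function
near 45 ml/min; they do not affect correlations.

## Statistical layer

**Bilateral correlation.** With both kidneys per subject, kidneys are not
independent. The estimator is a bivariate Gaussian random-intercept model:
kidney measurement $u_{ik} = \mu + a_i + e_{ik}$ with subject effects
$a_i \sim N(0, \Sigma_B)$ and kidney residuals $e_{ik} \sim N(0, \Sigma_W)$;
the reported correlation is the total correlation of $\Sigma_B + \Sigma_W$.
With complete two-kidney subjects the MLE is closed-form through the
subject-mean / within-pair-difference decomposition; mixed kidney counts or
a boundary between-subject component fall back to Cholesky-parameterised
numeric ML. SE(r) uses the observed information and the delta method; the
95% CI applies the Fisher z-transform with that SE (equivalently, an
effective sample size $1/\mathrm{SE}_z^2 + 3$), and the p-value is the
normal test on the z scale. Simulation at 200 subjects gives 95% CI
coverage of about 95% (the acceptance suite verifies 92--98% over 500
replicates). When every subject contributes one kidney the model is not
identified beyond the total covariance and the estimator intentionally
degenerates to the ordinary Pearson analysis, flagged as such. The exact
variance structure behind published bilateral mixed-model correlations is
rarely spelled out; the shared-subject-intercept form here is the natural
minimal structure and is stated explicitly so results are reproducible.

**Multiplicity.** Benjamini-Hochberg step-up adjustment, applied per
36-test family (metric x tissue x phase within one waveform's table) — the
family structure that reproduces published adjusted columns; pooling both
waveforms into one 72-test family would change the adjusted values, and the
per-table reading is the one consistent with the worked example shipped as
`bilateral_corr_pvalues`. Printed "< 0.001" entries are encoded as 0.0005;
any encoding at or below 0.002 leaves the numeric entries' adjusted values
unchanged.

**Mixed-effects LASSO.** L1-penalised fixed effects over the metric panel
with a subject random intercept: glmnet coordinate descent on standardised
predictors alternates with moment-based variance-component re-estimation
and BLUP shrinkage of subject intercepts. The penalty is chosen by K-fold
cross-validation (default K = 5; published analyses state K-fold without
K) grouped by subject, minimising held-out deviance of fixed-effect
predictions (held-out subjects are new subjects, random intercept 0). The
headline $R^2$ is marginal — squared correlation of fixed-effect
predictions with the outcome — with the conditional value also reported;
coefficients are returned on both the standardised and original scales
(predictors are standardised before penalisation, the convention that makes
the L1 penalty scale-free). Complete cases only, mirroring cohorts where
eGFR/mGFR are measured in subsets.

**Group tests.** Proteinuria contrasts use Welch's unequal-variance t-test:
with group sizes as unbalanced as 22 vs 4 the pooled-variance test is not
defensible, and the Welch statistic reproduces published group p-values
from the printed summary moments (t = 2.79, p = 0.041 for the cortical
axial-diffusivity contrast rebuilt from means 2.34/2.09, SDs 0.19/0.16).

**eGFR augmentation.** Bivariable OLS of mGFR on eGFR plus one metric (or
metric and volume); the metric's added value is the two-sided t-test of its
coefficient. Collinear predictors abort with the offending names.

## Numerical choices and degenerate inputs

- Stage-2 optimisation: L-BFGS-B, `factr 1e4`, three starts; non-positive
  high-b signals mark the voxel failed rather than aborting a run.
- Tensor fits need 6 valid, non-coplanar directions; rank deficiency or
  fewer directions invalidate the voxel, never the run.
- Pseudodiffusion projection solves unconstrained least squares first
  (exact on consistent data) and switches to nonnegative least squares only
  when an amplitude crosses zero.
- Eigenvalue clamping at zero is flagged per voxel and counted in QC.
- BH validation rejects p outside [0, 1]; re-applying the adjustment to its
  own output is not an identity (the smallest adjusted value would be
  rescaled by m again), so adjusted values are never fed back in.
- All generators are seed-deterministic; identical configurations with
  identical seeds are byte-identical.

## Problem sizes used in the test suite

Unit tests run phantoms of 24 x 24 x 8 voxels and fit dozens to hundreds of
voxels; the acceptance suite uses 1000-voxel recovery panels, a 100-voxel
dense-grid SSE oracle (200 x 200 grid), 200-subject cohorts, 500-replicate
CI-coverage and 50-replicate LASSO support-recovery simulations. These
sizes give Monte-Carlo error comfortably below the asserted tolerances
while keeping the full suite in the low minutes on one core.

## Known limitations

- The segmented fitter's accuracy domain excludes slow pseudodiffusion
  ($D_p \lesssim 10 D_t$), as quantified above.
- The phantom's geometric realism is minimal by design; it validates
  estimators, not segmentation or registration.
- The bilateral correlation model assumes a common within-subject
  covariance across subjects and Gaussian margins.
- LASSO variance components are moment-based between coordinate-descent
  steps rather than jointly profiled; with two kidneys per subject and the
  cohort sizes targeted here the difference is well below selection noise.
- Proteinuria shifts are multiplicative mean shifts; no attempt is made to
  model dispersion changes in the positive group.
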