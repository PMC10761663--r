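---
title: "Short-window FDG-PET kinetic modelling with a triple-injection protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-window FDG-PET kinetic modelling with a triple-injection protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petwin)
```

## The problem

Parametric FDG-PET estimates the rate constants of glucose uptake —
influx $K_1$ (ml/g/min), efflux $k_2$ (1/min), phosphorylation $k_3$
(1/min), and the net influx rate $K_i = K_1 k_3 / (k_2 + k_3)$ — from
dynamic images. Conventional protocols need an hour-long acquisition from
tracer injection plus an arterial input function (AIF) from blood
sampling. `petwin` implements an alternative acquisition design: the
tracer dose is split into three boluses (at 0, 42.5 and 49 min, one third
each), the subject rests outside the scanner for 36 min, and a single
24-min imaging session then captures

* a late brain window (36–39 min, 2 × 90 s frames) — the tail of the
  tissue response to the first bolus;
* a cardiac window (39–48 min; 3 × 60 s, 3 × 20 s, 4 × 30 s, 3 × 60 s
  frames) over the left-ventricular blood pool, spanning the second bolus
  so that both the tail of the first input peak and the rise and peak of
  the second are measured; and
* an early brain window (48–60 min; 2 × 90 s, 3 × 180 s frames) spanning
  the third bolus — the early tissue response that identifies the
  individual micro-parameters.

The AIF is recovered *by model fitting* from the 9-min cardiac window
alone, and the kinetic parameters from the two brain windows, so the
whole pipeline is noninvasive and fits a standard field-of-view scanner.

## Models

**Input function.** The third-order Feng bolus model
$f(t) = A_1 t e^{-\mu_1 t} + A_2 (e^{-\mu_2 t} - e^{-\mu_1 t})$
is convolved with the three-impulse injection train:
$C_p(t) = \sum_j w_j f(t - t_j)$ with dose fractions $w_j$ (default 1/3
each, configurable). Reference parameter values used by the simulation
designs are $A_1 = 263 \pm 120$, $A_2 = 16 \pm 1.32$ kBq/ml,
$\mu_1 = 3.56 \pm 1.31$, $\mu_2 = 0.029 \pm 0.012$ 1/min, with
$\mu_1 > \mu_2$ (fast washout vs slow clearance). The fourth-order Feng
variant is deliberately not implemented: with three convolved impulses
its extra degrees of freedom are not identifiable from a 9-min window.

**Tissue model.** The irreversible two-tissue compartment model with a
vascular term:
$$C_T(t) = (1 - v_b)\left(\left[\tfrac{K_1 k_2}{k_2+k_3}
e^{-(k_2+k_3)t} + \tfrac{K_1 k_3}{k_2+k_3}\right] \otimes C_p\right)(t)
+ v_b C_p(t),$$
with $v_b$ fixed at 0.03 for brain tissue everywhere (estimation and
simulation alike). $k_4 = 0$: FDG-6-phosphate is treated as trapped over
a 60-min horizon. Decay correction is assumed already applied upstream;
no decay term appears in either model.

**Patlak analysis.** After pseudo-equilibrium the transform
$y = C_T(t)/C_p(t)$ vs $x = \int_0^t C_p / C_p(t)$ is linear with slope
$K_i$; `fit_patlak()` uses ordinary linear least squares on frames with
midtimes in 15–36 min by default. The plasma integral starts at time
zero of the first injection (the curves are zero there), anchored by a
zero-activity point — the validation window begins at injection, so no
earlier history exists.

## Numerical design

* **Frame values are frame averages.** PET frames measure mean activity,
  so simulated curves are averaged over each frame, not evaluated at
  midpoints. For the input function the average is computed exactly from
  the closed-form antiderivative of the Feng model. For the tissue model
  the convolution itself is evaluated in closed form (the kernel is a
  constant plus one exponential, and an exponential convolved with the
  Feng terms has an elementary antiderivative) and frame-averaged by
  composite Simpson quadrature on 8 subintervals per frame. Frames that
  contain an injection time in their interior (42.33–42.67 and
  48–49.5 min in the canonical schedule) are split at the injection
  before quadrature, because $C_p$ has a derivative kink there; without
  the split the affected frame averages are biased by up to 0.7%, with it
  the quadrature error is below $10^{-4}$ relative. The test suite
  cross-checks the closed-form tissue curves against an independent
  stiff-ODE integration of the compartment system for all 27 simulation
  parameter sets.
* **Fitting.** Both fits are bounded trust-region Levenberg–Marquardt
  least squares (`minpack.lm::nls.lm`), unweighted, with step and cost
  tolerances $10^{-8}$ and at most 500 iterations. Classic LM has no box
  constraints; the bounded trust-region variant matches the intent of
  "LM with bounds". The AIF fit uses an analytic Jacobian (the model is
  linear in $A_1, A_2$; the $\mu$ derivatives are elementary).
  Non-convergence is flagged on the returned object, never thrown, and
  flagged fits still contribute their estimates to study summaries with
  the count reported alongside.
* **Bounds and starts.** AIF bounds follow the simulation-study rule
  0.5 × the smallest and 2 × the largest parameter value in the design
  grid; a "human" style with $A_1 \in [300, 800]$ kBq/ml is provided.
  The same construction rule, applied to the kinetic simulation grid,
  gives the default 2TCM bounds ($K_1 \in [0.025, 0.2]$,
  $k_2 \in [0.025, 0.5]$, $k_3 \in [0.01, 0.08]$). Starting values are
  the bound midpoints for the AIF and $(0.1, 0.1, 0.05)$ for the 2TCM;
  both are configurable and, for well-posed noiseless data, immaterial
  (recovery is exact from either start).
* **Degenerate cases.** $k_2 + k_3 = 0$ uses the analytic limit (the
  impulse response is the constant $K_1$) in the forward model, while
  $K_i$ is undefined and raises; a fit whose optimum collapses to
  $k_2 + k_3 = 0$ is flagged rather than raised. Patlak points with
  nonpositive plasma activity are dropped with a warning.

## The noise model and its time unit

Frame noise is additive Gaussian with standard deviation
$c \sqrt{C / \Delta t}$ — variance proportional to activity and inversely
proportional to frame duration, the usual surrogate for count statistics
in decay-corrected PET curves. One independent draw per frame; negative
noisy values are retained, since clipping would bias low-activity
frames upward.

The two Monte-Carlo study designs use different duration units inside the
noise term, and this is deliberate. With $\Delta t$ in minutes the AIF
study's noise levels ($c = 0.15$ low, $0.6$ high) give left-ventricle
curves with a few-percent to ~20% frame noise — the intended regime.
Applying the same unit to the tissue study's levels ($c = 0.1$, $0.4$)
would give 10–50% noise on brain ROI curves, an SNR under which
three-parameter compartment fits from seven frames are wildly unstable
(mean $k_2$ errors of tens to hundreds of percent) and which no one would
call realistic for ROI-averaged parametric PET. With $\Delta t$ in
seconds those same levels give ~0.4%/1.7% frame noise and the documented
sub-10% recovery errors. `add_frame_noise()` therefore defaults to the
minute convention, and the tissue-curve study design (and the phantom
generator, which emulates the same acquisitions) sets
`noise_dt_unit = "s"`; both are explicit, overridable fields.

## The Monte-Carlo study drivers

`aif_recovery_study()` simulates all 81 combinations of mean and
mean ± SD of the four Feng parameters on the canonical 50-frame 60-min
schedule, adds noise, fits from the 13 cardiac-window frames, and scores
the regenerated curve against the noiseless one over the full 60 min with
two metrics evaluated on the frame grid: the AUC percentage error
(trapezoid over frame midtimes) and the NRMSE (root mean squared relative
error per repetition, averaged over repetitions). Summaries report, per
noise level, the mean ± SD across the 81 combinations of the
per-combination *mean absolute* per-repetition AUC error; the signed mean
is kept alongside in the per-cell table. The absolute reading is used for
the headline summary because the signed-mean bias is an order of
magnitude smaller than the published table rows, which scale linearly
with $c$ exactly as a mean-absolute error of a nearly unbiased estimator
does. A noiseless fit recovers the parameters to near machine precision,
so the $c = 0$ row of the summary is numerically zero rather than the
small optimizer floor a looser stopping rule would leave.

`tac_recovery_study()` simulates the 27 combinations of
$K_1 \in \{0.05, 0.075, 0.1\}$, $k_2 \in \{0.05, 0.15, 0.25\}$,
$k_3 \in \{0.02, 0.03, 0.04\}$ (with $v_b = 0.03$) driven by the
mean-parameter triple-injection input, and fits each noisy replicate
using only the short-window frames. The input function handed to the
kinetic fit is not the ground truth: it is re-estimated by `fit_aif()`
from the noiseless cardiac-window samples, mirroring the pipeline (the
tissue study adds noise to tissue curves only). The
`include_early_window` flag reruns the design without the 36–39 min
frames, which isolates how much those two frames stabilize the
micro-parameters; the net influx rate, being a macro-parameter, is
expected to degrade far less. Per-cell RNG substreams are derived
arithmetically from the master seed, so results are independent of cell
execution order and reproducible end to end.

Default repetitions are 1000 per cell; the test suite and the acceptance
script run 200, which keeps the pooled-mean sampling error a fraction of
the tolerances being checked while the full suite stays desk-scale (the
two studies are ~32,000 and ~11,000 bounded fits respectively).

## The phantom generator

`brain_phantom_geometry()` builds a 48 × 48 × 24 grid (4 × 4 × 5 mm
voxels) containing a concentric-ellipsoid brain — gray-matter shell
($K_1 = 0.08$, $k_2 = 0.11$, $k_3 = 0.04$; typical human values), white-
matter core ($0.05, 0.07, 0.03$), zero-uptake CSF ventricles — plus a
separate blood-pool sphere modelled as $v_b = 1$ with zero tissue
exchange, so its voxels carry exactly the input function (this is why the
container admits $v_b = 1$). `synth_phantom()` renders every voxel's
frame-averaged curve and adds independent frame noise per voxel, and
returns the generating maps as ground truth. Voxel-wise fitting
(`voxelwise_maps()`) is restricted by a mask; the natural mask is the
uptake regions (gray + white matter) — relative recovery error is
undefined where the truth is zero, and the blood pool is the input, not
tissue.

What the phantom emulates: region-wise FDG kinetics under the
triple-injection schedule, frame-duration-scaled voxel noise, the
left-ventricle ROI measurement (a 10-mm sphere over the blood pool), and
the short-window vs validation-window comparison (2TCM $K_i$ from
36–60 min vs Patlak $K_i$ from 15–36 min). What it does not emulate:
scanner resolution and partial-volume blur (smoothing is available but
not part of generation), attenuation/scatter/reconstruction artifacts,
motion, anatomical variability, and within-region parameter
heterogeneity. Passing phantom tests therefore demonstrates estimator
correctness under the stated noise model, not clinical performance.

In-plane Gaussian smoothing (`gaussian_smooth()`) is 2D per axial slice —
matching how reconstructed dynamic images are usually filtered — with
reflective boundaries (a choice; nothing hinges on it for interior
voxels) and $\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$ per axis in voxel
units. Component resolutions combine as the root sum of squares
(`combined_fwhm()`); note that for the scanner components 4.37, 2 and
4.11 mm this formula gives 6.32 mm, slightly below the 6.4 mm sometimes
quoted for that combination — the formula is implemented as stated and
the discrepancy left unreconciled.

## Known limitations

* The reversible model ($k_4 > 0$) is out of scope, as are dispersion,
  delay and metabolite corrections, and whole-blood-to-plasma
  conversion.
* At the high tissue-noise level the $k_2$ and $k_3$ estimate
  distributions are heavy-tailed and clipped at the fit bounds, so their
  pooled mean errors are sensitive to the random seed at a few hundred
  repetitions per cell; the per-cell tables expose the spread.
* The human acquisition's reconstruction frame list contains one more
  60-s block than the 60-min acquisition can hold; the simulation
  schedule, whose durations sum to exactly 60 min, is treated as
  canonical throughout.
* Voxel world coordinates are `index × voxel size` with no
  affine/orientation handling: sufficient for phantoms and axis-aligned
  NIfTI, not for arbitrarily oriented clinical data.

## A worked micro-example

```{r}
p <- standard_protocol()
truth <- feng_reference()$mean

# simulate the frame-sampled input, restrict to the cardiac window, fit
tac <- sample_aif(truth, p$injections, p$schedule)
fit <- fit_aif(tac[select_window(p$schedule, c(39, 48)), ], p$injections)
tidy(fit)

# a tissue curve and its short-window kinetic fit
ct <- tac_2tcm(tcm_params(0.075, 0.15, 0.03), truth, p$injections,
               p$schedule)
idx <- sort(c(select_window(p$schedule, c(36, 39)),
              select_window(p$schedule, c(48, 60))))
tidy(fit_2tcm(ct[idx, ], fit$estimate, p$injections))
```
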