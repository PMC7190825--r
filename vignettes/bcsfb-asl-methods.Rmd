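---
title: "Quantifying blood-CSF barrier water delivery from multi-TI ASL: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood-CSF barrier water delivery from multi-TI ASL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcsfbasl)
```

## The measurement problem

The choroid plexus (CP), the secretory epithelium lining the brain's
ventricles, moves water from blood into cerebrospinal fluid across the
blood-CSF barrier (BCSFB). A non-invasive measure of this delivery can be
obtained with arterial spin labelling (ASL) MRI: arterial blood water is
magnetically inverted in the neck, and after an inflow time TI an image is
acquired in which labelled water that has crossed into ventricular CSF
contributes to the control-minus-label difference signal ΔM.

The trick that isolates the CSF destination compartment is an ultra-long
echo time. Transverse relaxation attenuates each compartment by
$\exp(-\mathrm{TE}/T_2)$; at TE = 220 ms with mouse-brain values of
$T_2$ = 38, 30 and 200 ms for parenchyma, blood and CSF, the surviving
fractions are about 0.3%, 0.07% and 33%. Blood and tissue signal is
effectively nulled and the voxel-level partial-volume problem of a
low-resolution (32 × 32) readout disappears, because only CSF contributes.
`t2_attenuation()` implements this arithmetic.

## Kinetic models

Both delivery models in the package are solutions of the same
single-compartment delivery integral: a rectangular arterial bolus of
labelled water arriving after transit time $\delta$, lasting $\tau$,
decaying at the arterial rate $R_{1a} = 1/T_{1,\mathrm{blood}}$ while in
transit, and decaying at the destination compartment's apparent rate after
delivery:

$$
\Delta M(t) \;=\; \frac{2 M_0 f \alpha}{\varphi}
\int_{\delta}^{\min(t,\,\delta+\tau)} e^{-s R_{1a}}\,
e^{-(t-s)\,R_{1,\mathrm{dest}}}\, \mathrm{d}s .
$$

Carrying out the integral gives the closed form used by
`bcsfb_delta_m()`:

$$
\Delta M(t) = \frac{2 M_0 f \alpha}{\varphi}\,
e^{-t\,R_{1\mathrm{app}}}\,
\frac{e^{\min(t,\delta+\tau)\,\Delta R} - e^{\delta\,\Delta R}}{\Delta R},
\qquad \Delta R = R_{1\mathrm{app}} - R_{1a},
$$

zero for $t \le \delta$. For the ventricular (BCSFB) signal the
destination rate $R_{1\mathrm{app}}$ is the apparent longitudinal rate of
CSF, estimated per subject from the long-TE control signal; $\varphi$ is
the blood-CSF partition coefficient (taken as 1); $f$ is the rate of
labelled blood-water delivery to ventricular CSF — the physiological
quantity of interest. No intravascular term is needed because the long TE
removes blood signal. For the cortical signal, `buxton_delta_m()` uses the
same integral with the standard pulsed-ASL tissue clearance
$1/T_1' = 1/T_{1,\mathrm{tissue}} + f/\lambda$ and partition coefficient
$\lambda$, i.e. the general kinetic model for FAIR ASL.

When $\Delta R \to 0$ the quotient above degenerates; below
$|\Delta R| < 10^{-6}\,\mathrm{s^{-1}}$ the implementation switches to the
analytic limit $\min(t,\delta+\tau)-\delta$, the scale at which
double-precision cancellation would otherwise dominate. Continuity at
$t = \delta$ and $t = \delta + \tau$ and agreement with direct numerical
quadrature of the integral (`delivery_convolution_oracle()`, adaptive
quadrature with error below $10^{-10}$) are enforced by the test suite to
$10^{-8}$ relative over randomised parameters.

A note on parameterisation: the fitted amplitude of the cortical model is
often written with $f/\lambda$ folded into a blood-equilibrium
magnetisation. Here `fit_buxton()` keeps $f$ native (s⁻¹ per ml of
tissue) and divides by $\lambda$ inside the model, so cerebral blood flow
in ml/100 g/min is simply $6000 f$ at a tissue density of 1 g/ml — the
same CBF either way.

```{r forward-models}
kp <- kinetic_params(f = 24 / 6000, delta = 1, tau = 3, r1app = 1 / 4.0)
round(bcsfb_delta_m(c(0.2, 0.75, 1.5, 2.75, 4, 6.5), kp), 5)
```

## Estimation

All fits are bounded Levenberg-Marquardt least squares (`minpack.lm`),
unweighted. Per-compartment $M_0$ and $T_1$ come from the inversion
recovery of the control signal,
$S(\mathrm{TI}) = M_0 (1 - 2\beta e^{-\mathrm{TI}/T_1})$, where the
inversion-efficiency factor $\beta \in (0,1]$ is fitted by default
(magnitude mouse data rarely achieve perfect inversion); it can be fixed
via `fix_beta`. Signed data are the default; `magnitude = TRUE` fits
absolute values after restoring polarity by a null-point search over
prefix sign flips, which is robust to the sign ambiguity of magnitude
reconstruction. One numerical detail: $\beta$ is initialised just inside
its upper bound, because a box-constrained Levenberg-Marquardt step cannot
move a parameter started exactly on a bound.

The ventricular fit (`fit_bcsfb()`) estimates $f$, $\delta$ and $\tau$
from the dimensionless ΔM/M0$_\mathrm{corr}$ series with $\alpha$,
$\varphi$, $R_{1a}$ and $R_{1\mathrm{app}}$ fixed. Bounds are
$f \in [0, 0.1\,\mathrm{s^{-1}}]$, $\delta \in [0, \max \mathrm{TI}]$,
$\tau \in [0.1, 10]$ s. Because $\delta$ and $\tau$ trade off in a shallow
valley, the fit is started three times at $\delta$ = 0.2, 0.5 and 1.0 s;
the best residual sum of squares wins, ties broken towards the smaller
$\delta$. Whether the bolus width should be fitted at all is genuinely
open — the FAIR bolus width is geometry-dependent and rarely known — so
$\tau$ is free by default with a `pin_tau` option to fix it.

Two identifiability caveats the test suite documents explicitly. First,
with six TIs, distinct $(f, \delta, \tau)$ triples can generate curves
identical to near machine precision, so noiseless round-trip recovery is
guaranteed for the curve (to $10^{-8}$) but for $f$ itself only to about
$10^{-3}$ in the flattest corners of the valley. Second, under
protocol-level noise the same valley inflates per-fit variance of $f$ and
produces a modest convexity bias (group means recovered within roughly
10% at the default noise level); reported group statistics therefore rest
on the cohort averaging the acquisition design provides, as they do in
practice.

Uncertainties are local standard errors from the reduced Gauss-Newton
covariance at the optimum (parameters pinned at a bound are reported
without a standard error). Per-fit standard errors are an artifact
addition — in-vivo work typically reports only across-animal SEM — and
are used in the tests as sanity bands, not as inferential claims.

`fit_dapp()` fits the mono-exponential diffusion model
$S(b) = S_0 e^{-b D_\mathrm{app}}$: closed form for two b-values,
log-linear least squares for more. The apparent (pseudo-)diffusion
coefficient distinguishes extravascular from intravascular label: flowing
blood shows a much larger $D_\mathrm{app}$ than free CSF, so a long-TE
difference signal whose $D_\mathrm{app}$ matches the CSF control signal
carries no vascular contamination.

## The quantification pipeline

`quantify_subject()` composes the stages for one animal:

1. pairwise control − label subtraction, averaged over repetitions
   (`pairwise_subtract()`; the order is configurable for datasets with the
   opposite convention);
2. ROI aggregation — mean over a cortical ROI, sum over the 12-voxel
   (3 × 2, twice) ventricle ROI;
3. inversion-recovery fits of the control series at each TE: tissue
   $M_0, T_1$ at TE = 20 ms, CSF $M_0, T_1$ at TE = 220 ms, with
   $R_{1\mathrm{app}} = 1/T_{1,\mathrm{CSF}}$ passed to the BCSFB fit;
4. ventricle partial-volume correction
   $M_{0,\mathrm{corr}} = M_0 \cdot V_\mathrm{ROI} / V_\mathrm{vent}$
   (`m0_correction()`), with the anatomical ventricle volume supplied from
   structural-image segmentation. Without it the normalisation factor —
   and hence $f$ — tracks ventricle size through partial-volume dilution;
5. kinetic fits and unit conversions: $f \times 6000$ to ml/100 ml/min,
   the total delivery rate $(f/100) V_\mathrm{ROI}$ in µl/min, and, given
   a CP mass (histology, density 1 g/cm³), CP blood flow
   $(\mathrm{total}/E)/m_\mathrm{CP} \times 100$ in ml/100 g/min at an
   assumed single-pass extraction fraction $E = 1$.

A unit subtlety worth stating: the delivery rate reported in
ml/100 ml/min is normalised by the *functional ROI volume* (11.25 mm³),
not by the anatomical CSF volume — that is what the M0 correction
arranges, and it is why total delivery = $f/100 \times V_\mathrm{ROI}$
reproduces the reported arithmetic (24 ml/100 ml/min → 2.7 µl/min) and
why the estimate is invariant to ventricle size at fixed CP delivery. The
package follows that arithmetic throughout and treats the per-CSF-ml
reading of the unit as a documented ambiguity.

Cohort statistics are deliberately plain: pooled two-sample t-tests
(Welch optional), one-tailed by default matching planned directional
group comparisons; Pearson correlation with two-sided p for flow-volume
association; mean absolute difference for scan-rescan reproducibility. No
multiple-testing correction is applied (single planned comparisons), and
no automatic outlier removal — a logged ±2 SD exclusion flag exists but
is off by default.

## The digital phantom

`make_phantom()` and `simulate_acquisition()` exist so that every stage of
the pipeline can be exercised, end to end, with known ground truth and no
scanner data. The phantom is a 32 × 32 single slice at
0.625 × 0.625 × 2.4 mm: a dorsal band of pure cortical tissue and two
caudal 3 × 2 ventricle blobs — the 12-voxel functional ROI — whose CSF
partial-volume fractions sum exactly to the requested anatomical ventricle
volume (default 3.75 mm³, i.e. four voxels' worth spread across twelve
voxels). Simulation is the forward composition of the models above:
control = compartment-weighted inversion recovery × T2 attenuation
(× diffusion attenuation when a b-value is set); label = control −
compartment-weighted ΔM; Gaussian noise per repetition, per voxel, seeded.

Design choices, and what they imply about test coverage:

- **ROI voxels hold CSF plus signal-free background only** (cortex
  fraction 0 there). This keeps the long-TE control sum a pure CSF signal,
  making the M0-correction invariance property exact. Real periventricular
  voxels contain parenchyma whose residual 0.3% signal leaks into the ROI;
  that leakage (a ≲2% effect on the CSF $M_0$) is deliberately not
  simulated, so passing the 1%-invariance test says the correction logic
  is right, not that real data are free of T2 leakage.
- **Default kinetics**: CSF transit time 1.0 s, cortical transit 0.3 s,
  bolus duration 3 s for both compartments — values in the range a FAIR
  experiment with a 19.2 mm labelling slab produces; they are stated
  choices, not fitted to any dataset.
- **Default truths**: delivery 24 ml/100 ml/min and CBF 283 ml/100 g/min
  for a single adult subject (the characterisation-cohort means);
  ageing-cohort simulations use 20 vs 13 ml/100 ml/min and 251 vs 218
  ml/100 g/min with between-subject SDs inferred from printed SEMs
  (SEM × √n, e.g. 1 × √12 ≈ 3.5).
- **Noise**: Gaussian, default SD 0.2 signal units against a unit-fraction
  $M_0$ of 100 — calibrated so the ROI-summed peak ΔM is about ten times
  the noise of the 20-repetition average, consistent with the long-TE
  difference signal being roughly a tenth of the standard ASL signal.
  Rician noise is not simulated: the analysis operates on ROI-summed,
  repetition-averaged signals where the Gaussian approximation is sound;
  magnitude-specific bias at very low voxel SNR is out of scope.
- **Not simulated**: CSF pulsation/motion (addressed experimentally by a
  wide labelling slab, not computationally), dispersion of the bolus,
  exchange across additional compartments, registration error.

`simulate_cohort()` draws per-subject truths (truncated normals, optional
linear flow-volume association with the marginal SD held fixed) and
returns the paired 5-repetition TE = 20 ms and 20-repetition TE = 220 ms
series per subject plus a truth table, so recovery can be scored exactly.

```{r cohort, eval = FALSE}
sim <- simulate_cohort(cohort_spec(n = 12, f_mean = 20, label = "adult"),
                       seed = 1)
quantify_cohort(sim)
```

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on simulated
data at the study's own scale: 32 × 32 single-slice phantoms, six TIs,
5/20 repetitions, cohorts of 11-12 subjects, 100-draw oracle comparisons,
and 200-replicate Monte-Carlo bias checks — a few seconds to a few tens
of seconds in total on one core.

## Limitations

- ROI-level quantification only, by design: one global delivery estimate
  per ventricle system, no voxelwise mapping.
- The labelling efficiency α entering quantification is assumed (default
  1.0, configurable); it is not estimated from the data.
- Pseudo-continuous labelling (human protocols) has no closed form here;
  the models are pulsed-ASL (FAIR) forms.
- The CP blood-flow conversion inherits the uncertainty of the CP mass
  and the 100% extraction assumption; computed from group means it is
  arithmetically a few percent below a per-animal average, so it should
  be read as a scale, not a precise rate.
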