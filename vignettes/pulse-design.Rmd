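---
title: "Comprehensive 4D pTx spatial-spectral pulse design: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive 4D pTx spatial-spectral pulse design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptxspsp)
```

## The problem

At ultra-high field (7 T), single-channel excitation of a thin imaging
slab suffers from two coupled problems: transmit-field (B1+)
inhomogeneity makes the flip angle spatially nonuniform, and the large
chemical shift of fat (around -1000 Hz) interacts with bipolar
slab-selective gradients to excite spurious out-of-slab fat signal
("fat odd lobes": sub-pulses played on opposite gradient polarities
acquire inconsistent chemical-shift phases, so fat is partially excited
at spatially displaced locations). Parallel transmission (pTx) —
independent RF waveforms on each element of a multi-channel coil —
provides the degrees of freedom to fix both at once, provided the design
problem is posed over the right domain.

`ptxspsp` implements a comprehensive four-dimensional (1D spectral x 3D
spatial) pulse design: rather than designing the in-plane weighting and
the slab-selective sub-pulse separately, a single optimization shapes
channel-wise RF waveforms, played on prescribed 3D gradients, against an
excitation target defined jointly in space and resonance frequency over
four regions:

* **inside-slab water** — target flip `alpha0` at the water resonance
  (0 Hz);
* **out-of-slab water** — target 0 at 0 Hz;
* **fat** — target 0 at five stopband frequencies (-1200, -1100,
  -1000, -900, -800 Hz), spatially spanning the *whole* brain, which is
  what removes the odd lobes;
* **don't-care** — the transition bands flanking the slab, excluded
  from the optimization.

## The design model

In the small-tip-angle (STA) regime the transverse excitation at
position $r$ and spectral offset $f$ is linear in the RF. With the
excitation k-space convention $k(t) = -\gamma \int_t^T G(s)\,ds$, the
matrix element for channel $c$ and time sample $t_j$ is

$$ A[(r,f),(c,j)] = i\,\gamma\,\Delta t\; b_c(r)\,
   e^{\,i 2\pi (\Delta f_0(r)+f)(t_j-T)}\, e^{\,i k(t_j)\cdot r}, $$

with $b_c$ the complex channel sensitivity, $\Delta f_0$ the measured
off-resonance, and $T$ the end of the waveform. Flip angles are kept in
degrees and RF in microtesla throughout. Stacking the three active
regions gives the regularized magnitude-least-squares problem

$$ \arg\min_x \;\big\| |A_{iw}x| - \alpha_0 \big\|_2^2
   + \lambda_1 \|A_{ow}x\|_2^2 + \lambda_2 \|A_f x\|_2^2
   + \beta\, \Delta t \|x\|_2^2 , $$

solved by the variable exchange method (VEM): alternate the exact phase
update $z \leftarrow e^{i \arg(A_{iw} x)}$ with the exact regularized
linear solve for $x$ given $z$ (stacked normal equations). Both
half-steps minimize the same joint surrogate, so the objective is
non-increasing — the package asserts this at every iteration. Because
the normal matrix does not change across iterations it is inverted once;
each subsequent iteration costs only matrix-vector products.

Magnitude least squares is non-convex: VEM converges to a local
minimum that depends on the starting point. The default start is a
circularly-polarized (CP-like) configuration — equal channel waveforms
with azimuthal phase increments, scaled to the target — which behaves
like the birdcage excitation the design is meant to improve on; a
seeded random start is also available, and the test suite checks VEM
(best of a few random starts) against a dense brute-force phase search
on tiny problems.

### Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `alpha0` | `ernst_angle()` = 12.76 | degrees | in-slab target; Ernst angle for TR 50 ms, T1 2 s |
| `lambda1` | 2 | – | out-of-slab water suppression weight |
| `lambda2` | 8 | – | fat stopband suppression weight |
| `beta_reg` | 2000 | deg^2 per uT^2 s | integrated-RF-power weight |
| `passband_width` | 48 | mm | inside-slab water thickness |
| `transition_fraction` | 0.10 | – | transition band per side; effective thickness = 1.1 x passband |
| `g_max`, `slew_max` | 70, 200 | mT/m, T/m/s | gradient hardware limits |
| `raster` | 2 | us | waveform discretization step |

The power-regularization scalar deserves a note. Squared-degree
residuals and a squared-microtesla penalty only balance after fixing a
unit convention; this package defines the power term as
$\beta \sum_j |x_j|^2 \Delta t$ — $\beta$ weights *integrated* RF power
in $\mu T^2\,$s — which makes the regularization independent of the
raster choice (halving $\Delta t$ doubles the sample count but leaves
both the system matrices' Gram scale and the power term unchanged).
Under this convention the default $\beta = 2000$ produces peak RF
amplitudes around 10 uT on the synthetic head model, comfortably inside
the ~15 uT amplifier range of clinical 7 T systems, while leaving
in-slab fidelity essentially unconstrained. $\lambda_1, \lambda_2,
\beta$ are all exposed.

## Gradient waveforms

The slab-selective gradient is three pairs of alternating-polarity
trapezoids oscillating at a 1 ms period (maximum-slew ramps, plateau
default 25 mT/m), followed by a minimum-time rewinder of *half* the lobe
area and polarity opposite to the final lobe. The half-area rewinder is
the multi-lobe generalization of slice refocusing: it centers the
slab-axis k-space excursion about zero, so the excitation k-space value
seen at the center of every lobe is exactly refocused at the end of the
pulse. With the default limits the rewinder adds ~0.31 ms for a total of
~3.3 ms. The plateau amplitude is not itself load-bearing — it sets the
sub-slab spatial resolution available to the optimizer (per-lobe
excursion ~1250 rad/m, i.e. ~5 mm, far finer than the 48 mm slab) — and
is exposed as a parameter.

The in-plane trajectory evaluates the spherical SPINS parameterization

$$ r_k(t) = \frac{k_{max}}{1+e^{\alpha_s (t/T_p-\beta_s)}},\quad
   \theta_k(t) = u t,\quad \varphi_k(t) = v t $$

with $k_{max} = 20$ rad/m, $\alpha_s = 10$, $\beta_s = 0.5$, $u = 8\pi$
rad/ms, $v = 2\pi$ rad/ms, and keeps only the two transverse components
as the 2D in-plane trajectory — the only reading consistent with pairing
a 1D slab-selective waveform with "in-plane" gradients. $T_p$ equals
the 3 ms oscillation window: the rewinder carries no RF, and RF is
allowed during gradient ramps (the optimizer sees the true
time-resolved trajectory), which with 8 channels at the 2 us raster
gives the 1500 x 8 = 12000 RF unknowns of the full-size problem. The
transverse SPINS components vanish at both ends of the window
($\theta_k$ is a multiple of $\pi$ there), so no separate in-plane
rewinder is needed at the default settings; `k_to_gradient()`
nevertheless appends a minimum-time per-axis rewinder whenever a
prescribed trajectory does not terminate at the k-space origin, and
falls back to uniform time dilation if a prescribed trajectory exceeds
the slew limit.

One convention is worth stating explicitly: waveform validation checks
amplitude and sample-to-sample slew *within* the emitted window. The
SPINS gradient is nonzero at $t = 0$, which a scanner realizes by
ramping up before the RF window opens; a leading ramp-in is outside the
designed pulse and is not represented.

## Calibration inputs and down-sampling

No measured calibration data ships with the package; `generate_calibration()`
synthesizes the inputs the design consumes, emulating an 8-channel 7 T
head coil on the standard calibration grid (80 axial slices at 3 mm
isotropic): an ellipsoidal brain mask; per-channel complex
sensitivities built from ring-placed Gaussian falloff magnitudes with
azimuthal phase increments $2\pi c/C$ (center-bright in CP combination)
plus smooth seeded per-channel perturbations; and an off-resonance
field from a low-order polynomial plus localized Gaussian blobs,
demeaned over the brain and scaled to a prescribed standard deviation
(default 50 Hz). `b1_inhomogeneity = 0` and `b0_severity = 0`
degenerate to perfectly homogeneous maps, which several tests exploit.
What the generator does *not* emulate: scalp fat compartments (the fat
stopband is prescribed over the whole brain mask, so no separate fat
geometry is needed), coil-element coupling, measurement noise in the
maps, and the dielectric asymmetries of real heads. Passing tests
therefore demonstrate correctness of the machinery and the *relative*
behavior of designs, not absolute in vivo performance numbers.

Design matrices use region-specific block-average down-sampling of the
calibration maps: inside-slab water at 6 mm in-plane and native
through-plane resolution; out-of-slab water and fat at 18 mm in-plane
and 9 mm through-plane. Block averaging (rather than decimation) is the
variance-minimizing aggregation; sample positions are cell centers.
Evaluation, by contrast, is always at the native grid over every brain
voxel.

## Bloch evaluation

Designs are judged by hard-pulse Bloch simulation (an `Rcpp`/Armadillo
kernel): per 2 us step, one exact rotation about the effective field —
transverse $\sum_c b_c(r)\,rf_c(t)$, longitudinal
$(\Delta f_0(r)+f) + \bar\gamma\, G(t)\cdot r$ — with relaxation
neglected (3.3 ms pulse vs. T2 of tens of ms). The integrator is
verified against a matrix-exponential propagator to 1e-6 and against the
closed-form hard-pulse flip $\gamma B_1 \tau$; the STA matrices agree
with it to well under 1% at small flips on the 2 us raster. On
deliberately coarse rasters (20 us, used to shrink test problems) the
midpoint phase approximation inside one sample becomes the dominant
STA-vs-Bloch discrepancy; the agreement test therefore runs at the
native raster.

On top of the simulator sit: `slab_profile()` (flip traced along the
slab axis through the in-plane center, FWHM by linear interpolation at
half the plateau median, plateau = samples within 80% of the peak);
`spsp_response()` (a -1300..300 Hz sweep in 100 Hz steps, intensity
`sin(flip)` averaged over three centerlines, interpolated to 10 Hz — the
simulated counterpart of a phantom frequency-sweep experiment); and
`delay_scan()` (gradients time-shifted against RF on a 1 us resampled
raster — sample replication, so the zero-delay row reproduces the
undelayed physics exactly — re-simulated and reported as water/fat RMSE
per delay).

## Baselines

`design_spokes()` implements the traditional comparison: six identical
sinc sub-pulses (TBWP 6, 0.3 ms) on bipolar slab lobes whose amplitude
follows $G = BW/(\bar\gamma\,\Delta z)$ (9.79 mT/m for a 48 mm slab),
at six in-plane k-space locations — five on a circle of radius
$2\pi/240\,\mathrm{mm}$, one at the origin, the standard symmetric
low-k heuristic — reached by triangular blips between lobes (built with
a 20% slew margin and rescaled to realize each inter-spoke k-step
exactly on the discrete raster). Channel-and-spoke weights are solved by
the same VEM machinery on inside-slab water samples only (three slices
spanning the slab at 6 mm in-plane), mirroring how such pulses are
designed in practice; that blindness to the fat stopband is precisely
what the comprehensive design removes.

`design_binomial()` implements the single-channel composite-pulse
alternative: six sub-pulses weighted 1-5-10-10-5-1 (normalized to the
target flip), spaced 0.5 ms so fat at -1000 Hz accrues $\pi$ between
sub-pulse centers — the alternating sum $1-5+10-10+5-1 = 0$ nulls fat —
on bipolar or monopolar (fly-back) slab gradients. `optimal_tbwp()`
maximizes the sub-pulse time-bandwidth product under the constraint
that ramps, plateau-only RF, and (monopolar) an equal-area fly-back all
fit within the inter-pulse interval: for bipolar timing the closed form
is $G^* = \tau s/4$, $T_{rf} = \tau/2$; for monopolar the fly-back
consumes RF time and the optimum drops by ~70% at matched timing — the
ratio is independent of slab thickness, and in this model also of the
inter-pulse duration. Because the objective is zero on the infeasible
high-amplitude plateau, the search uses a coarse amplitude grid before
local refinement.

## Metrics and cohort protocol

`compute_metrics()` reports RMSE against the four-region target (target
`alpha0` in-slab at 0 Hz; 0 for out-of-slab water and for fat pooled
over the five stopband frequencies) and the in-slab coefficient of
variation, all on the native evaluation grid. CoV uses the population
standard deviation (the flip map is the complete voxel set, not a
sample). In-slab and out-of-slab water RMSE are reported separately,
with the pooled value alongside. `run_cohort()` repeats
generate-design-evaluate across seeds and tabulates per-subject rows
with a mean +/- SD footer; per-subject values on synthetic heads are not
comparable to measured-calibration values, so the suite asserts
consistency properties (determinism per seed, small across-cohort
spread) rather than absolute numbers.

## Problem sizes used by the tests

The test suite exercises the full pipeline on a 24^3 grid at 8 mm (192 mm
field of view, ~4300 brain voxels) with a 20 us RF raster — 150 RF
samples x 8 channels = 1200 unknowns, in-slab/stopband down-sampling at
the same multiples of the native resolution as the full-size
prescription (2x, and 6x/3x). These sizes were chosen so that a
complete design plus whole-brain Bloch evaluation runs in a few seconds
while preserving every structural property of the full problem; the
full-size configuration (80 slices at 3 mm, 2 us raster, 12000
unknowns) runs through the same code paths via the command-line
interface.

## Known limitations

* The STA formulation is valid for small flips; at the 13 degree target
  the linearization error is at the percent level, consistent with the
  residual in-slab RMSE floor.
* No SAR or peak-power constraint is imposed — `beta_reg` penalizes
  integrated power globally, which is not a local-SAR surrogate.
* The published regularization scalar for the power term is tied to an
  unstated unit convention; this package's raster-invariant integrated-
  power convention reproduces sensible amplitudes but is its own choice.
* The synthetic coil model is qualitative; quantitative RMSE/CoV values
  on it should only be compared *between* designs, not against values
  obtained with measured calibrations.
* Gradient imperfections are modeled only as a pure isotropic delay
  (`delay_scan()`); eddy currents and waveform distortion are out of
  scope.
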