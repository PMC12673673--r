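# ptxspsp

Parallel-transmission (pTx) spatial-spectral RF pulse design for
slab-selective, uniform, water-only excitation at ultra-high field MRI.

## What it does, and for whom

At 7 T, exciting a thin imaging slab with a uniform flip angle while
leaving fat unexcited is hard: the transmit field of a head coil is
inhomogeneous, and bipolar slab-selective gradients interact with the
~-1000 Hz chemical shift of fat to produce spurious out-of-slab fat
excitation ("fat odd lobes"). This package — aimed at MR physicists and
pulse-sequence developers — implements a comprehensive 4D pulse design
that solves both problems in a single optimization over 1D spectral x
3D spatial space, together with everything needed to evaluate it:
a synthetic multi-channel calibration generator, a hard-pulse Bloch
simulator, traditional multi-spoke and binomial baselines, and
excitation-quality metrics.

The design problem is regularized magnitude least squares in the
small-tip-angle regime,

    argmin_x  || |A_iw x| - alpha0 ||^2 + lambda1 ||A_ow x||^2
              + lambda2 ||A_f x||^2 + beta * dt * ||x||^2

where `x` concatenates the channel-wise RF waveforms, and `A_iw`,
`A_ow`, `A_f` are spatial-domain system matrices for inside-slab water
(target flip `alpha0`, the Ernst angle ~13 deg), out-of-slab water
(target 0 at the water resonance), and a 400 Hz-wide fat stopband
(target 0 at -1200...-800 Hz over the whole brain). The problem is
solved by the variable exchange method; RF plays on three pairs of
bipolar slab trapezoids (1 ms period, minimum-time rewinder, ~3.3 ms
total) with a SPINS-like 2D in-plane trajectory for in-slab flip-angle
homogenization. See `vignette("pulse-design")` for the model,
assumptions and numerical choices.

## Worked example

A reduced-scale version of the full pipeline (24^3 grid at 8 mm, 20 us
raster) that runs in a few seconds:

```r
library(ptxspsp)

grid    <- grid_geometry(c(24, 24, 24), voxel_size = 8)
cal     <- generate_calibration(n_channels = 8, grid, seed = 1)
regions <- define_regions(cal, slab_center = 0, passband_width = 48)
limits  <- hardware_limits(raster_us = 20)

des <- design_spsp4d(cal, regions, limits = limits,
                     iw_inplane = 16, sb_inplane = 48, sb_throughplane = 24,
                     max_iter = 400)
ev  <- evaluate_design(des$wf, cal, regions)
print(ev$metrics)
#> metrics_report: RMSE-water(in) 1.663 deg, CoV 11.90%, RMSE-water(out) 2.491 deg, RMSE-fat 2.196 deg

sp  <- design_spokes(cal, regions, inplane_res = 16, limits = limits)
msp <- evaluate_design(sp$wf, cal, regions)$metrics
print(msp)
#> metrics_report: RMSE-water(in) 2.492 deg, CoV 17.87%, RMSE-water(out) 0.074 deg, RMSE-fat 4.881 deg

metrics_delta(ev$metrics, msp)[c("cov_water_in", "rmse_fat")]
#> cov_water_in     rmse_fat
#>    -33.40731    -55.00395
```

Reading the numbers: the 4D design reaches an in-slab flip-angle RMSE
of 1.66 deg against the 12.76 deg Ernst-angle target with an in-slab
coefficient of variation of 11.9%, and holds the Bloch-simulated fat
flip to 2.2 deg RMSE across the five stopband frequencies over the whole
brain. The traditional six-spoke design on the same synthetic subject
is less uniform (CoV 17.9%) and — being designed on in-slab water only —
leaves more than twice the fat excitation; the deltas (-33% CoV, -55%
fat RMSE) are the package's directional reproduction of the headline
comparison. The spoke design's sinc sub-pulses do give it a cleaner
out-of-slab water profile; the comprehensive design trades a little of
that against its fat stopband.

The full-size configuration (80 slices at 3 mm, 2 us raster, 12000 RF
unknowns) runs through the same functions, or from the shell:

```sh
Rscript inst/cli/ptxspsp.R synth-calib --channels 8 --shape 80,80,80 --voxel 3 --seed 1 --out calib
Rscript inst/cli/ptxspsp.R design --calib calib --passband 48 --out pulse.tsv
Rscript inst/cli/ptxspsp.R simulate --calib calib --waveform pulse.tsv --out metrics.tsv
Rscript inst/cli/ptxspsp.R tbwp-report --inter-pulse 0.4,0.5,0.6
```

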