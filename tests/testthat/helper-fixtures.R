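# Shared reduced-scale fixtures, built once per test run.
#
# The study conditions are the paper's setup scaled to a 24^3 grid at 8 mm
# (192 mm field of view) so the full design -> Bloch-evaluation pipeline
# runs in seconds: design down-sampling keeps the native-resolution
# multiples of the full-size prescription (2x native in-plane for in-slab
# water, 6x/3x in-plane/through-plane for the stopbands) and the RF raster
# is 20 us instead of 2 us (same oscillation window, so 150 RF samples per
# channel).

fixture_env <- new.env()

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

fix_grid <- function() grid_geometry(c(24, 24, 24), 8)

fix_cal <- function() fixture("cal", function()
  generate_calibration(8, fix_grid(), seed = 1, b0_severity = 50,
                       b1_inhomogeneity = 1))

fix_regions <- function() fixture("regions", function()
  define_regions(fix_cal(), 0, 48))

fix_limits <- function() hardware_limits(raster_us = 20)

fix_design4d <- function() fixture("design4d", function()
  design_spsp4d(fix_cal(), fix_regions(), limits = fix_limits(),
                iw_inplane = 16, sb_inplane = 48, sb_throughplane = 24,
                max_iter = 400))

fix_spokes <- function() fixture("spokes", function()
  design_spokes(fix_cal(), fix_regions(), inplane_res = 16,
                limits = fix_limits()))

fix_metrics4d <- function() fixture("metrics4d", function()
  evaluate_design(fix_design4d()$wf, fix_cal(), fix_regions())$metrics)

fix_metrics_spokes <- function() fixture("metrics_spokes", function()
  evaluate_design(fix_spokes()$wf, fix_cal(), fix_regions())$metrics)

# a waveform set with explicit RF, for direct physics checks
make_wf <- function(rf, grad, raster_us, rf_support = seq_len(nrow(grad)),
                    limits = hardware_limits(raster_us = raster_us)) {
  structure(list(rf = rf, grad = grad, raster_us = raster_us,
                 rf_support = rf_support,
                 t_total_ms = nrow(grad) * raster_us * 1e-3,
                 slab_axis = 3L, limits = limits), class = "waveform_set")
}

# small random magnitude-least-squares problem with empty stopbands
make_mls_problem <- function(A, alpha0, beta_reg, power_scale = 1) {
  structure(list(A_iw = A,
                 A_ow = matrix(0i, 0, ncol(A)),
                 A_f = matrix(0i, 0, ncol(A)),
                 alpha0 = alpha0, lambda1 = 0, lambda2 = 0,
                 beta_reg = beta_reg, power_scale = power_scale,
                 n_channels = 1L, n_t = ncol(A)),
            class = "design_problem")
}

random_complex_matrix <- function(n, m, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * m), imaginary = rnorm(n * m)), n, m)
}
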