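#' Objective of the regularized magnitude-least-squares design problem
#'
#' Total objective
#' `sum((|A_iw x| - alpha0)^2) + lambda1 ||A_ow x||^2 +
#'  lambda2 ||A_f x||^2 + beta ||x||^2`,
#' decomposed term by term for logging.
#'
#' @param p a `design_problem`.
#' @param x complex RF vector (microtesla per sample).
#' @return list with `total`, `fidelity`, `ow`, `fat`, `power` (deg^2).
#' @export
mls_objective <- function(p, x) {
  riw <- Mod(p$A_iw %*% x) - p$alpha0
  fidelity <- sum(riw^2)
  ow <- if (nrow(p$A_ow)) p$lambda1 * sum(Mod(p$A_ow %*% x)^2) else 0
  fat <- if (nrow(p$A_f)) p$lambda2 * sum(Mod(p$A_f %*% x)^2) else 0
  ps <- if (is.null(p$power_scale)) 1 else p$power_scale
  power <- p$beta_reg * ps * sum(Mod(x)^2)
  list(total = fidelity + ow + fat + power,
       fidelity = fidelity, ow = ow, fat = fat, power = power)
}

#' Circularly-polarized warm-start RF vector
#'
#' All channels share a constant waveform with azimuthal phase increments
#' `2 pi (c-1)/n_channels`, scaled by least squares so the mean in-slab
#' response magnitude is `alpha0`.
#' @keywords internal
cp_init <- function(p) {
  n_t <- p$n_t
  x <- complex(modulus = rep(1, p$n_channels * p$n_t),
               argument = rep(2 * pi * (seq_len(p$n_channels) - 1) /
                                p$n_channels, each = n_t))
  resp <- Mod(p$A_iw %*% x)
  sc <- p$alpha0 * sum(resp) / sum(resp^2)
  if (!is.finite(sc) || sc <= 0) sc <- 1
  x * sc
}

#' Solve the design problem by the variable exchange method
#'
#' Alternates (a) the phase update `z <- exp(i arg(A_iw x))` and (b) the
#' exact regularized linear least-squares update
#' `x <- argmin ||A_iw x - alpha0 z||^2 + lambda1 ||A_ow x||^2 +
#'  lambda2 ||A_f x||^2 + beta ||x||^2`,
#' solved through the stacked normal equations. Both half-steps minimize
#' the joint surrogate exactly, so the objective is non-increasing across
#' iterations; the iteration stops when the relative objective change
#' falls below `tol` or at `max_iter`. Because the normal matrix is fixed
#' across iterations it is factorized (inverted) once.
#'
#' @param p a `design_problem`.
#' @param init initial RF vector, or `"cp"` (default, circularly-polarized
#'   warm start) or `"random"`.
#' @param tol relative objective-change stopping threshold.
#' @param max_iter maximum number of variable-exchange cycles.
#' @param seed seed for `init = "random"`.
#' @return object of class `solver_state`: `x`, `z`, `objective`,
#'   `iterations`, `history` (data.frame of per-iteration objective
#'   terms), `converged`.
#' @export
vem_solve <- function(p, init = "cp", tol = 1e-5, max_iter = 500L,
                      seed = 1L) {
  stopifnot(tol > 0, p$beta_reg > 0 || nrow(p$A_iw) >= ncol(p$A_iw))
  n_unk <- ncol(p$A_iw)
  if (is.character(init)) {
    x <- switch(init,
      cp = cp_init(p),
      random = {
        set.seed(as.integer(seed))
        complex(real = rnorm(n_unk, 0, 0.1),
                imaginary = rnorm(n_unk, 0, 0.1))
      },
      stop("unknown init spec"))
  } else x <- as.complex(init)

  H <- crossprod(Conj(p$A_iw), p$A_iw)
  if (nrow(p$A_ow)) H <- H + p$lambda1 * crossprod(Conj(p$A_ow), p$A_ow)
  if (nrow(p$A_f)) H <- H + p$lambda2 * crossprod(Conj(p$A_f), p$A_f)
  ps <- if (is.null(p$power_scale)) 1 else p$power_scale
  diag(H) <- diag(H) + p$beta_reg * ps
  Hinv <- solve(H)

  obj <- mls_objective(p, x)
  history <- data.frame(iteration = 0L, total = obj$total,
                        fidelity = obj$fidelity, ow = obj$ow,
                        fat = obj$fat, power = obj$power)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ax <- as.vector(p$A_iw %*% x)
    z <- ifelse(Mod(ax) > 0, ax / Mod(ax), 1 + 0i)
    x_new <- as.vector(Hinv %*% (p$alpha0 * crossprod(Conj(p$A_iw), z)))
    obj_new <- mls_objective(p, x_new)
    if (!is.finite(obj_new$total))
      stop("non-finite objective; aborting variable exchange")
    history <- rbind(history,
                     data.frame(iteration = it, total = obj_new$total,
                                fidelity = obj_new$fidelity, ow = obj_new$ow,
                                fat = obj_new$fat, power = obj_new$power))
    rel <- abs(obj$total - obj_new$total) / max(obj$total, .Machine$double.eps)
    x <- x_new
    obj <- obj_new
    if (rel < tol) { converged <- TRUE; break }
  }
  structure(list(x = x, z = if (exists("z")) z else NULL,
                 objective = obj$total, terms = obj, iterations = it,
                 history = history, converged = converged),
            class = "solver_state")
}

#' @export
print.solver_state <- function(x, ...) {
  cat(sprintf(
    "solver_state: %d iterations (%s), objective %.4g (fidelity %.4g, ow %.4g, fat %.4g, power %.4g)\n",
    x$iterations, if (x$converged) "converged" else "max_iter",
    x$objective, x$terms$fidelity, x$terms$ow, x$terms$fat, x$terms$power))
  invisible(x)
}

#' Design a comprehensive 4D pTx spatial-spectral pulse
#'
#' End-to-end convenience wrapper: assembles the bipolar slab gradient
#' and SPINS-like in-plane trajectory, builds the four-region design
#' problem, solves it by variable exchange, and returns the waveform set
#' with the solved RF installed.
#'
#' @param cal a `calibration_set`.
#' @param regions a [define_regions()] result.
#' @param alpha0,lambda1,lambda2,beta_reg design-problem parameters, see
#'   [build_design_problem()].
#' @param limits a [hardware_limits()] (its raster sets the RF raster).
#' @param n_pairs,period_ms,plateau slab-gradient prescription, see
#'   [bipolar_slab_gradient()].
#' @param spins a [spins_params()]; `t_p` defaults to the oscillation
#'   window.
#' @param iw_inplane,sb_inplane,sb_throughplane down-sampling resolutions
#'   (mm) for the design matrices.
#' @param tol,max_iter,init solver controls, see [vem_solve()].
#' @return list with `wf` (the designed `waveform_set`), `problem`,
#'   `state`.
#' @export
design_spsp4d <- function(cal, regions, alpha0 = ernst_angle(),
                          lambda1 = 2, lambda2 = 8, beta_reg = 2000,
                          limits = hardware_limits(),
                          n_pairs = 3L, period_ms = 1, plateau = 25,
                          spins = NULL,
                          iw_inplane = 6, sb_inplane = 18,
                          sb_throughplane = 9,
                          tol = 1e-5, max_iter = 500L, init = "cp") {
  sg <- bipolar_slab_gradient(n_pairs, period_ms, plateau, limits)
  if (is.null(spins)) spins <- spins_params(t_p = sg$t_osc_ms)
  k2 <- spins_inplane_trajectory(spins, limits$raster_us)
  ip <- k_to_gradient(k2, limits$raster_us, limits)
  wf0 <- assemble_waveforms(sg, ip$grad, rf = NULL, limits = limits,
                            slab_axis = cal$grid$slab_axis)
  prob <- build_design_problem(
    cal, regions, wf0, alpha0, lambda1, lambda2, beta_reg,
    iw_inplane = iw_inplane,
    sb_inplane = sb_inplane, sb_throughplane = sb_throughplane)
  st <- vem_solve(prob, init = init, tol = tol, max_iter = max_iter)
  wf <- set_rf(wf0, st$x, prob$n_channels)
  list(wf = wf, problem = prob, state = st)
}
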