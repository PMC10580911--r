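# Nonlinear fitting of individual progress curves.
#
# The model has four free parameters (v0, vs, k, A0); the depletion factor
# gamma is never free — it is recomputed from (Et, It, v0, vs) at every
# evaluation, which keeps the fit self-consistent with the steady-state
# depletion theory. vs is reparameterized as f*v0 with f in [0, 1] so the
# bound vs <= v0 is structural, and the lower bound on f guarantees
# gamma < 1 throughout the search.

#' Fit one inhibited progress curve to the tight slow-binding model
#'
#' Bounded Levenberg-Marquardt least squares of `(v0, vs, k, A0)` with the
#' depletion factor recomputed from the candidate velocities at every step
#' (never a free parameter). On non-convergence the fit restarts up to
#' `max_restarts` times from jittered rate constants; a persistent failure
#' is returned flagged, not thrown.
#'
#' @param curve a `progress_curve` with `inhibitor_conc > 0` and >= 8 points.
#' @param Et total enzyme concentration (M).
#' @param max_restarts multi-start attempts on non-convergence (default 5).
#' @return An object of class `progress_fit`: `v0`, `vs`, `k` (1/s), `A0`,
#'   `gamma`, `residual_rms`, `converged`, `k_identifiable`, `covariance`,
#'   `n_points`, plus the curve's `It` and id.
#' @export
fit_progress_curve <- function(curve, Et, max_restarts = 5) {
  stopifnot(inherits(curve, "progress_curve"), Et > 0)
  if (curve$inhibitor_conc <= 0)
    stop("inhibitor_conc must be > 0 (use fit_uninhibited for the It = 0 trace)")
  t <- curve$times
  y <- curve$signal
  n <- length(t)
  if (n < 8) stop("need at least 8 points to fit the progress-curve model")
  It <- curve$inhibitor_conc

  local_slope <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(y[idx] ~ t[idx]))[2])
  }
  n_head <- max(5, ceiling(0.1 * n))
  n_tail <- max(5, ceiling(0.2 * n))
  v0_init <- max(local_slope(seq_len(n_head)), 1e-12)
  vs_init <- local_slope(seq(n - n_tail + 1, n))
  vs_init <- min(max(vs_init, 0), v0_init)

  # gamma < 1 requires (1 - f)^2 < It/Et; tighten slightly inside the bound
  f_lo <- if (It < Et) 1 - sqrt(0.999 * It / Et) else
    1 - sqrt(0.999 * min(It / Et, 1))
  f_lo <- max(f_lo, 1e-6)
  f_init <- min(max(vs_init / v0_init, f_lo + 1e-3), 0.999)

  # crude curvature timescale: time to cover half the head-to-tail slope change
  k_init <- 5 / diff(range(t))
  A0_init <- y[1]

  resid_fn <- function(par) {
    v0 <- par[1]; f <- par[2]; k <- par[3]; A0 <- par[4]
    g <- Et * (1 - f)^2 / It
    g <- min(g, 1 - 1e-12)
    eval_progress_model(v0, f * v0, k, A0, g, t) - y
  }

  lower <- c(1e-12, f_lo, 1e-6, -Inf)
  upper <- c(Inf, 1, 1, Inf)
  k_starts <- k_init * c(1, 0.2, 5, 0.04, 25, 125)[seq_len(max_restarts + 1)]
  best <- NULL
  for (ks in k_starts) {
    start <- c(v0 = v0_init, f = f_init, k = min(max(ks, 1e-6), 1), A0 = A0_init)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (fit$info %in% 1:4 && fit$deviance <= best$deviance + 0) best <- fit
    # accept early when converged and residuals are at noise level
    if (fit$info %in% 1:4) break
  }
  if (is.null(best)) {
    return(structure(
      list(curve_id = curve$curve_id, inhibitor_conc = It, Et = Et,
           v0 = NA_real_, vs = NA_real_, k = NA_real_, A0 = NA_real_,
           gamma = NA_real_, residual_rms = NA_real_, converged = FALSE,
           k_identifiable = FALSE, covariance = NULL, n_points = n),
      class = "progress_fit"))
  }

  p <- best$par
  v0 <- p[["v0"]]; f <- p[["f"]]; k <- p[["k"]]; A0 <- p[["A0"]]
  vs <- f * v0
  g <- min(Et * (1 - f)^2 / It, 1 - 1e-12)
  rms <- sqrt(best$deviance / n)
  converged <- best$info %in% 1:4
  # vs ~ v0 makes the trace linear: k then has no leverage
  k_identifiable <- f < 0.999

  covmat <- tryCatch({
    h <- best$hessian
    s2 <- best$deviance / max(n - 4, 1)
    v <- s2 * solve(h)
    dimnames(v) <- list(c("v0", "f", "k", "A0"), c("v0", "f", "k", "A0"))
    v
  }, error = function(e) NULL)

  structure(
    list(curve_id = curve$curve_id, inhibitor_conc = It, Et = Et,
         v0 = v0, vs = vs, k = k, A0 = A0, gamma = g,
         residual_rms = rms, converged = converged,
         k_identifiable = k_identifiable, covariance = covmat, n_points = n),
    class = "progress_fit")
}

#' @export
print.progress_fit <- function(x, ...) {
  cat(sprintf("<progress_fit> %s (It = %.3g nM)\n", x$curve_id,
              x$inhibitor_conc * 1e9))
  cat(sprintf("  v0 = %.4g AU/s, vs = %.4g AU/s, k = %.4g /s, gamma = %.4f\n",
              x$v0, x$vs, x$k, x$gamma))
  cat(sprintf("  rms = %.3g AU over %d points; converged: %s%s\n",
              x$residual_rms, x$n_points, x$converged,
              if (!x$k_identifiable) " (k unidentifiable: vs ~ v0)" else ""))
  invisible(x)
}

#' Initial velocity of an uninhibited progress curve
#'
#' Ordinary least-squares slope over the linear portion of the It = 0 trace.
#' When the assay design is supplied, only points below 20% of the
#' theoretical plateau (`A0 + extinction * path * S0`) enter the regression
#' (at least 10 points); otherwise all points are used.
#'
#' @param curve a `progress_curve` with `inhibitor_conc == 0`.
#' @param design optional `assay_design` providing the plateau rule.
#' @return Estimated v0 (signal/s), > 0.
#' @export
fit_uninhibited <- function(curve, design = NULL) {
  stopifnot(inherits(curve, "progress_curve"))
  if (curve$inhibitor_conc != 0)
    stop("fit_uninhibited expects the It = 0 reference curve")
  t <- curve$times; y <- curve$signal
  keep <- rep(TRUE, length(t))
  if (!is.null(design)) {
    plateau <- design$A0 +
      design$product_extinction * design$path_length * design$S0
    keep <- (y - design$A0) < 0.2 * (plateau - design$A0)
    if (sum(keep) < 10) keep <- seq_along(t) <= max(10, sum(keep))
  }
  slope <- unname(stats::coef(stats::lm(y[keep] ~ t[keep]))[2])
  if (!is.finite(slope) || slope <= 0)
    stop("uninhibited slope is not positive; check data orientation")
  slope
}

#' Fit a full inhibition series and extract the apparent Ki'
#'
#' Convenience driver: routes the It = 0 curve to [fit_uninhibited()], fits
#' every inhibited curve with [fit_progress_curve()], and runs the Henderson
#' regression.
#'
#' @param curves list of `progress_curve` objects (one series).
#' @param Et total enzyme concentration (M).
#' @param design optional `assay_design` (used for the uninhibited slope rule).
#' @return List with `fits` (inhibited fits), `v0_uninhibited` (or NA if no
#'   It = 0 curve present) and `henderson` (a `henderson_result`).
#' @export
fit_inhibition_series <- function(curves, Et, design = NULL) {
  is_zero <- vapply(curves, function(cv) cv$inhibitor_conc == 0, logical(1))
  v0_ref <- if (any(is_zero))
    fit_uninhibited(curves[[which(is_zero)[1]]], design) else NA_real_
  fits <- lapply(curves[!is_zero], fit_progress_curve, Et = Et)
  list(fits = fits, v0_uninhibited = v0_ref,
       henderson = henderson_ki(fits, Et))
}
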