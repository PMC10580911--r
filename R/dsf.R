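# DSF melting-curve analysis.
#
# The environment-sensitive dye reports unfolding as a fluorescence rise;
# the melting temperature is the half-point of that transition. Above the
# fluorescence maximum the dye-protein aggregate quenches, so the two-state
# Boltzmann model is valid only up to the peak — curves are truncated there
# before fitting.

#' Truncate a melt curve at its fluorescence maximum
#'
#' Drops the post-peak quench tail: returns the curve up to and including
#' its global fluorescence maximum. A maximum at the very first point means
#' the curve is inverted (or already fully quenched) and is an error.
#'
#' @param curve a `melt_curve`.
#' @return A `melt_curve` (unchanged if the maximum is the last point).
#' @export
truncate_quench <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  imax <- which.max(curve$fluorescence)
  if (imax == 1) stop("fluorescence maximum at the first point: inverted curve")
  if (imax == length(curve$fluorescence)) return(curve)
  melt_curve(curve$temperatures[seq_len(imax)],
             curve$fluorescence[seq_len(imax)],
             curve$replicate_id)
}

# Boltzmann sigmoid with linear native and unfolded baselines.
boltzmann_melt <- function(bn, mn, bu, mu, tm, a, T) {
  native <- bn + mn * T
  unfolded <- bu + mu * T
  native + (unfolded - native) / (1 + exp((tm - T) / a))
}

#' Fit a melt curve to a Boltzmann sigmoid with linear baselines
#'
#' Model: `F(T) = N(T) + (U(T) - N(T)) / (1 + exp((tm - T)/a))` with linear
#' native `N` and unfolded `U` baselines; `tm` is the half-transition point
#' by construction. Curves should be quench-truncated first (see
#' [truncate_quench()]). If the transition amplitude does not exceed three
#' times the local noise scale the result is flagged (no transition,
#' `tm = NA`) rather than thrown.
#'
#' @param curve a `melt_curve` (quench-truncated).
#' @return An object of class `melt_fit`: `tm` (degrees C), `a`
#'   (transition width, degrees C), `baseline_native`, `baseline_unfolded`
#'   (intercept/slope pairs), `method = "sigmoid"`, `residual_rms`,
#'   `converged`, `no_transition`.
#' @export
fit_melt_sigmoid <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  T <- curve$temperatures
  F <- curve$fluorescence
  n <- length(T)

  n_edge <- max(5, round(0.15 * n))
  lo <- seq_len(n_edge)
  hi <- seq(n - n_edge + 1, n)
  fit_n <- stats::lm(F[lo] ~ T[lo])
  fit_u <- stats::lm(F[hi] ~ T[hi])
  noise_scale <- stats::sd(stats::resid(fit_n))
  amplitude <- abs(mean(F[hi]) - mean(F[lo]))
  flagged <- function() structure(
    list(tm = NA_real_, a = NA_real_,
         baseline_native = c(intercept = NA_real_, slope = NA_real_),
         baseline_unfolded = c(intercept = NA_real_, slope = NA_real_),
         method = "sigmoid", residual_rms = NA_real_,
         converged = FALSE, no_transition = TRUE,
         replicate_id = curve$replicate_id),
    class = "melt_fit")
  if (amplitude <= 3 * max(noise_scale, .Machine$double.eps * max(abs(F), 1)) ||
      amplitude == 0)
    return(flagged())

  # initial tm: half-crossing of a heavily smoothed trace (robust to noise),
  # with the derivative estimate and mid-range as fallback starts
  w <- max(5, 2 * floor(n / 100) + 1)
  Fs <- as.numeric(stats::filter(F, rep(1 / w, w), sides = 2))
  half <- (mean(F[lo]) + max(Fs, na.rm = TRUE)) / 2
  cross <- which(Fs >= half)[1]
  tm_starts <- unique(c(if (is.finite(cross)) T[cross],
                        tryCatch(tm_by_derivative(curve),
                                 error = function(e) NULL),
                        stats::median(T)))
  resid_fn <- function(par)
    boltzmann_melt(par[1], par[2], par[3], par[4], par[5], par[6], T) - F
  fit <- NULL
  for (tm0 in tm_starts) {
    start <- c(bn = unname(stats::coef(fit_n)[1]), mn = unname(stats::coef(fit_n)[2]),
               bu = unname(stats::coef(fit_u)[1]), mu = unname(stats::coef(fit_u)[2]),
               tm = tm0, a = max(diff(range(T)) / 30, 0.5))
    cand <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         lower = c(-Inf, -Inf, -Inf, -Inf, min(T), 0.01),
                         upper = c(Inf, Inf, Inf, Inf, max(T), diff(range(T))),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(cand) && (is.null(fit) || cand$deviance < fit$deviance))
      fit <- cand
  }
  if (is.null(fit)) return(flagged())
  p <- fit$par
  structure(
    list(tm = p[["tm"]], a = p[["a"]],
         baseline_native = c(intercept = p[["bn"]], slope = p[["mn"]]),
         baseline_unfolded = c(intercept = p[["bu"]], slope = p[["mu"]]),
         method = "sigmoid",
         residual_rms = sqrt(fit$deviance / n),
         converged = fit$info %in% 1:4, no_transition = FALSE,
         replicate_id = curve$replicate_id),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  if (isTRUE(x$no_transition)) {
    cat(sprintf("<melt_fit> %s: no transition detected\n", x$replicate_id))
  } else {
    cat(sprintf("<melt_fit> %s: Tm = %.2f C (width a = %.2f C, %s)\n",
                x$replicate_id, x$tm, x$a, x$method))
  }
  invisible(x)
}

#' Melting temperature from the smoothed first derivative
#'
#' Cross-check for the sigmoid fit: the temperature at which the smoothed
#' dF/dT is maximal. For symmetric transitions this agrees with the sigmoid
#' half-point to within one temperature grid step.
#'
#' @param curve a `melt_curve` (quench-truncated), >= 20 points.
#' @param window running-mean smoothing window in points (odd, default 5).
#' @return Tm estimate (degrees C).
#' @export
tm_by_derivative <- function(curve, window = 5) {
  stopifnot(inherits(curve, "melt_curve"))
  T <- curve$temperatures
  F <- curve$fluorescence
  if (length(T) < 20) stop("need at least 20 points")
  if (window %% 2 == 0) window <- window + 1
  Fs <- as.numeric(stats::filter(F, rep(1 / window, window), sides = 2))
  dF <- diff(Fs) / diff(T)
  Tm_grid <- (T[-1] + T[-length(T)]) / 2
  ok <- is.finite(dF)
  if (!any(ok)) stop("derivative undefined everywhere")
  imax <- which(ok)[which.max(dF[ok])]
  if (max(dF[ok]) <= 0) stop("no rising transition found")
  Tm_grid[imax]
}

#' Fit replicate melt curves and summarize Tm
#'
#' Each replicate is quench-truncated and fitted independently; Tm is
#' reported as mean and sd across replicates.
#'
#' @param curves list of `melt_curve` replicates.
#' @param method `"sigmoid"` (default) or `"derivative"`.
#' @return List with `fits`, `tm_values`, `tm_mean`, `tm_sd`, `method`.
#' @export
fit_melt_replicates <- function(curves, method = c("sigmoid", "derivative")) {
  method <- match.arg(method)
  fits <- lapply(curves, function(cv) {
    cv <- truncate_quench(cv)
    if (method == "sigmoid") fit_melt_sigmoid(cv)
    else list(tm = tm_by_derivative(cv), method = "derivative",
              replicate_id = cv$replicate_id)
  })
  tms <- vapply(fits, function(f) f$tm, numeric(1))
  list(fits = fits, tm_values = tms,
       tm_mean = mean(tms, na.rm = TRUE),
       tm_sd = stats::sd(tms[is.finite(tms)]),
       method = method)
}
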