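# Tight slow-binding progress-curve model.
#
# One-step association E + I <-> EI with enzyme and inhibitor mutually
# depleted (tight binding) and association slow on the assay timescale gives
# the integrated product curve
#
#   A(t) = vs*t + (1-g)*(v0-vs)/(k*g) * ln[(1 - g*exp(-k*t))/(1 - g)] + A0
#
# where v0 and vs are initial and steady-state velocities, k the observed
# approach rate and g ("gamma") the depletion factor. Gamma is fully
# determined by the steady-state velocities and the totals:
#
#   gamma = Et * (1 - vs/v0)^2 / It
#
# which equals x1/x2, the ratio of the roots of the equilibrium binding
# quadratic x^2 - (Et + It + Ki')x + Et*It = 0.

#' Depletion factor of the tight-binding progress-curve model
#'
#' Computes `gamma = Et * (1 - vs/v0)^2 / It`, the depletion factor coupling
#' the integrated tight-binding progress-curve model to the steady-state
#' velocities. Equals the ratio x1/x2 of the roots of the equilibrium
#' binding quadratic, hence always in `[0, 1)` for a reachable steady state.
#'
#' @param Et total enzyme concentration (M), > 0.
#' @param It total inhibitor concentration (M), > 0.
#' @param v0 initial velocity (signal/s), > 0.
#' @param vs steady-state velocity (signal/s), `0 <= vs <= v0`.
#' @return The dimensionless depletion factor, in `[0, 1)`.
#' @seealso [morrison_fraction()], [eval_progress_model()]
#' @export
gamma_of <- function(Et, It, v0, vs) {
  if (!is.finite(Et) || Et <= 0) stop("Et must be positive")
  if (!is.finite(It) || It <= 0) stop("It must be positive")
  if (!is.finite(v0) || v0 <= 0) stop("v0 must be positive")
  if (!is.finite(vs) || vs < 0) stop("vs must be non-negative")
  if (vs > v0) stop("vs must not exceed v0")
  g <- Et * (1 - vs / v0)^2 / It
  if (g >= 1)
    stop("gamma >= 1: velocities inconsistent with a reachable steady state ",
         "(infinitely tight binding at this enzyme/inhibitor ratio)")
  g
}

#' Morrison steady-state velocity fraction for tight binding
#'
#' Closed-form steady-state fractional velocity vs/v0 for an enzyme titrated
#' by a tight-binding inhibitor: `vs/v0 = (Et - x1)/Et`, with `x1` the
#' smaller root of `x^2 - (Et + It + ki_app) x + Et*It = 0` (the equilibrium
#' complex concentration). Evaluated in the numerically stable product form
#' so the classical limit Et -> 0 is exact.
#'
#' @param Et total enzyme concentration (M), > 0.
#' @param It total inhibitor concentration (M), >= 0.
#' @param ki_app apparent inhibition constant (M), > 0.
#' @return Fractional velocity in (0, 1].
#' @export
morrison_fraction <- function(Et, It, ki_app) {
  if (!is.finite(Et) || Et <= 0) stop("Et must be positive")
  if (!is.finite(It) || It < 0) stop("It must be non-negative")
  if (!is.finite(ki_app) || ki_app <= 0) stop("ki_app must be positive")
  if (It == 0) return(1)
  b <- Et + It + ki_app
  disc <- b^2 - 4 * Et * It
  if (disc < 0) stop("internal error: negative discriminant in binding quadratic")
  x1 <- 2 * Et * It / (b + sqrt(disc))  # smaller root, stable form
  (Et - x1) / Et
}

# Roots (x1 <= x2) of the equilibrium binding quadratic; stable for x1.
binding_quadratic_roots <- function(Et, It, ki_app) {
  b <- Et + It + ki_app
  disc <- max(b^2 - 4 * Et * It, 0)
  x2 <- (b + sqrt(disc)) / 2
  x1 <- Et * It / x2
  c(x1 = x1, x2 = x2)
}

#' Evaluate the tight slow-binding progress-curve model
#'
#' Integrated product signal for slow, tight binding:
#' `A(t) = vs*t + (1-gamma)*(v0-vs)/(k*gamma) *
#'   log((1 - gamma*exp(-k*t))/(1 - gamma)) + A0`.
#' At `gamma = 0` the log term is 0/0; the analytic limit
#' `A(t) = vs*t + (v0-vs)*(1 - exp(-k*t))/k + A0` (classical slow binding,
#' no depletion) is used there. Interior evaluation goes through `log1p`,
#' so tiny positive gamma is continuous with the limit.
#'
#' @param v0 initial velocity (signal/s).
#' @param vs steady-state velocity (signal/s), `vs <= v0`.
#' @param k observed rate constant (1/s), > 0.
#' @param A0 baseline signal at t = 0.
#' @param gamma depletion factor in `[0, 1)`.
#' @param t times (s), >= 0; vectorized.
#' @return Signal values at `t`.
#' @export
eval_progress_model <- function(v0, vs, k, A0, gamma, t) {
  if (!is.finite(gamma) || gamma < 0 || gamma >= 1)
    stop("gamma must lie in [0, 1)")
  if (k <= 0) stop("k must be positive")
  if (vs > v0) stop("vs must not exceed v0")
  if (any(t < 0)) stop("t must be non-negative")
  e <- exp(-k * t)
  if (gamma < .Machine$double.eps) {
    vs * t + (v0 - vs) * (1 - e) / k + A0
  } else {
    vs * t + (1 - gamma) * (v0 - vs) / (k * gamma) *
      (log1p(-gamma * e) - log1p(-gamma)) + A0
  }
}

#' Henderson linearization for the apparent inhibition constant
#'
#' Regresses `y = It / (1 - vs/v0)` on `x = v0/vs` across an inhibition
#' series of tight-binding fits. For exact Morrison steady states the
#' identity `It/(1 - vs/v0) = ki_app * v0/vs + Et` holds, so the slope is
#' the apparent inhibition constant and the intercept should equal the total
#' enzyme concentration (reported as a diagnostic). The regression fits a
#' free intercept; constraining the line through the origin biases the slope
#' upward by a share of Et.
#'
#' @param fits list of `progress_fit` objects (each carries its It).
#' @param Et total enzyme concentration (M), for the intercept diagnostic.
#' @return An object of class `henderson_result`: `ki_app` (M, the slope),
#'   `intercept` (M), `r_squared`, `slope_stderr`, `points` (data frame of
#'   the regression coordinates), `n_curves`.
#' @export
henderson_ki <- function(fits, Et) {
  stopifnot("Et must be positive" = Et > 0)
  if (!is.list(fits) || length(fits) < 2)
    stop("need at least 2 progress fits")
  xs <- ys <- its <- numeric(0)
  for (f in fits) {
    if (!inherits(f, "progress_fit"))
      stop("fits must be progress_fit objects")
    if (f$inhibitor_conc <= 0) stop("Henderson points require It > 0")
    if (f$vs >= f$v0 * (1 - 1e-9)) {
      warning(sprintf("curve %s has vs = v0 (no inhibition); excluded",
                      f$curve_id))
      next
    }
    xs <- c(xs, f$v0 / f$vs)
    ys <- c(ys, f$inhibitor_conc / (1 - f$vs / f$v0))
    its <- c(its, f$inhibitor_conc)
  }
  if (length(xs) < 2) stop("fewer than 2 usable points for the Henderson regression")
  if (length(unique(signif(its, 12))) < 2)
    stop("Henderson regression needs at least 2 distinct inhibitor concentrations")
  fit <- stats::lm(ys ~ xs)
  sm <- suppressWarnings(summary(fit))  # noiseless series fit perfectly
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("Henderson slope is not positive; check curve orientation")
  structure(
    list(ki_app = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         slope_stderr = unname(sm$coefficients[2, 2]),
         points = data.frame(x = xs, y = ys, It = its),
         n_curves = length(xs),
         Et = Et,
         intercept_minus_Et = unname(stats::coef(fit)[1]) - Et),
    class = "henderson_result"
  )
}

#' @export
print.henderson_result <- function(x, ...) {
  cat("Henderson analysis of a tight-binding inhibition series\n")
  cat(sprintf("  apparent Ki'      : %.4g nM (slope; se %.2g nM)\n",
              x$ki_app * 1e9, x$slope_stderr * 1e9))
  cat(sprintf("  intercept         : %.4g nM (theory: Et = %.4g nM)\n",
              x$intercept * 1e9, x$Et * 1e9))
  cat(sprintf("  r-squared         : %.6f over %d curves\n",
              x$r_squared, x$n_curves))
  invisible(x)
}

#' Endpoint normalization of an inhibited progress curve
#'
#' Divides a test curve by the final (highest) signal of its matched
#' uninhibited reference and reports percent inhibition as
#' `100 * (1 - final normalized test value)`.
#'
#' @param test inhibited `progress_curve`.
#' @param reference matched uninhibited `progress_curve`.
#' @return List with `normalized` (numeric series) and `percent_inhibition`.
#' @export
normalize_endpoint <- function(test, reference) {
  stopifnot(inherits(test, "progress_curve"), inherits(reference, "progress_curve"))
  ref_final <- reference$signal[length(reference$signal)]
  if (ref_final <= reference$signal[1])
    stop("final reference signal does not exceed its baseline; cannot normalize")
  norm <- test$signal / ref_final
  list(normalized = norm,
       percent_inhibition = 100 * (1 - norm[length(norm)]))
}
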