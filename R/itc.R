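# Independent (identical, non-interacting) binding-sites ITC isotherm.
#
# Displacement-cell bookkeeping: each injection pushes an equal volume of
# cell liquid out, so cell species are diluted and titrant accumulates with
# the standard half-displacement correction. With cumulative injected
# volume dV through injection i:
#
#   Mt_i = M0 * (1 - dV/2V0) / (1 + dV/2V0)
#   Xt_i = Xs * (dV/V0)     / (1 + dV/2V0)
#
# The fraction of sites occupied solves the single-site quadratic in
# Theta; cumulative heat Q_i = n * Theta_i * Mt_i * dH * V0 and the
# observed injection heat is the difference plus the average-displacement
# term (dVi/V0) * (Q_i + Q_{i-1}) / 2.

#' Cell concentrations after i injections
#'
#' @param design a `titration_design`.
#' @param i injection index (1-based); vectorized.
#' @return Data frame with columns `injection`, `Mt` (cell species, M),
#'   `Xt` (titrant, M) and `molar_ratio` (Xt/Mt).
#' @export
injection_concentrations <- function(design, i = seq_len(design$n_injections)) {
  stopifnot(inherits(design, "titration_design"))
  if (any(i < 1) || any(i > design$n_injections))
    stop("injection index out of range")
  dV <- cumsum(design$injection_volumes)[i]
  V0 <- design$cell_volume
  if (any(dV >= V0)) stop("cumulative injected volume exceeds the cell volume")
  Mt <- design$cell_conc * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0))
  Xt <- design$syringe_conc * (dV / V0) / (1 + dV / (2 * V0))
  data.frame(injection = i, Mt = Mt, Xt = Xt, molar_ratio = Xt / Mt)
}

# Occupied-site fraction: smaller root of
# Theta^2 - Theta(1 + r + K) + r = 0, r = Xt/(n Mt), K = kd/(n Mt).
# Stable product form keeps Theta in [0, 1].
site_fraction <- function(n, kd, Mt, Xt) {
  r <- Xt / (n * Mt)
  K <- kd / (n * Mt)
  b <- 1 + r + K
  disc <- pmax(b^2 - 4 * r, 0)
  theta <- 2 * r / (b + sqrt(disc))
  if (any(theta < -1e-12 | theta > 1 + 1e-12))
    stop("internal error: site fraction outside [0, 1]")
  pmin(pmax(theta, 0), 1)
}

#' Expected per-injection heats under the independent-sites model
#'
#' @param n stoichiometry (sites per cell molecule), > 0.
#' @param kd dissociation constant (M), > 0.
#' @param delta_h molar binding enthalpy (J/mol), signed (exothermic < 0).
#' @param design a `titration_design`.
#' @param dilution_correction apply the average-displacement heat term
#'   (default TRUE).
#' @return Numeric vector of heats (J), one per injection.
#' @export
expected_heats <- function(n, kd, delta_h, design, dilution_correction = TRUE) {
  stopifnot(inherits(design, "titration_design"), n > 0, kd > 0)
  cc <- injection_concentrations(design)
  theta <- site_fraction(n, kd, cc$Mt, cc$Xt)
  Q <- n * theta * cc$Mt * delta_h * design$cell_volume
  Qprev <- c(0, Q[-length(Q)])
  dq <- Q - Qprev
  if (dilution_correction) {
    dq <- dq + (design$injection_volumes / design$cell_volume) * (Q + Qprev) / 2
  }
  dq
}

#' Subtract blank (titrant-into-buffer) heats
#'
#' @param heats an `injection_heats` object with `blank_heats` present.
#' @return An `injection_heats` object with blanks subtracted and cleared.
#' @export
subtract_blank <- function(heats) {
  stopifnot(inherits(heats, "injection_heats"))
  if (is.null(heats$blank_heats))
    stop("no blank_heats present to subtract")
  injection_heats(heats$heats - heats$blank_heats)
}

#' Wiseman conditioning parameter
#'
#' `c = n * M0 / kd`; the dissociation constant is well determined roughly
#' for 1 < c < 1000.
#'
#' @param n stoichiometry.
#' @param kd dissociation constant (M).
#' @param design a `titration_design` (supplies M0).
#' @return Dimensionless c value.
#' @export
c_value <- function(n, kd, design) {
  stopifnot(inherits(design, "titration_design"))
  n * design$cell_conc / kd
}

#' Fit integrated ITC heats to the independent-binding-sites isotherm
#'
#' Least-squares `(n, kd, delta_h)` against [expected_heats()], with kd
#' searched on the log scale and multi-started over several decades. Blank
#' heats, if attached, are subtracted first. A conditioning warning is
#' attached (and emitted) when the Wiseman c value leaves `[1, 1000]`; when
#' the isotherm explains little of the heat variance the fit is flagged
#' `no_binding`.
#'
#' @param heats an `injection_heats` object.
#' @param design a `titration_design`.
#' @param init optional named list with starting `n`, `kd`, `delta_h`.
#' @param drop_first discard the first injection before fitting (common
#'   practice for syringe-tip diffusion artifacts; default FALSE).
#' @param dilution_correction apply the displacement heat term (default TRUE).
#' @return An object of class `binding_fit`: `n_sites`, `kd` (M), `delta_h`
#'   (J/mol), `c_value`, `residual_rms` (J), `covariance`, `converged`,
#'   `conditioning_warning`, `no_binding`.
#' @export
fit_itc <- function(heats, design, init = NULL, drop_first = FALSE,
                    dilution_correction = TRUE) {
  stopifnot(inherits(heats, "injection_heats"),
            inherits(design, "titration_design"))
  if (!is.null(heats$blank_heats)) heats <- subtract_blank(heats)
  q <- heats$heats
  if (length(q) != design$n_injections)
    stop("number of heats does not match the titration design")
  use <- rep(TRUE, length(q))
  if (drop_first) use[1] <- FALSE
  if (sum(use) < 6) stop("need at least 6 usable injections")
  ratios <- injection_concentrations(design)$molar_ratio[use]
  if (length(unique(signif(ratios, 10))) < 3)
    stop("need at least 3 distinct molar-ratio points")

  M0 <- design$cell_conc
  # initialization: enthalpy from the first retained (nearly saturating)
  # injection; stoichiometry near 1; kd multi-started across decades
  inj_moles <- design$syringe_conc * design$injection_volumes
  dh0 <- if (!is.null(init$delta_h)) init$delta_h else
    q[which(use)[1]] / inj_moles[which(use)[1]]
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1e4
  n0 <- if (!is.null(init$n)) init$n else 1
  kd_starts <- if (!is.null(init$kd)) init$kd else
    M0 * c(1e-3, 1e-2, 1e-1, 1, 1e-4)

  resid_fn <- function(par) {
    n <- exp(par[1]); kd <- exp(par[2]); dh <- par[3]
    expected_heats(n, kd, dh, design, dilution_correction)[use] - q[use]
  }
  best <- NULL
  for (kd0 in kd_starts) {
    start <- c(log_n = log(n0), log_kd = log(kd0), dh = dh0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         lower = c(log(1e-3), log(1e-15), -Inf),
                         upper = c(log(1e3), log(1), Inf),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(n_sites = NA_real_, kd = NA_real_,
                          delta_h = NA_real_, c_value = NA_real_,
                          residual_rms = NA_real_, covariance = NULL,
                          converged = FALSE, conditioning_warning = FALSE,
                          no_binding = FALSE, n_used = sum(use)),
                     class = "binding_fit"))

  n_hat <- exp(best$par[[1]]); kd_hat <- exp(best$par[[2]])
  dh_hat <- best$par[[3]]
  rms <- sqrt(best$deviance / sum(use))
  ss_tot <- sum((q[use] - mean(q[use]))^2)
  r2 <- if (ss_tot > 0) 1 - best$deviance / ss_tot else 0
  no_binding <- r2 < 0.5 || abs(dh_hat) * n_hat * M0 * design$cell_volume <
    3 * stats::sd(q[use]) / sqrt(sum(use))
  cval <- c_value(n_hat, kd_hat, design)
  cond_warn <- is.finite(cval) && (cval > 1000 || cval < 1)
  if (cond_warn)
    warning(sprintf("Wiseman c = %.3g outside [1, 1000]: kd weakly identified",
                    cval))
  covmat <- tryCatch({
    s2 <- best$deviance / max(sum(use) - 3, 1)
    v <- s2 * solve(best$hessian)
    dimnames(v) <- list(c("log_n", "log_kd", "dh"), c("log_n", "log_kd", "dh"))
    v
  }, error = function(e) NULL)

  structure(
    list(n_sites = n_hat, kd = kd_hat, delta_h = dh_hat, c_value = cval,
         residual_rms = rms, covariance = covmat,
         converged = best$info %in% 1:4,
         conditioning_warning = cond_warn, no_binding = no_binding,
         r_squared = r2, n_used = sum(use)),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Independent-binding-sites ITC fit\n")
  cat(sprintf("  n  = %.3f sites\n", x$n_sites))
  cat(sprintf("  KD = %.4g nM\n", x$kd * 1e9))
  cat(sprintf("  dH = %.4g kJ/mol\n", x$delta_h / 1000))
  cat(sprintf("  c  = %.3g%s\n", x$c_value,
              if (isTRUE(x$conditioning_warning)) "  ** outside [1, 1000] **" else ""))
  if (isTRUE(x$no_binding)) cat("  NOTE: no binding signal detected\n")
  invisible(x)
}
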