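# Mechanistic synthetic-data generators.
#
# Progress curves come from the one-step association scheme
#   E + I <-> EI   (kon_app, koff), with product formed at
#   dP/dt = vspec * (Et - [EI]) / Et.
# The [EI](t) equation is a Riccati equation with equilibrium roots x1 < x2
# of x^2 - (Et + It + Ki')x + Et*It = 0:
#   x(t) = x1 (1 - e^{-kt}) / (1 - (x1/x2) e^{-kt}),  k = kon_app (x2 - x1),
# and the integrated product curve is exactly the tight slow-binding model
# with v0 = eps*l*vspec, vs = v0 (Et - x1)/Et, gamma = x1/x2. An
# independent stiff ODE integration of the full species system is provided
# as a cross-validation mode.

#' Built-in study fixtures
#'
#' Named simulation scenarios mirroring the assay designs of a
#' propeptide-protease inhibition study, with ground-truth parameters
#' attached:
#' \describe{
#'   \item{pernisine_25C}{2 nM protease, 0.5 mM Suc-AAPL-pNA, inhibitor
#'     0/1/2/4/8 nM, 1800 s window at 25 C; truth Ki' = 0.33 nM.}
#'   \item{pernisine_50C}{same design at 50 C, 900 s window, faster
#'     association; truth Ki' = 20 pM.}
#'   \item{itc_25C}{19 x 5 uL of 100 uM titrant into 5 uM protein, 950 uL
#'     cell; truth n = 0.68, KD = 96 nM, dH = -50 kJ/mol.}
#'   \item{itc_50C}{same geometry; truth n = 0.89, KD = 1.3 nM (high-c
#'     regime), dH = -50 kJ/mol.}
#'   \item{dsf_UP}{25 to 99 C ramp at 0.05 C/s; truth Tm = 67.8 C, width
#'     a = 1.5 C (unprocessed propeptide-protease complex).}
#'   \item{dsf_AP}{same ramp; truth Tm = 85.2 C (autoprocessed complex).}
#' }
#'
#' @param name fixture name.
#' @return A list with `name`, `kind` (`"progress"`, `"itc"` or `"dsf"`),
#'   `design`, and `truth`.
#' @export
propkin_fixture <- function(name = c("pernisine_25C", "pernisine_50C",
                                     "itc_25C", "itc_50C",
                                     "dsf_UP", "dsf_AP")) {
  name <- match.arg(name)
  switch(name,
    pernisine_25C = list(
      name = name, kind = "progress",
      design = assay_design(Et = 2e-9, S0 = 5e-4, temperature = 25,
                            duration = 1800, sampling_interval = 2,
                            v0_abs = 2e-4),
      truth = slow_binding_params(kon_app = 2e6, koff = 0.33e-9 * 2e6),
      it_grid = c(0, 1, 2, 4, 8) * 1e-9),
    pernisine_50C = list(
      name = name, kind = "progress",
      design = assay_design(Et = 2e-9, S0 = 5e-4, temperature = 50,
                            duration = 900, sampling_interval = 1,
                            v0_abs = 4e-4),
      truth = slow_binding_params(kon_app = 5e6, koff = 0.020e-9 * 5e6),
      it_grid = c(0, 1, 2, 4, 8) * 1e-9),
    itc_25C = list(
      name = name, kind = "itc",
      design = titration_design(cell_volume = 950e-6, cell_conc = 5e-6,
                                syringe_conc = 100e-6,
                                injection_volumes = rep(5e-6, 19),
                                temperature = 25),
      truth = list(n = 0.68, kd = 96e-9, delta_h = -5e4)),
    itc_50C = list(
      name = name, kind = "itc",
      design = titration_design(cell_volume = 950e-6, cell_conc = 5e-6,
                                syringe_conc = 100e-6,
                                injection_volumes = rep(5e-6, 19),
                                temperature = 50),
      truth = list(n = 0.89, kd = 1.3e-9, delta_h = -5e4)),
    dsf_UP = list(
      name = name, kind = "dsf",
      design = list(t_min = 25, t_max = 99, step = 0.05),
      truth = list(tm = 67.8, a = 1.5,
                   bn = 50, mn = 2, bu = 3000, mu = -5)),
    dsf_AP = list(
      name = name, kind = "dsf",
      design = list(t_min = 25, t_max = 99, step = 0.05),
      truth = list(tm = 85.2, a = 1.5,
                   bn = 50, mn = 2, bu = 3000, mu = -5))
  )
}

# Map mechanistic rate constants + design to the observable progress-curve
# parameters (v0, vs, k, gamma) on the absorbance scale.
riccati_observables <- function(params, design, It) {
  Et <- design$Et
  v0 <- design$v0_abs
  if (It == 0)
    return(list(v0 = v0, vs = v0, k = NA_real_, gamma = 0,
                x1 = 0, x2 = NA_real_))
  ki <- params$ki_app
  if (ki > 0) {
    r <- binding_quadratic_roots(Et, It, ki)
  } else {
    r <- c(x1 = min(Et, It), x2 = max(Et, It))  # irreversible limit
  }
  x1 <- r[["x1"]]; x2 <- r[["x2"]]
  list(v0 = v0, vs = v0 * (Et - x1) / Et,
       k = params$kon_app * (x2 - x1),
       gamma = x1 / x2, x1 = x1, x2 = x2)
}

#' Simulate one slow tight-binding progress curve
#'
#' Generates the A410 trace for the one-step association mechanism either
#' from the closed-form Riccati solution (`mode = "analytic"`) or by stiff
#' numerical integration of the full species system (`mode = "ode"`; the
#' independent cross-check). Noise is multiplicative Gaussian on the
#' absorbance. The free-substrate approximation is monitored: if the
#' uninhibited trace would consume more than 10% of the substrate over the
#' window a warning is emitted.
#'
#' @param params a `slow_binding_params` (ground truth).
#' @param design an `assay_design`.
#' @param It total inhibitor concentration (M) for this curve.
#' @param noise a `sim_noise`; its seed (if non-NULL) seeds the draw.
#' @param mode `"analytic"` or `"ode"`.
#' @param curve_id label (default derived from It).
#' @return A `progress_curve`.
#' @export
simulate_progress_curve <- function(params, design, It, noise = no_noise(),
                                    mode = c("analytic", "ode"),
                                    curve_id = NULL) {
  stopifnot(inherits(params, "slow_binding_params"),
            inherits(design, "assay_design"), It >= 0)
  mode <- match.arg(mode)
  if (is.null(curve_id)) curve_id <- sprintf("It_%.3gnM", It * 1e9)
  t <- seq(0, design$duration, by = design$sampling_interval)
  eps_l <- design$product_extinction * design$path_length

  # free-substrate check on the uninhibited rate (upper bound on consumption)
  consumed <- design$v0_abs / eps_l * design$duration
  if (consumed > 0.10 * design$S0)
    warning(sprintf(
      "substrate consumption ~%.0f%% exceeds the 10%% free-substrate budget",
      100 * consumed / design$S0))

  A <- if (mode == "analytic") {
    ob <- riccati_observables(params, design, It)
    if (It == 0) {
      design$A0 + ob$v0 * t
    } else if (ob$x1 == ob$x2 || !is.finite(ob$k) || ob$k == 0) {
      # double-root (koff = 0, It = Et): x(t) = x1^2 kon t / (1 + x1 kon t)
      x1 <- ob$x1; kon <- params$kon_app
      # P(t) = vspec/Et * int (Et - x) = vspec t - vspec/Et * int x dt
      # int_0^t x ds = x1 t - log(1 + x1 kon t)/kon
      vspec <- design$v0_abs / eps_l
      P <- vspec * t - vspec / design$Et *
        (x1 * t - log1p(x1 * kon * t) / kon)
      design$A0 + eps_l * P
    } else {
      eval_progress_model(ob$v0, ob$vs, ob$k, design$A0, ob$gamma, t)
    }
  } else {
    sim_progress_ode(params, design, It, t)
  }
  A_noisy <- if (noise$progress_rel_sigma > 0) {
    with_seed(noise$seed, function()
      A * (1 + stats::rnorm(length(A), 0, noise$progress_rel_sigma)))
  } else A
  progress_curve(curve_id, It, t, A_noisy)
}

# Full-species ODE integration (E, I, EI, P); returns A410 at times t.
# Carrying all species makes mass conservation a real (testable) property
# of the integrator rather than an identity.
sim_progress_ode <- function(params, design, It, t) {
  eps_l <- design$product_extinction * design$path_length
  vspec <- design$v0_abs / eps_l
  Et <- design$Et
  rhs <- function(time, state, p) {
    E <- state[1]; I <- state[2]; EI <- state[3]
    flux <- p$kon * E * I - p$koff * EI
    list(c(-flux, -flux, flux, p$vspec * E / p$Et))
  }
  out <- deSolve::lsoda(
    y = c(E = Et, I = It, EI = 0, P = 0), times = t, func = rhs,
    parms = list(kon = params$kon_app, koff = params$koff,
                 vspec = vspec, Et = Et),
    rtol = 1e-11, atol = c(1e-16, 1e-16, 1e-16, 1e-14), maxsteps = 1e5)
  if (nrow(out) != length(t))
    stop("ODE integration failed to reach the end of the window")
  attr_out <- design$A0 + eps_l * out[, "P"]
  attr(attr_out, "species") <- out
  attr_out
}

#' Simulate a full inhibition series
#'
#' One progress curve per inhibitor concentration in the fixture grid
#' (default 0/1/2/4/8 nM), drawn from a single seeded noise stream so the
#' whole series is reproducible from `(fixture, seed)`.
#'
#' @param fixture a progress fixture from [propkin_fixture()].
#' @param noise a `sim_noise`.
#' @param mode `"analytic"` or `"ode"`.
#' @return List of `progress_curve` objects.
#' @export
simulate_inhibition_series <- function(fixture, noise = no_noise(),
                                       mode = "analytic") {
  stopifnot(fixture$kind == "progress")
  per_curve_noise <- sim_noise(noise$progress_rel_sigma, noise$itc_abs_sigma,
                               noise$dsf_rel_sigma, seed = NULL)
  with_seed(noise$seed, function()
    lapply(fixture$it_grid, function(It)
      simulate_progress_curve(fixture$truth, fixture$design, It,
                              per_curve_noise, mode)))
}

#' Simulate integrated ITC injection heats
#'
#' Expected heats under the independent-sites isotherm plus additive
#' Gaussian noise; optionally a constant dilution-heat offset is added and
#' returned in `blank_heats` (mimicking a titrant-into-buffer blank).
#'
#' @param fixture an itc fixture from [propkin_fixture()].
#' @param noise a `sim_noise`.
#' @param dilution_offset constant blank heat per injection (J, default 0).
#' @return An `injection_heats` object.
#' @export
simulate_itc <- function(fixture, noise = no_noise(), dilution_offset = 0) {
  stopifnot(fixture$kind == "itc")
  tr <- fixture$truth
  q <- expected_heats(tr$n, tr$kd, tr$delta_h, fixture$design)
  nq <- length(q)
  q_noisy <- with_seed(noise$seed, function()
    q + dilution_offset +
      if (noise$itc_abs_sigma > 0)
        stats::rnorm(nq, 0, noise$itc_abs_sigma) else 0)
  injection_heats(q_noisy,
                  blank_heats = if (dilution_offset != 0)
                    rep(dilution_offset, nq) else NULL)
}

#' Simulate a DSF melt curve
#'
#' Boltzmann sigmoid with linear baselines on the ramp grid (default
#' 25 to 99 C in 0.05 C steps, i.e. 1 s sampling at 0.05 C/s), optional
#' exponential dye-quench decay beyond `tm + 3a`, multiplicative noise.
#'
#' @param fixture a dsf fixture from [propkin_fixture()].
#' @param noise a `sim_noise`.
#' @param quench include the post-transition quench tail (default TRUE).
#' @param quench_tau quench decay scale (degrees C, default 4).
#' @param decimate keep every `decimate`-th point (default 1 = full grid).
#' @param replicate_id label.
#' @return A `melt_curve`.
#' @export
simulate_melt <- function(fixture, noise = no_noise(), quench = TRUE,
                          quench_tau = 4, decimate = 1,
                          replicate_id = fixture$name) {
  stopifnot(fixture$kind == "dsf")
  d <- fixture$design; tr <- fixture$truth
  T <- seq(d$t_min, d$t_max, by = d$step)
  if (decimate > 1) T <- T[seq(1, length(T), by = decimate)]
  F <- boltzmann_melt(tr$bn, tr$mn, tr$bu, tr$mu, tr$tm, tr$a, T)
  if (quench) {
    onset <- tr$tm + 3 * tr$a
    F <- F * exp(-pmax(0, T - onset) / quench_tau)
  }
  F_noisy <- if (noise$dsf_rel_sigma > 0) {
    with_seed(noise$seed, function()
      F * (1 + stats::rnorm(length(F), 0, noise$dsf_rel_sigma)))
  } else F
  melt_curve(T, F_noisy, replicate_id)
}
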