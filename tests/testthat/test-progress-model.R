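test_that("gamma_of matches its definition and the binding-quadratic root ratio", {
  # no inhibition: vs = v0 gives gamma = 0
  expect_identical(gamma_of(2 * nM, 8 * nM, 1, 1), 0)

  # complete inhibition at equimolarity sits on the gamma = 1 boundary
  expect_error(gamma_of(2 * nM, 2 * nM, 1, 0), "gamma >= 1")

  # gamma from Morrison steady-state velocities equals x1/x2 of the quadratic
  for (ki in c(0.033, 0.33, 3.3) * nM) {
    for (It in c(1, 2, 4, 8, 15) * nM) {
      fr <- morrison_fraction(2 * nM, It, ki)
      r <- oracle_roots(2 * nM, It, ki)
      expect_equal(gamma_of(2 * nM, It, 1, fr), r$x1 / r$x2,
                   tolerance = 1e-12)
    }
  }

  expect_error(gamma_of(0, 1 * nM, 1, 0.5))
  expect_error(gamma_of(2 * nM, 0, 1, 0.5))
  expect_error(gamma_of(2 * nM, 8 * nM, 1, 1.5), "vs must not exceed v0")
})

test_that("morrison_fraction matches the quadratic-root oracle and its limits", {
  expect_identical(morrison_fraction(2 * nM, 0, 0.33 * nM), 1)

  # brute-force root: x1 ~ 1.951 nM so vs/v0 ~ 0.025
  r <- oracle_roots(2 * nM, 15 * nM, 0.33 * nM)
  expect_equal(morrison_fraction(2 * nM, 15 * nM, 0.33 * nM),
               (2 * nM - r$x1) / (2 * nM), tolerance = 1e-12)
  expect_equal(morrison_fraction(2 * nM, 15 * nM, 0.33 * nM), 0.0247,
               tolerance = 1e-2)

  # classical (non-tight) limit: vs/v0 -> 1/(1 + It/Ki)
  expect_equal(morrison_fraction(1e-15, 1 * nM, 1 * nM), 0.5,
               tolerance = 1e-6)
})

test_that("vs/v0 is strictly decreasing in It and increasing in ki_app", {
  its <- seq(0.5, 20, length.out = 15) * nM
  kis <- c(0.01, 0.1, 1, 10) * nM
  for (ki in kis) {
    fr <- vapply(its, function(It) morrison_fraction(2 * nM, It, ki), 0)
    expect_true(all(diff(fr) < 0))
  }
  for (It in its) {
    fr <- vapply(kis, function(ki) morrison_fraction(2 * nM, It, ki), 0)
    expect_true(all(diff(fr) > 0))
  }
})

test_that("eval_progress_model honors t = 0, the gamma -> 0 limit and domain", {
  expect_equal(eval_progress_model(1e-3, 1e-4, 1e-3, 0.02, 0.5, 0), 0.02)

  # continuity at the depletion-free limit
  lim <- function(v0, vs, k, A0, t) vs * t + (v0 - vs) * (1 - exp(-k * t)) / k + A0
  for (t in c(10, 100, 1000)) {
    expect_equal(eval_progress_model(1e-3, 2e-4, 5e-3, 0.02, 1e-12, t),
                 lim(1e-3, 2e-4, 5e-3, 0.02, t), tolerance = 1e-8)
  }

  expect_error(eval_progress_model(1, 0.5, 1e-3, 0, 1, 10), "gamma")
  expect_error(eval_progress_model(1, 0.5, 1e-3, 0, -0.1, 10), "gamma")
})

test_that("model with Riccati-mapped parameters equals the integrated ODE curve", {
  # the closed-form map is recomputed here from polyroot, independent of the
  # package's internal mapping
  d <- assay_design(Et = 2 * nM, S0 = 5e-4, duration = 1800,
                    sampling_interval = 10, v0_abs = 2e-4)
  p <- slow_binding_params(kon_app = 1e6, koff = 3.3e-4)
  ob <- oracle_observables(1e6, 3.3e-4, d$Et, 4 * nM, d$v0_abs)
  t <- seq(0, 1800, by = 10)
  a_model <- eval_progress_model(ob$v0, ob$vs, ob$k, d$A0, ob$gamma, t)
  a_ode <- simulate_progress_curve(p, d, 4 * nM, no_noise(), mode = "ode")
  expect_equal(a_model, a_ode$signal, tolerance = 1e-7)
})

test_that("Henderson regression is exact on Morrison steady states", {
  Et <- 2 * nM
  ki <- 0.33 * nM
  fits <- morrison_fits(Et, ki, c(1, 2, 4, 8) * nM)
  h <- henderson_ki(fits, Et)
  expect_equal(h$ki_app, ki, tolerance = 1e-10)
  expect_equal(h$intercept, Et, tolerance = 1e-10)
  expect_equal(h$r_squared, 1, tolerance = 1e-12)
  expect_equal(h$n_curves, 4L)
})

test_that("forcing the Henderson line through the origin biases the slope upward", {
  for (ki in c(0.05, 0.33, 2) * nM) {
    for (Et in c(1, 2, 5) * nM) {
      fits <- morrison_fits(Et, ki, c(1, 2, 4, 8) * nM)
      h <- henderson_ki(fits, Et)
      x <- h$points$x
      y <- h$points$y
      slope_origin <- sum(x * y) / sum(x * x)
      expect_gt(slope_origin, h$ki_app)
    }
  }
})

test_that("Henderson regression rejects degenerate input", {
  Et <- 2 * nM
  fits <- morrison_fits(Et, 0.33 * nM, c(4, 4) * nM)
  expect_error(henderson_ki(fits, Et), "distinct inhibitor concentrations")
  expect_error(henderson_ki(fits[1], Et), "at least 2")

  # a curve with vs = v0 is excluded with a warning
  free <- structure(list(curve_id = "free", inhibitor_conc = 1 * nM, Et = Et,
                         v0 = 1, vs = 1, k = 1, A0 = 0, gamma = 0,
                         converged = TRUE, k_identifiable = FALSE),
                    class = "progress_fit")
  fits3 <- c(morrison_fits(Et, 0.33 * nM, c(2, 8) * nM), list(free))
  expect_warning(h <- henderson_ki(fits3, Et), "excluded")
  expect_equal(h$n_curves, 2L)
})

test_that("endpoint normalization reports percent inhibition", {
  t <- seq(0, 100, by = 5)
  ref <- progress_curve("ref", 0, t, 0.02 + 5e-3 * t)
  expect_equal(normalize_endpoint(ref, ref)$percent_inhibition, 0)

  half <- progress_curve("half", 1 * nM, t, (0.02 + 5e-3 * t) / 2)
  expect_equal(normalize_endpoint(half, ref)$percent_inhibition, 50)

  flat <- progress_curve("flat", 0, t, rep(0.02, length(t)))
  expect_error(normalize_endpoint(ref, flat), "baseline")

  # inhibition strictly increasing in It on the simulated 25 C series
  fx <- propkin_fixture("pernisine_25C")
  curves <- simulate_inhibition_series(fx, no_noise())
  ref_sim <- curves[[1]]
  pct <- vapply(curves[-1], function(cv)
    normalize_endpoint(cv, ref_sim)$percent_inhibition, 0)
  expect_true(all(diff(pct) > 0))
})
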