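test_that("noiseless progress curves are recovered essentially exactly", {
  # slow-association design: the fit must still find the global optimum
  d <- assay_design(Et = 2 * nM, S0 = 5e-4, duration = 1800,
                    sampling_interval = 2, v0_abs = 2e-4)
  p <- slow_binding_params(kon_app = 1e5, koff = 3.3e-5)
  truth <- oracle_observables(1e5, 3.3e-5, d$Et, 4 * nM, d$v0_abs)
  cv <- simulate_progress_curve(p, d, 4 * nM)
  f <- fit_progress_curve(cv, d$Et)
  expect_true(f$converged)
  expect_equal(f$v0, truth$v0, tolerance = 1e-3)
  expect_equal(f$vs, truth$vs, tolerance = 1e-3)
  expect_equal(f$k, truth$k, tolerance = 1e-3)
  expect_equal(f$A0, d$A0, tolerance = 1e-6)
  # stored gamma is consistent with the stored velocities (model coupling)
  expect_equal(f$gamma, d$Et * (1 - f$vs / f$v0)^2 / cv$inhibitor_conc,
               tolerance = 1e-9)
})

test_that("an uninhibited trace passed to the tight-binding fitter is flagged", {
  d <- assay_design(Et = 2 * nM, S0 = 5e-4, duration = 1800,
                    sampling_interval = 2, v0_abs = 2e-4)
  t <- seq(0, 1800, by = 2)
  cv <- progress_curve("oops", 4 * nM, t, d$A0 + d$v0_abs * t)
  f <- fit_progress_curve(cv, d$Et)
  expect_true(f$converged)
  expect_gte(f$vs / f$v0, 0.999)
  expect_false(f$k_identifiable)
})

test_that("1% multiplicative noise leaves parameter recovery within 10%", {
  fx <- propkin_fixture("pernisine_25C")
  truth <- oracle_observables(fx$truth$kon_app, fx$truth$koff,
                              fx$design$Et, 4 * nM, fx$design$v0_abs)
  for (s in 1:5) {
    cv <- simulate_progress_curve(fx$truth, fx$design, 4 * nM,
                                  sim_noise(seed = s))
    f <- fit_progress_curve(cv, fx$design$Et)
    expect_true(f$converged)
    expect_lt(abs(f$v0 - truth$v0) / truth$v0, 0.1)
    expect_lt(abs(f$vs - truth$vs) / truth$vs, 0.1)
    expect_lt(abs(f$k - truth$k) / truth$k, 0.1)
  }
})

test_that("fit_progress_curve validates its input", {
  cv <- progress_curve("tiny", 4 * nM, 0:6, seq(0, 0.6, by = 0.1))
  expect_error(fit_progress_curve(cv, 2 * nM), "at least 8 points")
  cv0 <- progress_curve("zero", 0, 0:20, 0.02 + 1e-3 * (0:20))
  expect_error(fit_progress_curve(cv0, 2 * nM), "fit_uninhibited")
})

test_that("fit_uninhibited returns the linear slope and rejects bad input", {
  t <- seq(0, 1000, by = 10)
  cv <- progress_curve("ref", 0, t, 0.02 + 5e-4 * t)
  expect_equal(fit_uninhibited(cv), 5e-4, tolerance = 1e-10)

  # simulated depletion-free trace: slope equals the design velocity
  fx <- propkin_fixture("pernisine_25C")
  sim <- simulate_inhibition_series(fx, no_noise())[[1]]
  expect_equal(fit_uninhibited(sim, fx$design), fx$design$v0_abs,
               tolerance = 1e-3)

  flat <- progress_curve("flat", 0, t, rep(0.02, length(t)))
  expect_error(fit_uninhibited(flat), "not positive")
  inh <- progress_curve("inh", 1 * nM, t, 0.02 + 5e-4 * t)
  expect_error(fit_uninhibited(inh), "It = 0")
})

test_that("full noiseless series recovers the fixture Ki' end to end", {
  for (nm in c("pernisine_25C", "pernisine_50C")) {
    fx <- propkin_fixture(nm)
    curves <- simulate_inhibition_series(fx, no_noise())
    res <- fit_inhibition_series(curves, fx$design$Et, fx$design)
    expect_equal(res$henderson$ki_app, fx$truth$ki_app, tolerance = 5e-3)
    expect_equal(res$henderson$intercept, fx$design$Et, tolerance = 5e-3)
    expect_equal(res$v0_uninhibited, fx$design$v0_abs, tolerance = 1e-3)
  }
})
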