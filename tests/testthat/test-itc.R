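design_std <- function(temp = 25)
  titration_design(cell_volume = 950e-6, cell_conc = 5 * uM,
                   syringe_conc = 100 * uM,
                   injection_volumes = rep(5e-6, 19), temperature = temp)

test_that("displacement-cell concentrations follow the dilution formulas", {
  d <- design_std()

  # single 5 uL injection: direct arithmetic from the stated formulas
  cc1 <- injection_concentrations(d, 1)
  dv <- 5e-6 / 950e-6
  expect_equal(cc1$Mt, 5 * uM * (1 - dv / 2) / (1 + dv / 2), tolerance = 1e-12)
  expect_equal(cc1$Xt, 100 * uM * dv / (1 + dv / 2), tolerance = 1e-12)

  # mass balance cross-check for small dV/V0: injected moles vs Xt*(V0+dV)
  injected <- 100 * uM * 5e-6
  expect_equal(cc1$Xt * (950e-6 + 5e-6), injected, tolerance = 5e-3)

  # tiny injection limit -> (M0, 0)
  d_tiny <- titration_design(950e-6, 5 * uM, 100 * uM, c(1e-12, 5e-6))
  cc0 <- injection_concentrations(d_tiny, 1)
  expect_equal(cc0$Mt, 5 * uM, tolerance = 1e-6)
  expect_equal(cc0$Xt, 0, tolerance = 1e-12)

  # the printed geometry spans the equivalence point: final ratio ~ 2.1
  cc <- injection_concentrations(d)
  expect_equal(cc$molar_ratio[19], 2.105, tolerance = 1e-3)
  expect_error(injection_concentrations(d, 20), "out of range")
})

test_that("expected heats match the mass-balance oracle and limits", {
  d <- design_std()

  # zero enthalpy -> zero heats
  expect_equal(expected_heats(0.68, 96 * nM, 0, d), rep(0, 19))

  # kd -> 0 stoichiometric limit: titration step function
  q <- expected_heats(0.68, 1e-15, -5e4, d, dilution_correction = FALSE)
  cc <- injection_concentrations(d)
  eq_idx <- which(cc$molar_ratio > 0.68)[1]
  inj_moles <- 100 * uM * 5e-6
  pre <- seq_len(eq_idx - 2)
  expect_equal(q[pre], rep(-5e4 * inj_moles, length(pre)), tolerance = 0.01)
  # post-equivalence all sites stay full; the only heat left is the
  # bound-complex dilution signature n*dH*V0*(Mt_i - Mt_{i-1}), exactly
  post <- seq(eq_idx + 1, 19)
  dq_dilution <- 0.68 * -5e4 * d$cell_volume * diff(cc$Mt)[post - 1]
  expect_equal(q[post], dq_dilution, tolerance = 1e-6)
  expect_true(all(abs(q[post]) < 0.06 * abs(-5e4 * inj_moles)))

  # independent mass-balance oracle (uniroot on the raw binding equation)
  q2 <- expected_heats(0.68, 96 * nM, -5e4, d)
  B <- vapply(seq_len(19), function(i)
    oracle_bound(0.68, 96 * nM, cc$Mt[i], cc$Xt[i]), 0)
  Q <- B * -5e4 * d$cell_volume
  Qprev <- c(0, Q[-19])
  q_oracle <- Q - Qprev + (d$injection_volumes / d$cell_volume) * (Q + Qprev) / 2
  expect_equal(q2, q_oracle, tolerance = 1e-9)
})

test_that("site fraction is within [0,1] and non-decreasing along the titration", {
  d <- design_std()
  cc <- injection_concentrations(d)
  for (kd in c(1.3, 10, 96, 1000) * nM) {
    q <- expected_heats(0.8, kd, -5e4, d, dilution_correction = FALSE)
    Q <- cumsum(q)
    theta <- Q / (0.8 * cc$Mt * -5e4 * d$cell_volume)
    expect_true(all(theta >= -1e-12 & theta <= 1 + 1e-12))
    expect_true(all(diff(theta) > -1e-12))
  }
})

test_that("total heat is conserved through the injection bookkeeping", {
  d <- design_std()
  q <- expected_heats(0.68, 96 * nM, -5e4, d)
  cc <- injection_concentrations(d)
  corr <- (d$injection_volumes / d$cell_volume)
  # strip the average-displacement terms back out injection by injection
  Q <- numeric(19)
  Qprev <- 0
  for (i in 1:19) {
    Q[i] <- (q[i] + Qprev * (1 - corr[i] / 2)) / (1 + corr[i] / 2)
    Qprev <- Q[i]
  }
  B_final <- oracle_bound(0.68, 96 * nM, cc$Mt[19], cc$Xt[19])
  expect_equal(Q[19], B_final * -5e4 * d$cell_volume, tolerance = 1e-6)
})

test_that("blank subtraction is element-wise and validated", {
  h <- injection_heats(c(-25, -20, -10) * 1e-6, blank_heats = rep(0, 3))
  expect_equal(subtract_blank(h)$heats, h$heats)
  h2 <- injection_heats(c(-25, -20, -10) * 1e-6,
                        blank_heats = c(-25, -20, -10) * 1e-6)
  expect_equal(subtract_blank(h2)$heats, rep(0, 3))
  expect_error(injection_heats(1:3, blank_heats = 1:2), "length")
  expect_error(subtract_blank(injection_heats(1:3)), "no blank")

  # simulator round trip: constant dilution offset added then subtracted
  fx <- propkin_fixture("itc_25C")
  clean <- simulate_itc(fx)
  offset <- simulate_itc(fx, dilution_offset = -1e-6)
  expect_equal(subtract_blank(offset)$heats, clean$heats, tolerance = 1e-12)
})

test_that("noiseless independent-sites fits recover the fixture truths", {
  fx <- propkin_fixture("itc_25C")
  f <- fit_itc(simulate_itc(fx), fx$design)
  expect_true(f$converged)
  expect_false(f$conditioning_warning)
  expect_equal(f$n_sites, 0.68, tolerance = 1e-4)
  expect_equal(f$kd, 96 * nM, tolerance = 1e-4)
  expect_equal(f$delta_h, -5e4, tolerance = 1e-4)

  # high-c regime: n and dH recovered, kd weakly identified, warning fires
  fx2 <- propkin_fixture("itc_50C")
  expect_warning(f2 <- fit_itc(simulate_itc(fx2), fx2$design),
                 "outside \\[1, 1000\\]")
  expect_true(f2$conditioning_warning)
  expect_equal(f2$n_sites, 0.89, tolerance = 0.01)
  expect_equal(f2$delta_h, -5e4, tolerance = 0.01)
  expect_lt(abs(log2(f2$kd / (1.3 * nM))), 1)  # within a factor of 2
})

test_that("dropping the first injection barely shifts a noiseless fit", {
  fx <- propkin_fixture("itc_25C")
  h <- simulate_itc(fx)
  f_keep <- fit_itc(h, fx$design)
  f_drop <- fit_itc(h, fx$design, drop_first = TRUE)
  expect_lt(abs(f_drop$n_sites - f_keep$n_sites) / f_keep$n_sites, 0.02)
})

test_that("noisy fits recover kd within tolerance and input is validated", {
  fx <- propkin_fixture("itc_25C")
  kds <- vapply(1:20, function(s) {
    h <- simulate_itc(fx, sim_noise(itc_abs_sigma = 0.5e-6, seed = s))
    suppressWarnings(fit_itc(h, fx$design))$kd
  }, 0)
  expect_lte(stats::median(abs(kds - 96 * nM) / (96 * nM)), 0.15)

  # pure noise, no binding signal -> flagged
  set.seed(99)
  h0 <- injection_heats(stats::rnorm(19, 0, 0.5e-6))
  f0 <- suppressWarnings(fit_itc(h0, fx$design))
  expect_true(f0$no_binding)

  d_small <- titration_design(950e-6, 5 * uM, 100 * uM, rep(5e-6, 5))
  expect_error(fit_itc(injection_heats(rep(-1e-6, 5)), d_small),
               "at least 6")
})

test_that("Wiseman c value is the conditioning ratio", {
  d <- design_std()
  expect_equal(c_value(1, 96 * nM, d), 5e-6 / 96e-9, tolerance = 1e-12)
  expect_equal(c_value(1, 5 * uM, d), 1)
  expect_equal(c_value(0.89, 1.3 * nM, d), 0.89 * 5e-6 / 1.3e-9,
               tolerance = 1e-12)
})
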