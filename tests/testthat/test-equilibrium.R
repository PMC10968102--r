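test_that("gamma_order evaluates the detergent-release order", {
  expect_equal(gamma_order(ref_system()), (2 * 56 - 59) / 55)
  expect_equal(round(gamma_order(ref_system()), 2), 0.96)
  expect_warning(sys0 <- micelle_system(Nm = 30, Nd = 60, Ne = 55),
                 "gamma")
  expect_equal(gamma_order(sys0), 0)
  expect_equal(gamma_order(micelle_system(55, 55, Ne = 55)), 1)
})

test_that("kd_from_state implements the micellar-solvent expression", {
  st <- list(m = 1, d = 1, det_e = 1)
  expect_equal(kd_from_state(st, 0.5), 1)
  # gamma = 0 reduces to the plain dissociation constant
  st <- list(m = 2e-5, d = 5e-5, det_e = 3e-3)
  expect_equal(kd_from_state(st, 0), st$m^2 / st$d)
  # direct evaluation at the worked concentrations
  st <- list(m = 3.78e-5, d = 5.11e-5, det_e = 3.168e-3)
  expect_equal(kd_from_state(st, 0.963636),
               3.78e-5^2 / (5.11e-5 * 3.168e-3^0.963636), tolerance = 1e-12)
  expect_equal(kd_from_state(st, 0.963636), 7.16e-3, tolerance = 2e-3)
  expect_error(kd_from_state(list(m = 1, d = 0, det_e = 1), 1), "infinite")
  expect_error(kd_from_state(list(m = 1, d = 1, det_e = 0), 1), "> 0")
})

test_that("delta_g and kd_from_delta_g are exact inverses", {
  expect_equal(delta_g(1, 300), 0)
  expect_equal(delta_g(6.87e-3, 303.15), -3.0, tolerance = 1e-3)
  for (x in c(-5, -3, -0.1, 0.5)) {
    expect_equal(delta_g(kd_from_delta_g(x, 303.15), 303.15), x,
                 tolerance = 1e-12)
  }
})

test_that("solve_equilibrium hits the dissociation limits", {
  params_hi <- equilibrium_params(1e6, ref_system())
  params_lo <- equilibrium_params(1e-12, ref_system())
  expect_lt(solve_equilibrium(params_hi, 1.4e-4, 5.6e-2)$f_dimer, 1e-3)
  expect_gt(solve_equilibrium(params_lo, 1.4e-4, 5.6e-2)$f_dimer, 0.999)
})

test_that("solve_equilibrium reproduces the 73% dimer benchmark", {
  kd <- kd_from_delta_g(-3.0, 303.15)
  st <- solve_equilibrium(equilibrium_params(kd, ref_system()),
                          1.4e-4, 9.8e-3)
  expect_equal(st$f_dimer, 0.73, tolerance = 0.02 / 0.73)
  # independent oracle: dense grid scan
  f_oracle <- grid_scan_fdimer(kd, 1.4e-4, 9.8e-3, ref_system())
  expect_lt(abs(st$f_dimer - f_oracle), 1e-5)
})

test_that("returned states satisfy exact mass and detergent balance", {
  kd <- kd_from_delta_g(-3.0, 303.15)
  params <- equilibrium_params(kd, ref_system())
  for (det0 in c(7e-3, 9.8e-3, 2.8e-2, 5.6e-2)) {
    st <- solve_equilibrium(params, 1.4e-4, det0)
    expect_equal(st$m + 2 * st$d, 1.4e-4, tolerance = 1e-10)
    expect_equal(st$det_e + 56 * st$m + 59 * st$d + 1.5e-3, det0,
                 tolerance = 1e-12)
    # round trip through the dissociation-constant expression
    expect_equal(kd_from_state(st, st$gamma) / kd, 1, tolerance = 1e-8)
  }
})

test_that("solver matches the grid-scan oracle on random parameter draws", {
  set.seed(2024)
  for (i in 1:20) {
    nm <- runif(1, 40, 80)
    nd <- runif(1, 10, 2 * nm - 5)   # keep gamma > 0
    sys <- micelle_system(Nm = nm, Nd = nd, Ne = 55, CMC = 1.5e-3)
    kd <- 10^runif(1, -5, -1)
    p0 <- 10^runif(1, -4.5, -3.5)
    det0 <- runif(1, 80, 500) * p0
    f <- solve_equilibrium(equilibrium_params(kd, sys), p0, det0)$f_dimer
    f_oracle <- grid_scan_fdimer(kd, p0, det0, sys)
    expect_lt(abs(f - f_oracle), 1e-5)
  }
})

test_that("f_dimer is strictly decreasing in detergent", {
  kd <- kd_from_delta_g(-3.0, 303.15)
  params <- equilibrium_params(kd, ref_system())
  det0 <- seq(7e-3, 5.6e-2, length.out = 12)
  f <- predict_f_dimer(params, 1.4e-4, det0)
  expect_true(all(diff(f) < 0))
})

test_that("the standard-state limit holds at 1 M detergent", {
  # for det0 >> Nm*p0, Nd*p0, CMC the full model and the DetE ~ Det0
  # simplification agree to < 0.5%
  kd <- kd_from_delta_g(-3.0, 303.15)
  sys <- ref_system()
  p0 <- 1e-5; det0 <- 1
  f_full <- solve_equilibrium(equilibrium_params(kd, sys), p0, det0)$f_dimer
  g <- gamma_order(sys)
  # simplified: M^2/D = kd * det0^gamma, quadratic in f
  k2 <- kd * det0^g
  f_simple <- uniroot(function(f) ((1 - f) * p0)^2 / (f * p0 / 2) - k2,
                      c(1e-12, 1 - 1e-12), tol = 1e-15)$root
  expect_lt(abs(f_full - f_simple) / f_simple, 0.005)
})

test_that("infeasible and degenerate inputs fail loudly", {
  params <- equilibrium_params(1e-2, ref_system())
  expect_error(solve_equilibrium(params, 1.4e-4, 1e-3), "no micelles")
  # detergent pool too small for any state
  expect_error(solve_equilibrium(params, 1e-2, 1.6e-3),
               "insufficient micellar detergent")
  expect_error(equilibrium_params(-1, ref_system()), "> 0")
  expect_error(micelle_system(0, 59), "> 0")
})
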