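test_that("identical seed and config give byte-identical output", {
  cfg <- generator_config(noise_sigma = 0.02)
  a <- generate_titration_series(cfg, seed = 99)
  b <- generate_titration_series(cfg, seed = 99)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$spectra, `[[`, "intensity"),
                   lapply(b$spectra, `[[`, "intensity"))
  c1 <- generate_titration_series(cfg, seed = 100)
  expect_false(identical(a$spectra[[1]]$intensity, c1$spectra[[1]]$intensity))
})

test_that("noiseless spectra equal the analytic sum of their components", {
  cfg <- generator_config(noise_sigma = 0, suppression_delay = 0,
                          dp_ratios = 100)
  gen <- generate_titration_series(cfg, seed = 1)
  sp <- gen$spectra[[1]]
  f <- gen$truth$f_dimer[1]
  manual <- rep(0, length(sp$ppm))
  comps <- data.frame(
    center = c(cfg$shifts["M"], cfg$shifts["D"],
               cfg$shifts["M"] + cfg$cis_offset,
               cfg$shifts["D"] + cfg$cis_offset),
    fwhm = c(cfg$fwhm["M"], cfg$fwhm["D"], cfg$fwhm["M"], cfg$fwhm["D"]),
    area = c((1 - f) * 0.9, f * 0.9, (1 - f) * 0.1, f * 0.1))
  for (i in 1:4)
    manual <- manual + lorentzian_profile(comps$center[i], comps$fwhm[i],
                                          comps$area[i], sp$ppm, sp$sfrq)
  expect_equal(max(abs(sp$intensity - manual)), 0)
})

test_that("titration truth is strictly decreasing and hits the benchmark", {
  cfg <- generator_config()   # dH/dS defaults, 30 C, D:P 50-400
  gen <- generate_titration_series(cfg, seed = 1)
  f <- gen$truth$f_dimer[gen$truth$regime == "slow"]
  expect_true(all(diff(f) < 0))
  f70 <- gen$truth$f_dimer[gen$truth$dp_ratio == 70]
  expect_equal(f70, 0.73, tolerance = 0.04)
  # chain conservation: trans + cis areas sum to 1 per bound spectrum
  expect_true(all(abs(rowSums(cbind(f, 1 - f))) - 1 < 1e-12))
})

test_that("low-detergent points come out as fast exchange and are excluded", {
  cfg <- generator_config(dp_ratios = c(10, 30, 50, 100, 200, 400))
  gen <- generate_titration_series(cfg, seed = 3)
  expect_equal(gen$truth$regime[gen$truth$dp_ratio %in% c(10, 30)],
               c("fast", "fast"))
  expect_equal(gen$truth$regime[gen$truth$dp_ratio >= 50],
               rep("slow", 4))
  # classifier agrees on the rendered spectra
  reg <- vapply(gen$spectra, exchange_regime, character(1),
                refs = cfg$shifts)
  expect_equal(unname(reg[c("dp010", "dp030")]), c("fast", "fast"))
  expect_equal(unname(reg["dp400"]), "slow")
})

test_that("temperature series obey the sign of the generating entropy", {
  cfg <- generator_config(temperatures = seq(278.15, 323.15, length.out = 6))
  gen <- generate_temperature_series(cfg, seed = 2)
  expect_true(all(diff(gen$truth$f_dimer) < 0))  # dH<0, dS<0: cooling dimerises
  cfg0 <- generator_config(delta_h = 0, delta_s = 0,
                           temperatures = seq(278.15, 323.15, length.out = 4))
  gen0 <- generate_temperature_series(cfg0, seed = 2)
  expect_lt(diff(range(gen0$truth$f_dimer)), 1e-9)
  # truth carries the exact linear free energy
  expect_equal(gen$truth$delta_g,
               cfg$delta_h - gen$truth$temperature * cfg$delta_s)
})

test_that("temperature series populations support full parameter recovery", {
  cfg <- generator_config(sigma_f = 0.02)
  sys <- ref_system()
  dh_hat <- vapply(1:25, function(i) {
    pts <- simulate_temperature_points(cfg, seed = i)
    vant_hoff_fit(points_to_delta_g(pts, sys))$delta_h
  }, numeric(1))
  expect_lt(abs(mean(dh_hat) + 8.88), 0.3)
})

test_that("descriptor datasets carry their stated signal-to-noise", {
  gen0 <- generate_descriptor_dataset(20, noise_rel = 0, seed = 1)
  res <- optimize_composite(gen0$table, gen0$table$target,
                            c(gravy = 1, arom = 1))
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_error(generate_descriptor_dataset(3), "at least 4")
  # noise equal to signal SD halves the expected R2
  r2 <- vapply(1:200, function(i) {
    g <- generate_descriptor_dataset(40, noise_rel = 1, seed = i)
    cor(composite_value(g$table, g$truth$coefs), g$table$target)^2
  }, numeric(1))
  expect_equal(mean(r2), 0.5, tolerance = 0.05)
})

test_that("infeasible generator configs name the offending ratios", {
  cfg <- generator_config(p0 = 5e-3, dp_ratios = c(2, 5))
  expect_error(generate_titration_series(cfg, seed = 1), "D:P")
})
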