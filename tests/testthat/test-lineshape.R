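test_that("lorentzian_profile has the closed-form height, width and area", {
  sfrq <- 600
  area <- 2.7; fwhm <- 12; center <- 10.2
  # wide window: +/- 500 fwhm = +/- 6000 Hz = 10 ppm, so the slowly decaying
  # Lorentzian tails contribute < 0.1% truncation error to the integral
  ppm <- seq(center - 10, center + 10, length.out = 4e5 + 1)
  y <- lorentzian_profile(center, fwhm, area, ppm, sfrq)
  # height at centre
  expect_equal(max(y), 2 * area / (pi * fwhm), tolerance = 1e-6)
  hz <- ppm * sfrq
  expect_equal(sum(y) * (hz[2] - hz[1]), area, tolerance = 1e-3)
  # measured half-height width
  above <- range(hz[y >= max(y) / 2])
  expect_equal(diff(above), fwhm, tolerance = 1e-2)
  expect_error(lorentzian_profile(10, -1, 1, ppm, sfrq), "> 0")
})

test_that("a single noiseless Lorentzian is recovered to 1e-6", {
  sp <- make_lorentz_spectrum(data.frame(center = 10.2, fwhm = 12, area = 3.5))
  fit <- fit_components(sp, c(10.0, 10.4), n_components = 1)
  expect_equal(fit$peaks$center, 10.2, tolerance = 1e-6)
  expect_equal(fit$peaks$fwhm, 12, tolerance = 1e-6 * 12)
  expect_equal(fit$peaks$area, 3.5, tolerance = 1e-6 * 3.5)
  expect_lt(fit$residual_rms, 1e-8 * max(sp$intensity))
})

test_that("two components at 2x fwhm separation recover areas at SNR 50", {
  # separation 2*fwhm = 24 Hz = 0.04 ppm at 600 MHz
  truth <- data.frame(center = c(10.18, 10.22), fwhm = c(12, 12),
                      area = c(1, 0.6))
  sp <- make_lorentz_spectrum(truth, noise = 1 / 50, seed = 21)
  fit <- fit_components(sp, c(10.05, 10.35), n_components = 2)
  expect_equal(fit$peaks$area, truth$area, tolerance = 0.02)
})

test_that("a 10% minor satellite is recovered within 20% at SNR 100", {
  truth <- data.frame(center = c(10.12, 10.2, 10.32), fwhm = c(10, 10, 18),
                      area = c(0.1, 0.5, 0.4))
  sp <- make_lorentz_spectrum(truth, noise = 1 / 100, seed = 22)
  fit <- fit_components(sp, c(10.0, 10.45), n_components = 3)
  expect_equal(fit$peaks$area[1], 0.1, tolerance = 0.2)
  expect_equal(fit$peaks$area[2:3], c(0.5, 0.4), tolerance = 0.05)
})

test_that("descending ppm axes are accepted and fits are scale invariant", {
  truth <- data.frame(center = c(10.15, 10.3), fwhm = c(10, 16),
                      area = c(0.5, 0.8))
  sp <- make_lorentz_spectrum(truth, noise = 0.005, seed = 30)
  sp_desc <- spectrum1d(rev(sp$ppm), rev(sp$intensity * 1e4), sfrq = 600)
  refs <- c(M = 10.15, D = 10.3)
  f1 <- populations(assign_peaks(
    fit_components(sp, c(10.0, 10.45), 2)$peaks, refs))
  f2 <- populations(assign_peaks(
    fit_components(sp_desc, c(10.0, 10.45), 2)$peaks, refs))
  expect_equal(f1$f_dimer, f2$f_dimer, tolerance = 1e-6)
  expect_error(spectrum1d(c(1, 1, 2), 1:3, 600), "monotone")
})

test_that("relaxation_correct inverts the generator decay exactly", {
  pk <- data.frame(area = c(1, 1), fwhm = c(5, 20))
  delay <- 0.01
  decayed <- pk
  decayed$area <- pk$area * exp(-delay * pi * pk$fwhm)
  corrected <- relaxation_correct(decayed, delay)
  expect_equal(corrected$area, pk$area, tolerance = 1e-6)
  # closed-form factor for a 10 Hz line and 10 ms delay
  one <- relaxation_correct(data.frame(area = 1, fwhm = 10), 0.01)
  expect_equal(one$area, exp(0.01 * pi * 10), tolerance = 1e-12)
  expect_equal(exp(0.01 * pi * 10), 1.369, tolerance = 1e-3)
  # zero delay is the identity
  expect_equal(relaxation_correct(pk, 0)$area, pk$area)
  expect_error(relaxation_correct(pk, -1), ">= 0")
})

test_that("populations implements the chain-proportional convention", {
  pk <- data.frame(area = c(1, 1), fwhm = c(10, 18),
                   assignment = c("M", "D"))
  expect_equal(populations(pk)$f_dimer, 0.5)
  pk$area <- c(0, 1)
  expect_equal(populations(pk)$f_dimer, 1)
  # cis satellites excluded by default, reported as f_minor
  pk <- data.frame(area = c(0.45, 0.45, 0.05, 0.05), fwhm = c(10, 18, 10, 18),
                   assignment = c("M", "D", "cis_M", "cis_D"))
  pop <- populations(pk)
  expect_equal(pop$f_dimer, 0.5)
  expect_equal(pop$f_minor, 0.1)
  pop_inc <- populations(pk, include_cis = TRUE)
  expect_equal(pop_inc$f_dimer, 0.5)
  expect_error(populations(data.frame(area = 1, fwhm = 1,
                                      assignment = "unassigned")), "M or D")
})

test_that("assignment by proximity prefers larger areas for trans forms", {
  pk <- data.frame(center = c(10.19, 10.21, 10.35), fwhm = c(10, 10, 18),
                   area = c(0.1, 0.9, 0.5), assignment = "unassigned")
  out <- assign_peaks(pk, c(M = 10.20, D = 10.35), window = 0.03)
  expect_equal(out$assignment, c("cis_M", "M", "D"))
})

test_that("exchange_regime classifies fast, slow and aqueous spectra", {
  refs <- c(W = 10.05, M = 10.20, D = 10.35)
  # resolved peaks at the bound references -> slow
  slow <- make_lorentz_spectrum(data.frame(center = c(10.2, 10.35),
                                           fwhm = c(10, 18),
                                           area = c(0.5, 0.5)))
  expect_equal(exchange_regime(slow, refs), "slow")
  # one peak midway between W and D -> fast
  fast <- make_lorentz_spectrum(data.frame(center = 10.2 - 0.0005,
                                           fwhm = 10, area = 1))
  expect_equal(exchange_regime(fast, c(W = 10.05, D = 10.35)), "fast")
  # one peak at the aqueous reference -> fast (water regime)
  aq <- make_lorentz_spectrum(data.frame(center = 10.05, fwhm = 8, area = 1))
  expect_equal(exchange_regime(aq, refs), "fast")
})

test_that("end-to-end recovery across dimer fractions is unbiased", {
  cfg <- generator_config(noise_sigma = 0.01, suppression_delay = 0.005)
  refs <- cfg$shifts[c("M", "D")]
  full <- c(refs, setNames(refs + cfg$cis_offset, c("cis_M", "cis_D")))
  for (f_true in c(0.1, 0.5, 0.9)) {
    peaks <- data.frame(
      center = unname(c(full["M"], full["D"], full["cis_M"], full["cis_D"])),
      fwhm = c(10, 18, 10, 18),
      area = c((1 - f_true) * 0.9, f_true * 0.9,
               (1 - f_true) * 0.1, f_true * 0.1))
    peaks$area <- peaks$area * exp(-cfg$suppression_delay * pi * peaks$fwhm)
    sp <- make_lorentz_spectrum(peaks, noise = 0.01,
                                seed = round(1000 * f_true))
    fit <- fit_components(sp, c(10.0, 10.45), n_components = 4,
                          init = data.frame(center = unname(full),
                                            fwhm = rep(8, 4)))
    pk <- relaxation_correct(assign_peaks(fit$peaks, full),
                             cfg$suppression_delay)
    pop <- populations(pk)
    expect_lt(abs(pop$f_dimer - f_true), 0.01)
  }
})
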