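# Ground-truthed synthetic data: NMR titration and temperature series obeying
# the micellar-solvent + van't Hoff model, and descriptor datasets with known
# composite structure. Defaults emulate a 0.14 mM beta-hairpin peptide sample
# titrated with DPC at 30 C (titration) or held at D:P 400:1 over 5-50 C
# (temperature series): dH = -8.88 kcal/mol, dS = -19.0e-3 kcal/(mol K),
# Nm = 56, Nd = 59, Ne = 55, CMC = 1.5 mM, ~10% cis-satellite population.

#' Generator configuration
#'
#' Collects every knob of the synthetic spectral generators, with defaults
#' matching the conditions of the system the package models. Reference shifts
#' and line widths are plausible placeholders recorded in the config (the
#' underlying experimental figure does not print them as text).
#'
#' @param delta_h,delta_s generating thermodynamics (kcal/mol, kcal/(mol K)).
#' @param Nm,Nd,Ne,CMC micellar-solvent model parameters (molar CMC).
#' @param p0 total peptide concentration, molar.
#' @param dp_ratios detergent-to-peptide molar ratios for a titration.
#' @param dp_ratio fixed D:P ratio for a temperature series.
#' @param temperature fixed temperature (K) for a titration.
#' @param temperatures temperature grid (K) for a temperature series.
#' @param shifts named ppm reference shifts for the aqueous (`W`),
#'   micelle-bound monomer (`M`) and dimer (`D`) signals.
#' @param cis_offset ppm offset of cis-satellites from their parent signal.
#' @param fwhm named line widths in Hz per form.
#' @param cis_fraction minor cis-conformer population (of each species).
#' @param noise_sigma additive Gaussian noise, relative to the maximum clean
#'   intensity.
#' @param sigma_f Gaussian noise applied to dimer fractions by the
#'   population-level simulators.
#' @param suppression_delay water-suppression delay in s (0 = no decay).
#' @param sfrq spectrometer frequency, MHz.
#' @param axis_range,n_points ppm window and sampling of synthetic spectra.
#' @param kpart water-to-micelle partition constant (1/M of micellar
#'   detergent) governing the low-detergent fast-exchange regime; pure
#'   generator plumbing chosen so binding completes near D:P 50:1.
#' @param bind_threshold bound fraction above which a spectrum is emitted in
#'   the micelle-bound slow-exchange regime.
#' @param seed integer seed recorded in the ground truth.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(delta_h = -8.88, delta_s = -19.0e-3,
                             Nm = 56, Nd = 59, Ne = 55, CMC = 1.5e-3,
                             p0 = 1.4e-4,
                             dp_ratios = c(50, 70, 100, 130, 170, 230, 300, 400),
                             dp_ratio = 400,
                             temperature = 303.15,
                             temperatures = seq(278.15, 323.15, length.out = 10),
                             shifts = c(W = 10.05, M = 10.20, D = 10.35),
                             cis_offset = -0.08,
                             fwhm = c(W = 8, M = 10, D = 18),
                             cis_fraction = 0.10,
                             noise_sigma = 0.01,
                             sigma_f = 0.02,
                             suppression_delay = 0,
                             sfrq = 600,
                             axis_range = c(9.8, 10.6),
                             n_points = 2048,
                             kpart = 3500,
                             bind_threshold = 0.95,
                             seed = 1L) {
  if (any(dp_ratios <= 0) || dp_ratio <= 0) stop("D:P ratios must be positive",
                                                 call. = FALSE)
  if (cis_fraction < 0 || cis_fraction >= 0.5)
    stop("cis_fraction must be in [0, 0.5)", call. = FALSE)
  if (noise_sigma < 0 || sigma_f < 0) stop("noise must be >= 0", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

.cfg_system <- function(config) {
  micelle_system(Nm = config$Nm, Nd = config$Nd, Ne = config$Ne,
                 CMC = config$CMC)
}

.cfg_kd <- function(config, temperature) {
  dg <- config$delta_h - temperature * config$delta_s
  kd_from_delta_g(dg, temperature)
}

# fraction of peptide bound to micelles in the pre-saturation regime
.bound_fraction <- function(config, det0) {
  mic <- pmax(det0 - config$CMC, 0)
  config$kpart * mic / (1 + config$kpart * mic)
}

# build one clean spectrum (component peak list -> profile sum)
.render_spectrum <- function(config, peak_df, id, temperature, p0, det0,
                             noise_sigma) {
  ppm <- seq(config$axis_range[1], config$axis_range[2],
             length.out = config$n_points)
  clean <- rep(0, config$n_points)
  for (i in seq_len(nrow(peak_df)))
    clean <- clean + lorentzian_profile(peak_df$center[i], peak_df$fwhm[i],
                                        peak_df$area_decayed[i], ppm,
                                        config$sfrq)
  noisy <- clean
  if (noise_sigma > 0)
    noisy <- clean + rnorm(config$n_points, sd = noise_sigma * max(clean))
  spectrum1d(ppm, noisy, sfrq = config$sfrq, temperature = temperature,
             p0 = p0, det0 = det0, id = id)
}

# component table for a micelle-bound slow-exchange spectrum at dimer chain
# fraction f; areas are chain-proportional (total = p0 in concentration units)
.bound_components <- function(config, f) {
  cf <- config$cis_fraction
  peaks <- data.frame(
    assignment = c("M", "D", "cis_M", "cis_D"),
    center = c(config$shifts["M"], config$shifts["D"],
               config$shifts["M"] + config$cis_offset,
               config$shifts["D"] + config$cis_offset),
    fwhm = c(config$fwhm["M"], config$fwhm["D"],
             config$fwhm["M"], config$fwhm["D"]),
    area = c((1 - f) * (1 - cf), f * (1 - cf), (1 - f) * cf, f * cf),
    stringsAsFactors = FALSE)
  peaks[peaks$area > 0, , drop = FALSE]
}

.decay_areas <- function(peaks, delay) {
  peaks$area_decayed <- peaks$area * exp(-delay * pi * peaks$fwhm)
  peaks
}

#' Generate a synthetic detergent-titration spectral series
#'
#' For each D:P ratio the generator either (a) emits a fast-exchange spectrum
#' — a single population-weighted resonance between the aqueous and bound
#' shifts, governed by a simple water/micelle partition constant — when the
#' detergent is at/below the CMC or binding is incomplete, or (b) computes the
#' dimer chain fraction from the equilibrium model (Kd(T) from the generating
#' thermodynamics), synthesizes monomer and dimer Lorentzians with
#' chain-proportional areas plus cis satellites, applies the
#' water-suppression decay `exp(-delay * pi * fwhm)` per line, and adds
#' Gaussian noise. Identical seed + config give byte-identical output.
#'
#' @param config a [generator_config].
#' @param seed overrides `config$seed` when given.
#' @return a list with `spectra` (list of [spectrum1d]) and `truth` (data
#'   frame of per-spectrum ground truth) plus the echoed `config`.
#' @export
generate_titration_series <- function(config = generator_config(),
                                      seed = config$seed) {
  set.seed(seed)
  Tk <- config$temperature
  kd <- .cfg_kd(config, Tk)
  sys <- .cfg_system(config)
  spectra <- list()
  truth <- list()
  for (r in config$dp_ratios) {
    det0 <- r * config$p0
    id <- sprintf("dp%03d", round(r))
    bf <- if (det0 > config$CMC) .bound_fraction(config, det0) else 0
    if (bf < config$bind_threshold) {
      # fast exchange: single averaged peak between W and the bound position
      f <- NA_real_
      bound_shift <- config$shifts["D"]   # dimer dominates on first binding
      center <- (1 - bf) * config$shifts["W"] + bf * bound_shift
      width <- (1 - bf) * config$fwhm["W"] + bf * config$fwhm["D"]
      peaks <- data.frame(assignment = "avg", center = center, fwhm = width,
                          area = 1, stringsAsFactors = FALSE)
      regime <- "fast"
    } else {
      st <- tryCatch(solve_equilibrium(equilibrium_params(kd, sys),
                                       config$p0, det0),
                     error = function(e)
                       stop("infeasible micellar point at D:P ", r, ": ",
                            conditionMessage(e), call. = FALSE))
      f <- st$f_dimer
      peaks <- .bound_components(config, f)
      regime <- "slow"
    }
    peaks <- .decay_areas(peaks, config$suppression_delay)
    spectra[[id]] <- .render_spectrum(config, peaks, id, Tk, config$p0, det0,
                                      config$noise_sigma)
    truth[[id]] <- data.frame(
      id = id, dp_ratio = r, p0 = config$p0, det0 = det0, temperature = Tk,
      regime = regime, f_dimer = f, bound_fraction = bf,
      kd_std = kd, seed = seed, suppression_delay = config$suppression_delay,
      stringsAsFactors = FALSE)
  }
  list(spectra = spectra, truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       config = config, seed = seed)
}

#' Generate a synthetic temperature spectral series
#'
#' Fixed D:P ratio (default 400:1), one spectrum per temperature; Kd(T) is
#' derived from the generating enthalpy/entropy via the linear free-energy
#' model. Ground truth includes the exact free energy at each temperature.
#'
#' @inheritParams generate_titration_series
#' @return as [generate_titration_series()]; truth gains a `delta_g` column.
#' @export
generate_temperature_series <- function(config = generator_config(),
                                        seed = config$seed) {
  if (length(config$temperatures) < 3)
    stop("need at least 3 temperatures", call. = FALSE)
  set.seed(seed)
  det0 <- config$dp_ratio * config$p0
  sys <- .cfg_system(config)
  spectra <- list()
  truth <- list()
  for (Tk in config$temperatures) {
    kd <- .cfg_kd(config, Tk)
    id <- sprintf("T%05.1fK", Tk)
    st <- solve_equilibrium(equilibrium_params(kd, sys), config$p0, det0)
    peaks <- .decay_areas(.bound_components(config, st$f_dimer),
                          config$suppression_delay)
    spectra[[id]] <- .render_spectrum(config, peaks, id, Tk, config$p0, det0,
                                      config$noise_sigma)
    truth[[id]] <- data.frame(
      id = id, dp_ratio = config$dp_ratio, p0 = config$p0, det0 = det0,
      temperature = Tk, regime = "slow", f_dimer = st$f_dimer,
      delta_g = config$delta_h - Tk * config$delta_s, kd_std = kd,
      seed = seed, suppression_delay = config$suppression_delay,
      stringsAsFactors = FALSE)
  }
  list(spectra = spectra, truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       config = config, seed = seed)
}

#' Simulate noisy titration populations (no spectra)
#'
#' Population-level counterpart of [generate_titration_series()]: true dimer
#' fractions from the equilibrium model with Gaussian noise `sigma_f` added
#' directly to the fractions (clamped to \[0, 1\]). This is the input contract
#' of [fit_titration()].
#'
#' @inheritParams generate_titration_series
#' @return a data frame of titration points (`p0`, `det0`, `temperature`,
#'   `f_dimer`, `f_dimer_true`).
#' @export
simulate_titration_points <- function(config = generator_config(),
                                      seed = config$seed) {
  set.seed(seed)
  kd <- .cfg_kd(config, config$temperature)
  sys <- .cfg_system(config)
  det0 <- config$dp_ratios * config$p0
  f_true <- .fdimer_solve(kd, config$p0, det0, sys)
  f_obs <- pmin(pmax(f_true + rnorm(length(f_true), sd = config$sigma_f), 0), 1)
  data.frame(p0 = config$p0, det0 = det0, temperature = config$temperature,
             f_dimer = f_obs, f_dimer_true = f_true,
             f_dimer_err = config$sigma_f)
}

#' Simulate noisy temperature-series populations (no spectra)
#'
#' @inheritParams generate_titration_series
#' @return a data frame with one row per temperature (`p0`, `det0`,
#'   `temperature`, `f_dimer`, `f_dimer_true`, `delta_g_true`).
#' @export
simulate_temperature_points <- function(config = generator_config(),
                                        seed = config$seed) {
  set.seed(seed)
  sys <- .cfg_system(config)
  det0 <- config$dp_ratio * config$p0
  Tk <- config$temperatures
  kd <- .cfg_kd(config, Tk)
  f_true <- .fdimer_solve(kd, config$p0, det0, sys)
  f_obs <- pmin(pmax(f_true + rnorm(length(f_true), sd = config$sigma_f), 0), 1)
  data.frame(p0 = config$p0, det0 = det0, temperature = Tk,
             f_dimer = f_obs, f_dimer_true = f_true,
             delta_g_true = config$delta_h - Tk * config$delta_s,
             f_dimer_err = config$sigma_f)
}

#' Free energies from observed populations at frozen aggregation numbers
#'
#' Converts per-condition dimer fractions into standard-state free energies by
#' inverting the equilibrium expression with `Nm`/`Nd` held fixed (typically
#' at values from a detergent titration fit).
#'
#' @param points data frame with `f_dimer`, `p0`, `det0`, `temperature` (K).
#' @param system a [micelle_system] with the frozen aggregation numbers.
#' @return the data frame with added `kd_std` and `delta_g` columns.
#' @export
points_to_delta_g <- function(points, system) {
  kd <- kd_from_population(points$f_dimer, points$p0, points$det0, system)
  points$kd_std <- kd
  points$delta_g <- delta_g(kd, points$temperature)
  points
}

#' Generate a synthetic descriptor dataset with known composite structure
#'
#' Random descriptor columns over realistic ranges (GRAVY in \[-1.5, 1.5\],
#' AROM in \[0, 0.35\], CHARGE in \{2..9\}, and unit-uniform extras) and a
#' target built as a known linear combination plus Gaussian noise whose SD is
#' `noise_rel` times the SD of the noiseless signal.
#'
#' @param n_peptides number of rows (>= 4).
#' @param coefs named numeric vector of true coefficients over descriptor
#'   columns (names among `gravy`, `arom`, `charge`, or new columns which will
#'   be generated U(0,1)).
#' @param noise_rel noise SD relative to signal SD.
#' @param seed RNG seed.
#' @return list with `table` (descriptors + `target`) and `truth`.
#' @export
generate_descriptor_dataset <- function(n_peptides,
                                        coefs = c(gravy = 1, arom = 8),
                                        noise_rel = 0,
                                        seed = 1L) {
  if (n_peptides < 4) stop("need at least 4 peptides", call. = FALSE)
  set.seed(seed)
  tab <- data.frame(peptide_id = sprintf("pep%03d", seq_len(n_peptides)))
  gen <- list(gravy = function(n) runif(n, -1.5, 1.5),
              arom = function(n) runif(n, 0, 0.35),
              charge = function(n) sample(2:9, n, replace = TRUE))
  for (nm in names(coefs)) {
    f <- if (nm %in% names(gen)) gen[[nm]] else function(n) runif(n)
    tab[[nm]] <- f(n_peptides)
  }
  signal <- composite_value(tab, coefs)
  sigma <- noise_rel * sd(signal)
  tab$target <- signal + if (sigma > 0) rnorm(n_peptides, sd = sigma) else 0
  list(table = tab,
       truth = list(coefs = coefs, noise_rel = noise_rel, sigma = sigma,
                    seed = seed))
}

#' Packaged peptide fixtures (FASTA + activity table)
#'
#' Returns the paths of the small plain-text fixtures shipped with the
#' package: a FASTA of beta-hairpin/helical AMP sequences (the capitellacin
#' entry is reconstructed from its published residue identities; all other
#' sequences are external-literature fixtures, flagged as such in their
#' headers) and a minimal-hemolytic-concentration table with censoring flags.
#'
#' @return list with `fasta` and `activity` file paths.
#' @export
fixture_peptides <- function() {
  list(fasta = system.file("extdata", "amp_peptides.fasta",
                           package = "peptidimer", mustWork = TRUE),
       activity = system.file("extdata", "amp_activity.csv",
                              package = "peptidimer", mustWork = TRUE))
}
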