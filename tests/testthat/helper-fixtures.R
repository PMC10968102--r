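# Shared fixtures. The capitellacin sequence is reconstructed from its
# published residue identities (Ser1 ... Gly20).
CAP_SEQ <- "SPRVCIRVCRNGVCYRRCWG"

capitellacin <- function(label_n15 = FALSE) {
  peptide_sequence(CAP_SEQ, id = "capitellacin",
                   disulfide_pairs = list(c(5, 18), c(9, 14)),
                   label_n15 = label_n15)
}

# reference micelle system used throughout: fitted aggregation numbers of the
# monomer- and dimer-bearing DPC micelles
ref_system <- function() micelle_system(Nm = 56, Nd = 59, Ne = 55, CMC = 1.5e-3)

# independent dense-grid-scan oracle for the dimer fraction: scans f over a
# uniform grid and returns the sign-change location of the log-residual
grid_scan_fdimer <- function(kd_std, p0, det0, system, n_grid = 1e6) {
  g <- gamma_order(system)
  f <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  m <- (1 - f) * p0
  d <- f * p0 / 2
  dete <- det0 - system$CMC - system$Nm * m - system$Nd * d
  ok <- dete > 0
  resid <- 2 * log(m[ok]) - log(d[ok]) - g * log(dete[ok]) - log(kd_std)
  fok <- f[ok]
  i <- which(diff(sign(resid)) != 0)[1]
  if (is.na(i)) return(NA_real_)
  # linear interpolation across the sign change
  fok[i] + (fok[i + 1] - fok[i]) * abs(resid[i]) /
    (abs(resid[i]) + abs(resid[i + 1]))
}

make_lorentz_spectrum <- function(peaks, ppm = seq(9.8, 10.6, length.out = 2048),
                                  sfrq = 600, noise = 0, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  y <- rep(0, length(ppm))
  for (i in seq_len(nrow(peaks)))
    y <- y + lorentzian_profile(peaks$center[i], peaks$fwhm[i], peaks$area[i],
                                ppm, sfrq)
  if (noise > 0) y <- y + rnorm(length(ppm), sd = noise * max(y))
  spectrum1d(ppm, y, sfrq = sfrq, ...)
}
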