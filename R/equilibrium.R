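# Micellar-solvent model of peptide dimerization in detergent micelles.
#
# The dimer dissociation equilibrium 2 M(micelle) <-> D(micelle) + released
# detergent is described by
#
#   Kd = [M]^2 / ([D] * [DetE]^gamma),
#   [DetE] = [Det0] - Nm*[M] - Nd*[D] - CMC,
#   gamma  = (2*Nm - Nd) / Ne,
#
# where [M], [D] are molar concentrations of micelle-bound monomer and dimer,
# [DetE] is the detergent in empty (peptide-free) micelles, Ne/Nm/Nd are
# detergent aggregation numbers of empty, monomer- and dimer-bearing micelles
# and CMC the critical micelle concentration. gamma is the apparent reaction
# order with respect to detergent: the number of detergent molecules released
# on dimerization, expressed as a fraction of an empty micelle. At the
# standard state [Det0] = 1 M the constant reduces to Kd_std = [M]^2/[D], which
# makes free energies comparable across detergent concentrations.
#
# Of the two possible readings of the typeset equilibrium expression only
# Kd = M^2/(D * DetE^gamma) makes the dimer dissociate as detergent is added
# (monomer population growing with detergent), which is the observed behaviour;
# the alternative (M^2/D) * DetE^gamma is rejected.

#' Micelle system parameters
#'
#' @param Nm,Nd aggregation numbers (detergent molecules per micelle) of the
#'   monomer- and dimer-bearing micelles.
#' @param Ne aggregation number of empty micelles (default 55, DPC).
#' @param CMC critical micelle concentration in molar (default 1.5e-3 M, DPC).
#' @return an object of class `micelle_system`.
#' @export
micelle_system <- function(Nm, Nd, Ne = 55, CMC = 1.5e-3) {
  stopifnot(is.numeric(Nm), is.numeric(Nd), is.numeric(Ne), is.numeric(CMC))
  if (Nm <= 0 || Nd <= 0 || Ne <= 0) stop("aggregation numbers must be > 0",
                                          call. = FALSE)
  if (CMC < 0) stop("CMC must be >= 0", call. = FALSE)
  sys <- structure(list(Nm = Nm, Nd = Nd, Ne = Ne, CMC = CMC),
                   class = "micelle_system")
  if (gamma_order(sys) <= 0)
    warning("gamma = (2*Nm - Nd)/Ne <= 0: no detergent is released on ",
            "dimerization; the detergent-release model is not physically ",
            "meaningful", call. = FALSE)
  sys
}

#' Apparent reaction order with respect to detergent
#'
#' `gamma = (2*Nm - Nd)/Ne`: the number of detergent molecules released per
#' dimerization event as a fraction of an empty micelle.
#'
#' @param system a [micelle_system].
#' @return dimensionless reaction order.
#' @export
gamma_order <- function(system) {
  (2 * system$Nm - system$Nd) / system$Ne
}

#' Equilibrium parameters (standard-state dissociation constant + system)
#'
#' @param kd_std dissociation constant at the `[Det0] = 1 M` standard state;
#'   carries units of M^(1-gamma).
#' @param system a [micelle_system].
#' @return an object of class `equilibrium_params`.
#' @export
equilibrium_params <- function(kd_std, system) {
  if (!is.numeric(kd_std) || kd_std <= 0) stop("kd_std must be > 0", call. = FALSE)
  if (!inherits(system, "micelle_system")) stop("system must be a micelle_system",
                                                call. = FALSE)
  structure(list(kd_std = kd_std, system = system), class = "equilibrium_params")
}

#' Dissociation constant from an equilibrium state
#'
#' `Kd = [M]^2 / ([D] * [DetE]^gamma)`, all concentrations molar.
#'
#' @param state a list/state with molar fields `m`, `d`, `det_e` (as returned
#'   by [solve_equilibrium()]).
#' @param g the apparent reaction order (see [gamma_order()]).
#' @return the dissociation constant in M^(1-g).
#' @export
kd_from_state <- function(state, g) {
  if (state$d <= 0) stop("dimer concentration is zero: Kd is infinite",
                         call. = FALSE)
  if (state$det_e <= 0) stop("empty-micelle detergent must be > 0", call. = FALSE)
  state$m^2 / (state$d * state$det_e^g)
}

#' Free energy of dimerization from a dissociation constant
#'
#' `dG = R * T * ln(Kd)` with R = 1.98720e-3 kcal/(mol K). Negative values
#' indicate favourable dimerization (Kd < 1 in standard units).
#'
#' @param kd dissociation constant (standard state).
#' @param temperature absolute temperature in K.
#' @return free energy in kcal/mol.
#' @export
delta_g <- function(kd, temperature) {
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  .R_KCAL * temperature * log(kd)
}

#' Dissociation constant from a free energy
#'
#' Inverse of [delta_g()]: `Kd = exp(dG / (R * T))`.
#'
#' @param dg free energy in kcal/mol.
#' @param temperature absolute temperature in K.
#' @return dissociation constant.
#' @export
kd_from_delta_g <- function(dg, temperature) {
  if (any(temperature <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  exp(dg / (.R_KCAL * temperature))
}

# Vectorised safeguarded Newton solver for the dimer fraction f in (0, 1).
# g(f) = 2*log(M) - log(D) - gamma*log(DetE) - log(kd) is strictly decreasing
# in f (for gamma > 0 and Nm > Nd/2), running from +Inf at f -> 0 to -Inf at
# f -> 1, so the root is unique. Arguments are recycled to a common length.
.fdimer_solve <- function(kd_std, p0, det0, system, tol = 1e-12,
                          max_iter = 200L) {
  g <- gamma_order(system)
  n <- max(length(kd_std), length(p0), length(det0))
  kd <- rep_len(kd_std, n); p0 <- rep_len(p0, n); det0 <- rep_len(det0, n)
  if (any(p0 <= 0)) stop("p0 must be > 0", call. = FALSE)
  if (any(det0 <= system$CMC))
    stop("no micelles: det0 must exceed the CMC", call. = FALSE)
  # DetE(f) = a + b*f is linear in f; restrict the search to the feasible
  # sub-interval of (0, 1) where DetE > 0 (the peptide cannot sequester more
  # detergent than the micellar pool holds, so low-f states may be infeasible
  # even when the equilibrium state itself is fine)
  a <- det0 - system$CMC - system$Nm * p0
  b <- p0 * (system$Nm - system$Nd / 2)
  eps <- 1e-12
  lo <- rep(eps, n); hi <- rep(1 - eps, n)
  pos <- b > 0; neg <- b < 0
  lo[pos] <- pmax(lo[pos], -a[pos] / b[pos] + eps)
  hi[neg] <- pmin(hi[neg], -a[neg] / b[neg] - eps)
  zero <- !pos & !neg
  if (any((zero & a <= 0) | lo >= hi))
    stop("insufficient micellar detergent: DetE <= 0 on the feasible branch",
         call. = FALSE)
  gfun <- function(f) {
    m <- (1 - f) * p0
    d <- f * p0 / 2
    dete <- a + b * f
    2 * log(m) - log(d) - g * log(dete) - log(kd)
  }
  # g is strictly decreasing on the feasible interval when gamma > 0; verify
  # the sign change so degenerate parameter draws fail loudly
  if (any(gfun(lo) < 0) || any(gfun(hi) > 0))
    stop("no equilibrium root in the feasible dimer-fraction interval",
         call. = FALSE)
  f <- (lo + hi) / 2
  for (iter in seq_len(max_iter)) {
    val <- gfun(f)
    conv <- abs(val) < tol
    if (all(conv)) break
    # maintain the bracket (g is decreasing; f always lies inside it)
    up <- which(val > 0 & !conv); dn <- which(val < 0 & !conv)
    lo[up] <- f[up]
    hi[dn] <- f[dn]
    dete <- a + b * f
    dval <- -2 / (1 - f) - 1 / f - g * b / dete
    fn <- f - val / dval
    # fall back to bisection when Newton leaves the bracket
    bad <- !is.finite(fn) | fn <= lo | fn >= hi
    fn[bad] <- (lo[bad] + hi[bad]) / 2
    act <- !conv
    f[act] <- fn[act]
  }
  if (any(abs(gfun(f)) > 1e-6))
    stop("equilibrium solver failed to converge", call. = FALSE)
  f
}

#' Solve the micellar-solvent equilibrium for species concentrations
#'
#' Finds the unique dimer fraction `f` in (0, 1) such that with
#' `M = (1 - f) * p0`, `D = f * p0 / 2` and
#' `DetE = det0 - CMC - Nm*M - Nd*D` the relation
#' `M^2 / (D * DetE^gamma) = kd_std` holds. `f` is the fraction of peptide
#' *chains* in dimers, `2[D]/p0`: each chain carries one reporter proton, so
#' NMR integrals are chain-proportional.
#'
#' @param params an [equilibrium_params] object.
#' @param p0 total peptide concentration, molar.
#' @param det0 total detergent concentration, molar (must exceed the CMC).
#' @return a list of class `equilibrium_state` with fields `m`, `d`, `det_e`
#'   (molar), `f_dimer`, plus the `kd_std` and `gamma` used.
#' @export
solve_equilibrium <- function(params, p0, det0) {
  stopifnot(inherits(params, "equilibrium_params"))
  sys <- params$system
  f <- .fdimer_solve(params$kd_std, p0, det0, sys)
  m <- (1 - f) * p0
  d <- f * p0 / 2
  det_e <- det0 - sys$CMC - sys$Nm * m - sys$Nd * d
  structure(list(m = m, d = d, det_e = det_e, f_dimer = f,
                 kd_std = params$kd_std, gamma = gamma_order(sys)),
            class = "equilibrium_state")
}

#' Predicted dimer fraction over a titration
#'
#' Vectorised convenience wrapper around the equilibrium solver.
#'
#' @inheritParams solve_equilibrium
#' @param p0,det0 vectors of molar concentrations (recycled).
#' @return numeric vector of chain dimer fractions.
#' @export
predict_f_dimer <- function(params, p0, det0) {
  .fdimer_solve(params$kd_std, p0, det0, params$system)
}

#' Dimer fraction implied by an observed population (inverse problem)
#'
#' Converts an observed chain dimer fraction back to a dissociation constant at
#' fixed aggregation numbers: used to turn per-spectrum populations into
#' per-condition free energies.
#'
#' @param f_dimer observed chain dimer fraction(s) in (0, 1).
#' @param p0,det0 molar concentrations (recycled).
#' @param system a [micelle_system].
#' @return dissociation constant(s), standard-state units.
#' @export
kd_from_population <- function(f_dimer, p0, det0, system) {
  n <- max(length(f_dimer), length(p0), length(det0))
  f <- rep_len(pmin(pmax(f_dimer, 1e-9), 1 - 1e-9), n)
  p0 <- rep_len(p0, n); det0 <- rep_len(det0, n)
  m <- (1 - f) * p0
  d <- f * p0 / 2
  det_e <- det0 - system$CMC - system$Nm * m - system$Nd * d
  if (any(det_e <= 0))
    stop("insufficient micellar detergent for the observed population",
         call. = FALSE)
  m^2 / (d * det_e^gamma_order(system))
}
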