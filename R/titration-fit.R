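# Nonlinear least-squares fit of the micellar-solvent model to an observed
# detergent titration of the dimer fraction.

# fixed 5-point Latin-hypercube fractions in [0,1]^3 (deterministic; each
# column is a permutation of the 5 strata midpoints)
.LHS5 <- matrix(c(0.1, 0.5, 0.9, 0.3, 0.7,
                  0.7, 0.1, 0.5, 0.9, 0.3,
                  0.3, 0.9, 0.1, 0.7, 0.5), ncol = 3)

#' Fit the micellar-solvent model to a detergent titration
#'
#' Weighted nonlinear least squares of observed chain dimer fractions against
#' the predictions of [solve_equilibrium()] over the free parameters
#' `kd_std` (searched on a log scale), `Nm` and `Nd`. The apparent reaction
#' order gamma is always reported as a derived quantity, never fit directly.
#' Optimization uses L-BFGS-B from five fixed Latin-hypercube starting points
#' within the parameter bounds; standard errors come from the Jacobian at the
#' optimum, `cov = s^2 (J' W J)^-1`.
#'
#' @param points a data frame with molar columns `p0`, `det0`, a `temperature`
#'   column in K (single value across rows), observed `f_dimer`, and optionally
#'   `f_dimer_err` (standard errors used as 1/sigma^2 weights).
#' @param Ne,CMC fixed system constants (empty-micelle aggregation number and
#'   critical micelle concentration in M).
#' @param fixed optional named list freezing parameters, e.g.
#'   `list(Nm = 56, Nd = 59)` for a one-parameter fit of `kd_std`.
#' @param bounds named list of length-2 numeric bounds; defaults
#'   `kd_std` in \[1e-8, 1e2\], `Nm`, `Nd` in \[10, 200\].
#' @param weights `"auto"` (1/sigma^2 when `f_dimer_err` is present, otherwise
#'   unweighted), `"none"`, or a numeric vector.
#' @return an object of class `titration_fit`: `params`
#'   ([equilibrium_params]), `estimates`, `se`, `gamma`, `delta_g` (kcal/mol at
#'   the series temperature), `residuals`, `fitted`, `rss`, `n`, `convergence`.
#' @export
fit_titration <- function(points, Ne = 55, CMC = 1.5e-3, fixed = list(),
                          bounds = list(kd_std = c(1e-8, 1e2),
                                        Nm = c(10, 200), Nd = c(10, 200)),
                          weights = c("auto", "none")) {
  req <- c("p0", "det0", "f_dimer")
  if (!all(req %in% names(points)))
    stop("points needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  n <- nrow(points)
  if (n < 4) stop("need at least 4 titration points", call. = FALSE)
  temp <- if ("temperature" %in% names(points)) unique(points$temperature)
          else NA_real_
  if (length(temp) > 1)
    stop("titration points must share a single temperature", call. = FALSE)
  if (max(points$det0) / min(points$det0) < 4)
    warning("detergent range spans < 4-fold; parameters may be poorly ",
            "determined", call. = FALSE)
  if (any(points$f_dimer < 0 | points$f_dimer > 1))
    stop("f_dimer observations must lie in [0, 1]", call. = FALSE)

  if (is.character(weights)) {
    weights <- match.arg(weights)
    w <- if (weights == "auto" && "f_dimer_err" %in% names(points) &&
             all(is.finite(points$f_dimer_err)) && all(points$f_dimer_err > 0))
      1 / points$f_dimer_err^2 else rep(1, n)
  } else {
    w <- rep_len(as.numeric(weights), n)
  }

  free_names <- setdiff(c("kd_std", "Nm", "Nd"), names(fixed))
  if (length(free_names) == 0L) stop("no free parameters", call. = FALSE)

  # internal parameterisation: log(kd_std), Nm, Nd
  to_theta <- function(p) {
    th <- c(log(p[["kd_std"]]), p[["Nm"]], p[["Nd"]])
    names(th) <- c("kd_std", "Nm", "Nd")
    th[free_names]
  }
  full_par <- function(theta) {
    p <- list(kd_std = NA_real_, Nm = NA_real_, Nd = NA_real_)
    p[names(fixed)] <- fixed
    if ("kd_std" %in% free_names) p$kd_std <- exp(theta[["kd_std"]])
    if ("Nm" %in% free_names) p$Nm <- theta[["Nm"]]
    if ("Nd" %in% free_names) p$Nd <- theta[["Nd"]]
    p
  }
  predict_f <- function(p) {
    # plain list, not the constructor: this sits in the optimizer's hot loop
    sys <- structure(list(Nm = p$Nm, Nd = p$Nd, Ne = Ne, CMC = CMC),
                     class = "micelle_system")
    .fdimer_solve(p$kd_std, points$p0, points$det0, sys)
  }
  obj <- function(theta) {
    p <- full_par(theta)
    pred <- tryCatch(predict_f(p), error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(1e6)
    sum(w * (points$f_dimer - pred)^2)
  }

  lo <- c(kd_std = log(bounds$kd_std[1]), Nm = bounds$Nm[1], Nd = bounds$Nd[1])
  hi <- c(kd_std = log(bounds$kd_std[2]), Nm = bounds$Nm[2], Nd = bounds$Nd[2])
  lo <- lo[free_names]; hi <- hi[free_names]

  # five Latin-hypercube starts mapped into the bounds
  dims <- match(free_names, c("kd_std", "Nm", "Nd"))
  starts <- lapply(seq_len(nrow(.LHS5)), function(i) {
    s <- lo + .LHS5[i, dims] * (hi - lo)
    names(s) <- free_names
    s
  })
  # heuristic start: micelles unperturbed by peptide, kd from the median point
  mid <- order(points$det0)[ceiling(n / 2)]
  sys0 <- micelle_system(Nm = Ne + 1, Nd = Ne + 4, Ne = Ne, CMC = CMC)
  kd0 <- tryCatch(kd_from_population(points$f_dimer[mid], points$p0[mid],
                                     points$det0[mid], sys0),
                  error = function(e) 1e-2)
  h <- c(kd_std = log(max(min(kd0, bounds$kd_std[2]), bounds$kd_std[1])),
         Nm = Ne + 1, Nd = Ne + 4)
  starts <- c(list(pmin(pmax(h[free_names], lo), hi)), starts)

  # explore from every start with a loose tolerance, then polish the best
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 60, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (best$value < 1e-16) break
  }
  if (is.null(best) || best$value >= 1e6)
    stop("titration fit failed to converge from any start", call. = FALSE)
  polish <- tryCatch(
    optim(best$par, obj, method = "L-BFGS-B", lower = lo, upper = hi,
          control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  at_bound <- abs(best$par - lo) < 1e-6 | abs(best$par - hi) < 1e-6
  if (any(at_bound))
    warning("parameter(s) pinned at bounds: ",
            paste(free_names[at_bound], collapse = ", "), call. = FALSE)

  p_hat <- full_par(best$par)
  sys_hat <- suppressWarnings(micelle_system(Nm = p_hat$Nm, Nd = p_hat$Nd,
                                             Ne = Ne, CMC = CMC))
  fitted <- predict_f(p_hat)
  resid <- points$f_dimer - fitted
  rss <- sum(w * resid^2)
  dof <- max(n - length(free_names), 1)
  s2 <- rss / dof

  # numeric Jacobian of predictions wrt the *natural* free parameters
  nat <- unlist(p_hat)[free_names]
  Jac <- matrix(NA_real_, n, length(free_names))
  for (j in seq_along(free_names)) {
    hstep <- max(abs(nat[j]), 1e-6) * 1e-5
    up <- nat; up[j] <- up[j] + hstep
    dn <- nat; dn[j] <- dn[j] - hstep
    pu <- p_hat; pu[free_names[j]] <- up[j]
    pd <- p_hat; pd[free_names[j]] <- dn[j]
    Jac[, j] <- (predict_f(pu) - predict_f(pd)) / (2 * hstep)
  }
  JtWJ <- crossprod(Jac * sqrt(w))
  se <- rep(NA_real_, length(free_names))
  covm <- tryCatch(s2 * solve(JtWJ), error = function(e) NULL)
  if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  names(se) <- free_names

  dg <- if (is.finite(temp)) delta_g(p_hat$kd_std, temp) else NA_real_
  structure(list(
    params = equilibrium_params(p_hat$kd_std, sys_hat),
    estimates = unlist(p_hat), se = se, gamma = gamma_order(sys_hat),
    temperature = temp, delta_g = dg,
    fitted = fitted, residuals = resid, rss = rss, n = n,
    weights = w, convergence = best$convergence,
    free = free_names, fixed = fixed, Ne = Ne, CMC = CMC),
    class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("<titration_fit>\n")
  cat(sprintf("  n = %d points, RSS = %.3g\n", x$n, x$rss))
  for (nm in c("kd_std", "Nm", "Nd")) {
    tag <- if (nm %in% x$free) sprintf("+/- %.3g", x$se[nm]) else "(fixed)"
    cat(sprintf("  %-7s = %.6g %s\n", nm, x$estimates[nm], tag))
  }
  cat(sprintf("  gamma  = %.4f (derived)\n", x$gamma))
  if (is.finite(x$delta_g))
    cat(sprintf("  dG(%.2f K) = %.3f kcal/mol\n", x$temperature, x$delta_g))
  invisible(x)
}
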