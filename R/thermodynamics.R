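# van't Hoff decomposition of the dimerization free energy: with negligible
# heat-capacity change, dG(T) = dH - T*dS is linear in T, so a weighted linear
# regression of dG on T yields dH (intercept) and dS (minus the slope).

#' van't Hoff fit of a free-energy temperature series
#'
#' Weighted linear regression of `dG` on `T`: `dG(T) = dH - T*dS`. The
#' intercept is the enthalpy, minus the slope the entropy. Standard errors come
#' from the regression.
#'
#' @param points data frame with columns `temperature` (K), `delta_g`
#'   (kcal/mol) and optionally `se` (kcal/mol, used as 1/se^2 weights).
#' @return an object of class `thermo_params` with fields `delta_h` (kcal/mol),
#'   `delta_s` (kcal/(mol K)), `delta_s_cal` (cal/(mol K)), `se_h`, `se_s`,
#'   `valid_range` (K), `fit` (the `lm` object).
#' @export
vant_hoff_fit <- function(points) {
  if (!all(c("temperature", "delta_g") %in% names(points)))
    stop("points needs columns temperature and delta_g", call. = FALSE)
  n <- nrow(points)
  if (n < 3) stop("need at least 3 temperature points", call. = FALSE)
  if (length(unique(points$temperature)) < 2)
    stop("temperatures must not all be identical", call. = FALSE)
  if (any(points$temperature <= 0)) stop("temperatures must be in K (> 0)",
                                         call. = FALSE)
  if (diff(range(points$temperature)) < 20)
    warning("temperature span < 20 K; dH and dS will be strongly correlated",
            call. = FALSE)
  w <- if ("se" %in% names(points) && all(is.finite(points$se)) &&
           all(points$se > 0)) 1 / points$se^2 else rep(1, n)
  fit <- lm(delta_g ~ temperature, data = points, weights = w)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(list(
    delta_h = unname(cf[1]), delta_s = unname(-cf[2]),
    delta_s_cal = unname(-cf[2]) * 1000,
    se_h = unname(se[1]), se_s = unname(se[2]),
    valid_range = range(points$temperature), n = n, fit = fit),
    class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>\n")
  cat(sprintf("  dH = %.3f +/- %.3f kcal/mol\n", x$delta_h, x$se_h))
  cat(sprintf("  dS = %.4f +/- %.4f kcal/(mol K)  [%.1f cal/(mol K)]\n",
              x$delta_s, x$se_s, x$delta_s_cal))
  cat(sprintf("  valid T range: %.2f - %.2f K (n = %d)\n",
              x$valid_range[1], x$valid_range[2], x$n))
  invisible(x)
}

#' Predicted free energy from thermodynamic parameters
#'
#' @param params a `thermo_params` object (or any list with `delta_h`,
#'   `delta_s`).
#' @param temperature temperature(s) in K.
#' @return `dH - T*dS` in kcal/mol.
#' @export
predict_delta_g <- function(params, temperature) {
  params$delta_h - temperature * params$delta_s
}

#' Entropic contribution T*dS
#'
#' @inheritParams predict_delta_g
#' @return `T * dS` in kcal/mol.
#' @export
t_delta_s <- function(params, temperature) {
  temperature * params$delta_s
}

#' Curvature (heat-capacity) check of a free-energy series
#'
#' Fits a quadratic in centred temperature and reports the second-order
#' coefficient with its t-test p-value. A non-significant coefficient
#' (p > 0.05) supports the linear van't Hoff model, i.e. a negligible
#' heat-capacity change on dimerization.
#'
#' @inheritParams vant_hoff_fit
#' @param alpha significance level for the linearity verdict.
#' @return list with `quad_coef` (kcal/(mol K^2)), `p_value`, `linear`
#'   (logical verdict), `fit`.
#' @export
curvature_check <- function(points, alpha = 0.05) {
  if (!all(c("temperature", "delta_g") %in% names(points)))
    stop("points needs columns temperature and delta_g", call. = FALSE)
  if (nrow(points) < 4) stop("need at least 4 points for a curvature check",
                             call. = FALSE)
  tc <- points$temperature - mean(points$temperature)
  fit <- lm(points$delta_g ~ tc + I(tc^2))
  sm <- summary(fit)$coefficients
  quad <- sm["I(tc^2)", "Estimate"]
  # residual variance can collapse to ~0 on exact lines; guard the p-value
  p <- if (is.na(sm["I(tc^2)", "Pr(>|t|)"])) 1 else sm["I(tc^2)", "Pr(>|t|)"]
  list(quad_coef = unname(quad), p_value = unname(p), linear = p > alpha,
       fit = fit)
}

#' Intermonomer hydrogen-bond estimate from the dimerization free energy
#'
#' Divides the favourable free energy by a per-bond increment (default
#' 0.5 kcal/mol per residue/hydrogen bond for beta-sheet formation in a
#' membrane) and rounds to the nearest integer (round-half-even, the R
#' default).
#'
#' @param delta_g free energy of dimerization, kcal/mol (must be negative).
#' @param per_bond free-energy gain per hydrogen bond, kcal/mol (> 0).
#' @return integer number of hydrogen bonds.
#' @export
hbond_estimate <- function(delta_g, per_bond = 0.5) {
  if (per_bond <= 0) stop("per_bond must be > 0", call. = FALSE)
  if (any(delta_g >= 0))
    stop("delta_g must be negative (favourable association)", call. = FALSE)
  as.integer(round(abs(delta_g) / per_bond))
}
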