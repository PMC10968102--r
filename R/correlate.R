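# Pearson correlation / ordinary least squares and composite-descriptor
# optimization used in the descriptor-activity analysis.

#' Pearson correlation with an ordinary least-squares line
#'
#' Fits `y = slope * x + intercept` and reports the squared Pearson correlation
#' with a two-sided p-value from the t statistic
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, both non-constant.
#' @return a list with `r`, `r_squared`, `p_value`, `slope`, `intercept`, `n`.
#' @export
pearson_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  r <- cor(x, y)
  r2 <- r * r
  if (1 - r2 <= .Machine$double.eps) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  slope <- r * sd(y) / sd(x)
  list(r = r, r_squared = r2, p_value = p,
       slope = slope, intercept = mean(y) - slope * mean(x), n = n)
}

#' Evaluate a composite descriptor
#'
#' A composite descriptor is a fixed linear combination of descriptor columns,
#' e.g. `c(gravy = 1, arom = 8)` for GRAVY + 8 x AROM.
#'
#' @param table data frame of descriptors.
#' @param terms named numeric vector of coefficients; names must be columns of
#'   `table`.
#' @return numeric vector of per-row composite values.
#' @export
composite_value <- function(table, terms) {
  if (length(terms) < 1L || is.null(names(terms)) || any(names(terms) == ""))
    stop("terms must be a named numeric vector with at least one term",
         call. = FALSE)
  missing_cols <- setdiff(names(terms), names(table))
  if (length(missing_cols) > 0L)
    stop("descriptor column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  mat <- as.matrix(table[names(terms)])
  if (anyNA(mat)) stop("missing values in descriptor columns", call. = FALSE)
  drop(mat %*% terms)
}

#' Optimize (or evaluate) a composite descriptor against a target
#'
#' Searches the coefficients of a linear combination of descriptor columns that
#' maximize the squared Pearson correlation with `target`. Because R-squared is
#' invariant to scale and shift of the composite, the first coefficient is held
#' fixed at its supplied value (default 1) to remove the degeneracy; the
#' remaining coefficients listed in `free` are optimized by Nelder-Mead from
#' multiple starts, one of which is derived from the ordinary-least-squares
#' solution (the closed-form maximizer of R-squared over all linear
#' combinations). With `free = character(0)` the composite is simply evaluated
#' at the supplied coefficients.
#'
#' @inheritParams composite_value
#' @param target numeric response vector (one value per row of `table`).
#' @param terms named numeric vector of starting coefficients.
#' @param free character vector naming the coefficients to optimize; defaults
#'   to every term except the first (the scale anchor).
#' @return a list with `terms` (coefficients used/found), `composite` (values),
#'   `r_squared`, `p_value`, `n`, `slope`, `intercept`, `optimized`.
#' @export
optimize_composite <- function(table, target, terms,
                               free = names(terms)[-1]) {
  target <- as.numeric(target)
  if (nrow(table) != length(target))
    stop("target length must match table rows", call. = FALSE)
  if (nrow(table) < 4) stop("need at least 4 observations", call. = FALSE)
  comp0 <- composite_value(table, terms)  # validates columns / NA
  free <- intersect(free, names(terms))

  if (length(free) == 0L) {
    if (sd(comp0) == 0) stop("composite is constant", call. = FALSE)
    fit <- pearson_fit(comp0, target)
    return(c(list(terms = terms, composite = comp0, optimized = FALSE), fit))
  }

  X <- as.matrix(table[names(terms)])
  objective <- function(theta) {
    tt <- terms; tt[free] <- theta
    v <- drop(X %*% tt)
    if (sd(v) < 1e-12) return(1)      # degenerate composite: worst case
    1 - cor(v, target)^2
  }

  # OLS-derived start: regress target on all columns; rescale so the anchor
  # coefficient matches its fixed value when possible.
  ols <- tryCatch(coef(lm(target ~ X))[-1], error = function(e) NULL)
  starts <- list(terms[free])
  if (!is.null(ols) && !anyNA(ols)) {
    names(ols) <- colnames(X)
    anchor <- setdiff(names(terms), free)[1]
    if (!is.na(anchor) && is.finite(ols[anchor]) && abs(ols[anchor]) > 1e-12) {
      scaled <- ols * (terms[anchor] / ols[anchor])
      starts <- c(starts, list(scaled[free]))
    } else {
      starts <- c(starts, list(ols[free]))
    }
  }
  # fixed spread of additional starts (deterministic, no RNG)
  for (mag in c(-10, -1, 0, 1, 10))
    starts <- c(starts, list(setNames(rep(mag, length(free)), free)))

  best <- NULL
  for (s in starts) {
    res <- tryCatch({
      if (length(free) == 1L) {
        # Brent in 1-D (Nelder-Mead is unreliable there)
        r <- optim(s, objective, method = "Brent",
                   lower = s - 100 * (abs(s) + 1),
                   upper = s + 100 * (abs(s) + 1))
        r$par <- setNames(r$par, free)
        r
      } else {
        optim(s, objective, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
      }
    }, error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("composite optimization failed to converge", call. = FALSE)
  terms[free] <- best$par
  comp <- drop(X %*% terms)
  if (sd(comp) == 0) stop("optimized composite is constant", call. = FALSE)
  fit <- pearson_fit(comp, target)
  c(list(terms = terms, composite = comp, optimized = TRUE), fit)
}
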