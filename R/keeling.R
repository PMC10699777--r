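#' Keeling-plot source signature regression
#'
#' When a source of fixed isotopic composition accumulates over an
#' ambient background, the mixture delta is exactly linear in the inverse
#' of total concentration, and the intercept at 1/C = 0 is the source
#' signature. The default is ordinary least squares of delta on 1/C
#' (model I); geometric-mean (model II) regression is available for the
#' case of comparable error on both axes.
#'
#' With exactly 2 distinct concentrations the line is exact and the
#' intercept standard error is undefined (returned as `NA`).
#'
#' @param concentrations N2O mole fractions (ppb), all positive, at least
#'   2 distinct values.
#' @param deltas Measured deltas (permil), same length.
#' @param method `"ols"` (default) or `"gmr"` (geometric-mean, model II).
#' @return Object of class `keeling_result`: `intercept` (source delta,
#'   permil), `slope`, `se_intercept`, `r2`, `n`, `method`.
#' @export
#' @examples
#' # ambient 330 ppb at 0 permil + source at 50 permil
#' keeling_fit(c(660, 1320), c(25, 37.5))$intercept  # 50
keeling_fit <- function(concentrations, deltas, method = c("ols", "gmr")) {
  method <- match.arg(method)
  if (any(concentrations <= 0))
    stop(errorCondition("concentrations must be positive",
                        class = c("n2osip_domain_error", "error")))
  if (length(unique(concentrations)) < 2)
    stop(errorCondition("need >= 2 distinct concentrations",
                        class = c("n2osip_degenerate_design_error", "error")))
  x <- 1 / concentrations
  y <- deltas
  n <- length(y)
  if (method == "ols") {
    fit <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(fit))
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
    se <- if (n >= 3) unname(sm$coefficients[1, 2]) else NA_real_
    r2 <- if (stats::var(y) == 0) 1 else sm$r.squared
  } else {
    sx <- stats::sd(x); sy <- stats::sd(y)
    r <- if (sy == 0) 1 else stats::cor(x, y)
    slope <- sign(ifelse(r == 0, 1, r)) * sy / sx
    intercept <- mean(y) - slope * mean(x)
    se <- NA_real_
    r2 <- r^2
  }
  structure(list(intercept = intercept, slope = slope, se_intercept = se,
                 r2 = r2, n = n, method = method),
            class = "keeling_result")
}

#' @export
print.keeling_result <- function(x, ...) {
  cat(sprintf(
    "<keeling_result> source delta %.2f permil (SE %.3g, R2 %.3f, n %d, %s)\n",
    x$intercept, x$se_intercept, x$r2, x$n, x$method))
  invisible(x)
}
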