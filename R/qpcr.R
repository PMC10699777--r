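#' Fit a qPCR standard curve
#'
#' Absolute quantification rests on the log-linear relation between the
#' quantification cycle and template input: Cq = intercept + slope *
#' log10(copies). The amplification efficiency follows from the slope as
#' E = 10^(-1/slope) - 1, so a perfectly doubling reaction (E = 1) has
#' slope -1/log10(2) = -3.3219 cycles per decade.
#'
#' @param copies Input copy numbers of the standards (> 0, >= 3 distinct
#'   dilution levels).
#' @param cq Measured quantification cycles, same length.
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r2`, `dynamic_range` (copies).
#' @export
#' @examples
#' cps <- 10^(7:2)
#' fit_standard_curve(cps, 35 - log10(cps) / log10(2))$efficiency  # 1
fit_standard_curve <- function(copies, cq) {
  if (any(copies <= 0))
    stop(errorCondition("standard copies must be positive",
                        class = c("n2osip_domain_error", "error")))
  if (length(unique(copies)) < 3)
    stop(errorCondition("need >= 3 dilution levels",
                        class = c("n2osip_degenerate_design_error", "error")))
  x <- log10(copies)
  fit <- stats::lm(cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop(errorCondition(
      "nonnegative standard-curve slope: inhibited or failed run",
      class = c("n2osip_curve_failure_error", "error")))
  r2 <- if (stats::var(cq) == 0) 1
        else suppressWarnings(summary(fit))$r.squared
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1, r2 = r2,
                 dynamic_range = range(copies)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.3f cycles/log10, E = %.1f%%, R2 %.4f, range %.3g-%.3g copies\n",
    x$slope, 100 * x$efficiency, x$r2, x$dynamic_range[1],
    x$dynamic_range[2]))
  invisible(x)
}

#' Quantify gene copies per gram of soil
#'
#' Inverts the standard curve for the copies in the reaction,
#' copies_rxn = 10^((cq - intercept)/slope), then scales to soil mass:
#' copies/g = copies_rxn * (elution volume / template volume) * dilution
#' / soil mass. Replicate Cq values are averaged (mean) before
#' quantification. There are no default conversion factors — the
#' metadata must state them.
#'
#' @param cq Quantification cycle(s); replicates are averaged.
#' @param curve A `standard_curve`.
#' @param meta List: `soil_mass_g`, `elution_ul`, `template_ul`,
#'   `dilution` (all positive).
#' @return List: `copies_per_g`, `copies_rxn`, `mean_cq`,
#'   `in_dynamic_range` flag.
#' @export
quantify <- function(cq, curve, meta) {
  stopifnot(inherits(curve, "standard_curve"))
  for (f in c("soil_mass_g", "elution_ul", "template_ul", "dilution")) {
    if (is.null(meta[[f]]) || meta[[f]] <= 0)
      stop(errorCondition(sprintf("meta$%s must be a positive number", f),
                          class = c("n2osip_config_error", "error")))
  }
  mean_cq <- mean(cq)
  copies_rxn <- 10^((mean_cq - curve$intercept) / curve$slope)
  in_range <- copies_rxn >= curve$dynamic_range[1] &
              copies_rxn <= curve$dynamic_range[2]
  list(copies_per_g = copies_rxn * (meta$elution_ul / meta$template_ul) *
         meta$dilution / meta$soil_mass_g,
       copies_rxn = copies_rxn, mean_cq = mean_cq,
       in_dynamic_range = in_range)
}

#' Replicate-level detection call
#'
#' A target is called detected when a configurable fraction of
#' replicates amplifies below the cycle limit (default: a majority of
#' replicates below 40 cycles). Non-amplifying replicates are encoded as
#' `NA`.
#'
#' @param cq_values Replicate Cq values (`NA` = no amplification).
#' @param limit_cycles Cycle threshold (default 40).
#' @param min_fraction Fraction of replicates that must amplify below
#'   the limit (default 0.5, strict majority).
#' @return Logical: detected or not.
#' @export
detection_call <- function(cq_values, limit_cycles = 40,
                           min_fraction = 0.5) {
  if (length(cq_values) < 1)
    stop(errorCondition("need >= 1 replicate",
                        class = c("n2osip_data_error", "error")))
  amplified <- !is.na(cq_values) & cq_values < limit_cycles
  mean(amplified) > min_fraction
}
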