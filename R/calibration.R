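#' Fit instrument calibration models for N2O isotopocule deltas
#'
#' Laser-spectroscopic N2O isotope analyzers show known mass dependencies:
#' the measured delta drifts with N2O concentration (approximately linear
#' in 1/[N2O]) and with CO2. The calibration model fitted here, per delta
#' channel (alpha, beta, 18O), is
#' \deqn{measured = b0 + b1 * true + b2 / [N2O] + b3 * [CO2]}
#' estimated by least squares from runs of certified reference standards
#' (USGS 51/52) measured across a grid of N2O and CO2 concentrations. The
#' functional form is deliberately explicit and swappable; it is linear
#' and therefore exactly invertible for the true delta.
#'
#' @param runs data.frame of standard measurements with columns
#'   `standard` (name matching `standards`), `n2o_ppm`, `co2_ppm`, and
#'   measured deltas `d15n_alpha`, `d15n_beta`, `d18o`.
#' @param standards Named list of certified values (as in
#'   `default_config()$standards`): each with `d15n_alpha`, `d15n_beta`,
#'   `d18o`.
#' @param valid_range_ppm Concentration range (ppm N2O) within which the
#'   model is considered calibrated.
#' @return Object of class `calibration_model`: per-channel coefficient
#'   vectors `c(b0, b_true, b_invc, b_co2)`, per-channel R2, and the
#'   validity range.
#' @export
fit_calibration <- function(runs, standards,
                            valid_range_ppm = c(0.6, 8)) {
  if (length(standards) < 2)
    stop(errorCondition("need >= 2 reference standards",
                        class = c("n2osip_degenerate_design_error", "error")))
  if (length(unique(runs$n2o_ppm)) < 3)
    stop(errorCondition(
      "need >= 3 N2O concentration levels (missing factor: n2o_ppm)",
      class = c("n2osip_degenerate_design_error", "error")))
  channels <- c("d15n_alpha", "d15n_beta", "d18o")
  coefs <- list(); r2 <- numeric(0)
  for (ch in channels) {
    true <- vapply(runs$standard, function(s) standards[[s]][[ch]], 0)
    X <- cbind(1, true, 1 / runs$n2o_ppm, runs$co2_ppm)
    if (qr(X)$rank < 4)
      stop(errorCondition(
        sprintf("rank-deficient calibration design for %s (missing factor)",
                ch),
        class = c("n2osip_degenerate_design_error", "error")))
    y <- runs[[ch]]
    b <- qr.solve(X, y)
    yhat <- drop(X %*% b)
    ss_res <- sum((y - yhat)^2)
    ss_tot <- sum((y - mean(y))^2)
    coefs[[ch]] <- stats::setNames(b, c("b0", "b_true", "b_invc", "b_co2"))
    r2[ch] <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  }
  structure(list(coefficients = coefs, r2 = r2,
                 valid_range_ppm = valid_range_ppm),
            class = "calibration_model")
}

#' Apply a calibration model to a reading
#'
#' Inverts the fitted calibration for each delta channel:
#' true = (measured - b0 - b2/[N2O] - b3*[CO2]) / b1, then rebuilds SP and
#' bulk delta15N from the corrected site deltas so the reading invariants
#' hold after correction. Readings outside the calibrated concentration
#' range are still corrected but flagged.
#'
#' @param reading An [isotopocule_reading()] (deltas on the measured
#'   scale; `n2o_ppb`, `co2_ppm` populated).
#' @param model A `calibration_model` from [fit_calibration()].
#' @return A corrected `isotopocule_reading` with attribute
#'   `out_of_range` (logical).
#' @export
apply_calibration <- function(reading, model) {
  stopifnot(inherits(reading, "isotopocule_reading"),
            inherits(model, "calibration_model"))
  n2o_ppm <- reading$n2o_ppb / 1000
  co2 <- if (is.na(reading$co2_ppm)) 0 else reading$co2_ppm
  correct <- function(ch, measured) {
    b <- model$coefficients[[ch]]
    if (abs(b["b_true"]) < 1e-12)
      stop(errorCondition(
        sprintf("calibration model not invertible for %s", ch),
        class = c("n2osip_numerical_error", "error")))
    unname((measured - b["b0"] - b["b_invc"] / n2o_ppm - b["b_co2"] * co2) /
             b["b_true"])
  }
  out <- isotopocule_reading(
    n2o_ppb = reading$n2o_ppb,
    d15n_alpha = correct("d15n_alpha", reading$d15n_alpha),
    d15n_beta = correct("d15n_beta", reading$d15n_beta),
    d18o = correct("d18o", reading$d18o),
    co2_ppm = reading$co2_ppm)
  rng <- model$valid_range_ppm
  attr(out, "out_of_range") <- n2o_ppm < rng[1] || n2o_ppm > rng[2]
  if (attr(out, "out_of_range"))
    warning(sprintf("N2O %.2f ppm outside calibrated range [%g, %g] ppm",
                    n2o_ppm, rng[1], rng[2]), call. = FALSE)
  out
}
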