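#' Convert a concentration slope to an areal N2O flux
#'
#' Under the ideal-gas law the recirculating system holds
#' n = P V / (R T) mol of air; a slope of s ppb s^-1 is then
#' s * 1e-9 * n mol N2O s^-1, carrying 28.014 g N per mol N2O (two N
#' atoms), divided by the collar area. The conversion is linear
#' (homogeneous of degree 1) in the slope.
#'
#' @param slope_ppb_s Concentration slope (ppb s^-1).
#' @param geom Geometry list: `collar_diameter_m` (or `area_m2`),
#'   `system_volume_l`, `temperature_k`, `pressure_kpa`.
#' @return Flux in ng N m^-2 s^-1.
#' @export
#' @examples
#' geom <- list(collar_diameter_m = 0.2, system_volume_l = 10,
#'              temperature_k = 313.15, pressure_kpa = 101.325)
#' convert_flux_units(1.0, geom)
convert_flux_units <- function(slope_ppb_s, geom) {
  area <- if (!is.null(geom$area_m2)) geom$area_m2 else collar_area_m2(geom)
  v <- geom$system_volume_l
  t <- geom$temperature_k
  p <- geom$pressure_kpa
  if (any(c(area, v, t, p) <= 0))
    stop(errorCondition("geometry fields must all be positive",
                        class = c("n2osip_domain_error", "error")))
  n_mol <- p * v / (R_GAS * t)   # kPa * L = J
  slope_ppb_s * n_mol * M_N2 / area   # 1e-9 (ppb) * 1e9 (g -> ng) cancel
}

#' Fit a chamber N2O flux with significance gating
#'
#' Ordinary least squares of N2O mole fraction on elapsed time over the
#' closure window after discarding an initial deadband (default: the
#' first 30 s of a 2-min closure, i.e. the fit uses the last 90 s). The
#' slope is converted to an areal flux via [convert_flux_units()]. If the
#' linear fit is not statistically significant (two-sided slope t test,
#' p > alpha), the flux is gated: reported as zero with `gated = TRUE`,
#' while slope, R2 and p are still returned for diagnostics.
#'
#' @param series A [chamber_series()] carrying geometry.
#' @param deadband_s Seconds discarded from the start of the closure.
#' @param alpha Significance level for gating (default 0.05).
#' @return Object of class `flux_estimate`: slope (ppb s^-1), intercept,
#'   r2, p_value, flux (ng N m^-2 s^-1), gated, window_s, n.
#' @export
fit_flux <- function(series, deadband_s = 30, alpha = 0.05) {
  stopifnot(inherits(series, "chamber_series"))
  keep <- series$time_s >= series$time_s[1] + deadband_s
  t <- series$time_s[keep]
  y <- series$n2o_ppb[keep]
  if (length(t) < 3)
    stop(errorCondition("fewer than 3 points after deadband",
                        class = c("n2osip_data_error", "error")))
  if (stats::var(t) == 0)
    stop(errorCondition("zero time variance in fit window",
                        class = c("n2osip_data_error", "error")))
  fit <- stats::lm(y ~ t)
  sm <- suppressWarnings(summary(fit))  # noiseless series fit perfectly
  slope <- unname(stats::coef(fit)[2])
  # residual variance can be exactly 0 on noiseless synthetic series
  p <- if (sm$sigma == 0) 0 else unname(sm$coefficients[2, 4])
  r2 <- sm$r.squared
  gated <- p > alpha
  flux <- if (gated) 0 else convert_flux_units(slope, series$geometry)
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r2 = r2, p_value = p, flux = flux, gated = gated,
         window_s = diff(range(t)), n = length(t)),
    class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf(
    "<flux_estimate> %.3g ng N m-2 s-1 (slope %.4g ppb/s, R2 %.3f, p %.3g%s)\n",
    x$flux, x$slope, x$r2, x$p_value, if (x$gated) ", gated to zero" else ""))
  invisible(x)
}

#' Tail-average delta15N index of a closure
#'
#' When chamber air is diluted by ambient make-up air the measured
#' delta15N never reaches the source value, so the tail average is an
#' *index* of how quickly labelled N appears in the emitted N2O — not an
#' absolute source signature. The conventional index is the mean raw
#' delta15N over the final 10 s of the closure.
#'
#' @param series A [chamber_series()] with a `d15n` stream.
#' @param tail_s Averaging window measured back from the last sample (s).
#' @return List: `star_d15n` (permil), `n` points averaged, and
#'   `index_only = TRUE` as a reminder of its status.
#' @export
star_delta15N <- function(series, tail_s = 10) {
  stopifnot(inherits(series, "chamber_series"))
  if (is.null(series$d15n))
    stop(errorCondition("series has no delta15N stream",
                        class = c("n2osip_missing_channel_error", "error")))
  keep <- series$time_s >= max(series$time_s) - tail_s
  if (!any(keep))
    stop(errorCondition("no points in tail window",
                        class = c("n2osip_data_error", "error")))
  list(star_d15n = mean(series$d15n[keep]), n = sum(keep),
       index_only = TRUE)
}

#' Summarize a flux pulse: peak and cumulative emission
#'
#' Given time-ordered flux estimates from repeated closures after a
#' wetting event, returns the peak flux (gated estimates count as zero;
#' ties broken by earliest time), the time of the peak, and the
#' trapezoidal integral of flux over time. Because instrument dropouts
#' leave gaps, the integral is reported with a gap diagnostic (largest
#' inter-sample gap and its fraction of the span) rather than silently
#' interpolated.
#'
#' @param estimates List of `flux_estimate` objects, or a numeric vector
#'   of fluxes.
#' @param time_h Time of each estimate (hours since wetting).
#' @param window_h Only estimates with `time_h <= window_h` are used
#'   (default 24).
#' @return List: `peak_flux`, `time_of_peak_h`, `cumulative` (flux units
#'   times hours), `max_gap_h`, `gap_fraction`, `n`.
#' @export
summarize_pulse <- function(estimates, time_h, window_h = 24) {
  flux <- if (is.numeric(estimates)) estimates
          else vapply(estimates, function(e) e$flux, 0)
  keep <- time_h <= window_h
  flux <- flux[keep]
  time_h <- time_h[keep]
  if (length(flux) == 0)
    stop(errorCondition("no estimates within the summary window",
                        class = c("n2osip_data_error", "error")))
  ord <- order(time_h)
  flux <- flux[ord]
  time_h <- time_h[ord]
  i_peak <- which(flux == max(flux))[1]
  cum <- if (length(flux) > 1)
    sum(diff(time_h) * (flux[-1] + flux[-length(flux)]) / 2) else 0
  gaps <- if (length(time_h) > 1) diff(time_h) else 0
  span <- diff(range(time_h))
  list(peak_flux = flux[i_peak], time_of_peak_h = time_h[i_peak],
       cumulative = cum, max_gap_h = max(gaps),
       gap_fraction = if (span > 0) max(gaps) / span else 0,
       n = length(flux))
}
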