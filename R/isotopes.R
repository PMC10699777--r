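#' Convert isotope ratios to delta notation and back
#'
#' Delta notation expresses a sample isotope ratio as the per-mil
#' deviation from a reference-standard ratio:
#' delta = (r_sample / r_standard - 1) * 1000. `delta_to_ratio()` is the
#' exact inverse.
#'
#' @param r_sample,r_standard Isotope ratios (e.g. 15N/14N), positive.
#' @param delta Delta value (permil), > -1000.
#' @return `ratio_to_delta()`: delta in permil. `delta_to_ratio()`: the
#'   ratio. Both vectorized.
#' @export
#' @examples
#' ratio_to_delta(2 * 0.0036765, 0.0036765)  # 1000 permil
ratio_to_delta <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop(errorCondition("isotope ratios must be positive",
                        class = c("n2osip_domain_error", "error")))
  (r_sample / r_standard - 1) * 1000
}

#' @rdname ratio_to_delta
#' @export
delta_to_ratio <- function(delta, r_standard) {
  if (any(r_standard <= 0))
    stop(errorCondition("standard ratio must be positive",
                        class = c("n2osip_domain_error", "error")))
  if (any(delta <= -1000))
    stop(errorCondition("delta must exceed -1000 permil",
                        class = c("n2osip_domain_error", "error")))
  r_standard * (1 + delta / 1000)
}

#' Site preference and bulk delta15N of N2O
#'
#' N2O is an asymmetric linear molecule; the site preference (SP) is the
#' delta15N of the central (alpha) nitrogen minus that of the terminal
#' (beta) nitrogen, and the bulk delta15N is their arithmetic mean. SP is
#' diagnostic of the producing process (e.g. bacterial denitrification vs
#' fungal denitrification vs nitrification).
#'
#' @param d_alpha,d_beta delta15N of the alpha and beta site (permil).
#' @return List with components `sp` and `bulk` (permil), vectorized.
#' @export
#' @examples
#' site_preference(0.48, 2.15)  # USGS 51: SP -1.67, bulk 1.315
site_preference <- function(d_alpha, d_beta) {
  if (any(!is.finite(d_alpha)) || any(!is.finite(d_beta)))
    stop(errorCondition("site deltas must be finite",
                        class = c("n2osip_domain_error", "error")))
  list(sp = d_alpha - d_beta, bulk = (d_alpha + d_beta) / 2)
}

#' Convert between delta values and 15N atom fractions
#'
#' Tracer work at 2 at\% 15N sits far outside the linear range of delta
#' notation, so mass balance is done on atom fractions:
#' R = r_standard * (1 + delta/1000), x = R / (1 + R). Exact inverses.
#'
#' @param delta delta15N (permil), > -1000.
#' @param x Atom fraction in (0, 1).
#' @param r_standard Reference 15N/14N ratio (default AIR, 0.0036765).
#' @return Atom fraction, or delta in permil.
#' @export
#' @examples
#' delta_to_atom_fraction(0)          # 0.0036630 (natural abundance)
#' atom_fraction_to_delta(0.02)       # ~4551 permil (2 at% label)
delta_to_atom_fraction <- function(delta, r_standard = R15_AIR) {
  r <- delta_to_ratio(delta, r_standard)
  r / (1 + r)
}

#' @rdname delta_to_atom_fraction
#' @export
atom_fraction_to_delta <- function(x, r_standard = R15_AIR) {
  if (any(x <= 0) || any(x >= 1))
    stop(errorCondition("atom fraction must lie in (0, 1)",
                        class = c("n2osip_domain_error", "error")))
  ratio_to_delta(x / (1 - x), r_standard)
}

#' Two-pool tracer mixing mass balance
#'
#' Fraction of N in a mixture that derives from an enriched tracer pool,
#' from 15N atom fractions: f = (x_mix - x_native) / (x_tracer -
#' x_native). Values slightly outside [0, 1] (instrument noise) are
#' clipped; violations beyond `tol` are clipped too but flagged.
#'
#' @param x_mix,x_native,x_tracer 15N atom fractions of the mixture, the
#'   natural-abundance pool and the tracer pool.
#' @param tol Tolerance before the out-of-bounds flag is raised
#'   (absolute, on f; default 0.02).
#' @return List with `f` (clipped to [0, 1]) and `out_of_bounds` flag.
#' @export
tracer_fraction <- function(x_mix, x_native, x_tracer, tol = 0.02) {
  if (abs(x_tracer - x_native) < 1e-12)
    stop(errorCondition("tracer and native pools are indistinguishable",
                        class = c("n2osip_domain_error", "error")))
  f_raw <- (x_mix - x_native) / (x_tracer - x_native)
  list(f = pmin(pmax(f_raw, 0), 1),
       out_of_bounds = f_raw < -tol | f_raw > 1 + tol)
}

#' Construct an isotopocule reading
#'
#' Holds one sample's per-isotopocule ratios and derived deltas. The two
#' defining identities — SP = delta15N_alpha - delta15N_beta and
#' delta15N_bulk = (alpha + beta)/2 — are recomputed from the site deltas,
#' never stored independently, so they hold by construction.
#'
#' @param n2o_ppb N2O mole fraction (ppb).
#' @param d15n_alpha,d15n_beta,d18o Deltas (permil).
#' @param co2_ppm Optional CO2 (ppm).
#' @param r15_std,r18_std Reference ratios used to populate the raw
#'   isotopocule ratios.
#' @return Object of class `isotopocule_reading`: a list with the deltas,
#'   `sp`, `d15n_bulk`, and ratios `r_alpha`, `r_beta`, `r_18`.
#' @export
isotopocule_reading <- function(n2o_ppb, d15n_alpha, d15n_beta, d18o,
                                co2_ppm = NA_real_,
                                r15_std = R15_AIR, r18_std = R18_VSMOW) {
  spb <- site_preference(d15n_alpha, d15n_beta)
  structure(
    list(n2o_ppb = n2o_ppb,
         d15n_alpha = d15n_alpha, d15n_beta = d15n_beta, d18o = d18o,
         sp = spb$sp, d15n_bulk = spb$bulk, co2_ppm = co2_ppm,
         r_alpha = delta_to_ratio(d15n_alpha, r15_std),
         r_beta = delta_to_ratio(d15n_beta, r15_std),
         r_18 = delta_to_ratio(d18o, r18_std)),
    class = "isotopocule_reading")
}

#' @export
print.isotopocule_reading <- function(x, ...) {
  cat(sprintf(
    "<isotopocule_reading> N2O %.0f ppb: SP %.2f, d15N_bulk %.2f, d18O %.2f permil\n",
    x$n2o_ppb[1], x$sp[1], x$d15n_bulk[1], x$d18o[1]))
  invisible(x)
}

#' Readings as a data.frame
#'
#' @param readings A list of `isotopocule_reading` objects (or one).
#' @return data.frame with one row per reading.
#' @export
readings_to_table <- function(readings) {
  if (inherits(readings, "isotopocule_reading")) readings <- list(readings)
  do.call(rbind, lapply(readings, function(r)
    data.frame(n2o_ppb = r$n2o_ppb, d15n_alpha = r$d15n_alpha,
               d15n_beta = r$d15n_beta, d18o = r$d18o, sp = r$sp,
               d15n_bulk = r$d15n_bulk, co2_ppm = r$co2_ppm)))
}
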