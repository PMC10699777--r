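# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Ideal-gas flux conversion, written out step by step.
oracle_flux <- function(slope_ppb_s, vol_l, area_m2, temp_k, press_kpa) {
  n_air_mol <- (press_kpa * 1000) * (vol_l / 1000) / (8.314462618 * temp_k)
  mol_n2o_per_s <- slope_ppb_s * 1e-9 * n_air_mol
  g_n_per_s <- mol_n2o_per_s * 28.014
  g_n_per_s * 1e9 / area_m2
}

# Brute-force episode splitter: walk the sorted times, cut at gaps.
oracle_split_lengths <- function(times, threshold) {
  times <- sort(times)
  lens <- integer(0)
  cur <- 1
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[i - 1] > threshold) {
      lens <- c(lens, cur)
      cur <- 0
    }
    cur <- cur + 1
  }
  c(lens, cur)
}

# Trapezoidal quadrature, independent of summarize_pulse.
oracle_trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

default_geom <- function() {
  list(collar_diameter_m = 0.2, system_volume_l = 10,
       temperature_k = 313.15, pressure_kpa = 101.325)
}

# Synthetic calibration instrument: measured = b0 + b1*true + b2/C + b3*CO2.
make_calibration_runs <- function(standards, coefs,
                                  n2o_ppm = c(0.5, 1, 2, 4),
                                  co2_ppm = c(330, 660, 990)) {
  grid <- expand.grid(standard = names(standards), n2o_ppm = n2o_ppm,
                      co2_ppm = co2_ppm, stringsAsFactors = FALSE)
  for (ch in c("d15n_alpha", "d15n_beta", "d18o")) {
    b <- coefs[[ch]]
    true <- vapply(grid$standard, function(s) standards[[s]][[ch]], 0)
    grid[[ch]] <- b[1] + b[2] * true + b[3] / grid$n2o_ppm +
      b[4] * grid$co2_ppm
  }
  grid
}
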