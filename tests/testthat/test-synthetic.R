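geom <- default_geom()
cfg <- default_config()

test_that("noiseless closures invert to the generating flux exactly", {
  scn <- pulse_scenario(baseline = 2, peak = 150, noise_sd_ppb = 0,
                        duration_h = 4, seed = 3)
  series <- gen_chamber_series(scn, geom)
  for (s in series) {
    e <- fit_flux(s, deadband_s = 30, alpha = 0.05)
    expect_equal(e$flux, attr(s, "true_flux"), tolerance = 1e-9)
  }
})

test_that("the strongest observed pulse is reproduced at its peak", {
  # peak parameter 414 ng N m-2 s-1 with near-zero baseline; closures
  # every 30 min from 15 min catch the peak at 45 min exactly
  scn <- pulse_scenario(baseline = 0, peak = 414, t_peak_min = 45,
                        noise_sd_ppb = 0, seed = 1)
  series <- gen_chamber_series(scn, geom)
  fluxes <- vapply(series, function(s) fit_flux(s)$flux, 0)
  expect_equal(max(fluxes), 414, tolerance = 1e-6)
  scn_noisy <- pulse_scenario(baseline = 0, peak = 414, seed = 2)
  noisy <- vapply(gen_chamber_series(scn_noisy, geom),
                  function(s) fit_flux(s)$flux, 0)
  expect_equal(max(noisy), 414, tolerance = 0.02)
})

test_that("generators are deterministic under a fixed seed", {
  a <- gen_chamber_series(pulse_scenario(seed = 7, duration_h = 2), geom)
  b <- gen_chamber_series(pulse_scenario(seed = 7, duration_h = 2), geom)
  expect_identical(a, b)
  ka <- gen_keeling_series(50, 330, 0, c(100, 500, 900), noise_sd = 1,
                           seed = 9)
  kb <- gen_keeling_series(50, 330, 0, c(100, 500, 900), noise_sd = 1,
                           seed = 9)
  expect_identical(ka, kb)
  pa <- gen_qpcr_plate(qpcr_scenario(seed = 5))
  pb <- gen_qpcr_plate(qpcr_scenario(seed = 5))
  expect_identical(pa, pb)
  ma <- gen_isotopocule_samples(mixture_scenario(seed = 4), cfg)
  mb <- gen_isotopocule_samples(mixture_scenario(seed = 4), cfg)
  expect_identical(ma, mb)
})

test_that("keeling generator obeys the hand mass balance", {
  s <- gen_keeling_series(source_delta = 50, ambient_ppb = 330,
                          ambient_delta = 0,
                          added_ppb_grid = c(330, 990), noise_sd = 0,
                          seed = 1)
  expect_equal(s$n2o_ppb, c(660, 1320))
  expect_equal(s$d15n, c(25, 37.5), tolerance = 1e-12)
  expect_error(gen_keeling_series(50, 330, 0, c(500, 500)),
               class = "n2osip_degenerate_design_error")
  expect_error(gen_keeling_series(50, 330, 0, c(-5, 100)),
               class = "n2osip_domain_error")
})

test_that("atom-fraction mixing differs from delta mixing only at tracer strength", {
  g <- seq(100, 1000, by = 100)
  lin <- gen_keeling_series(30, 330, 0, g, seed = 1)
  atom <- gen_keeling_series(30, 330, 0, g, seed = 1, mixing = "atom")
  expect_equal(atom$d15n, lin$d15n, tolerance = 1e-3)   # natural abundance
  lin2 <- gen_keeling_series(4551, 330, 0, g, seed = 1)
  atom2 <- gen_keeling_series(4551, 330, 0, g, seed = 1, mixing = "atom")
  expect_gt(max(abs(atom2$d15n - lin2$d15n)), 1)        # 2 at% tracer
})

test_that("mixture samples land on the shifted endmember point", {
  # single process, no reduction, no noise: identity
  scn <- mixture_scenario(fractions = c(bacterial_denitrification = 1),
                          f_rem = 1, noise_sd = 0, n = 3, seed = 2)
  out <- gen_isotopocule_samples(scn, cfg)
  pt <- attr(out, "process_points")[, "bacterial_denitrification"]
  for (rd in out) {
    expect_equal(rd$sp, unname(pt["sp"]), tolerance = 1e-9)
    expect_equal(rd$d15n_bulk, unname(pt["d15n"]), tolerance = 1e-9)
    expect_equal(rd$d18o, unname(pt["d18o"]), tolerance = 1e-9)
  }
  # SP within the bacterial-denitrification range (-7.5 to 3.7 permil)
  expect_gte(out[[1]]$sp, -7.5)
  expect_lte(out[[1]]$sp, 3.7)
  # reduction overprint follows delta0 + eps * ln(f)
  scn2 <- mixture_scenario(f_rem = 0.0855, noise_sd = 0, n = 1, seed = 2)
  out2 <- gen_isotopocule_samples(scn2, cfg)
  expect_equal(out2[[1]]$sp, unname(pt["sp"]) + (-6) * log(0.0855),
               tolerance = 1e-9)
  expect_error(mixture_scenario(f_rem = 0),
               class = "n2osip_domain_error")
  expect_error(
    gen_isotopocule_samples(
      mixture_scenario(fractions = c(martian_denitrification = 1)), cfg),
    class = "n2osip_config_error")
})

test_that("mixture fractions weight the process points linearly", {
  scn <- mixture_scenario(
    fractions = c(bacterial_denitrification = 0.25,
                  fungal_denitrification = 0.75),
    f_rem = 1, noise_sd = 0, n = 1, seed = 6)
  out <- gen_isotopocule_samples(scn, cfg)
  pts <- attr(out, "process_points")
  expect_equal(out[[1]]$sp,
               unname(0.25 * pts["sp", 1] + 0.75 * pts["sp", 2]),
               tolerance = 1e-9)
})

test_that("qPCR plates follow the log-linear cycle model", {
  # perfect doubling: 10x dilution spaces Cq by 1/log10(2) = 3.3219
  scn <- qpcr_scenario(efficiency = 1, cq_noise_sd = 0, seed = 1)
  plate <- gen_qpcr_plate(scn)
  std <- plate[plate$role == "standard", ]
  cq_by_level <- tapply(std$cq, std$input_copies, mean)
  expect_equal(as.numeric(diff(rev(cq_by_level))), rep(3.321928, 5),
               tolerance = 1e-6)
  # noiseless plate inverts to the generating efficiency
  curve <- fit_standard_curve(std$input_copies, std$cq)
  expect_equal(curve$efficiency, 1, tolerance = 1e-9)
  expect_equal(curve$r2, 1)
  # slope for a 65% efficient assay: -1/log10(1.65)
  scn65 <- qpcr_scenario(efficiency = 0.65, cq_noise_sd = 0, seed = 1)
  std65 <- gen_qpcr_plate(scn65)
  std65 <- std65[std65$role == "standard", ]
  c65 <- fit_standard_curve(std65$input_copies, std65$cq)
  expect_equal(c65$slope, -1 / log10(1.65), tolerance = 1e-9)
  expect_equal(round(c65$slope, 3), -4.598)
  expect_error(qpcr_scenario(standard_copies = c(10, 100)),
               class = "n2osip_domain_error")
})
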