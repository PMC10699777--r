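cfg <- default_config()
rp <- cfg$rayleigh

test_that("substrate correction is a pure translation of the boxes", {
  em <- build_endmembers(cfg$endmembers, cfg$substrates)
  raw <- cfg$endmembers$bacterial_denitrification
  cor <- em$bacterial_denitrification
  expect_equal(cor$d18o, raw$d18o - 9)        # water at -9 permil
  expect_equal(cor$d15n, raw$d15n + 7.2)      # NO3- at +7.2 permil
  expect_equal(cor$sp, raw$sp)                # SP never shifted
  for (nm in names(em)) {
    for (ax in c("sp", "d15n", "d18o"))
      expect_equal(diff(em[[nm]][[ax]]), diff(cfg$endmembers[[nm]][[ax]]))
  }
})

test_that("zero substrate signatures leave the boxes unchanged", {
  em0 <- build_endmembers(cfg$endmembers,
                          list(d18o_h2o = 0, d15n_no3 = 0, d15n_nh4 = 0))
  for (nm in names(em0))
    for (ax in c("sp", "d15n", "d18o"))
      expect_equal(em0[[nm]][[ax]], cfg$endmembers[[nm]][[ax]])
})

test_that("a declared but missing substrate is a config error", {
  expect_error(build_endmembers(cfg$endmembers, list(d18o_h2o = -9)),
               "d15n_", class = "n2osip_config_error")
})

test_that("Rayleigh shift: identity at f=1, closed form, open limit", {
  start <- c(sp = -1.9, d15n = 5, d18o = 20)
  expect_equal(rayleigh_shift(start, rp, 1), start)
  # closed form evaluated independently: delta0 + eps * ln f
  shifted <- rayleigh_shift(start, rp, 0.0855)
  expect_equal(unname(shifted["sp"]), -1.9 + (-6) * log(0.0855),
               tolerance = 1e-12)
  expect_equal(round(unname(shifted["sp"]), 2), 12.86)
  # open system is bounded: as f -> 0 the shift tends to -eps
  open <- list(eps_sp = -6, eps_15 = -7, eps_18 = -15, mode = "open")
  near0 <- rayleigh_shift(start, open, 1e-12)
  expect_equal(unname(near0["sp"]), -1.9 + 6, tolerance = 1e-6)
  expect_error(rayleigh_shift(start, rp, 0), class = "n2osip_domain_error")
})

test_that("rayleigh_shift and invert_f_remaining are exact inverses", {
  f_grid <- exp(seq(log(0.001), 0, length.out = 41))
  start <- c(sp = -1.9, d15n = 5, d18o = 20)
  for (mode in c("closed", "open")) {
    p <- rp; p$mode <- mode
    shifted <- rayleigh_shift(start, p, f_grid)
    f_back <- invert_f_remaining(shifted[, "sp"], start["sp"], p$eps_sp,
                                 mode)$f
    expect_equal(unname(f_back), f_grid, tolerance = 1e-12)
  }
  # the documented worked inversion
  expect_equal(round(invert_f_remaining(12.8, -1.9, -6, "closed")$f, 4),
               0.0863)
  expect_equal(invert_f_remaining(5, 5, -6, "closed")$f, 1)
  # measurement lighter than start: clipped and flagged, not an error
  inc <- invert_f_remaining(-10, 5, -6, "closed")
  expect_equal(inc$f, 1)
  expect_true(inc$out_of_bounds)
})

test_that("classification: in-box points, exact corners, reduction overprint", {
  em <- build_endmembers(cfg$endmembers, cfg$substrates)
  bd <- em$bacterial_denitrification
  inside <- c(sp = mean(bd$sp), d15n = mean(bd$d15n), d18o = mean(bd$d18o))
  cl <- classify_point(inside, em, rp)
  expect_equal(cl$process, "bacterial_denitrification")
  expect_equal(cl$f_rem, 1)
  expect_equal(cl$residual, 0, tolerance = 1e-9)
  expect_true(all(cl$membership["bacterial_denitrification", ]))

  fd <- em$fungal_denitrification
  corner <- c(sp = fd$sp[1], d15n = fd$d15n[1], d18o = fd$d18o[1])
  cl2 <- classify_point(corner, em, rp, f_grid = 1)
  expect_equal(cl2$process, "fungal_denitrification")
  expect_equal(cl2$residual, 0, tolerance = 1e-9)

  # a strongly reduced bacterial-denitrification product: SP driven from
  # -1.9 up to ~12.8 permil sits in no box but on the bD trajectory
  start <- c(sp = -1.9, d15n = mean(bd$d15n), d18o = mean(bd$d18o))
  reading <- rayleigh_shift(start, rp, 0.086)
  cl3 <- classify_point(reading, em, rp)
  expect_equal(cl3$process, "bacterial_denitrification")
  expect_lt(cl3$f_rem, 1)
  expect_false(any(cl3$membership[, "sp"] & cl3$membership[, "d15n"] &
                     cl3$membership[, "d18o"]))
})

test_that("classification uses only the available axes", {
  em <- build_endmembers(cfg$endmembers, cfg$substrates)
  bd <- em$bacterial_denitrification
  cl <- classify_point(c(sp = mean(bd$sp), d15n = NA, d18o = NA), em, rp)
  expect_equal(cl$axes_used, "sp")
  expect_error(classify_point(c(sp = NA, d15n = NA, d18o = NA), em, rp),
               class = "n2osip_insufficient_data_error")
})

test_that("uncertainty collapses for zero-width boxes and is seeded", {
  em <- build_endmembers(cfg$endmembers, cfg$substrates)
  bd <- em$bacterial_denitrification
  pt <- c(sp = mean(bd$sp), d15n = mean(bd$d15n), d18o = mean(bd$d18o))
  degen <- list(bacterial_denitrification = list(
    sp = rep(pt["sp"], 2), d15n = rep(pt["d15n"], 2),
    d18o = rep(pt["d18o"], 2)))
  reading <- rayleigh_shift(pt, rp, 0.3)
  u <- partition_uncertainty(reading, degen, rp, n_draws = 20, seed = 5)
  cl <- classify_point(reading, degen, rp)
  expect_true(all(abs(u$f_rem_quantiles - cl$f_rem) < 1e-9))
  expect_equal(unname(u$process_weights), 1)
  u2 <- partition_uncertainty(reading, degen, rp, n_draws = 20, seed = 5)
  expect_identical(u$f_rem_quantiles, u2$f_rem_quantiles)
})

test_that("uncertainty intervals cover the generating f_rem", {
  # coverage simulation: readings from a known (process, f_rem) with
  # 2 permil noise; the 90% interval over box/epsilon draws should cover
  # the truth in most replicates
  em <- build_endmembers(cfg$endmembers, cfg$substrates)
  bd <- em["bacterial_denitrification"]
  p <- rp
  set.seed(99)
  hits <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    truth <- c(sp = runif(1, bd[[1]]$sp[1], bd[[1]]$sp[2]),
               d15n = runif(1, bd[[1]]$d15n[1], bd[[1]]$d15n[2]),
               d18o = runif(1, bd[[1]]$d18o[1], bd[[1]]$d18o[2]))
    f_true <- runif(1, 0.1, 0.9)
    reading <- rayleigh_shift(truth, p, f_true) + rnorm(3, sd = 2)
    u <- partition_uncertainty(reading, bd, p, n_draws = 60,
                               seed = 1000 + i,
                               f_grid = exp(seq(log(0.01), 0,
                                                length.out = 100)))
    q <- u$f_rem_quantiles
    hits <- hits + (f_true >= q[1] && f_true <= q[3])
  }
  expect_gte(hits / n_rep, 0.85)
})
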