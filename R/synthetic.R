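# Seeded evaluation that leaves the caller's RNG state untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  expr
}

#' Rewetting pulse shape
#'
#' Flux trajectory after wetting a dry soil: linear rise from the
#' baseline to the peak over `t_peak_min`, then exponential decay back
#' towards the baseline with time constant `tau_min`. With the defaults
#' (peak at 45 min, tau 60 min) emissions peak within the first hour and
#' are back near baseline within ~4 hours, the canonical dryland pulse.
#' The shape is a named, swappable function — pass an alternative via
#' `shape` in [gen_chamber_series()].
#'
#' @param t_min Minutes since wetting (vectorized).
#' @param baseline,peak Flux levels (ng N m^-2 s^-1), peak >= baseline.
#' @param t_peak_min Time to peak (min).
#' @param tau_min Decay time constant (min).
#' @return Flux (ng N m^-2 s^-1).
#' @export
pulse_flux <- function(t_min, baseline, peak, t_peak_min, tau_min) {
  rise <- pmin(pmax(t_min, 0) / t_peak_min, 1)
  decay <- exp(-pmax(t_min - t_peak_min, 0) / tau_min)
  baseline + (peak - baseline) * rise * decay
}

#' Pulse emission scenario
#'
#' Parameters of a synthetic rewetting experiment. Defaults describe the
#' strongest observed pulses: a 414 ng N m^-2 s^-1 peak over a ~1 ng
#' baseline, peak at 45 min, decay constant 60 min, closures of 120 s at
#' 1 Hz every 30 min starting 15 min after wetting, over 24 h, with
#' 0.3 ppb 1-s instrument noise on a 330 ppb ambient background.
#'
#' @param baseline,peak Flux (ng N m^-2 s^-1), `peak >= baseline >= 0`.
#' @param t_peak_min,tau_min Pulse timing (min), `tau_min > 0`.
#' @param interval_min Closure spacing (min).
#' @param closure_len_s Closure length (s).
#' @param start_min First closure (min after wetting).
#' @param duration_h Schedule length (h).
#' @param cadence_s Sampling cadence within a closure (s).
#' @param noise_sd_ppb 1-s concentration noise sd (ppb), >= 0.
#' @param ambient_ppb Ambient N2O (ppb).
#' @param seed Integer seed.
#' @return List of class `pulse_scenario`.
#' @export
pulse_scenario <- function(baseline = 1, peak = 414, t_peak_min = 45,
                           tau_min = 60, interval_min = 30,
                           closure_len_s = 120, start_min = 15,
                           duration_h = 24, cadence_s = 1,
                           noise_sd_ppb = 0.3, ambient_ppb = 330,
                           seed = 1L) {
  if (!(peak >= baseline && baseline >= 0))
    stop(errorCondition("need peak >= baseline >= 0",
                        class = c("n2osip_domain_error", "error")))
  if (tau_min <= 0 || noise_sd_ppb < 0)
    stop(errorCondition("tau_min must be > 0 and noise sd >= 0",
                        class = c("n2osip_domain_error", "error")))
  structure(as.list(environment()), class = "pulse_scenario")
}

#' Generate chamber closures from a pulse scenario
#'
#' For each scheduled closure the true flux (from [pulse_flux()] at the
#' closure start) is converted to a concentration slope by inverting
#' [convert_flux_units()] for the supplied geometry; the closure trace is
#' ambient + slope * t plus iid Gaussian noise. With zero noise the
#' least-squares slope of every closure reproduces the generating flux
#' exactly.
#'
#' @param scn A [pulse_scenario()].
#' @param geom Chamber geometry (as in `default_config()$chamber_geometry`).
#' @param chamber_id Chamber label.
#' @return List of [chamber_series()], one per closure, each with
#'   attributes `true_flux` (ng N m^-2 s^-1) and `closure_start_min`.
#' @export
gen_chamber_series <- function(scn, geom = default_config()$chamber_geometry,
                               chamber_id = "C1") {
  stopifnot(inherits(scn, "pulse_scenario"))
  starts <- seq(scn$start_min, scn$duration_h * 60, by = scn$interval_min)
  conv <- convert_flux_units(1, geom)   # flux per unit slope
  with_seed(scn$seed, {
    out <- vector("list", length(starts))
    for (i in seq_along(starts)) {
      flux <- pulse_flux(starts[i], scn$baseline, scn$peak,
                         scn$t_peak_min, scn$tau_min)
      slope <- flux / conv
      t <- seq(0, scn$closure_len_s, by = scn$cadence_s)
      conc <- scn$ambient_ppb + slope * t +
        stats::rnorm(length(t), sd = scn$noise_sd_ppb)
      s <- chamber_series(chamber_id, t, conc, geometry = geom)
      attr(s, "true_flux") <- flux
      attr(s, "closure_start_min") <- starts[i]
      out[[i]] <- s
    }
    out
  })
}

#' Isotopocule mixture scenario
#'
#' A mixture of process endmembers overprinted by partial N2O reduction.
#' Each named process contributes a fixed fraction; its true point
#' (SP, delta15N_bulk, delta18O) is drawn once, uniformly inside its
#' substrate-corrected endmember box. The fraction-weighted mean point is
#' then shifted along the Rayleigh reduction trajectory at `f_rem`, and
#' each of `n` samples adds iid Gaussian noise per delta axis. The
#' defaults describe the laboratory incubations the package models: six
#' mesocosms, pure bacterial denitrification, strong reduction
#' (f_rem ~ 0.086, which carries an SP of ~-1.9 up to ~12.8 permil under
#' the default eps_SP = -6), and 2 permil analytical noise.
#'
#' @param fractions Named nonnegative fractions summing to 1; names must
#'   be endmember processes.
#' @param f_rem Fraction of N2O remaining after reduction, in (0, 1].
#' @param noise_sd Per-delta analytical noise sd (permil).
#' @param n Number of samples (mesocosms).
#' @param n2o_ppb Sample N2O mole fraction(s) (ppb), recycled to n.
#' @param seed Integer seed.
#' @return List of class `mixture_scenario`.
#' @export
mixture_scenario <- function(fractions = c(bacterial_denitrification = 1),
                             f_rem = 0.086, noise_sd = 2, n = 6,
                             n2o_ppb = 2000, seed = 1L) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop(errorCondition("fractions must be >= 0 and sum to 1",
                        class = c("n2osip_domain_error", "error")))
  if (f_rem <= 0 || f_rem > 1)
    stop(errorCondition("f_rem must lie in (0, 1]",
                        class = c("n2osip_domain_error", "error")))
  structure(as.list(environment()), class = "mixture_scenario")
}

#' Generate isotopocule readings from a mixture scenario
#'
#' @param scn A [mixture_scenario()].
#' @param cfg A `run_config` supplying endmember boxes, substrates and
#'   Rayleigh parameters. Boxes are substrate-corrected internally via
#'   [build_endmembers()].
#' @return List of [isotopocule_reading()]s with attributes
#'   `process_points` (drawn true endmember points), `true_mix`
#'   (pre-reduction mixture point) and `true_shifted` (post-reduction,
#'   pre-noise point).
#' @export
gen_isotopocule_samples <- function(scn, cfg = default_config()) {
  stopifnot(inherits(scn, "mixture_scenario"))
  if (scn$f_rem <= 0)
    stop(errorCondition("f_rem = 0: log undefined",
                        class = c("n2osip_domain_error", "error")))
  boxes <- build_endmembers(cfg$endmembers, cfg$substrates)
  missing <- setdiff(names(scn$fractions), names(boxes))
  if (length(missing))
    stop(errorCondition(
      sprintf("process(es) not in endmember definitions: %s",
              paste(missing, collapse = ", ")),
      class = c("n2osip_config_error", "error")))
  with_seed(scn$seed, {
    pts <- sapply(names(scn$fractions), function(nm) {
      b <- boxes[[nm]]
      c(sp = stats::runif(1, b$sp[1], b$sp[2]),
        d15n = stats::runif(1, b$d15n[1], b$d15n[2]),
        d18o = stats::runif(1, b$d18o[1], b$d18o[2]))
    })
    true_mix <- drop(pts %*% scn$fractions)  # linear mixing in delta/SP
    shifted <- rayleigh_shift(true_mix, cfg$rayleigh, scn$f_rem)
    n2o <- rep_len(scn$n2o_ppb, scn$n)
    out <- vector("list", scn$n)
    for (i in seq_len(scn$n)) {
      sp <- shifted["sp"] + stats::rnorm(1, sd = scn$noise_sd)
      bulk <- shifted["d15n"] + stats::rnorm(1, sd = scn$noise_sd)
      d18o <- shifted["d18o"] + stats::rnorm(1, sd = scn$noise_sd)
      out[[i]] <- isotopocule_reading(
        n2o_ppb = n2o[i],
        d15n_alpha = unname(bulk + sp / 2),
        d15n_beta = unname(bulk - sp / 2),
        d18o = unname(d18o))
    }
    attr(out, "process_points") <- pts
    attr(out, "true_mix") <- true_mix
    attr(out, "true_shifted") <- shifted
    out
  })
}

#' Generate a two-source Keeling mixing series
#'
#' A fixed-composition soil source accumulates over an ambient
#' background: at each grid point the total concentration is ambient +
#' added, and the mixture delta is the concentration-weighted mean of the
#' ambient and source deltas (`mixing = "delta"`, exact for the Keeling
#' model) or the exact atom-fraction mass balance (`mixing = "atom"`,
#' preferred for enriched-tracer sources above ~1 at\%). With zero noise
#' and delta mixing, [keeling_fit()] on the output recovers the source
#' delta to numerical precision.
#'
#' @param source_delta Source delta15N (permil).
#' @param ambient_ppb,ambient_delta Background concentration (ppb) and
#'   delta (permil).
#' @param added_ppb_grid Source-derived N2O added at each point (ppb,
#'   all > 0, at least 2 distinct totals).
#' @param noise_sd Delta noise sd (permil).
#' @param seed Integer seed.
#' @param mixing `"delta"` (linear in delta) or `"atom"` (exact atom
#'   fraction).
#' @return A [chamber_series()] whose `d15n` stream holds the mixture
#'   deltas and `n2o_ppb` the total concentrations; attribute
#'   `true_deltas` carries the noise-free mixture deltas.
#' @export
gen_keeling_series <- function(source_delta, ambient_ppb, ambient_delta,
                               added_ppb_grid, noise_sd = 0, seed = 1L,
                               mixing = c("delta", "atom")) {
  mixing <- match.arg(mixing)
  if (any(added_ppb_grid <= 0))
    stop(errorCondition("added concentrations must be positive",
                        class = c("n2osip_domain_error", "error")))
  total <- ambient_ppb + added_ppb_grid
  if (length(unique(total)) < 2)
    stop(errorCondition("need >= 2 distinct total concentrations",
                        class = c("n2osip_degenerate_design_error", "error")))
  if (mixing == "delta") {
    d_true <- (ambient_ppb * ambient_delta +
                 added_ppb_grid * source_delta) / total
  } else {
    x_amb <- delta_to_atom_fraction(ambient_delta)
    x_src <- delta_to_atom_fraction(source_delta)
    x_mix <- (ambient_ppb * x_amb + added_ppb_grid * x_src) / total
    d_true <- atom_fraction_to_delta(x_mix)
  }
  d <- with_seed(seed,
                 d_true + stats::rnorm(length(d_true), sd = noise_sd))
  s <- chamber_series("keeling", seq_along(total) - 1, total, d15n = d)
  attr(s, "true_deltas") <- d_true
  s
}

#' qPCR plate scenario
#'
#' Standards follow Cq = cq_ref - log10(copies / ref_copies) /
#' log10(1 + efficiency) plus Gaussian cycle noise; unknowns are
#' generated from their true copy numbers the same way. Defaults: a
#' six-level 10x serial dilution from 1e7 copies run in triplicate at
#' 66\% efficiency, 0.15-cycle noise, and one unknown whose 4.27e5
#' copies per reaction correspond to ~7.1e7 copies per gram of soil
#' under a typical extraction (0.5 g soil, 100 uL elution, 1.2 uL
#' template).
#'
#' @param standard_copies Strictly decreasing dilution series (copies
#'   per reaction).
#' @param efficiency Amplification efficiency in (0, 1].
#' @param cq_ref Cq at `ref_copies`.
#' @param ref_copies Reference copy number for `cq_ref`.
#' @param replicates Technical replicates per level (default 3).
#' @param cq_noise_sd Cycle noise sd.
#' @param unknown_copies Named or unnamed true copies per reaction of
#'   unknown samples.
#' @param seed Integer seed.
#' @return List of class `qpcr_scenario`.
#' @export
qpcr_scenario <- function(standard_copies = 10^(7:2), efficiency = 0.66,
                          cq_ref = 12, ref_copies = 1e7, replicates = 3,
                          cq_noise_sd = 0.15,
                          unknown_copies = c(unknown1 = 4.27e5),
                          seed = 1L) {
  if (any(diff(standard_copies) >= 0))
    stop(errorCondition("standard dilution must be strictly decreasing",
                        class = c("n2osip_domain_error", "error")))
  if (efficiency <= 0 || efficiency > 1)
    stop(errorCondition("efficiency must lie in (0, 1]",
                        class = c("n2osip_domain_error", "error")))
  structure(as.list(environment()), class = "qpcr_scenario")
}

#' Generate a qPCR results table from a scenario
#'
#' @param scn A [qpcr_scenario()].
#' @param target Target label (default `"narG"`).
#' @return data.frame with columns `well`, `target`, `sample`, `role`
#'   (`standard`/`unknown`/`ntc`), `input_copies` (NA for non-standards)
#'   and `cq` (NA for NTCs).
#' @export
gen_qpcr_plate <- function(scn, target = "narG") {
  stopifnot(inherits(scn, "qpcr_scenario"))
  true_cq <- function(copies)
    scn$cq_ref - log10(copies / scn$ref_copies) / log10(1 + scn$efficiency)
  with_seed(scn$seed, {
    rows <- list()
    for (i in seq_along(scn$standard_copies)) {
      cps <- scn$standard_copies[i]
      for (r in seq_len(scn$replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample = sprintf("std_%d", i), role = "standard",
          input_copies = cps,
          cq = true_cq(cps) + stats::rnorm(1, sd = scn$cq_noise_sd))
      }
    }
    unk_names <- names(scn$unknown_copies) %||%
      sprintf("unknown%d", seq_along(scn$unknown_copies))
    for (i in seq_along(scn$unknown_copies)) {
      for (r in seq_len(scn$replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample = unk_names[i], role = "unknown", input_copies = NA_real_,
          cq = true_cq(scn$unknown_copies[i]) +
            stats::rnorm(1, sd = scn$cq_noise_sd))
      }
    }
    for (r in seq_len(scn$replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = "ntc", role = "ntc", input_copies = NA_real_,
        cq = NA_real_)
    }
    plate <- do.call(rbind, rows)
    plate <- cbind(well = sprintf("W%02d", seq_len(nrow(plate))),
                   target = target, plate)
    rownames(plate) <- NULL
    plate
  })
}
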