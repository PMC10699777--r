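#' Default run configuration
#'
#' Builds the configuration object consumed by every pipeline stage. The
#' defaults encode the study conditions the package ships with:
#' \itemize{
#'   \item chamber geometry: 20 cm collar diameter, 10 L recirculating
#'     system volume (chamber + ~6 L sample loop), 313.15 K (a 40 degree C
#'     soil surface), 101.325 kPa;
#'   \item flux window: 30 s deadband then the last 90 s of a 120 s
#'     closure, slope gated to zero at alpha = 0.05;
#'   \item tracer: label at 2 at\% 15N, natural abundance at the AIR ratio
#'     (atom fraction 0.0036630);
#'   \item substrates: deionized irrigation water at -9 permil
#'     delta18O-H2O; soil NO3-/NO2- at +7.2 permil delta15N; NH4+ at 0;
#'   \item Rayleigh net isotope effects of N2O -> N2 reduction:
#'     eps_SP = -6, eps15 = -7, eps18 = -15 permil, closed system. The
#'     effects are literature-informed defaults, not measurements — review
#'     them before interpreting real data;
#'   \item reference standards: USGS 51 and USGS 52 certified values;
#'   \item endmember boxes for nitrification, nitrifier denitrification,
#'     bacterial denitrification, fungal denitrification and
#'     chemodenitrification, expressed substrate-relative (delta15N) and
#'     water-relative (delta18O) so [build_endmembers()] can translate
#'     them onto the measurement scale.
#' }
#'
#' @return A nested list of class `run_config`, already validated.
#' @seealso [read_run_config()], [validate_config()]
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$standards$USGS51$sp  # -1.67 permil
default_config <- function() {
  cfg <- list(
    chamber_geometry = list(
      collar_diameter_m = 0.20,
      system_volume_l = 10,
      temperature_k = 313.15,
      pressure_kpa = 101.325
    ),
    flux_window = list(
      deadband_s = 30,
      fit_span_s = 90,
      alpha = 0.05
    ),
    io = list(
      episode_split_s = 120
    ),
    tracer = list(
      atom_fraction_label = 0.02,
      atom_fraction_natural = R15_AIR / (1 + R15_AIR)
    ),
    substrates = list(
      d18o_h2o = -9,
      d15n_no3 = 7.2,   # combined NO3-/NO2- signature
      d15n_nh4 = 0
    ),
    rayleigh = list(
      eps_sp = -6,
      eps_15 = -7,
      eps_18 = -15,
      mode = "closed"
    ),
    standards = list(
      USGS51 = list(d15n_bulk = 1.32, d15n_alpha = 0.48, d15n_beta = 2.15,
                    sp = -1.67, d18o = 41.23),
      USGS52 = list(d15n_bulk = 0.44, d15n_alpha = 13.52, d15n_beta = -12.64,
                    sp = 26.15, d18o = 40.64)
    ),
    endmembers = list(
      nitrification = list(
        sp = c(28.8, 36.8), d15n = c(-62.0, -47.0), d18o = c(18.0, 48.0),
        d15n_basis = "nh4", d18o_basis = "water"
      ),
      nitrifier_denitrification = list(
        sp = c(-13.6, 1.9), d15n = c(-56.9, -36.3), d18o = c(-10.0, 7.0),
        d15n_basis = "nh4", d18o_basis = "water"
      ),
      bacterial_denitrification = list(
        sp = c(-7.5, 3.7), d15n = c(-54.2, -10.2), d18o = c(10.6, 23.5),
        d15n_basis = "no3", d18o_basis = "water"
      ),
      fungal_denitrification = list(
        sp = c(27.2, 39.9), d15n = c(-50.5, -19.7), d18o = c(35.5, 50.4),
        d15n_basis = "no3", d18o_basis = "water"
      ),
      chemodenitrification = list(
        sp = c(20.1, 25.7), d15n = c(-35.0, -10.0), d18o = c(20.0, 46.6),
        d15n_basis = "no3", d18o_basis = "water"
      )
    ),
    calibration = list(
      valid_range_ppm = c(0.6, 8)
    ),
    seed = 1L
  )
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Checks the structural invariants every stage relies on: range fields
#' are ordered low <= high, atom fractions lie in (0, 1), temperature,
#' pressure and volumes are positive, the gating level alpha is in (0, 1),
#' the Rayleigh mode is "closed" or "open", and each certified standard's
#' site preference equals alpha minus beta within printed rounding.
#'
#' @param cfg A configuration list (as from [default_config()] or
#'   [read_run_config()]).
#' @return `cfg`, classed `run_config`, invisibly unchanged otherwise.
#'   Throws a classed error (`n2osip_config_error`) naming the violated
#'   invariant.
#' @export
validate_config <- function(cfg) {
  fail <- function(msg) {
    stop(errorCondition(msg, class = c("n2osip_config_error", "error")))
  }
  g <- cfg$chamber_geometry
  if (is.null(g)) fail("config missing 'chamber_geometry'")
  for (f in c("collar_diameter_m", "system_volume_l", "temperature_k",
              "pressure_kpa")) {
    v <- g[[f]]
    if (is.null(v) || !is.numeric(v) || v <= 0)
      fail(sprintf("chamber_geometry$%s must be a positive number", f))
  }
  fw <- cfg$flux_window
  if (is.null(fw$alpha) || fw$alpha <= 0 || fw$alpha >= 1)
    fail("flux_window$alpha must lie in (0, 1)")
  if (fw$deadband_s < 0 || fw$fit_span_s <= 0)
    fail("flux_window deadband/fit span must be nonnegative/positive")
  tr <- cfg$tracer
  for (f in c("atom_fraction_label", "atom_fraction_natural")) {
    v <- tr[[f]]
    if (is.null(v) || v <= 0 || v >= 1)
      fail(sprintf("tracer$%s must lie in (0, 1)", f))
  }
  if (!cfg$rayleigh$mode %in% c("closed", "open"))
    fail("rayleigh$mode must be 'closed' or 'open'")
  for (f in c("eps_sp", "eps_15", "eps_18"))
    if (!is.finite(cfg$rayleigh[[f]]))
      fail(sprintf("rayleigh$%s must be finite", f))
  for (nm in names(cfg$endmembers)) {
    box <- cfg$endmembers[[nm]]
    for (ax in c("sp", "d15n", "d18o")) {
      rng <- box[[ax]]
      if (length(rng) != 2 || rng[1] > rng[2])
        fail(sprintf("endmember '%s' %s range must satisfy low <= high",
                     nm, ax))
    }
  }
  for (nm in names(cfg$standards)) {
    s <- cfg$standards[[nm]]
    if (abs(s$sp - (s$d15n_alpha - s$d15n_beta)) > 0.02)
      fail(sprintf(
        "standard '%s': certified SP differs from alpha - beta by > 0.02",
        nm))
  }
  structure(cfg, class = "run_config")
}

#' Read / write run configuration files
#'
#' Configurations are stored as a single YAML document mirroring the list
#' structure of [default_config()]. Fields absent from the file fall back
#' to the package defaults, so a config file only needs to state what
#' differs from them. `write_run_config()` and `read_run_config()` round
#' trip: a written config parses back to an equal object.
#'
#' @param path Path to a YAML configuration file.
#' @return `read_run_config()`: a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("config file not found: %s", path),
                        class = c("n2osip_io_error", "error")))
  }
  user <- yaml::read_yaml(path)
  cfg <- modify_defaults(unclass(default_config()), user)
  validate_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A `run_config` object.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

# Recursive merge: values in `user` override `base`; nested lists merge.
modify_defaults <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- modify_defaults(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

# Collar area (m^2) from config geometry.
collar_area_m2 <- function(geom) pi * geom$collar_diameter_m^2 / 4
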