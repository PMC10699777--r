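#' Construct a chamber closure time series
#'
#' A `chamber_series` holds one chamber closure: elapsed time in seconds
#' since the closure started, the N2O mole fraction trace, and optional
#' CO2 and raw delta15N streams, together with the geometry needed to turn
#' a concentration slope into an areal flux.
#'
#' @param chamber_id Identifier of the chamber/collar.
#' @param time_s Numeric vector, seconds since closure start, strictly
#'   increasing, length >= 2.
#' @param n2o_ppb N2O mole fraction (ppb), positive, same length.
#' @param co2_ppm Optional CO2 mole fraction (ppm).
#' @param d15n Optional raw delta15N stream (permil).
#' @param geometry List with `collar_diameter_m`, `system_volume_l`,
#'   `temperature_k`, `pressure_kpa` (as in a `run_config`).
#' @return An object of class `chamber_series`.
#' @export
chamber_series <- function(chamber_id, time_s, n2o_ppb, co2_ppm = NULL,
                           d15n = NULL, geometry = NULL) {
  time_s <- as.numeric(time_s)
  n2o_ppb <- as.numeric(n2o_ppb)
  if (length(time_s) < 2)
    stop(errorCondition("chamber series needs >= 2 points",
                        class = c("n2osip_data_error", "error")))
  if (length(n2o_ppb) != length(time_s))
    stop(errorCondition("time and concentration lengths differ",
                        class = c("n2osip_data_error", "error")))
  d <- diff(time_s)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1] + 1
    stop(errorCondition(
      sprintf("non-monotonic time within series at row %d", i),
      class = c("n2osip_data_error", "error")))
  }
  if (any(n2o_ppb <= 0))
    stop(errorCondition("N2O mole fractions must be positive",
                        class = c("n2osip_data_error", "error")))
  structure(
    list(chamber_id = as.character(chamber_id), time_s = time_s,
         n2o_ppb = n2o_ppb, co2_ppm = co2_ppm, d15n = d15n,
         geometry = geometry),
    class = "chamber_series")
}

#' @export
print.chamber_series <- function(x, ...) {
  cat(sprintf("<chamber_series> chamber %s: %d points over %.0f s, N2O %.1f-%.1f ppb\n",
              x$chamber_id, length(x$time_s), diff(range(x$time_s)),
              min(x$n2o_ppb), max(x$n2o_ppb)))
  invisible(x)
}

#' Read a chamber concentration table into closure series
#'
#' Parses a delimited table of automated-chamber output (columns
#' `timestamp`, `chamber_id`, `n2o_ppb`; optional `co2_ppm`, `d15n_raw`)
#' and splits it into one [chamber_series()] per chamber and closure
#' episode. Timestamps may be ISO-8601 strings or epoch seconds; internal
#' time is seconds since episode start. A new episode begins wherever the
#' gap between consecutive timestamps of one chamber exceeds
#' `cfg$io$episode_split_s` (default 120 s — one closure is 2 min).
#'
#' @param path CSV file path (comma-separated, header, "." decimal).
#' @param config A `run_config`; supplies the split threshold and the
#'   geometry attached to every returned series.
#' @return A list of `chamber_series`, ordered by chamber id then episode
#'   start time, named `<chamber_id>.<episode>`.
#' @export
read_chamber_table <- function(path, config = default_config()) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("n2osip_io_error", "error")))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#")
  required <- c("timestamp", "chamber_id", "n2o_ppb")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(errorCondition(
      sprintf("missing mandatory column(s): %s",
              paste(missing, collapse = ", ")),
      class = c("n2osip_format_error", "error")))
  tab$.t <- parse_timestamp(tab$timestamp)
  split_s <- config$io$episode_split_s
  out <- list()
  for (cid in unique(tab$chamber_id)) {
    sub <- tab[tab$chamber_id == cid, , drop = FALSE]
    sub <- sub[order(sub$.t), , drop = FALSE]
    dt <- diff(sub$.t)
    if (any(dt == 0)) {
      i <- which(dt == 0)[1]
      stop(errorCondition(
        sprintf("duplicate timestamp for chamber %s at row %d", cid,
                as.integer(rownames(sub)[i + 1])),
        class = c("n2osip_data_error", "error")))
    }
    episode <- cumsum(c(0, dt > split_s))
    for (ep in unique(episode)) {
      rows <- sub[episode == ep, , drop = FALSE]
      if (nrow(rows) < 2) next
      out[[sprintf("%s.%d", cid, ep + 1)]] <- chamber_series(
        chamber_id = cid,
        time_s = rows$.t - rows$.t[1],
        n2o_ppb = rows$n2o_ppb,
        co2_ppm = if ("co2_ppm" %in% names(rows)) rows$co2_ppm,
        d15n = if ("d15n_raw" %in% names(rows)) rows$d15n_raw,
        geometry = config$chamber_geometry)
    }
  }
  out
}

# ISO-8601 strings or epoch seconds -> numeric seconds.
parse_timestamp <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num)) return(num)
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(t))
    stop(errorCondition("unparseable timestamp(s)",
                        class = c("n2osip_format_error", "error")))
  as.numeric(t)
}

#' Write / read a results table
#'
#' Long-format results (fluxes, deltas, partition fractions, copy
#' numbers) are written as CSV with a leading `# units:` comment line so
#' the units travel with the file. Written values round trip at full
#' precision through [read_results()].
#'
#' @param table A nonempty data.frame.
#' @param path Output path.
#' @param units Optional named character vector mapping column names to
#'   unit strings; recorded in the header comment.
#' @return `write_results()`: `path`, invisibly. `read_results()`: the
#'   data.frame, with a `units` attribute when present in the file.
#' @export
write_results <- function(table, path, units = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop(errorCondition("results table must be a nonempty data.frame",
                        class = c("n2osip_data_error", "error")))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(units)) {
    writeLines(sprintf("# units: %s",
                       paste(names(units), units, sep = "=", collapse = ";")),
               con)
  }
  utils::write.csv(format_full_precision(table), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1)
  has_units <- startsWith(first, "# units:")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (has_units) {
    spec <- strsplit(sub("^# units: ", "", first), ";")[[1]]
    kv <- strsplit(spec, "=")
    units <- vapply(kv, `[`, "", 2)
    names(units) <- vapply(kv, `[`, "", 1)
    attr(tab, "units") <- units
  }
  tab
}

# Numerics serialized with 17 significant digits so read.csv reproduces
# them bit-for-bit.
format_full_precision <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 17)
      }, "")
    }
  }
  df
}
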