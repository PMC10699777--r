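#' Translate literature endmember boxes onto the measurement scale
#'
#' Literature compilations report the isotopic composition of N2O from
#' each producing process relative to its substrate: delta15N relative to
#' the nitrogen substrate (NO3-/NO2- for denitrification and
#' chemodenitrification, NH4+ for nitrification) and delta18O relative to
#' soil water. To compare measurements against the boxes, each axis range
#' is translated (added to) by the measured substrate signature. Site
#' preference is substrate-independent and is never shifted. Correction
#' is a pure translation: box widths are conserved exactly.
#'
#' @param boxes Named list of endmember boxes (see
#'   `default_config()$endmembers`): each with `sp`, `d15n`, `d18o`
#'   2-vectors and `d15n_basis` (`"no3"`, `"nh4"` or `"none"`),
#'   `d18o_basis` (`"water"` or `"none"`).
#' @param substrates List with `d18o_h2o`, `d15n_no3` (combined
#'   NO3-/NO2-), `d15n_nh4` (permil). A basis declared by a box but
#'   absent here is a config error.
#' @return The boxes with `d15n`/`d18o` ranges shifted, and a
#'   `corrected = TRUE` marker per box.
#' @export
#' @examples
#' cfg <- default_config()
#' em <- build_endmembers(cfg$endmembers, cfg$substrates)
#' em$bacterial_denitrification$d18o  # water-corrected (-9 applied)
build_endmembers <- function(boxes, substrates) {
  shift_for <- function(basis, axis) {
    key <- switch(paste(axis, basis, sep = "."),
                  "d15n.no3" = "d15n_no3",
                  "d15n.no2" = "d15n_no3",   # combined NO3-/NO2- value
                  "d15n.nh4" = "d15n_nh4",
                  "d18o.water" = "d18o_h2o",
                  NULL)
    if (is.null(key)) return(0)
    v <- substrates[[key]]
    if (is.null(v))
      stop(errorCondition(
        sprintf("substrate signature '%s' required by a box but missing",
                key),
        class = c("n2osip_config_error", "error")))
    v
  }
  lapply(boxes, function(box) {
    b <- box
    b$d15n <- box$d15n + shift_for(box$d15n_basis %||% "none", "d15n")
    b$d18o <- box$d18o + shift_for(box$d18o_basis %||% "none", "d18o")
    b$corrected <- TRUE
    b
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rayleigh shift of N2O isotope values under partial reduction
#'
#' As N2O is reduced to N2 with net isotope effects eps, the residual
#' N2O is progressively enriched. With `f_rem` the fraction of N2O
#' remaining:
#' \itemize{
#'   \item closed system: delta = delta0 + eps * ln(f_rem)
#'   \item open (steady-state) system: delta = delta0 - eps * (1 - f_rem)
#' }
#' Site preference is treated as a delta-like coordinate with its own
#' effect `eps_sp`. The sign convention is shared between modes: with the
#' conventional negative eps of N2O reduction, both enrich the residual
#' pool as f_rem falls (the open-system shift is bounded by -eps).
#' [invert_f_remaining()] is the exact inverse on each axis.
#'
#' @param start Named numeric: `sp`, `d15n`, `d18o` (permil) of the N2O
#'   produced (before reduction).
#' @param params List: `eps_sp`, `eps_15`, `eps_18` (permil, typically
#'   negative so the residual pool is enriched), `mode` = `"closed"` or
#'   `"open"`.
#' @param f_rem Fraction of N2O remaining, in (0, 1]. Vectorized.
#' @return For scalar `f_rem` a named vector (`sp`, `d15n`, `d18o`); for
#'   vector `f_rem` a 3-column matrix with one row per value.
#' @export
#' @examples
#' p <- list(eps_sp = -6, eps_15 = -7, eps_18 = -15, mode = "closed")
#' rayleigh_shift(c(sp = -1.9, d15n = 0, d18o = 0), p, 0.0855)["sp"]  # 12.85
rayleigh_shift <- function(start, params, f_rem) {
  if (any(f_rem <= 0) || any(f_rem > 1))
    stop(errorCondition("f_rem must lie in (0, 1]",
                        class = c("n2osip_domain_error", "error")))
  eps <- c(sp = params$eps_sp, d15n = params$eps_15, d18o = params$eps_18)
  fac <- switch(params$mode,
                closed = log(f_rem),
                open = f_rem - 1,
                stop(errorCondition("mode must be 'closed' or 'open'",
                                    class = c("n2osip_domain_error", "error"))))
  out <- outer(fac, eps) +
    matrix(start[c("sp", "d15n", "d18o")], nrow = length(f_rem), ncol = 3,
           byrow = TRUE)
  colnames(out) <- c("sp", "d15n", "d18o")
  if (length(f_rem) == 1) out[1, ] else out
}

#' Invert the Rayleigh model for the fraction of N2O remaining
#'
#' Exact inverse of [rayleigh_shift()] on one axis:
#' closed: f = exp((measured - start) / eps);
#' open: f = 1 + (measured - start) / eps.
#' Results outside (0, 1] (e.g. a measurement lighter than the start for
#' negative eps) are clipped to 1 and flagged, not thrown: the data may
#' simply show no reduction plus noise.
#'
#' @param measured,start Delta values on one axis (permil).
#' @param epsilon Net isotope effect on that axis (permil, nonzero).
#' @param mode `"closed"` or `"open"`.
#' @return List: `f` (clipped to (0, 1]), `out_of_bounds` flag.
#' @export
#' @examples
#' invert_f_remaining(12.8, -1.9, -6, "closed")$f  # 0.0863
invert_f_remaining <- function(measured, start, epsilon,
                               mode = c("closed", "open")) {
  mode <- match.arg(mode)
  if (any(epsilon == 0))
    stop(errorCondition("epsilon must be nonzero",
                        class = c("n2osip_domain_error", "error")))
  f_raw <- if (mode == "closed") exp((measured - start) / epsilon)
           else 1 + (measured - start) / epsilon
  list(f = pmin(pmax(f_raw, .Machine$double.xmin), 1),
       out_of_bounds = f_raw > 1 + 1e-9 | f_raw <= 0)
}

# Candidate start points searched within one box: 8 corners + centroid.
box_candidates <- function(box) {
  g <- expand.grid(sp = box$sp, d15n = box$d15n, d18o = box$d18o)
  rbind(as.matrix(g),
        centroid = c(mean(box$sp), mean(box$d15n), mean(box$d18o)))
}

#' Classify an N2O isotope reading against process endmembers
#'
#' The geometric inference behind dual-isotope source attribution: test
#' the reading for membership in each (substrate-corrected) endmember
#' box, and find the process whose Rayleigh reduction trajectory passes
#' closest to it. The search is deterministic: start points are each
#' box's 8 corners plus centroid, f_rem runs over a fixed log-spaced grid
#' (default 200 points on [0.01, 1]), and the residual is the unweighted
#' Euclidean distance (permil) over the axes available in the reading
#' (axes may be NA). Axis weights can be supplied to down-weight noisy
#' axes.
#'
#' @param reading Named numeric with any of `sp`, `d15n`, `d18o`
#'   (permil); NA axes are ignored. An [isotopocule_reading()] is also
#'   accepted.
#' @param boxes Corrected endmember boxes from [build_endmembers()].
#' @param params Rayleigh parameter list (see [rayleigh_shift()]).
#' @param f_grid Grid of f_rem values searched (default 200 log-spaced on
#'   [0.01, 1]).
#' @param weights Optional named axis weights (default 1 each).
#' @return Object of class `partition_result`: `process` (argmin),
#'   `f_rem`, `residual` (permil), `start` (best start point),
#'   `membership` (process x axis logical matrix of box membership at
#'   f_rem = 1), and `per_process` residual minima.
#' @export
classify_point <- function(reading, boxes, params,
                           f_grid = exp(seq(log(0.01), 0, length.out = 200)),
                           weights = c(sp = 1, d15n = 1, d18o = 1)) {
  if (inherits(reading, "isotopocule_reading"))
    reading <- c(sp = reading$sp, d15n = reading$d15n_bulk,
                 d18o = reading$d18o)
  if (length(boxes) == 0)
    stop(errorCondition("no endmember boxes supplied",
                        class = c("n2osip_data_error", "error")))
  axes <- c("sp", "d15n", "d18o")
  avail <- axes[axes %in% names(reading) & is.finite(reading[axes])]
  if (length(avail) == 0)
    stop(errorCondition("reading has no finite axes",
                        class = c("n2osip_insufficient_data_error", "error")))
  w <- weights[avail]
  fac <- switch(params$mode, closed = log(f_grid), open = f_grid - 1)
  eps <- c(sp = params$eps_sp, d15n = params$eps_15, d18o = params$eps_18)

  membership <- matrix(NA, nrow = length(boxes), ncol = 3,
                       dimnames = list(names(boxes), axes))
  best <- list(residual = Inf)
  per_process <- stats::setNames(numeric(length(boxes)), names(boxes))
  for (nm in names(boxes)) {
    box <- boxes[[nm]]
    for (ax in axes) {
      if (ax %in% avail)
        membership[nm, ax] <- reading[ax] >= box[[ax]][1] &
                              reading[ax] <= box[[ax]][2]
    }
    cand <- box_candidates(box)
    best_box <- Inf
    for (i in seq_len(nrow(cand))) {
      # shifted trajectory from this start across the whole f grid
      res2 <- rep(0, length(f_grid))
      for (ax in avail)
        res2 <- res2 +
          (w[[ax]] * (cand[i, ax] + eps[[ax]] * fac - reading[[ax]]))^2
      j <- which.min(res2)
      if (res2[j] < best_box) best_box <- res2[j]
      if (res2[j] < best$residual^2) {
        best <- list(process = nm, f_rem = f_grid[j],
                     residual = sqrt(res2[j]), start = cand[i, ])
      }
    }
    per_process[nm] <- sqrt(best_box)
  }
  structure(list(process = best$process, f_rem = best$f_rem,
                 residual = best$residual, start = best$start,
                 membership = membership, per_process = per_process,
                 axes_used = avail),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "<partition_result> %s, f_rem = %.3f (residual %.3g permil over %s)\n",
    x$process, x$f_rem, x$residual, paste(x$axes_used, collapse = "/")))
  invisible(x)
}

#' Monte-Carlo uncertainty for the source partition
#'
#' Propagates the width of the endmember boxes (and optionally a range on
#' each net isotope effect) through [classify_point()]: each draw places
#' a point uniformly inside every box, draws eps values uniformly within
#' their ranges, classifies every reading against those (zero-width)
#' endmembers, and records the attributed process and f_rem. Seeded and
#' reproducible.
#'
#' @param readings A list of named reading vectors (or a single one), as
#'   accepted by [classify_point()].
#' @param boxes Corrected endmember boxes.
#' @param params Rayleigh parameters; elements `eps_sp`, `eps_15`,
#'   `eps_18` may each be a length-2 range instead of a scalar.
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed.
#' @param probs Quantile probabilities for f_rem (default 5/50/95\%).
#' @param f_grid Passed to [classify_point()].
#' @return List: `f_rem_quantiles`, `process_weights` (proportion of
#'   draw-reading pairs attributed to each process), `draws` data.frame.
#' @export
partition_uncertainty <- function(readings, boxes, params, n_draws = 200,
                                  seed = 1,
                                  probs = c(0.05, 0.5, 0.95),
                                  f_grid = exp(seq(log(0.01), 0,
                                                   length.out = 200))) {
  if (n_draws < 1)
    stop(errorCondition("n_draws must be >= 1",
                        class = c("n2osip_domain_error", "error")))
  if (!is.list(readings) || !is.null(names(readings)) &&
      any(names(readings) %in% c("sp", "d15n", "d18o")))
    readings <- list(readings)
  rng_or_scalar <- function(v) if (length(v) == 2) stats::runif(1, v[1], v[2]) else v
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  recs <- vector("list", n_draws * length(readings))
  k <- 0
  for (d in seq_len(n_draws)) {
    pt_boxes <- lapply(boxes, function(box) {
      pt <- c(stats::runif(1, box$sp[1], box$sp[2]),
              stats::runif(1, box$d15n[1], box$d15n[2]),
              stats::runif(1, box$d18o[1], box$d18o[2]))
      list(sp = rep(pt[1], 2), d15n = rep(pt[2], 2), d18o = rep(pt[3], 2))
    })
    p <- params
    p$eps_sp <- rng_or_scalar(params$eps_sp)
    p$eps_15 <- rng_or_scalar(params$eps_15)
    p$eps_18 <- rng_or_scalar(params$eps_18)
    for (r in seq_along(readings)) {
      cl <- classify_point(readings[[r]], pt_boxes, p, f_grid = f_grid)
      k <- k + 1
      recs[[k]] <- data.frame(draw = d, reading = r, process = cl$process,
                              f_rem = cl$f_rem, residual = cl$residual)
    }
  }
  draws <- do.call(rbind, recs)
  wt <- table(factor(draws$process, levels = names(boxes)))
  pw <- stats::setNames(as.numeric(wt) / sum(wt), names(boxes))
  list(f_rem_quantiles = stats::quantile(draws$f_rem, probs = probs),
       process_weights = pw,
       draws = draws)
}
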