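# Calibration curves, probabilistic calibration, and highest-density regions.
#
# Calendar convention throughout the package: integer calendar years BP
# (before AD 1950), BP = 1950 - AD with astronomical year numbering, so
# AD 201 <-> 1749 BP and year 0 exists. Curve grids are canonicalized to
# strictly increasing cal BP on construction.

#' Construct a calibration curve
#'
#' A calibration curve maps calendar age (cal BP) to expected radiocarbon
#' age (14C yr BP) with a 1-sigma curve uncertainty, as in the IntCal
#' series. The grid is canonicalized to strictly increasing cal BP.
#'
#' @param cal_bp Numeric vector of calendar years BP (strictly monotone).
#' @param c14_age Numeric vector of radiocarbon ages (14C yr BP), one per
#'   grid point.
#' @param sigma_curve Numeric vector of 1-sigma curve errors (14C yr),
#'   non-negative, one per grid point.
#' @param name Text identifier for the curve.
#' @return An object of class `cal_curve`: a list with elements `cal_bp`,
#'   `c14_age`, `sigma_curve` (equal-length numeric vectors, `cal_bp`
#'   strictly increasing) and `name`.
#' @examples
#' cal_curve(c(0, 10, 20), c(100, 115, 130), c(10, 12, 9))
#' @export
cal_curve <- function(cal_bp, c14_age, sigma_curve, name = "curve") {
  cal_bp <- as.numeric(cal_bp)
  c14_age <- as.numeric(c14_age)
  sigma_curve <- as.numeric(sigma_curve)
  n <- length(cal_bp)
  if (n < 2) {
    stop("insufficient curve: need at least 2 grid points, got ", n)
  }
  if (length(c14_age) != n || length(sigma_curve) != n) {
    stop("cal_bp, c14_age and sigma_curve must have equal length")
  }
  if (any(!is.finite(cal_bp)) || any(!is.finite(c14_age)) ||
      any(!is.finite(sigma_curve))) {
    stop("calibration curve values must be finite")
  }
  o <- order(cal_bp)
  cal_bp <- cal_bp[o]
  c14_age <- c14_age[o]
  sigma_curve <- sigma_curve[o]
  if (any(diff(cal_bp) == 0)) {
    stop("duplicate cal_bp grid values in calibration curve")
  }
  if (any(sigma_curve < 0)) {
    stop("sigma_curve must be non-negative everywhere")
  }
  structure(
    list(cal_bp = cal_bp, c14_age = c14_age, sigma_curve = sigma_curve,
         name = name),
    class = "cal_curve"
  )
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve> '%s': %d points, %g to %g cal BP\n",
              x$name, length(x$cal_bp), min(x$cal_bp), max(x$cal_bp)))
  invisible(x)
}

#' Read a calibration curve from a text file
#'
#' Parses IntCal-style three-column tables (cal BP, 14C age BP, 1-sigma
#' error). Lines beginning with `#` are comments; fields may be separated
#' by commas and/or whitespace. Extra columns are ignored. The `plain`
#' dialect is a bare 3-column CSV with the same column order.
#'
#' @param source Path to a readable text file (or a connection).
#' @param dialect `"intcal"` (comma and/or whitespace separated, `#`
#'   comments) or `"plain"` (3-column CSV). Both are parsed by the same
#'   tolerant reader; the distinction is documentary.
#' @param name Curve name; defaults to the file name.
#' @return A [cal_curve] with strictly increasing `cal_bp`.
#' @export
read_calibration_curve <- function(source, dialect = c("intcal", "plain"),
                                   name = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(source)
  if (is.null(name)) {
    name <- if (is.character(source)) basename(source) else "curve"
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("insufficient curve: no data rows in ", name)
  rows <- lapply(idx, function(i) {
    fields <- strsplit(trimws(lines[[i]]), "[,\t ]+")[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed calibration curve row at line %d: %s",
                   i, lines[[i]]))
    }
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (any(is.na(vals))) {
      stop(sprintf("malformed calibration curve row at line %d: %s",
                   i, lines[[i]]))
    }
    vals
  })
  m <- do.call(rbind, rows)
  cal_curve(m[, 1], m[, 2], m[, 3], name = name)
}

#' Interpolate a calibration curve onto a regular (annual) grid
#'
#' Linear interpolation of both the 14C age and the curve error onto a
#' regular calendar grid spanning the input range; input endpoints are
#' preserved exactly.
#'
#' @param curve A [cal_curve].
#' @param resolution Grid step in calendar years (default 1 = annual).
#' @return A [cal_curve] on the regular grid.
#' @export
interpolate_curve <- function(curve, resolution = 1) {
  stopifnot(inherits(curve, "cal_curve"))
  if (resolution < 1) stop("resolution must be >= 1 year")
  span <- max(curve$cal_bp) - min(curve$cal_bp)
  if (resolution > span) {
    stop("resolution (", resolution, ") coarser than curve span (", span, ")")
  }
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = resolution)
  if (isTRUE(all.equal(grid, curve$cal_bp))) {
    return(curve)
  }
  mu <- stats::approx(curve$cal_bp, curve$c14_age, xout = grid)$y
  sg <- stats::approx(curve$cal_bp, curve$sigma_curve, xout = grid)$y
  cal_curve(grid, mu, sg, name = curve$name)
}

is_annual <- function(curve) {
  all(diff(curve$cal_bp) == 1)
}

#' Construct a calibrated density
#'
#' Internal-facing constructor for a discrete probability mass over a
#' contiguous annual calendar grid.
#'
#' @param grid Integer cal BP years, contiguous and increasing.
#' @param mass Non-negative mass per grid year.
#' @param normalized Logical; whether `mass` sums to 1.
#' @param meta List of provenance metadata (trim bounds, clipped mass).
#' @return An object of class `cal_density`.
#' @export
cal_density <- function(grid, mass, normalized = TRUE, meta = list()) {
  grid <- as.numeric(grid)
  mass <- as.numeric(mass)
  stopifnot(length(grid) == length(mass))
  if (length(grid) > 1 && any(diff(grid) != 1)) {
    stop("cal_density grid must be annual and contiguous")
  }
  if (any(mass < 0)) stop("cal_density mass must be non-negative")
  if (normalized && abs(sum(mass) - 1) > 1e-9) {
    stop("normalized cal_density must sum to 1 within 1e-9")
  }
  structure(list(grid = grid, mass = mass, normalized = normalized,
                 meta = meta),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  cat(sprintf("<cal_density> %d yr [%g, %g] cal BP, total mass %.6f%s\n",
              length(x$grid), min(x$grid), max(x$grid), sum(x$mass),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Calibrate a radiocarbon determination
#'
#' For each calendar year t on the curve grid the posterior mass is
#' proportional to the Normal density of the measured 14C age at mean
#' mu(t) and standard deviation sqrt(sigma^2 + sigma_curve(t)^2) (a flat
#' prior over calendar years). The support is trimmed to the years
#' carrying at least 1 - 1e-6 of the total mass; trim bounds are recorded
#' in `meta`.
#'
#' @param c14_age Uncalibrated radiocarbon age (14C yr BP).
#' @param sigma 1-sigma measurement error (14C yr), > 0.
#' @param curve A [cal_curve] on an annual grid (see [interpolate_curve]).
#' @param normalize If `TRUE` (default) the returned mass sums to 1.
#' @return A [cal_density] over the trimmed annual grid.
#' @examples
#' crv <- identity_curve(0, 3000)
#' d <- calibrate(1000, 20, crv)
#' sum(d$mass)
#' @export
calibrate <- function(c14_age, sigma, curve, normalize = TRUE) {
  stopifnot(inherits(curve, "cal_curve"))
  if (!is.finite(c14_age)) stop("c14_age must be finite")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is_annual(curve)) {
    stop("curve must be on an annual grid; see interpolate_curve()")
  }
  sd_tot <- sqrt(sigma^2 + curve$sigma_curve^2)
  within <- abs(c14_age - curve$c14_age) <= 10 * sd_tot
  if (!any(within)) {
    stop("out of curve: determination ", c14_age, " +/- ", sigma,
         " lies more than 10 combined sigma outside curve '",
         curve$name, "' everywhere")
  }
  # contiguous evaluation range (mass beyond 10 sigma is negligible)
  i0 <- min(which(within))
  i1 <- max(which(within))
  idx <- i0:i1
  dens <- stats::dnorm(c14_age, mean = curve$c14_age[idx], sd = sd_tot[idx])
  total <- sum(dens)
  if (total <= 0) {
    stop("out of curve: zero total mass for determination ", c14_age)
  }
  cum <- cumsum(dens) / total
  rcum <- rev(cumsum(rev(dens))) / total
  # drop at most 5e-7 of mass from each tail: retained >= 1 - 1e-6
  lo <- which(cum > 5e-7)[1]
  hi <- length(idx) + 1 - which(rev(rcum) > 5e-7)[1]
  keep <- idx[lo:hi]
  mass <- dens[lo:hi]
  dropped <- 1 - sum(mass) / total
  if (normalize) mass <- mass / sum(mass)
  cal_density(curve$cal_bp[keep], mass, normalized = normalize,
              meta = list(c14_age = c14_age, sigma = sigma,
                          curve = curve$name,
                          trim = c(curve$cal_bp[keep[1]],
                                   curve$cal_bp[keep[length(keep)]]),
                          trimmed_mass = dropped))
}

#' Calendar window (closed interval in cal BP)
#'
#' @param start_bp Older bound (cal BP), inclusive.
#' @param end_bp Younger bound (cal BP), inclusive; `start_bp >= end_bp`.
#' @return An object of class `cal_window`.
#' @examples
#' cal_window(1750, 150)
#' @export
cal_window <- function(start_bp, end_bp) {
  if (!is.finite(start_bp) || !is.finite(end_bp)) {
    stop("window bounds must be finite")
  }
  if (start_bp < end_bp) {
    stop("cal_window requires start_bp >= end_bp (start is the older bound)")
  }
  structure(list(start_bp = start_bp, end_bp = end_bp), class = "cal_window")
}

#' @export
print.cal_window <- function(x, ...) {
  cat(sprintf("<cal_window> %g-%g cal BP\n", x$start_bp, x$end_bp))
  invisible(x)
}

#' Highest-density region of a calibrated density
#'
#' The smallest set of grid years (selected by descending mass; ties
#' broken toward older years) whose cumulative mass reaches `level`,
#' returned as maximal contiguous closed intervals.
#'
#' @param density A normalized [cal_density].
#' @param level Coverage probability, strictly between 0 and 1
#'   (default 0.95).
#' @return A list of [cal_window] intervals, oldest first.
#' @export
hpd_region <- function(density, level = 0.95) {
  stopifnot(inherits(density, "cal_density"))
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  if (!density$normalized || abs(sum(density$mass) - 1) > 1e-6) {
    stop("hpd_region requires a normalized density")
  }
  # descending mass; ties toward older (larger BP) years
  o <- order(-density$mass, -density$grid)
  cum <- cumsum(density$mass[o])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(o)
  years <- sort(density$grid[o[seq_len(k)]], decreasing = TRUE)
  runs <- split(years, cumsum(c(1, diff(years) != -1)))
  unname(lapply(runs, function(r) cal_window(max(r), min(r))))
}

#' Do any of a set of calendar intervals intersect a window?
#'
#' Closed-interval intersection: touching bounds count as overlap.
#'
#' @param region List of [cal_window] intervals (e.g. from [hpd_region]).
#' @param window A [cal_window].
#' @return `TRUE` iff any interval intersects the window.
#' @export
overlaps_window <- function(region, window) {
  stopifnot(inherits(window, "cal_window"))
  if (inherits(region, "cal_window")) region <- list(region)
  any(vapply(region, function(w) {
    w$start_bp >= window$end_bp && w$end_bp <= window$start_bp
  }, logical(1)))
}

#' Identity calibration curve
#'
#' A synthetic curve with mu(t) = t and constant curve error, on an
#' annual grid. With zero curve error, calibration against this curve
#' collapses to the discretized measurement density, which makes it the
#' natural backbone for simulation and validation.
#'
#' @param min_bp,max_bp Grid bounds (cal BP).
#' @param sigma_curve Constant 1-sigma curve error (default 0).
#' @return A [cal_curve].
#' @export
identity_curve <- function(min_bp = -100, max_bp = 3000, sigma_curve = 0) {
  grid <- seq(min_bp, max_bp, by = 1)
  cal_curve(grid, grid, rep(sigma_curve, length(grid)),
            name = "identity")
}

#' Wiggly synthetic calibration curve
#'
#' mu(t) = t + A sin(2 pi t / P): a sinusoidal perturbation of the
#' identity curve that mimics the plateaus and cliffs of real
#' atmospheric curves.
#'
#' @param min_bp,max_bp Grid bounds (cal BP).
#' @param amplitude Perturbation amplitude A in 14C years.
#' @param period Perturbation period P in calendar years.
#' @param sigma_curve Constant 1-sigma curve error.
#' @return A [cal_curve].
#' @export
wiggly_curve <- function(min_bp = -100, max_bp = 3000, amplitude = 20,
                         period = 300, sigma_curve = 5) {
  grid <- seq(min_bp, max_bp, by = 1)
  mu <- grid + amplitude * sin(2 * pi * grid / period)
  cal_curve(grid, mu, rep(sigma_curve, length(grid)), name = "wiggly")
}

#' Export a calibrated density to CSV
#'
#' Writes columns `cal_bp`, `mass`.
#'
#' @param density A [cal_density].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(density, path) {
  stopifnot(inherits(density, "cal_density"))
  utils::write.csv(data.frame(cal_bp = density$grid, mass = density$mass),
                   path, row.names = FALSE)
  invisible(path)
}
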