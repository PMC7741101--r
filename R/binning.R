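# Site-phase binning and SPD assembly.
#
# Binning controls investigation bias: heavily dated site occupations are
# collapsed to one averaged density per phase, so a site contributes in
# proportion to its phases, not to its dating budget.

#' Cluster same-site dates into occupation-phase bins
#'
#' Single-linkage agglomeration cut at height `h`, applied per site: two
#' dates share a bin iff they are connected by a chain of same-site
#' dates whose consecutive clustering-key gaps are all `<= h` (a gap of
#' exactly `h` merges). The clustering key is the uncalibrated 14C age
#' for radiocarbon dates and the cal BP year for tree-ring dates. Phase
#' indices within a site are ordered by bin mean key, oldest (largest
#' BP) first. Dates at different sites are never co-binned.
#'
#' @param dates Data frame with columns `id`, `site_id`, `key`.
#' @param h Linkage cut height in years (default 100).
#' @return An object of class `site_phase_bins`: a list of bins, each a
#'   list with `site_id`, `phase_index`, `members` (date ids),
#'   `key_values`; plus attributes `h` and `n_dates`.
#' @examples
#' d <- data.frame(id = 1:4, site_id = "S1", key = c(1000, 1080, 1160, 1400))
#' length(bin_dates(d))  # 2 phases
#' @export
bin_dates <- function(dates, h = 100) {
  stopifnot(is.data.frame(dates),
            all(c("id", "site_id", "key") %in% names(dates)))
  if (h <= 0) stop("h must be > 0")
  if (any(!is.finite(dates$key))) stop("clustering keys must be finite")
  if (anyDuplicated(dates$id)) stop("date ids must be unique")
  bins <- list()
  for (site in unique(dates$site_id)) {
    rows <- dates[dates$site_id == site, , drop = FALSE]
    o <- order(rows$key)
    rows <- rows[o, , drop = FALSE]
    # single-linkage components on a line: split where the sorted gap > h
    grp <- cumsum(c(1, diff(rows$key) > h))
    site_bins <- lapply(split(seq_len(nrow(rows)), grp), function(ix) {
      list(site_id = site,
           phase_index = NA_integer_,
           members = rows$id[ix],
           key_values = rows$key[ix])
    })
    means <- vapply(site_bins, function(b) mean(b$key_values), numeric(1))
    site_bins <- site_bins[order(-means)]  # oldest phase first
    for (k in seq_along(site_bins)) site_bins[[k]]$phase_index <- k
    bins <- c(bins, site_bins)
  }
  structure(bins, class = "site_phase_bins", h = h, n_dates = nrow(dates))
}

#' @export
print.site_phase_bins <- function(x, ...) {
  cat(sprintf("<site_phase_bins> %d bins over %d dates (h = %g)\n",
              length(x), attr(x, "n_dates"), attr(x, "h")))
  invisible(x)
}

#' Bin membership as a data frame
#'
#' @param bins A `site_phase_bins` object.
#' @return Data frame with columns `id`, `site_id`, `phase_index`,
#'   `bin_id` (`"<site>.<phase>"`).
#' @export
bin_assignments <- function(bins) {
  stopifnot(inherits(bins, "site_phase_bins"))
  do.call(rbind, lapply(bins, function(b) {
    data.frame(id = b$members, site_id = b$site_id,
               phase_index = b$phase_index,
               bin_id = paste(b$site_id, b$phase_index, sep = "."),
               stringsAsFactors = FALSE)
  }))
}

#' Degenerate (single-year) density for a tree-ring date
#'
#' A tree-ring cutting date fixes its calendar year exactly, so its
#' "calibrated" density is degenerate: Pr(X = k0) = 1 at the date's cal
#' BP year and 0 elsewhere. Representing it this way lets tree-ring
#' dates flow through the same binning and SPD machinery as radiocarbon
#' dates.
#'
#' @param year_ad Calendar year AD of the outermost ring.
#' @return A normalized [cal_density] with unit mass at
#'   `ad_to_bp(year_ad)`.
#' @examples
#' degenerate_density(700)  # mass 1 at 1250 cal BP
#' @export
degenerate_density <- function(year_ad) {
  stopifnot(length(year_ad) == 1, is.finite(year_ad))
  cal_density(ad_to_bp(year_ad), 1, normalized = TRUE,
              meta = list(year_ad = year_ad, degenerate = TRUE))
}

#' Average calibrated densities within a bin
#'
#' Pointwise arithmetic mean over the union grid (years absent from a
#' member density carry zero mass there). With normalized inputs the
#' result is normalized.
#'
#' @param densities Non-empty list of normalized [cal_density] objects.
#' @return A [cal_density] over the union grid.
#' @export
bin_average <- function(densities) {
  if (length(densities) == 0) stop("bin_average requires a non-empty list")
  stopifnot(all(vapply(densities, inherits, logical(1), "cal_density")))
  if (!all(vapply(densities, function(d) d$normalized, logical(1)))) {
    stop("bin_average requires normalized densities")
  }
  if (length(densities) == 1) return(densities[[1]])
  lo <- min(vapply(densities, function(d) min(d$grid), numeric(1)))
  hi <- max(vapply(densities, function(d) max(d$grid), numeric(1)))
  grid <- lo:hi
  acc <- numeric(length(grid))
  for (d in densities) {
    ix <- (min(d$grid) - lo + 1):(max(d$grid) - lo + 1)
    acc[ix] <- acc[ix] + d$mass
  }
  cal_density(grid, acc / length(densities), normalized = TRUE,
              meta = list(n_members = length(densities)))
}

#' Build a summed probability distribution from site-phase bins
#'
#' Each bin contributes the pointwise mean of its members' calibrated
#' densities; the SPD is the pointwise sum of those bin averages over an
#' annual grid. With normalized inputs the SPD's total mass equals the
#' number of bins minus any mass clipped outside the grid.
#'
#' @param bins A `site_phase_bins` object.
#' @param densities Named list mapping date id to [cal_density]; every
#'   bin member must be present.
#' @param grid A [cal_window] defining the SPD grid (annual, closed).
#' @return An object of class `spd_series`: list with `grid` (cal BP,
#'   increasing), `density`, and `meta` (`n_dates`, `n_bins`,
#'   `clipped_mass`, `normalized`, smoothing/scaling provenance).
#' @export
build_spd <- function(bins, densities, grid) {
  stopifnot(inherits(bins, "site_phase_bins"), inherits(grid, "cal_window"))
  if (length(bins) == 0) stop("build_spd requires at least one bin")
  gyears <- grid$end_bp:grid$start_bp
  total <- numeric(length(gyears))
  clipped <- 0
  n_dates <- 0L
  for (b in bins) {
    ids <- as.character(b$members)
    if (!all(ids %in% names(densities))) {
      stop("missing calibrated density for date(s): ",
           paste(setdiff(ids, names(densities)), collapse = ", "))
    }
    avg <- bin_average(densities[ids])
    n_dates <- n_dates + length(ids)
    inside <- avg$grid >= grid$end_bp & avg$grid <= grid$start_bp
    clipped <- clipped + sum(avg$mass[!inside])
    if (any(inside)) {
      ix <- avg$grid[inside] - grid$end_bp + 1
      total[ix] <- total[ix] + avg$mass[inside]
    }
  }
  norm_in <- all(vapply(densities, function(d) d$normalized, logical(1)))
  spd_series(gyears, total,
             meta = list(n_dates = n_dates, n_bins = length(bins),
                         clipped_mass = clipped, normalized = norm_in,
                         h = attr(bins, "h"),
                         smoothing = NULL, scaling_factor = NULL))
}

#' Construct an SPD series object
#'
#' @param grid Annual, contiguous cal BP years (increasing).
#' @param density Non-negative per-year values.
#' @param meta Provenance list (`n_dates`, `n_bins`, smoothing, scaling).
#' @return An object of class `spd_series`.
#' @export
spd_series <- function(grid, density, meta = list()) {
  grid <- as.numeric(grid)
  density <- as.numeric(density)
  stopifnot(length(grid) == length(density))
  if (length(grid) > 1 && any(diff(grid) != 1)) {
    stop("spd_series grid must be annual and contiguous")
  }
  if (any(density < 0)) stop("spd_series density must be non-negative")
  structure(list(grid = grid, density = density, meta = meta),
            class = "spd_series")
}

#' @export
print.spd_series <- function(x, ...) {
  cat(sprintf("<spd_series> %d yr [%g, %g] cal BP, total mass %.4f",
              length(x$grid), min(x$grid), max(x$grid), sum(x$density)))
  if (!is.null(x$meta$n_bins)) {
    cat(sprintf(" (%d bins, %d dates)", x$meta$n_bins, x$meta$n_dates))
  }
  cat("\n")
  invisible(x)
}

#' Export an SPD series to CSV (with JSON metadata sidecar)
#'
#' Writes columns `cal_bp, year_ad, density`; if `meta_path` is given,
#' the series metadata is written there as JSON.
#'
#' @param spd An `spd_series`.
#' @param path Output CSV path.
#' @param meta_path Optional JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_spd_csv <- function(spd, path, meta_path = NULL) {
  stopifnot(inherits(spd, "spd_series"))
  utils::write.csv(data.frame(cal_bp = spd$grid,
                              year_ad = bp_to_ad(spd$grid),
                              density = spd$density),
                   path, row.names = FALSE)
  if (!is.null(meta_path)) {
    writeLines(jsonlite::toJSON(spd$meta, auto_unbox = TRUE, pretty = TRUE,
                                null = "null"),
               meta_path)
  }
  invisible(path)
}
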