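# SPD post-processing: Gaussian smoothing, area-equalized scaling against
# a reference population series, and descriptive series comparison.

gaussian_kernel <- function(window, sd) {
  if (window %% 2 == 0) stop("smoothing window must be odd")
  if (sd <= 0) stop("smoothing sd must be > 0")
  half <- (window - 1) / 2
  i <- -half:half
  w <- exp(-i^2 / (2 * sd^2))
  w / sum(w)
}

#' Smooth an SPD with a centre-aligned Gaussian kernel
#'
#' Convolution with weights w(i) proportional to exp(-i^2 / (2 sd^2))
#' over a centred window. At the series edges the kernel is truncated to
#' the available years and renormalized, which leaves constant series
#' unchanged everywhere and conserves total mass whenever the series
#' carries no mass within a half-window of its edges (the usual regime
#' for tail-trimmed SPDs).
#'
#' @param spd An `spd_series`.
#' @param window Odd kernel width in years (default 21).
#' @param sd Kernel standard deviation in years (default 5).
#' @return The smoothed `spd_series`; `meta$smoothing` records the
#'   parameters.
#' @export
smooth_spd <- function(spd, window = 21, sd = 5) {
  stopifnot(inherits(spd, "spd_series"))
  w <- gaussian_kernel(window, sd)
  half <- (window - 1) / 2
  x <- spd$density
  n <- length(x)
  out <- as.numeric(stats::filter(x, w, method = "convolution", sides = 2))
  # edges: truncated kernel, renormalized over the years that exist
  edge <- c(seq_len(min(half, n)), seq.int(max(n - half + 1, 1), n))
  for (i in unique(edge)) {
    j <- max(1, i - half):min(n, i + half)
    wij <- w[j - i + half + 1]
    out[i] <- sum(x[j] * wij) / sum(wij)
  }
  meta <- spd$meta
  meta$smoothing <- list(window = window, sd = sd)
  spd_series(spd$grid, out, meta = meta)
}

#' Expand a period-resolved population series to annual person-years
#'
#' Piecewise-constant expansion: a period's estimate applies to every
#' calendar year in `[start_ad, end_ad)`.
#'
#' @param pop Data frame with `start_ad`, `end_ad`, `estimate`
#'   (non-overlapping, ordered periods).
#' @return Data frame with columns `year_ad`, `cal_bp`, `persons`, one
#'   row per covered year.
#' @export
annualize_population <- function(pop) {
  pop <- validate_population(pop)
  years <- unlist(lapply(seq_len(nrow(pop)), function(i) {
    seq(pop$start_ad[i], pop$end_ad[i] - 1)
  }))
  persons <- unlist(lapply(seq_len(nrow(pop)), function(i) {
    rep(pop$estimate[i], pop$end_ad[i] - pop$start_ad[i])
  }))
  data.frame(year_ad = years, cal_bp = ad_to_bp(years), persons = persons)
}

#' Scale an SPD so its area matches a reference population series
#'
#' Over the overlap window the population series is expanded to annual
#' person-years and the SPD is multiplied by
#' `sum(person-years) / sum(SPD density)`, so that after scaling the two
#' areas over the overlap agree exactly. This puts a unitless relative
#' density and an absolute population reconstruction on the same axis
#' for visual and descriptive comparison.
#'
#' @param spd An `spd_series`.
#' @param pop Population data frame (`start_ad`, `end_ad`, `estimate`).
#' @param overlap A [cal_window]; must intersect both series' supports.
#' @return The scaled `spd_series`; `meta$scaling_factor` records the
#'   factor.
#' @export
scale_to_reference <- function(spd, pop, overlap) {
  stopifnot(inherits(spd, "spd_series"), inherits(overlap, "cal_window"))
  ann <- annualize_population(pop)
  in_pop <- ann$cal_bp >= overlap$end_bp & ann$cal_bp <= overlap$start_bp
  in_spd <- spd$grid >= overlap$end_bp & spd$grid <= overlap$start_bp
  pop_sum <- sum(ann$persons[in_pop])
  spd_sum <- sum(spd$density[in_spd])
  if (!any(in_pop) || pop_sum <= 0) {
    stop("population series has no mass in the overlap window")
  }
  if (!any(in_spd) || spd_sum <= 0) {
    stop("SPD has zero mass in the overlap window")
  }
  factor <- pop_sum / spd_sum
  scale_by_factor(spd, factor)
}

#' Multiply an SPD by a constant factor
#'
#' @param spd An `spd_series`.
#' @param k Positive factor.
#' @return The scaled `spd_series`; `meta$scaling_factor` accumulates
#'   multiplicatively.
#' @export
scale_by_factor <- function(spd, k) {
  stopifnot(inherits(spd, "spd_series"))
  if (!is.finite(k) || k <= 0) stop("scaling factor must be > 0")
  meta <- spd$meta
  prev <- if (is.null(meta$scaling_factor)) 1 else meta$scaling_factor
  meta$scaling_factor <- prev * k
  spd_series(spd$grid, spd$density * k, meta = meta)
}

series_on_grid <- function(x, gyears) {
  if (inherits(x, "spd_series")) {
    v <- numeric(length(gyears))
    common <- intersect(gyears, x$grid)
    v[match(common, gyears)] <- x$density[match(common, x$grid)]
    list(values = v, covered = gyears %in% x$grid)
  } else if (is.data.frame(x)) {
    ann <- annualize_population(x)
    v <- numeric(length(gyears))
    common <- intersect(gyears, ann$cal_bp)
    v[match(common, gyears)] <- ann$persons[match(common, ann$cal_bp)]
    list(values = v, covered = gyears %in% ann$cal_bp)
  } else {
    stop("comparison series must be an spd_series or a population ",
         "data frame")
  }
}

#' Descriptive comparison of two annual series
#'
#' Deterministic, descriptive statistics for comparing a density series
#' against another series or a population reconstruction over an overlap
#' window: per-century mean values, peak year, the first year of
#' sustained post-peak decline, and the sign-agreement fraction of
#' smoothed first differences. No hypothesis test is implied.
#'
#' Both series are restricted to the years of the overlap window covered
#' by both, smoothed with the given kernel, and differenced. "Sustained
#' decline" means the first post-peak year opening a run of at least
#' `run` consecutive negative first differences of the smoothed series.
#'
#' @param a An `spd_series`.
#' @param b An `spd_series` or a population data frame (`start_ad`,
#'   `end_ad`, `estimate`).
#' @param overlap A [cal_window].
#' @param window,sd Smoothing kernel used for the derivative-based
#'   statistics (defaults 21 and 5).
#' @param run Run length (years) defining sustained decline
#'   (default 20).
#' @return An object of class `spd_comparison`: list with `overlap`,
#'   `peak_year_ad` (named, both series), `peak_diff_years`,
#'   `decline_onset_ad`, `sign_agreement`, `century_means` (data frame),
#'   and `overlay` (data frame of the aligned annual values).
#' @export
compare_series <- function(a, b, overlap, window = 21, sd = 5, run = 20) {
  stopifnot(inherits(a, "spd_series"), inherits(overlap, "cal_window"))
  gyears <- overlap$end_bp:overlap$start_bp
  sa <- series_on_grid(a, gyears)
  sb <- series_on_grid(b, gyears)
  both <- sa$covered & sb$covered
  if (!any(both)) stop("series do not overlap inside the window")
  gyears <- gyears[both]
  va <- sa$values[both]
  vb <- sb$values[both]

  # orient time-forward: increasing year AD
  years_ad <- rev(bp_to_ad(gyears))
  va_ad <- rev(va)
  vb_ad <- rev(vb)
  ka <- smooth_vec(va_ad, window, sd)
  kb <- smooth_vec(vb_ad, window, sd)

  peak <- function(vals) {
    # ties toward older years: earliest AD year attaining the maximum
    years_ad[which.max(vals)]
  }
  pa <- peak(ka)
  pb <- peak(kb)

  da <- diff(ka)
  db <- diff(kb)
  nz <- abs(da) > 0 | abs(db) > 0
  agree <- if (any(nz)) mean(sign(da[nz]) == sign(db[nz])) else 1

  onset <- function(d, peak_ad) {
    # d[i] is the change entering year years_ad[i + 1]
    neg <- d < 0
    for (i in which(years_ad[-1] > peak_ad)) {
      j <- i:(i + run - 1)
      if (max(j) <= length(d) && all(neg[j])) return(years_ad[i + 1])
    }
    NA_real_
  }

  cent <- floor(years_ad / 100) * 100
  century_means <- data.frame(
    century_ad = sort(unique(cent)),
    mean_a = as.numeric(tapply(va_ad, cent, mean)),
    mean_b = as.numeric(tapply(vb_ad, cent, mean))
  )

  structure(list(
    overlap = overlap,
    peak_year_ad = c(a = pa, b = pb),
    peak_diff_years = abs(pa - pb),
    decline_onset_ad = c(a = onset(da, pa), b = onset(db, pb)),
    sign_agreement = agree,
    century_means = century_means,
    overlay = data.frame(cal_bp = gyears, year_ad = bp_to_ad(gyears),
                         a = va, b = vb)
  ), class = "spd_comparison")
}

smooth_vec <- function(x, window, sd) {
  s <- spd_series(seq_along(x), x)
  smooth_spd(s, window = window, sd = sd)$density
}

#' @export
print.spd_comparison <- function(x, ...) {
  cat("<spd_comparison>\n")
  cat(sprintf("  peak years (AD):      a = %g, b = %g (|diff| = %g yr)\n",
              x$peak_year_ad[["a"]], x$peak_year_ad[["b"]],
              x$peak_diff_years))
  cat(sprintf("  decline onset (AD):   a = %s, b = %s\n",
              format(x$decline_onset_ad[["a"]]),
              format(x$decline_onset_ad[["b"]])))
  cat(sprintf("  sign agreement:       %.3f\n", x$sign_agreement))
  invisible(x)
}
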