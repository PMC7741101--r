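# Synthetic study generator: a known demographic truth (boom-bust by
# default), sites with county labels, radiocarbon measurement noise via
# inverse calibration, tree-ring symbol conventions, and deliberate
# contaminants at known rates so filter audits have exact expectations.
#
# Simulation law: deposition of datable events is proportional to
# population ("dates as data"). Optional thinning (taphonomic loss,
# per-county sampling weights) can be layered on by the caller.

#' Population trajectory model
#'
#' `boom_bust` grows exponentially at `growth_rate` per year toward
#' `peak_level` at `peak_ad` (bounded below by `floor_level`, flat
#' before `rise_start_ad`), then declines exponentially at
#' `decline_rate` per year - the canonical rise-to-~AD 1300-then-
#' collapse trajectory. The default growth rate of 0.007/yr corresponds
#' to a population roughly quadrupling over the two centuries before
#' the peak, the order of magnitude reconstructed for late
#' Pueblo-period regional growth; the default decline of 0.01/yr
#' removes ~95% of the population over the three centuries after the
#' peak. `constant` is flat; `custom` passes a period table through.
#'
#' @param shape One of `"boom_bust"`, `"constant"`, `"custom"`.
#' @param rise_start_ad Year AD before which the level is held at the
#'   floor (default 500).
#' @param peak_ad Peak year AD (default 1300).
#' @param peak_level Population at the peak (persons, default 20000).
#' @param growth_rate Exponential growth rate per year up to the peak
#'   (default 0.007).
#' @param decline_rate Exponential decline rate per year after the peak
#'   (default 0.01).
#' @param floor_level Baseline population level (default 500).
#' @param level Constant level for `shape = "constant"`.
#' @param table Period data frame for `shape = "custom"` (`start_ad`,
#'   `end_ad`, `estimate`).
#' @return An object of class `population_model`.
#' @export
population_model <- function(shape = c("boom_bust", "constant", "custom"),
                             rise_start_ad = 500, peak_ad = 1300,
                             peak_level = 20000, growth_rate = 0.007,
                             decline_rate = 0.01,
                             floor_level = 500, level = 1000,
                             table = NULL) {
  shape <- match.arg(shape)
  if (shape == "custom" && is.null(table)) {
    stop("custom population model requires a period table")
  }
  if (peak_level < 0 || floor_level < 0 || level < 0) {
    stop("population levels must be >= 0")
  }
  if (growth_rate <= 0 || decline_rate <= 0) {
    stop("growth_rate and decline_rate must be > 0")
  }
  structure(list(shape = shape, rise_start_ad = rise_start_ad,
                 peak_ad = peak_ad, peak_level = peak_level,
                 growth_rate = growth_rate, decline_rate = decline_rate,
                 floor_level = floor_level, level = level, table = table),
            class = "population_model")
}

model_level <- function(model, year_ad) {
  switch(model$shape,
    constant = rep(model$level, length(year_ad)),
    boom_bust = {
      lvl <- numeric(length(year_ad))
      pre <- year_ad < model$rise_start_ad
      rise <- year_ad >= model$rise_start_ad & year_ad <= model$peak_ad
      post <- year_ad > model$peak_ad
      lvl[pre] <- model$floor_level
      lvl[rise] <- pmax(model$floor_level,
                        model$peak_level *
                          exp(-model$growth_rate *
                                (model$peak_ad - year_ad[rise])))
      lvl[post] <- pmax(model$floor_level,
                        model$peak_level *
                          exp(-model$decline_rate *
                                (year_ad[post] - model$peak_ad)))
      lvl
    },
    stop("model_level undefined for shape ", model$shape)
  )
}

#' Evaluate a population model on an annual grid
#'
#' @param model A [population_model].
#' @param span A [cal_window] giving the calendar span (cal BP).
#' @return An annual period data frame (`start_ad`, `end_ad`,
#'   `estimate`) with one-year periods, suitable for
#'   [annualize_population] and [scale_to_reference].
#' @export
population_curve <- function(model, span) {
  stopifnot(inherits(model, "population_model"), inherits(span, "cal_window"))
  years <- bp_to_ad(span$start_bp):bp_to_ad(span$end_bp)
  if (model$shape == "custom") {
    tab <- validate_population(model$table)
    ann <- annualize_population(tab)
    keep <- ann$year_ad %in% years
    return(data.frame(start_ad = ann$year_ad[keep],
                      end_ad = ann$year_ad[keep] + 1,
                      estimate = ann$persons[keep]))
  }
  data.frame(start_ad = years, end_ad = years + 1,
             estimate = model_level(model, years))
}

#' Aggregate an annual population series into coarse periods
#'
#' Emulates period-resolved reconstructions (periods of a few decades to
#' a century) by averaging an annual series over fixed-width periods.
#'
#' @param pop Annual period data frame (from [population_curve]).
#' @param period_length Period width in years (default 50).
#' @return Period data frame (`start_ad`, `end_ad`, `estimate`).
#' @export
aggregate_population <- function(pop, period_length = 50) {
  ann <- annualize_population(pop)
  brk <- floor((ann$year_ad - min(ann$year_ad)) / period_length)
  do.call(rbind, lapply(split(seq_len(nrow(ann)), brk), function(ix) {
    data.frame(start_ad = min(ann$year_ad[ix]),
               end_ad = max(ann$year_ad[ix]) + 1,
               estimate = mean(ann$persons[ix]))
  }))
}

#' Sample event years proportionally to population
#'
#' I.i.d. draws of calendar years with probability proportional to the
#' annual population level (the dates-as-data deposition premise).
#'
#' @param pop Annual period data frame (`start_ad`, `end_ad`,
#'   `estimate`).
#' @param n Number of events.
#' @param seed Optional integer seed for reproducibility; when `NULL`
#'   the current RNG state is used.
#' @return Integer vector of `n` calendar years AD.
#' @export
sample_event_years <- function(pop, n, seed = NULL) {
  if (n <= 0) stop("n must be > 0")
  if (!is.null(seed)) set.seed(seed)
  ann <- annualize_population(pop)
  if (sum(ann$persons) <= 0) stop("population is zero everywhere")
  sample(ann$year_ad, n, replace = TRUE, prob = ann$persons)
}

#' Simulate a radiocarbon measurement of a calendar year
#'
#' Inverse calibration: the measured 14C age is drawn from a Normal with
#' mean mu(ad_to_bp(year)) from the curve and standard deviation
#' sqrt(sigma_meas^2 + sigma_curve^2); the recorded error is
#' `sigma_meas`. Vectorized over years.
#'
#' @param year_ad Calendar year(s) AD within the curve span.
#' @param curve A [cal_curve].
#' @param sigma_meas Reported 1-sigma measurement error(s), > 0.
#' @return Data frame with columns `c14_age` (rounded to the year) and
#'   `sigma`.
#' @export
uncalibrate <- function(year_ad, curve, sigma_meas) {
  stopifnot(inherits(curve, "cal_curve"))
  bp <- ad_to_bp(year_ad)
  if (any(bp < min(curve$cal_bp) | bp > max(curve$cal_bp))) {
    stop("year outside calibration curve span")
  }
  if (any(sigma_meas < 0)) stop("sigma_meas must be >= 0")
  mu <- stats::approx(curve$cal_bp, curve$c14_age, xout = bp)$y
  sg <- stats::approx(curve$cal_bp, curve$sigma_curve, xout = bp)$y
  sd_tot <- sqrt(sigma_meas^2 + sg^2)
  age <- mu
  noisy <- sd_tot > 0
  age[noisy] <- stats::rnorm(sum(noisy), mu[noisy], sd_tot[noisy])
  data.frame(c14_age = round(age), sigma = rep(sigma_meas,
                                               length.out = length(bp)))
}

split_county_key <- function(keys) {
  parts <- strsplit(keys, ",")
  data.frame(
    county = trimws(vapply(parts, `[`, character(1), 1)),
    state = trimws(vapply(parts, function(p) {
      if (length(p) > 1) p[[2]] else ""
    }, character(1))),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study. Defaults describe the
#' study conditions used throughout the package's validation: a
#' boom-bust trajectory peaking at AD 1300, events over AD 600-1700,
#' measurement errors uniform on 20-80 14C years, a 2:1
#' cutting:near-cutting symbol mix, near-cutting offsets of 0-3 years,
#' and small known counts of each contaminant class.
#'
#' @param seed Integer RNG seed.
#' @param n_events Number of clean radiocarbon events.
#' @param n_treering_events Number of clean tree-ring events.
#' @param n_sites Number of sites receiving events.
#' @param one_site_per_event If `TRUE`, each event gets its own site, so
#'   every site-phase bin is a singleton (useful for calibration-style
#'   experiments where the number of site-phases must be exact).
#' @param span_ad Event span in years AD (default `c(600, 1700)`).
#' @param sigma_range Uniform range for measurement errors (14C yr).
#' @param symbol_mix Named probabilities over
#'   `c("cutting", "near_cutting")` for clean tree-ring records.
#' @param offset_range Integer range of near-cutting offsets in years
#'   (default `c(0, 3)`).
#' @param curve_type `"identity"` or `"wiggly"`.
#' @param wiggle List with `amplitude` and `period` for the wiggly
#'   curve.
#' @param model A [population_model] (the demographic truth).
#' @param regions A [region_config].
#' @param contaminants Named integer list: `non_archaeological`,
#'   `sigma_outlier`, `duplicate_conflict` (pairs; each pair removes two
#'   records), `exact_duplicate`, `out_of_area`, `out_of_window`,
#'   `noncutting_symbol`, `treering_out_of_area`,
#'   `treering_out_of_window`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_events = 500L,
                              n_treering_events = 500L,
                              n_sites = 150L,
                              one_site_per_event = FALSE,
                              span_ad = c(600, 1700),
                              sigma_range = c(20, 80),
                              symbol_mix = c(cutting = 2 / 3,
                                             near_cutting = 1 / 3),
                              offset_range = c(0, 3),
                              curve_type = c("identity", "wiggly"),
                              wiggle = list(amplitude = 20, period = 300),
                              model = population_model(),
                              regions = region_config(),
                              contaminants = list(
                                non_archaeological = 5L,
                                sigma_outlier = 10L,
                                duplicate_conflict = 4L,
                                exact_duplicate = 3L,
                                out_of_area = 6L,
                                out_of_window = 4L,
                                noncutting_symbol = 8L,
                                treering_out_of_area = 5L,
                                treering_out_of_window = 4L)) {
  curve_type <- match.arg(curve_type)
  stopifnot(n_events > 0, n_treering_events > 0, n_sites > 0)
  stopifnot(length(offset_range) == 2,
            offset_range[1] >= 0, offset_range[2] <= 3,
            offset_range[1] <= offset_range[2])
  if (abs(sum(symbol_mix) - 1) > 1e-9) {
    stop("symbol_mix probabilities must sum to 1")
  }
  defaults <- list(non_archaeological = 0L, sigma_outlier = 0L,
                   duplicate_conflict = 0L, exact_duplicate = 0L,
                   out_of_area = 0L, out_of_window = 0L,
                   noncutting_symbol = 0L, treering_out_of_area = 0L,
                   treering_out_of_window = 0L)
  defaults[names(contaminants)] <- contaminants
  if (any(unlist(defaults) < 0)) stop("contaminant counts must be >= 0")
  structure(list(seed = as.integer(seed), n_events = n_events,
                 n_treering_events = n_treering_events, n_sites = n_sites,
                 one_site_per_event = one_site_per_event,
                 span_ad = span_ad, sigma_range = sigma_range,
                 symbol_mix = symbol_mix, offset_range = offset_range,
                 curve_type = curve_type, wiggle = wiggle, model = model,
                 regions = regions, contaminants = defaults),
            class = "simulation_config")
}

make_site_roster <- function(config, n_sites, prefix = "S") {
  counties <- config$regions$regions[[config$regions$study_region]]
  cs <- split_county_key(counties)
  pick <- sample.int(nrow(cs), n_sites, replace = TRUE)
  data.frame(site_id = sprintf("%s%04d", prefix, seq_len(n_sites)),
             county = cs$county[pick], state = cs$state[pick],
             stringsAsFactors = FALSE)
}

#' Build tree-ring records from event years
#'
#' Cutting dates record the event year exactly; near-cutting dates
#' subtract a uniform integer offset in `offset_range` (the outermost
#' preserved ring predates the death year by 0-3 years); symbols are
#' drawn from `symbol_mix`. Sites and counties come from `roster`.
#'
#' @param events Integer vector of true event years AD.
#' @param config A [simulation_config].
#' @param roster Site roster data frame (`site_id`, `county`, `state`);
#'   defaults to a fresh roster drawn from the study counties.
#' @return Tree-ring record data frame (`site_id`, `county`, `state`,
#'   `year_ad`, `symbol`, plus `true_year_ad`).
#' @export
make_treering_records <- function(events, config, roster = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- length(events)
  if (is.null(roster)) {
    roster <- make_site_roster(config, if (config$one_site_per_event) n
                               else config$n_sites, prefix = "T")
  }
  site_ix <- if (config$one_site_per_event) seq_len(n) else
    sample.int(nrow(roster), n, replace = TRUE)
  cls <- sample(names(config$symbol_mix), n, replace = TRUE,
                prob = config$symbol_mix)
  cutting_symbols <- c("B", "G", "L", "c", "r", "B+", "G+", "L+", "c+", "r+")
  symbol <- character(n)
  symbol[cls == "cutting"] <- sample(cutting_symbols,
                                     sum(cls == "cutting"), replace = TRUE)
  symbol[cls == "near_cutting"] <- sample(c("v", "v+"),
                                          sum(cls == "near_cutting"),
                                          replace = TRUE)
  offset <- integer(n)
  nc <- cls == "near_cutting"
  if (any(nc)) {
    offset[nc] <- sample(seq(config$offset_range[1], config$offset_range[2]),
                         sum(nc), replace = TRUE)
  }
  data.frame(site_id = roster$site_id[site_ix],
             county = roster$county[site_ix],
             state = roster$state[site_ix],
             year_ad = as.integer(events - offset),
             symbol = symbol,
             true_year_ad = as.integer(events),
             stringsAsFactors = FALSE)
}

#' Build radiocarbon records from event years
#'
#' Measurement errors are uniform on `config$sigma_range` (rounded to
#' the 14C year) and ages come from [uncalibrate] against `curve`.
#'
#' Clean records carry a pass-the-filters guarantee so that filter
#' audits on synthetic studies have exact expectations: measurements
#' whose (age, error) pair would trip the precision thresholds
#' (error above 300 14C yr or above 25% of the age) or whose
#' calibrated mode would fall outside the 1750-150 BP study window are
#' redrawn for the same true event year, emulating a laboratory
#' re-measurement.
#'
#' @param events Integer vector of true event years AD.
#' @param config A [simulation_config].
#' @param curve A [cal_curve].
#' @param roster Optional site roster (as in [make_treering_records]).
#' @param lab_prefix Prefix for generated laboratory numbers.
#' @return Radiocarbon record data frame (`lab_number`, `site_id`,
#'   `county`, `state`, `c14_age`, `sigma`, `is_archaeological`, plus
#'   `true_year_ad`).
#' @export
make_radiocarbon_records <- function(events, config, curve, roster = NULL,
                                     lab_prefix = "LAB") {
  stopifnot(inherits(config, "simulation_config"))
  n <- length(events)
  if (is.null(roster)) {
    roster <- make_site_roster(config, if (config$one_site_per_event) n
                               else config$n_sites, prefix = "R")
  }
  site_ix <- if (config$one_site_per_event) seq_len(n) else
    sample.int(nrow(roster), n, replace = TRUE)
  sigma <- round(stats::runif(n, config$sigma_range[1],
                              config$sigma_range[2]))
  meas <- uncalibrate(events, curve, sigma)
  # pass-the-filters guarantee for clean records (see Details)
  win <- config$regions$window
  margin <- if (config$curve_type == "wiggly") {
    2 * config$wiggle$amplitude
  } else {
    0
  }
  lo <- win$end_bp + margin
  hi <- win$start_bp - margin
  for (iter in 1:100) {
    bad <- meas$sigma > 300 | meas$sigma > 0.25 * meas$c14_age |
      meas$c14_age < lo | meas$c14_age > hi
    if (!any(bad)) break
    sigma[bad] <- round(stats::runif(sum(bad), config$sigma_range[1],
                                     config$sigma_range[2]))
    meas[bad, ] <- uncalibrate(events[bad], curve, sigma[bad])
  }
  data.frame(lab_number = sprintf("%s-%05d", lab_prefix, seq_len(n)),
             site_id = roster$site_id[site_ix],
             county = roster$county[site_ix],
             state = roster$state[site_ix],
             c14_age = meas$c14_age,
             sigma = meas$sigma,
             is_archaeological = TRUE,
             true_year_ad = as.integer(events),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Produces the four pipeline inputs - radiocarbon table, tree-ring
#' table, reference population series, calibration curve - from a known
#' demographic truth, plus exact bookkeeping of every injected
#' contaminant so filter reports have known expectations. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [simulation_config].
#' @param outdir Optional directory; when given, the CSV dialects are
#'   written there (`radiocarbon.csv`, `treering.csv`,
#'   `population.csv`, `curve.txt`).
#' @return An object of class `synthetic_study`: list with `radiocarbon`
#'   and `treering` record tables, `population` (period-resolved
#'   reference), `population_annual` (annual truth), `curve`,
#'   and `truth` (config echo, event years, expected per-rule filter
#'   counts).
#' @export
generate_study <- function(config = simulation_config(), outdir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  span <- cal_window(ad_to_bp(config$span_ad[1]),
                     ad_to_bp(config$span_ad[2]))
  curve <- switch(config$curve_type,
                  identity = identity_curve(-100, 3500),
                  wiggly = wiggly_curve(-100, 3500,
                                        amplitude = config$wiggle$amplitude,
                                        period = config$wiggle$period))
  pop <- population_curve(config$model, span)
  cont <- config$contaminants
  counties <- config$regions$regions[[config$regions$study_region]]

  # --- radiocarbon: clean events -------------------------------------
  ev_rc <- sample_event_years(pop, config$n_events)
  rc <- make_radiocarbon_records(ev_rc, config, curve)

  clean_like <- function(n, prefix) {
    if (n == 0) return(rc[0, , drop = FALSE])
    ev <- sample_event_years(pop, n)
    make_radiocarbon_records(ev, config, curve, lab_prefix = prefix)
  }

  extra <- list()
  # removed at rule 1: otherwise-clean but flagged non-archaeological
  na_rec <- clean_like(cont$non_archaeological, "NAT")
  if (nrow(na_rec)) na_rec$is_archaeological <- FALSE
  extra$non_archaeological <- na_rec
  # removed at rule 2: 1-sigma error beyond 300 14C years
  so <- clean_like(cont$sigma_outlier, "BIG")
  if (nrow(so)) so$sigma <- round(stats::runif(nrow(so), 301, 400))
  extra$sigma_outlier <- so
  # removed at rule 3: shared lab number, conflicting county
  if (cont$duplicate_conflict > 0) {
    a <- clean_like(cont$duplicate_conflict, "DUP")
    b <- a
    cs <- split_county_key(counties)
    for (i in seq_len(nrow(b))) {
      alt <- which(cs$county != a$county[i] | cs$state != a$state[i])
      pick <- alt[1 + (i - 1) %% length(alt)]
      b$county[i] <- cs$county[pick]
      b$state[i] <- cs$state[pick]
    }
    extra$duplicate_conflict <- rbind(a, b)
  }
  # collapsed at rule 3: byte-identical duplicate of a clean record
  if (cont$exact_duplicate > 0) {
    extra$exact_duplicate <- rc[sample.int(nrow(rc),
                                           cont$exact_duplicate), ,
                                drop = FALSE]
  }
  # removed at rule 4: county outside the study roster
  oa <- clean_like(cont$out_of_area, "OOA")
  if (nrow(oa)) {
    out_counties <- split_county_key(c("Maricopa, AZ", "Pinal, AZ",
                                       "Pima, AZ"))
    pick <- sample.int(nrow(out_counties), nrow(oa), replace = TRUE)
    oa$county <- out_counties$county[pick]
    oa$state <- out_counties$state[pick]
  }
  extra$out_of_area <- oa
  # removed at rule 5: far too old for the study window
  ow <- clean_like(cont$out_of_window, "OLD")
  if (nrow(ow)) {
    ow$c14_age <- round(stats::runif(nrow(ow), 2800, 3200))
    ow$sigma <- pmin(ow$sigma, 50)
  }
  extra$out_of_window <- ow

  radiocarbon <- do.call(rbind, c(list(rc), unname(extra)))
  radiocarbon <- radiocarbon[sample.int(nrow(radiocarbon)), , drop = FALSE]
  rownames(radiocarbon) <- NULL

  # --- tree-ring ------------------------------------------------------
  ev_tr <- sample_event_years(pop, config$n_treering_events)
  tr <- make_treering_records(ev_tr, config)
  tr_extra <- list()
  tr_like <- function(n) {
    if (n == 0) return(tr[0, , drop = FALSE])
    make_treering_records(sample_event_years(pop, n), config)
  }
  ns <- tr_like(cont$noncutting_symbol)
  if (nrow(ns)) ns$symbol <- sample(c("vv", "++", "inc"), nrow(ns),
                                    replace = TRUE)
  tr_extra$noncutting_symbol <- ns
  ta <- tr_like(cont$treering_out_of_area)
  if (nrow(ta)) {
    ta$county <- "Maricopa"
    ta$state <- "AZ"
  }
  tr_extra$treering_out_of_area <- ta
  tw <- tr_like(cont$treering_out_of_window)
  if (nrow(tw)) {
    tw$year_ad <- sample(c(1850L, 1900L, 150L, 100L), nrow(tw),
                         replace = TRUE)
  }
  tr_extra$treering_out_of_window <- tw
  treering <- do.call(rbind, c(list(tr), unname(tr_extra)))
  treering <- treering[sample.int(nrow(treering)), , drop = FALSE]
  rownames(treering) <- NULL

  truth <- list(
    config = config,
    event_years_rc = ev_rc,
    event_years_tr = ev_tr,
    expected_radiocarbon_report = list(
      input_n = nrow(radiocarbon),
      removed = list(non_archaeological = cont$non_archaeological,
                     error_threshold = cont$sigma_outlier,
                     duplicate_conflict = 2L * cont$duplicate_conflict,
                     out_of_area = cont$out_of_area,
                     window_overlap = cont$out_of_window),
      deduplicated = cont$exact_duplicate,
      retained_n = config$n_events),
    expected_treering_report = list(
      input_n = nrow(treering),
      removed = list(non_cutting_symbol = cont$noncutting_symbol,
                     out_of_area = cont$treering_out_of_area,
                     out_of_window = cont$treering_out_of_window),
      deduplicated = 0L,
      retained_n = config$n_treering_events)
  )

  study <- structure(list(radiocarbon = radiocarbon, treering = treering,
                          population = aggregate_population(pop),
                          population_annual = pop,
                          curve = curve, truth = truth),
                     class = "synthetic_study")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_radiocarbon_csv(radiocarbon, file.path(outdir, "radiocarbon.csv"))
    write_treering_csv(treering, file.path(outdir, "treering.csv"))
    utils::write.csv(study$population, file.path(outdir, "population.csv"),
                     row.names = FALSE)
    utils::write.table(
      data.frame(curve$cal_bp, curve$c14_age, curve$sigma_curve),
      file.path(outdir, "curve.txt"),
      sep = ",", row.names = FALSE, col.names = FALSE)
  }
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_study> %d radiocarbon records, ",
                     "%d tree-ring records (seed %d)\n"),
              nrow(x$radiocarbon), nrow(x$treering),
              x$truth$config$seed))
  invisible(x)
}
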