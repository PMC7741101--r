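# Cleaning rules for radiocarbon and tree-ring date tables, calendar
# conversions, and county-based study-region assignment, with per-rule
# audit trails.

#' Convert calendar years AD to calendar years BP
#'
#' BP = 1950 - AD, with astronomical year numbering for BC dates (year 0
#' exists), so AD 201 -> 1749 BP and AD 1798 -> 152 BP.
#'
#' @param year_ad Integer calendar year(s) AD (astronomical numbering).
#' @return Calendar year(s) BP.
#' @examples
#' ad_to_bp(c(201, 1798, 1950))
#' @export
ad_to_bp <- function(year_ad) 1950 - year_ad

#' Convert calendar years BP to calendar years AD
#'
#' Inverse of [ad_to_bp].
#'
#' @param cal_bp Calendar year(s) BP.
#' @return Calendar year(s) AD (astronomical numbering).
#' @export
bp_to_ad <- function(cal_bp) 1950 - cal_bp

#' Classify a tree-ring date symbol
#'
#' Dendrochronological convention: 'B', 'G', 'L', 'c' or 'r' symbols
#' (with or without a trailing '+') mark cutting dates, where the
#' outermost ring records the death year of the tree exactly; 'v' and
#' 'v+' mark near-cutting dates, within 0-3 years of the true outer
#' ring; every other symbol (e.g. 'vv') gives no such guarantee.
#'
#' @param symbol Character vector of symbol codes.
#' @return Character vector over `{"cutting", "near_cutting", "other"}`;
#'   every input maps to exactly one class.
#' @examples
#' classify_treering_symbol(c("r", "G+", "v+", "vv"))
#' @export
classify_treering_symbol <- function(symbol) {
  symbol <- trimws(as.character(symbol))
  out <- rep("other", length(symbol))
  out[grepl("^(B|G|L|c|r)\\+?$", symbol)] <- "cutting"
  out[symbol %in% c("v", "v+")] <- "near_cutting"
  out
}

#' Normalize a county key
#'
#' Case-folds, trims, and collapses internal whitespace so that county
#' joins are deterministic. A county key is the string
#' `"<county>, <state>"` (e.g. `"Montezuma, CO"`).
#'
#' @param x Character vector of county keys.
#' @return Normalized keys.
#' @export
normalize_county <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

county_key <- function(county, state = NULL) {
  county <- as.character(county)
  if (!is.null(state) && any(nzchar(trimws(state)))) {
    has_state <- nzchar(trimws(state))
    county[has_state] <- paste(trimws(county[has_state]),
                               trimws(state[has_state]), sep = ", ")
  }
  normalize_county(county)
}

#' Study-region configuration
#'
#' Maps region names to county rosters and carries the study window and
#' period of interest. Defaults follow the Upland US Southwest (UUSW)
#' study design: the Central Mesa Verde (CMV) region is approximated by
#' Montezuma county, Colorado; the Northern Rio Grande (NRG) by Los
#' Alamos, Rio Arriba, Sandoval, Santa Fe and Taos counties, New Mexico;
#' the UUSW roster is the full study-county list (configuration data, as
#' county membership derives from a GIS overlay outside this package's
#' scope). Regions may nest: a county can belong to several regions.
#'
#' @param regions Named list of character vectors of county keys
#'   (`"County, ST"`).
#' @param window Study window as a [cal_window] (default 1750-150 BP).
#' @param period_ad Period of interest in years AD (default
#'   `c(200, 1800)`).
#' @param study_region Name of the region whose roster defines "in the
#'   study area" for county trimming (default `"UUSW"`).
#' @return An object of class `region_config`.
#' @export
region_config <- function(regions = NULL,
                          window = cal_window(1750, 150),
                          period_ad = c(200, 1800),
                          study_region = "UUSW") {
  if (is.null(regions)) {
    cmv <- "Montezuma, CO"
    nrg <- c("Los Alamos, NM", "Rio Arriba, NM", "Sandoval, NM",
             "Santa Fe, NM", "Taos, NM")
    other <- c("Apache, AZ", "Coconino, AZ", "Navajo, AZ",
               "La Plata, CO", "Archuleta, CO", "Dolores, CO",
               "McKinley, NM", "Cibola, NM", "San Juan, NM",
               "San Juan, UT", "Grand, UT")
    regions <- list(UUSW = c(cmv, nrg, other), CMV = cmv, NRG = nrg)
  }
  stopifnot(is.list(regions), length(regions) > 0,
            !is.null(names(regions)), all(nzchar(names(regions))))
  if (any(vapply(regions, length, integer(1)) == 0)) {
    stop("region county lists must be non-empty")
  }
  stopifnot(inherits(window, "cal_window"))
  if (!study_region %in% names(regions)) {
    stop("study_region '", study_region, "' is not a configured region")
  }
  structure(list(regions = regions, window = window,
                 period_ad = period_ad, study_region = study_region),
            class = "region_config")
}

#' Assign a record's county to study regions
#'
#' @param county County key (`"County, ST"`), or a record-like list /
#'   one-row data.frame with `county` (and optionally `state`) fields.
#' @param config A [region_config].
#' @return Character vector of region names whose roster contains the
#'   county (possibly several: regions may nest). Unknown counties match
#'   no region and raise a warning.
#' @examples
#' cfg <- region_config()
#' assign_region("Montezuma, CO", cfg)
#' @export
assign_region <- function(county, config) {
  stopifnot(inherits(config, "region_config"))
  if (is.list(county) || is.data.frame(county)) {
    key <- county_key(county$county, county$state)
  } else {
    key <- normalize_county(county)
  }
  stopifnot(length(key) == 1)
  hit <- vapply(config$regions,
                function(cl) key %in% normalize_county(cl), logical(1))
  if (!any(hit) && nzchar(key)) {
    warning("county '", key, "' is not in any configured region")
  }
  names(config$regions)[hit]
}

record_region_mask <- function(county, state, region_counties) {
  county_key(county, state) %in% normalize_county(region_counties)
}

new_filter_report <- function(rules, input_n) {
  structure(list(input_n = input_n,
                 removed = stats::setNames(rep(0L, length(rules)), rules),
                 deduplicated = 0L,
                 retained_n = input_n),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> input %d -> retained %d\n",
              x$input_n, x$retained_n))
  for (r in names(x$removed)) {
    cat(sprintf("  removed by %-22s %d\n", paste0(r, ":"), x$removed[[r]]))
  }
  if (x$deduplicated > 0) {
    cat(sprintf("  deduplicated:                  %d\n", x$deduplicated))
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report A `filter_report` as returned by [filter_radiocarbon]
#'   or [filter_treering].
#' @param path Optional output path; if `NULL`, returns the JSON string.
#' @return The JSON string (invisibly, if written to `path`).
#' @export
filter_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  j <- jsonlite::toJSON(list(input_n = report$input_n,
                             removed = as.list(report$removed),
                             deduplicated = report$deduplicated,
                             retained_n = report$retained_n),
                        auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(j)
}

#' Clean a radiocarbon date table
#'
#' Applies the cleaning rules in fixed order: (1) drop non-archaeological
#' dates; (2) drop imprecise dates, those with 1-sigma errors above 300
#' 14C years and/or above 25% of the uncalibrated age (see `error_rule`);
#' (3) resolve duplicate laboratory numbers - records whose age, error
#' and county all match are collapsed to one (counted as deduplicated),
#' while conflicting duplicates are removed entirely; (4) trim to
#' counties in the study area; (5) keep dates whose 95% calibrated
#' highest-density region overlaps the study window.
#'
#' @param records Data frame with columns `lab_number`, `site_id`,
#'   `county` (optionally `state`), `c14_age`, `sigma`,
#'   `is_archaeological`.
#' @param curve A [cal_curve] (interpolated to an annual grid if needed).
#' @param config A [region_config].
#' @param error_rule `"either"` (default: either threshold alone removes)
#'   or `"both"` (only dates failing both thresholds are removed).
#' @param level Coverage level for the window-overlap rule
#'   (default 0.95).
#' @return A list with `records` (retained rows), `report` (a
#'   `filter_report` with per-rule removal counts in application order)
#'   and `densities` (calibrated [cal_density] objects for retained
#'   records, named by `lab_number`, reusable downstream).
#' @export
filter_radiocarbon <- function(records, curve, config,
                               error_rule = c("either", "both"),
                               level = 0.95) {
  error_rule <- match.arg(error_rule)
  stopifnot(inherits(config, "region_config"))
  rules <- c("non_archaeological", "error_threshold", "duplicate_conflict",
             "out_of_area", "window_overlap")
  rep_ <- new_filter_report(rules, nrow(records))
  if (nrow(records) == 0) {
    return(list(records = records, report = rep_,
                densities = list()))
  }
  stopifnot(all(c("lab_number", "site_id", "county", "c14_age", "sigma",
                  "is_archaeological") %in% names(records)))
  if (any(!nzchar(trimws(records$lab_number)))) {
    stop("lab_number must be non-empty for every record")
  }
  if (any(records$sigma <= 0)) stop("sigma must be > 0 for every record")
  if (!is_annual(curve)) curve <- interpolate_curve(curve)

  df <- records
  # 1. non-archaeological
  keep <- as.logical(df$is_archaeological)
  rep_$removed[["non_archaeological"]] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  # 2. error thresholds
  abs_bad <- df$sigma > 300
  rel_bad <- df$sigma > 0.25 * df$c14_age
  bad <- if (error_rule == "either") abs_bad | rel_bad else abs_bad & rel_bad
  rep_$removed[["error_threshold"]] <- sum(bad)
  df <- df[!bad, , drop = FALSE]

  # 3. duplicate laboratory numbers
  if (nrow(df) > 0) {
    key <- df$lab_number
    ckey <- county_key(df$county, df$state)
    drop_conflict <- logical(nrow(df))
    drop_dup <- logical(nrow(df))
    for (g in split(seq_len(nrow(df)), key)) {
      if (length(g) < 2) next
      same <- length(unique(df$c14_age[g])) == 1 &&
        length(unique(df$sigma[g])) == 1 &&
        length(unique(ckey[g])) == 1
      if (same) {
        drop_dup[g[-1]] <- TRUE
      } else {
        drop_conflict[g] <- TRUE
      }
    }
    rep_$removed[["duplicate_conflict"]] <- sum(drop_conflict)
    rep_$deduplicated <- sum(drop_dup)
    df <- df[!(drop_conflict | drop_dup), , drop = FALSE]
  }

  # 4. county trim to the study area
  if (nrow(df) > 0) {
    in_area <- record_region_mask(df$county, df$state,
                                  config$regions[[config$study_region]])
    rep_$removed[["out_of_area"]] <- sum(!in_area)
    df <- df[in_area, , drop = FALSE]
  }

  # 5. calibrated-window overlap
  densities <- list()
  if (nrow(df) > 0) {
    ok <- logical(nrow(df))
    dens <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      d <- tryCatch(calibrate(df$c14_age[i], df$sigma[i], curve),
                    error = function(e) NULL)
      if (!is.null(d) &&
          overlaps_window(hpd_region(d, level), config$window)) {
        ok[i] <- TRUE
        dens[[i]] <- d
      }
    }
    rep_$removed[["window_overlap"]] <- sum(!ok)
    densities <- stats::setNames(dens[ok], df$lab_number[ok])
    df <- df[ok, , drop = FALSE]
  }

  rep_$retained_n <- nrow(df)
  list(records = df, report = rep_, densities = densities)
}

#' Clean a tree-ring date table
#'
#' Keeps records whose symbol classifies as a cutting or near-cutting
#' date, whose county lies in the study area, and whose calendar year
#' falls inside the study window (closed bounds, in cal BP).
#'
#' @param records Data frame with columns `site_id`, `county`
#'   (optionally `state`), `year_ad`, `symbol`.
#' @param config A [region_config].
#' @return A list with `records` (retained rows) and `report` (a
#'   `filter_report`).
#' @export
filter_treering <- function(records, config) {
  stopifnot(inherits(config, "region_config"))
  rules <- c("non_cutting_symbol", "out_of_area", "out_of_window")
  rep_ <- new_filter_report(rules, nrow(records))
  if (nrow(records) == 0) {
    return(list(records = records, report = rep_))
  }
  stopifnot(all(c("site_id", "county", "year_ad", "symbol")
                %in% names(records)))
  df <- records
  cls <- classify_treering_symbol(df$symbol)
  keep <- cls %in% c("cutting", "near_cutting")
  rep_$removed[["non_cutting_symbol"]] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  if (nrow(df) > 0) {
    in_area <- record_region_mask(df$county, df$state,
                                  config$regions[[config$study_region]])
    rep_$removed[["out_of_area"]] <- sum(!in_area)
    df <- df[in_area, , drop = FALSE]
  }

  if (nrow(df) > 0) {
    bp <- ad_to_bp(df$year_ad)
    in_win <- bp >= config$window$end_bp & bp <= config$window$start_bp
    rep_$removed[["out_of_window"]] <- sum(!in_win)
    df <- df[in_win, , drop = FALSE]
  }

  rep_$retained_n <- nrow(df)
  list(records = df, report = rep_)
}

#' Read a radiocarbon date table (CSV dialect)
#'
#' Columns: `lab_number, site_id, county, state, c14_age_bp, sigma,
#' is_archaeological`.
#'
#' @param path CSV file path.
#' @return Data frame with internal column names (`c14_age` for
#'   `c14_age_bp`).
#' @export
read_radiocarbon_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lab_number", "site_id", "county", "state", "c14_age_bp",
            "sigma", "is_archaeological")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("radiocarbon CSV missing columns: ", paste(miss, collapse = ", "))
  }
  names(df)[names(df) == "c14_age_bp"] <- "c14_age"
  df$is_archaeological <- as.logical(df$is_archaeological)
  df
}

#' Write a radiocarbon date table (CSV dialect)
#'
#' @param records Radiocarbon data frame (internal column names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_radiocarbon_csv <- function(records, path) {
  out <- records
  names(out)[names(out) == "c14_age"] <- "c14_age_bp"
  cols <- c("lab_number", "site_id", "county", "state", "c14_age_bp",
            "sigma", "is_archaeological")
  utils::write.csv(out[, intersect(cols, names(out)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a tree-ring date table (CSV dialect)
#'
#' Columns: `site_id, county, state, year_ad, symbol`.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_treering_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "county", "state", "year_ad", "symbol")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("tree-ring CSV missing columns: ", paste(miss, collapse = ", "))
  }
  df
}

#' Write a tree-ring date table (CSV dialect)
#'
#' @param records Tree-ring data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_treering_csv <- function(records, path) {
  cols <- c("site_id", "county", "state", "year_ad", "symbol")
  utils::write.csv(records[, intersect(cols, names(records)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a period-resolved population series (CSV dialect)
#'
#' Columns: `start_ad, end_ad, estimate` - non-overlapping, ordered
#' periods with population estimates in persons, treated as
#' piecewise-constant over `[start_ad, end_ad)`.
#'
#' @param path CSV file path.
#' @return Data frame with the three columns, validated.
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_ad", "end_ad", "estimate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("population CSV missing columns: ", paste(miss, collapse = ", "))
  }
  validate_population(df)
}

validate_population <- function(pop) {
  stopifnot(all(c("start_ad", "end_ad", "estimate") %in% names(pop)))
  pop <- pop[order(pop$start_ad), , drop = FALSE]
  if (any(pop$end_ad <= pop$start_ad)) {
    stop("population periods must have end_ad > start_ad")
  }
  if (nrow(pop) > 1 && any(pop$start_ad[-1] < pop$end_ad[-nrow(pop)])) {
    stop("population periods must not overlap")
  }
  if (any(pop$estimate < 0)) stop("population estimates must be >= 0")
  pop
}
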