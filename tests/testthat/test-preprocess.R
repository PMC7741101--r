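test_that("AD/BP conversion anchors at 1950 with astronomical numbering", {
  expect_equal(ad_to_bp(201), 1749)
  expect_equal(ad_to_bp(1798), 152)
  expect_equal(ad_to_bp(1950), 0)
  expect_equal(ad_to_bp(0), 1950)       # year 0 exists
  expect_equal(bp_to_ad(ad_to_bp(-309)), -309)
})

test_that("tree-ring symbols classify per the cutting/near-cutting convention", {
  expect_equal(classify_treering_symbol(c("r", "G+", "B", "L+", "c")),
               rep("cutting", 5))
  expect_equal(classify_treering_symbol(c("v", "v+")),
               rep("near_cutting", 2))
  expect_equal(classify_treering_symbol(c("vv", "v++", "inc", "", "R")),
               rep("other", 5))
  # totality: every string maps to exactly one class
  set.seed(3)
  pool <- c("B", "G", "L", "c", "r", "v", "+", "x", "")
  rand <- replicate(200, paste(sample(pool, sample(0:3, 1), replace = TRUE),
                               collapse = ""))
  cls <- classify_treering_symbol(rand)
  expect_true(all(cls %in% c("cutting", "near_cutting", "other")))
  expect_length(cls, 200)
})

test_that("error thresholds remove imprecise dates under either/both modes", {
  crv <- identity_curve(0, 3000)
  cfg <- region_config()
  base <- clean_rc_table(4)

  r1 <- rbind(base, within(base[1, ], {
    lab_number <- "X-1"; c14_age <- 2000; sigma <- 301
  }))
  out <- filter_radiocarbon(r1, crv, cfg)
  expect_equal(out$report$removed[["error_threshold"]], 1)
  expect_equal(nrow(out$records), 4)

  r2 <- rbind(base, within(base[1, ], {
    lab_number <- "X-2"; c14_age <- 400; sigma <- 120
  }))
  out2 <- filter_radiocarbon(r2, crv, cfg)
  expect_equal(out2$report$removed[["error_threshold"]], 1)

  # under "both", sigma = 301 with age 2000 fails only the absolute arm
  out3 <- filter_radiocarbon(r1, crv, cfg, error_rule = "both")
  expect_equal(out3$report$removed[["error_threshold"]], 0)
  expect_equal(nrow(out3$records), 5)
})

test_that("duplicate lab numbers deduplicate when matching, drop when conflicting", {
  crv <- identity_curve(0, 3000)
  cfg <- region_config()
  base <- clean_rc_table(4)
  conflict_a <- within(base[1, ], { lab_number <- "DUP-1"; site_id <- "S90" })
  conflict_b <- within(conflict_a, { county <- "Taos"; state <- "NM" })
  match_a <- within(base[2, ], { lab_number <- "DUP-2"; site_id <- "S91" })
  match_b <- match_a
  tab <- rbind(base, conflict_a, conflict_b, match_a, match_b)
  expect_equal(nrow(tab), 8)

  out <- filter_radiocarbon(tab, crv, cfg)
  # hand audit: 4 clean singles + 1 deduplicated survivor
  expect_equal(out$report$removed[["duplicate_conflict"]], 2)
  expect_equal(out$report$deduplicated, 1)
  expect_equal(nrow(out$records), 5)
  expect_true("DUP-2" %in% out$records$lab_number)
  expect_false("DUP-1" %in% out$records$lab_number)
})

test_that("filter audit conserves counts, is idempotent and order-insensitive", {
  crv <- identity_curve(0, 3500)
  cfg <- region_config()
  st <- generate_study(simulation_config(seed = 5, n_events = 60,
                                         n_treering_events = 40))
  out <- filter_radiocarbon(st$radiocarbon, crv, cfg)
  expect_equal(out$report$retained_n + sum(out$report$removed) +
                 out$report$deduplicated,
               out$report$input_n)

  again <- filter_radiocarbon(out$records, crv, cfg)
  expect_equal(sum(again$report$removed) + again$report$deduplicated, 0)
  expect_equal(nrow(again$records), nrow(out$records))

  perm <- st$radiocarbon[sample.int(nrow(st$radiocarbon)), , drop = FALSE]
  out_p <- filter_radiocarbon(perm, crv, cfg)
  expect_setequal(out_p$records$lab_number, out$records$lab_number)

  tr <- filter_treering(st$treering, cfg)
  expect_equal(tr$report$retained_n + sum(tr$report$removed),
               tr$report$input_n)
  tr2 <- filter_treering(tr$records, cfg)
  expect_equal(sum(tr2$report$removed), 0)
})

test_that("empty input yields an empty result with a zeroed report", {
  crv <- identity_curve(0, 3000)
  cfg <- region_config()
  out <- filter_radiocarbon(clean_rc_table(0), crv, cfg)
  expect_equal(out$report$input_n, 0)
  expect_equal(sum(out$report$removed), 0)
  expect_equal(nrow(out$records), 0)
})

test_that("tree-ring filtering applies symbol, area and window rules", {
  cfg <- region_config()
  tab <- data.frame(
    site_id = c("A", "B", "C", "D"),
    county = c("Montezuma", "Taos", "Montezuma", "Maricopa"),
    state = c("CO", "NM", "CO", "AZ"),
    year_ad = c(1400, 1798, 1850, 1400),
    symbol = c("vv", "r", "v", "r"),
    stringsAsFactors = FALSE
  )
  out <- filter_treering(tab, cfg)
  expect_equal(out$report$removed[["non_cutting_symbol"]], 1)  # A
  expect_equal(out$report$removed[["out_of_area"]], 1)         # D
  expect_equal(out$report$removed[["out_of_window"]], 1)       # C: 100 BP
  expect_equal(out$records$site_id, "B")                       # 152 BP kept
})

test_that("counties map to nested study regions deterministically", {
  cfg <- region_config()
  expect_setequal(assign_region("Montezuma, CO", cfg), c("UUSW", "CMV"))
  expect_setequal(assign_region("Taos, NM", cfg), c("UUSW", "NRG"))
  expect_warning(r <- assign_region("Maricopa, AZ", cfg), "not in any")
  expect_length(r, 0)
  # record-style input and case/whitespace normalization
  expect_setequal(assign_region(list(county = "montezuma ", state = " co"),
                                cfg),
                  c("UUSW", "CMV"))
  expect_equal(normalize_county("  Rio   Arriba, NM "), "rio arriba, nm")
})

test_that("CSV dialects round-trip", {
  st <- generate_study(simulation_config(seed = 2, n_events = 20,
                                         n_treering_events = 15,
                                         contaminants = no_contaminants()))
  d <- withr::local_tempdir()
  write_radiocarbon_csv(st$radiocarbon, file.path(d, "rc.csv"))
  rc <- read_radiocarbon_csv(file.path(d, "rc.csv"))
  expect_equal(rc$c14_age, st$radiocarbon$c14_age)
  expect_equal(rc$lab_number, st$radiocarbon$lab_number)
  expect_type(rc$is_archaeological, "logical")

  write_treering_csv(st$treering, file.path(d, "tr.csv"))
  tr <- read_treering_csv(file.path(d, "tr.csv"))
  expect_equal(tr$year_ad, st$treering$year_ad)

  write.csv(st$population, file.path(d, "pop.csv"), row.names = FALSE)
  pop <- read_population_csv(file.path(d, "pop.csv"))
  expect_equal(pop$estimate, st$population$estimate)
  expect_error(read_radiocarbon_csv(file.path(d, "tr.csv")), "missing")
})
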