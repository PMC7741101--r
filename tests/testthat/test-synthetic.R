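test_that("population curves have the configured shape", {
  span <- cal_window(ad_to_bp(600), ad_to_bp(1700))
  flat <- population_curve(population_model("constant", level = 100), span)
  expect_true(all(flat$estimate == 100))
  expect_equal(nrow(flat), 1101)

  bb <- population_curve(population_model(), span)
  expect_equal(bb$start_ad[which.max(bb$estimate)], 1300)
  # monotone rise to the peak, monotone decline after (until the floor)
  rise <- bb$estimate[bb$start_ad <= 1300 & bb$start_ad >= 900]
  expect_true(all(diff(rise) > 0))
  post <- bb$estimate[bb$start_ad > 1300 & bb$start_ad <= 1600]
  expect_true(all(diff(post) < 0))

  tab <- data.frame(start_ad = c(700, 800), end_ad = c(800, 900),
                    estimate = c(5, 9))
  cust <- population_curve(population_model("custom", table = tab),
                           cal_window(ad_to_bp(700), ad_to_bp(899)))
  expect_equal(unique(cust$estimate[cust$start_ad < 800]), 5)
  expect_equal(unique(cust$estimate[cust$start_ad >= 800]), 9)
})

test_that("event years are sampled proportionally to population", {
  point <- data.frame(start_ad = 999:1001, end_ad = 1000:1002,
                      estimate = c(0, 50, 0))
  ev <- sample_event_years(point, 200, seed = 8)
  expect_true(all(ev == 1000))

  expect_identical(sample_event_years(point, 50, seed = 3),
                   sample_event_years(point, 50, seed = 3))
  expect_error(sample_event_years(
    data.frame(start_ad = 1, end_ad = 2, estimate = 0), 5), "zero")

  # uniform population: chi-square against uniform stays sub-critical
  unif <- data.frame(start_ad = 1001:1100, end_ad = 1002:1101,
                     estimate = rep(1, 100))
  crit <- qchisq(0.999, df = 99)
  hits <- vapply(1:20, function(s) {
    ev <- sample_event_years(unif, 10000, seed = s)
    obs <- tabulate(ev - 1000, nbins = 100)
    sum((obs - 100)^2 / 100) < crit
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("uncalibration inverts the curve and reproduces under a seed", {
  crv <- identity_curve(0, 3000)
  exact <- uncalibrate(950, crv, sigma_meas = 0)
  expect_equal(exact$c14_age, 1000)
  expect_equal(exact$sigma, 0)

  set.seed(5)
  a <- uncalibrate(rep(950, 10), crv, 25)
  set.seed(5)
  b <- uncalibrate(rep(950, 10), crv, 25)
  expect_identical(a, b)
  expect_error(uncalibrate(-3000, crv, 10), "outside")

  # round trip: the true year sits inside the 95% HPD about 95% of the time
  set.seed(77)
  n <- 400
  truth <- sample(600:1600, n, replace = TRUE)
  cover <- vapply(seq_len(n), function(i) {
    m <- uncalibrate(truth[i], crv, 25)
    r <- hpd_region(calibrate(m$c14_age, 25, crv))
    overlaps_window(r, cal_window(ad_to_bp(truth[i]), ad_to_bp(truth[i])))
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("tree-ring record generation honours symbols and offsets", {
  cfg_cut <- simulation_config(seed = 1, symbol_mix = c(cutting = 1))
  set.seed(1)
  ev <- sample(700:1500, 300, replace = TRUE)
  rec <- make_treering_records(ev, cfg_cut)
  expect_equal(rec$year_ad, ev)
  expect_true(all(classify_treering_symbol(rec$symbol) == "cutting"))

  cfg_near <- simulation_config(seed = 1, symbol_mix = c(near_cutting = 1))
  set.seed(2)
  rec2 <- make_treering_records(ev, cfg_near)
  off <- ev - rec2$year_ad
  expect_true(all(off >= 0 & off <= 3))

  # symbol frequencies within binomial tolerance at n = 5000
  cfg <- simulation_config(seed = 1)
  set.seed(6)
  big <- make_treering_records(sample(700:1500, 5000, replace = TRUE), cfg)
  p_cut <- mean(classify_treering_symbol(big$symbol) == "cutting")
  tol <- 4 * sqrt((2 / 3) * (1 / 3) / 5000)
  expect_lt(abs(p_cut - 2 / 3), tol)
})

test_that("synthetic studies are reproducible and clean when uncontaminated", {
  cfg <- simulation_config(seed = 13, n_events = 40, n_treering_events = 30)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$radiocarbon, s2$radiocarbon)
  expect_identical(s1$treering, s2$treering)
  expect_identical(s1$population, s2$population)

  clean <- generate_study(simulation_config(
    seed = 13, n_events = 40, n_treering_events = 30,
    contaminants = no_contaminants()))
  cfg_r <- region_config()
  rc <- filter_radiocarbon(clean$radiocarbon, clean$curve, cfg_r)
  expect_equal(sum(rc$report$removed) + rc$report$deduplicated, 0)
  tr <- filter_treering(clean$treering, cfg_r)
  expect_equal(sum(tr$report$removed), 0)

  # CSV export round-trips byte-identically under a fixed seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(cfg, outdir = d1)
  generate_study(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("injected contaminants appear in filter reports at exact counts", {
  cont <- list(non_archaeological = 7L, sigma_outlier = 100L,
               duplicate_conflict = 5L, exact_duplicate = 4L,
               out_of_area = 6L, out_of_window = 3L,
               noncutting_symbol = 9L, treering_out_of_area = 5L,
               treering_out_of_window = 4L)
  st <- generate_study(simulation_config(seed = 31, n_events = 80,
                                         n_treering_events = 60,
                                         contaminants = cont))
  cfgr <- region_config()
  rc <- filter_radiocarbon(st$radiocarbon, st$curve, cfgr)
  expect_equal(as.list(rc$report$removed),
               lapply(st$truth$expected_radiocarbon_report$removed,
                      as.numeric))
  expect_equal(rc$report$deduplicated, 4)
  expect_equal(rc$report$retained_n, 80)

  tr <- filter_treering(st$treering, cfgr)
  expect_equal(as.list(tr$report$removed),
               lapply(st$truth$expected_treering_report$removed,
                      as.numeric))
  expect_equal(tr$report$retained_n, 60)
})
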