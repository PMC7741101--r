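test_that("curve files are parsed, comments skipped, bad rows rejected", {
  f <- withr::local_tempfile(lines = c("0,100,10", "10,115,12", "20,130,9"))
  crv <- read_calibration_curve(f)
  expect_equal(crv$cal_bp, c(0, 10, 20))
  expect_equal(crv$c14_age, c(100, 115, 130))
  expect_equal(crv$sigma_curve, c(10, 12, 9))

  fh <- withr::local_tempfile(lines = c("# cal BP, 14C age, sigma",
                                        "0,100,10", "10,115,12", "20,130,9"))
  crv2 <- read_calibration_curve(fh)
  expect_equal(crv2[c("cal_bp", "c14_age", "sigma_curve")],
               crv[c("cal_bp", "c14_age", "sigma_curve")])

  fdup <- withr::local_tempfile(lines = c("0,100,10", "10,115,12",
                                          "10,116,12"))
  expect_error(read_calibration_curve(fdup), "duplicate")

  fbad <- withr::local_tempfile(lines = c("0,100,10", "ten,115,12"))
  expect_error(read_calibration_curve(fbad), "line 2")

  fshort <- withr::local_tempfile(lines = "0,100,10")
  expect_error(read_calibration_curve(fshort), "insufficient")

  # whitespace-separated IntCal style, extra columns ignored
  fws <- withr::local_tempfile(lines = c("# header", "0 100 10 999",
                                         "10 115 12 999"))
  expect_equal(read_calibration_curve(fws)$c14_age, c(100, 115))
})

test_that("interpolation is linear, endpoint-preserving, identity on annual grids", {
  crv <- cal_curve(c(0, 10), c(100, 120), c(10, 10))
  ann <- interpolate_curve(crv)
  expect_equal(ann$cal_bp, 0:10)
  expect_equal(ann$c14_age[ann$cal_bp == 5], 110)
  expect_equal(ann$sigma_curve[ann$cal_bp == 5], 10)
  expect_equal(ann$c14_age[c(1, 11)], c(100, 120))

  # hand linear interpolation oracle at cal BP 1
  crv2 <- cal_curve(c(0, 4), c(100, 108), c(8, 12))
  ann2 <- interpolate_curve(crv2)
  expect_equal(ann2$c14_age[ann2$cal_bp == 1], 102)
  expect_equal(ann2$sigma_curve[ann2$cal_bp == 1], 9)

  already <- cal_curve(0:5, 100:105, rep(1, 6))
  expect_identical(interpolate_curve(already), already)

  expect_error(interpolate_curve(crv, resolution = 50), "coarser")
})

test_that("calibration collapses to the discretized Normal on the identity curve", {
  crv <- identity_curve(0, 2000)
  sharp <- calibrate(1000, 1, crv)
  expect_equal(sharp$grid[which.max(sharp$mass)], 1000)
  expect_gt(sum(sharp$mass[abs(sharp$grid - 1000) <= 3]), 0.99)

  d <- calibrate(1000, 20, crv)
  ref <- dnorm(d$grid, 1000, 20)
  ref <- ref / sum(ref)
  expect_lt(max(abs(d$mass - ref)), 1e-12)
  expect_equal(sum(d$mass), 1, tolerance = 1e-9)
})

test_that("calibration matches a direct evaluation oracle on a toy curve", {
  crv <- interpolate_curve(toy_curve5())
  d <- calibrate(90, 10, crv, normalize = TRUE)
  # brute force: evaluate the posterior formula at every grid year kept
  sd_tot <- sqrt(10^2 + crv$sigma_curve^2)
  full <- dnorm(90, crv$c14_age, sd_tot)
  keep <- match(d$grid, crv$cal_bp)
  expect_equal(d$mass, full[keep] / sum(full[keep]), tolerance = 1e-9)
})

test_that("calibration errors on determinations far outside the curve", {
  crv <- identity_curve(0, 500)
  expect_error(calibrate(5000, 10, crv), "out of curve")
  expect_error(calibrate(1000, -1, crv), "sigma")
  expect_error(calibrate(1000, 10, cal_curve(c(0, 10), c(0, 10), c(0, 0))),
               "annual")
})

test_that("calibrated densities are shift-equivariant on the identity curve", {
  crv <- identity_curve(0, 3000)
  base <- calibrate(800, 30, crv)
  for (k in c(-200, 50, 500)) {
    shifted <- calibrate(800 + k, 30, crv)
    expect_equal(shifted$grid, base$grid + k)
    expect_equal(shifted$mass, base$mass, tolerance = 1e-12)
  }
})

test_that("normalized densities sum to one and trimming is recorded", {
  crv <- interpolate_curve(wiggly_curve(0, 2500))
  set.seed(42)
  for (i in 1:25) {
    age <- runif(1, 300, 2000)
    sg <- runif(1, 15, 120)
    d <- calibrate(age, sg, crv)
    expect_equal(sum(d$mass), 1, tolerance = 1e-9)
    expect_true(all(d$mass >= 0))
    expect_equal(diff(d$grid), rep(1, length(d$grid) - 1))
    expect_lte(d$meta$trimmed_mass, 1e-6)
  }
})

test_that("HPD regions handle degenerate, unimodal and multimodal densities", {
  pt <- cal_density(1250, 1)
  expect_equal(hpd_region(pt), list(cal_window(1250, 1250)))

  crv <- identity_curve(0, 2000)
  d <- calibrate(1000, 20, crv)
  r <- hpd_region(d, 0.95)
  expect_length(r, 1)
  expect_equal(r[[1]]$start_bp, 1039, tolerance = 2)
  expect_equal(r[[1]]$end_bp, 961, tolerance = 2)
  inside <- d$grid >= r[[1]]$end_bp & d$grid <= r[[1]]$start_bp
  expect_gte(sum(d$mass[inside]), 0.95)
  # minimal: dropping the least massive selected year dips below level
  expect_lt(sum(d$mass[inside]) - min(d$mass[inside]), 0.95)

  # multimodal 7-bin toy at years 6..0, against the rank oracle
  mass <- c(0.05, 0.30, 0.10, 0.02, 0.08, 0.35, 0.10)
  toy <- cal_density(0:6, rev(mass))
  r2 <- hpd_region(toy, 0.95)
  expect_length(r2, 2)
  got <- sort(unlist(lapply(r2, function(w) w$end_bp:w$start_bp)),
              decreasing = TRUE)
  expect_equal(got, oracle_hpd_years(toy$grid, toy$mass, 0.95))

  expect_error(hpd_region(cal_density(0:1, c(0.2, 0.2), normalized = FALSE)),
               "normalized")
})

test_that("HPD matches the brute-force rank-threshold oracle on random densities", {
  set.seed(11)
  for (i in 1:200) {
    m <- runif(20)
    m <- m / sum(m)
    d <- cal_density(100:119, m)
    lvl <- runif(1, 0.5, 0.99)
    got <- sort(unlist(lapply(hpd_region(d, lvl),
                              function(w) w$end_bp:w$start_bp)),
                decreasing = TRUE)
    want <- oracle_hpd_years(d$grid, d$mass, lvl)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("window overlap uses closed-interval intersection", {
  win <- cal_window(1750, 150)
  expect_false(overlaps_window(list(cal_window(1800, 1760)), win))
  expect_true(overlaps_window(list(cal_window(1800, 1750)), win))
  expect_true(overlaps_window(list(cal_window(2000, 1900),
                                   cal_window(1500, 1400)), win))
  expect_error(cal_window(100, 200), "start_bp >= end_bp")
})
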