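test_that("toy calibration curve is monotonic, deterministic and degenerates to identity", {
  cv <- generate_toy_calibration_curve(seed = 7)
  expect_true(all(diff(cv$c14_bp) > 0))
  expect_true(all(cv$error > 0))
  cv2 <- generate_toy_calibration_curve(seed = 7)
  expect_identical(cv$c14_bp, cv2$c14_bp)

  flat <- generate_toy_calibration_curve(wiggle_amplitude = 0, seed = 1)
  expect_equal(flat$c14_bp, flat$cal_bp)
  expect_equal(length(unique(flat$error)), 1L)

  expect_error(generate_toy_calibration_curve(window = c(0, 10)), "old_ka")
})

test_that("inverse-mapping a true age through the curve round-trips through calibration", {
  cv <- generate_toy_calibration_curve(seed = 3)
  m <- paleocc:::curve_c14_at(cv, 40.0)
  d <- calibrate(m, 0.001, cv, grid_step_ka = 0.005)
  expect_lt(abs(d$mode_ka - 40.0), 0.005 + 1e-9)
})

test_that("NPP generator honours amplitude, noise and determinism contracts", {
  cfg0 <- world_config(npp_amplitude = 0, noise_sd = 0, seed = 2)
  s0 <- generate_npp_series(cfg0, "R_1")
  expect_equal(length(unique(s0$npp)), 1L)
  expect_equal(coefficient_of_variation(s0$npp), 0)
  expect_true(all(s0$time_ka <= cfg0$window[1] & s0$time_ka >= cfg0$window[2]))

  cfg1 <- world_config(npp_amplitude = 0.04, noise_sd = 0.005, seed = 2)
  cfg2 <- world_config(npp_amplitude = 0.08, noise_sd = 0.005, seed = 2)
  cv1 <- coefficient_of_variation(generate_npp_series(cfg1, "R_1")$npp)
  cv2 <- coefficient_of_variation(generate_npp_series(cfg2, "R_1")$npp)
  expect_gt(cv2, cv1)

  expect_identical(generate_npp_series(cfg1, "R_3")$npp,
                   generate_npp_series(cfg1, "R_3")$npp)
  expect_true(all(generate_npp_series(cfg1, "R_3")$npp >= 0))
})

test_that("fauna generator obeys detection probability limits and closed-form richness", {
  pool <- default_species_pool()
  full <- generate_fauna("R_1", pool, 1, 10, seed = 1)
  expect_true(all(full == 1))
  none <- generate_fauna("R_1", pool, 0, 10, seed = 1)
  expect_true(all(none == 0))
  empty <- generate_fauna("R_1", pool[0, ], 0.5, 5, seed = 1)
  expect_equal(ncol(empty), 0L)
  expect_equal(nrow(empty), 5L)

  # pool of 20, p = 0.3, 100 levels: P(all species seen) = 1 - 20 * 0.7^100
  pool20 <- data.frame(species = sprintf("sp%02d", 1:20), mass_kg = 10)
  seen <- vapply(1:20, function(i) {
    inc <- generate_fauna("R", pool20, 0.3, 100, seed = i)
    sum(colSums(inc) > 0)
  }, numeric(1))
  expect_true(all(seen == 20))
})

test_that("chronometric date generator respects the curve, noise model and truth", {
  cfg <- world_config(n_regions = 2, sites_per_region = 4, seed = 9)
  cv <- generate_toy_calibration_curve(window = c(55, 0), seed = 9)
  hist <- data.frame(region = "R_1", site = sprintf("S%d", 1:4),
                     lon = 0, lat = 45, class = "NAI",
                     occ_old_ka = 48, occ_young_ka = 40)
  d0 <- generate_chronometric_dates(hist, cv, cfg,
                                    lab_error_model = function(n) rep(0, n))
  radio <- grepl("^radiocarbon", d0$method)
  expect_equal(d0$age[radio],
               paleocc:::curve_c14_at(cv, d0$.true_age_ka[radio]))

  # no sighting younger than the true end of occupation
  w <- generate_world(world_config(n_regions = 4, sites_per_region = 6, seed = 5))
  nai <- w$dates[grepl("NAI", w$dates$level), ]
  youngest <- tapply(nai$.true_age_ka, nai$region, min)
  truth <- w$regions$true_nai_end_ka[match(names(youngest), w$regions$region)]
  expect_true(all(youngest >= truth - 1e-9))

  # occupation outside the curve support is rejected
  hist_bad <- hist
  hist_bad$occ_old_ka <- 70
  expect_error(generate_chronometric_dates(hist_bad, cv, cfg), "support")
})

test_that("calibrated-mode error matches the lab error model over many dates", {
  cfg <- world_config(n_regions = 1, sites_per_region = 300, dates_per_site = 2,
                      seed = 21)
  cv <- generate_toy_calibration_curve(window = c(55, 0), seed = 21)
  hist <- data.frame(region = "R_1", site = sprintf("S%03d", 1:300),
                     lon = 0, lat = 45, class = "NAI",
                     occ_old_ka = 46, occ_young_ka = 38)
  sd_ka <- 0.4
  d <- generate_chronometric_dates(hist, cv, cfg,
                                   lab_error_model = function(n) rep(sd_ka * 1000, n))
  radio <- grepl("^radiocarbon", d$method)
  d <- d[radio, ][1:500, ]
  dens <- calibrate_dates(d, cv, grid_step_ka = 0.01)
  modes <- vapply(dens, function(x) x$mode_ka, 0)
  mae <- mean(abs(modes - d$.true_age_ka))
  # |N(0, sd)| has mean sd * sqrt(2/pi) ~ 0.8 sd; assert the same order
  expect_gt(mae, 0.5 * sd_ka)
  expect_lt(mae, 1.2 * sd_ka)
})

test_that("world generator encodes the CC-overlap effect and is deterministic", {
  w <- generate_world(world_config(n_regions = 30, sites_per_region = 2, seed = 3))
  expect_gt(cor(w$regions$true_overlap_ka, w$regions$true_cc_medium,
                method = "spearman"), 0)

  w2 <- generate_world(world_config(n_regions = 30, sites_per_region = 2, seed = 3))
  expect_identical(w$dates, w2$dates)
  expect_identical(w$regions, w2$regions)

  # null construction: with overlap_effect = 0 the correlation centres on 0
  r0 <- vapply(1:30, function(i) {
    wi <- generate_world(world_config(n_regions = 10, sites_per_region = 1,
                                      overlap_effect = 0, seed = 100 + i))
    cor(wi$regions$true_overlap_ka, wi$regions$true_cc_medium)
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.15)

  # all generated times inside the window
  expect_true(all(w$dates$.true_age_ka <= w$config$window[1] &
                    w$dates$.true_age_ka >= w$config$window[2]))
})

test_that("a full world can be written to plain-text artifacts with a manifest", {
  w <- generate_world(world_config(n_regions = 2, sites_per_region = 2, seed = 1))
  dir <- tempfile()
  write_world(w, dir)
  expect_true(file.exists(file.path(dir, "dates.tsv")))
  expect_true(file.exists(file.path(dir, "npp.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$config$seed, 1L)
  unlink(dir, recursive = TRUE)
})

test_that("end-to-end recovery: effect worlds yield a positive association most of the time", {
  expect_gte(power_simulation(), 0.8)
})
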