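test_that("delta bias correction applies the additive and multiplicative rules", {
  past <- c(1, 2, 3)
  expect_equal(delta_bias_correct(past, 5, 5, "additive"), past)
  expect_equal(delta_bias_correct(past, 10, 12, "additive"), past + 2)
  expect_equal(delta_bias_correct(c(10, 0, 30), 20, 30, "multiplicative"),
               c(15, 0, 45))
  expect_error(delta_bias_correct(past, 20, 0, "multiplicative"), "observed")
  # a zero simulated reference is floored, not fatal
  expect_true(all(is.finite(delta_bias_correct(past, 0, 10, "multiplicative"))))
})

test_that("size classes follow the 20/300 kg boundaries, medium-inclusive", {
  expect_equal(assign_size_class(19.9), "small")
  expect_equal(assign_size_class(20), "medium")
  expect_equal(assign_size_class(300), "medium")
  expect_equal(assign_size_class(301), "large")
  expect_error(assign_size_class(0.5), "excluded")
})

test_that("carrying capacity follows the closed form for a single-species guild", {
  p <- cc_params()
  npp <- toy_series(rep(0.25, 10))
  pcom <- list(region = "R_1",
               species = data.frame(species = "deer", mass_kg = 100))
  est <- estimate_cc(npp, pcom, p, n_draws = 0)
  expected <- p$f * 1e6 * p$npp_ref * (0.25 / p$npp_ref)^p$beta
  expect_equal(est$by_species$mean, expected, tolerance = 1e-9)
  expect_equal(est$by_class$mean, expected, tolerance = 1e-9)

  # NPP identically zero -> zero CC
  zero <- estimate_cc(toy_series(rep(0, 10)), pcom, p, n_draws = 0)
  expect_equal(zero$by_species$mean, 0)
})

test_that("CC is homogeneous in NPP at beta = 1 and additive over size classes", {
  p <- cc_params(beta = 1)
  pool <- default_species_pool()
  pcom <- list(region = "R_1", species = pool)
  set.seed(2)
  base_vals <- runif(20, 0.1, 0.4)
  e1 <- estimate_cc(toy_series(base_vals), pcom, p, n_draws = 0)
  e2 <- estimate_cc(toy_series(2 * base_vals), pcom, p, n_draws = 0)
  expect_equal(e2$by_species$mean, 2 * e1$by_species$mean, tolerance = 1e-9)

  # additivity: class CC is exactly the sum of member species CC
  agg <- tapply(e1$by_species$mean, e1$by_species$size_class, sum)
  expect_equal(e1$by_class$mean[match(names(agg), e1$by_class$size_class)],
               as.numeric(agg), tolerance = 1e-12)

  # pointwise monotonicity
  e3 <- estimate_cc(toy_series(base_vals + 0.05), pcom, p, n_draws = 0)
  expect_true(all(e3$by_species$mean >= e1$by_species$mean))
})

test_that("Monte-Carlo CIs bracket the mean and tighten with more draws", {
  p <- cc_params()
  pcom <- list(region = "R_1", species = default_species_pool())
  npp <- toy_series(rep(0.3, 20))
  est <- estimate_cc(npp, pcom, p, n_draws = 200, seed = 1)
  expect_true(all(est$by_class$lower <= est$by_class$mean + 1e-9))
  expect_true(all(est$by_class$upper >= est$by_class$mean - 1e-9))
  expect_true(all(est$by_class$lower >= 0))

  # CI of the Monte-Carlo quantiles stabilises (width shrinks stochastically)
  w200 <- with(estimate_cc(npp, pcom, p, n_draws = 200, seed = 3)$by_class,
               upper - lower)
  w2000 <- with(estimate_cc(npp, pcom, p, n_draws = 2000, seed = 3)$by_class,
                upper - lower)
  expect_lt(abs(mean(w2000) / mean(w200) - 1), 0.35)
})

test_that("validation recovers perfect and planted allometric densities", {
  p <- cc_params()
  pool <- default_species_pool()
  mk_parks <- function(noise_sd, seed) {
    set.seed(seed)
    do.call(rbind, lapply(1:30, function(pk) {
      sp <- pool[sample(nrow(pool), 10), ]
      data.frame(park = sprintf("P%02d", pk), species = sp$species,
                 pred = p$a * sp$mass_kg^p$b,
                 obs = p$a * sp$mass_kg^p$b * exp(rnorm(10, 0, noise_sd)))
    }))
  }
  perfect <- mk_parks(0, 1)
  v0 <- validate_cc(data.frame(park = perfect$park, species = perfect$species,
                               density = perfect$pred),
                    data.frame(park = perfect$park, species = perfect$species,
                               density = perfect$obs))
  expect_gt(v0$pooled_r, 0.99)
  expect_true(all(v0$per_park$r > 0.99))

  # lognormal noise sigma = 0.5: pooled r concentrates around the closed-form
  # attenuation sd(log10 pred) / sqrt(var(log10 pred) + (0.5/ln 10)^2)
  rs <- vapply(1:20, function(i) {
    d <- mk_parks(0.5, 100 + i)
    validate_cc(data.frame(park = d$park, species = d$species, density = d$pred),
                data.frame(park = d$park, species = d$species, density = d$obs))$pooled_r
  }, numeric(1))
  v_sig <- var(log10(p$a * pool$mass_kg^p$b))
  rho <- sqrt(v_sig / (v_sig + (0.5 / log(10))^2))
  expect_true(all(abs(rs - rho) < 0.12))
  expect_true(all(rs > 0.4 & rs < 0.99))

  # shuffling observed values across species destroys the correlation
  r_null <- vapply(1:20, function(i) {
    d <- mk_parks(0.5, 300 + i)
    set.seed(i)
    d$obs <- sample(d$obs)
    validate_cc(data.frame(park = d$park, species = d$species, density = d$pred),
                data.frame(park = d$park, species = d$species, density = d$obs))$pooled_r
  }, numeric(1))
  expect_lt(abs(mean(r_null)), 0.15)
})

test_that("parks with too few matched species are skipped with a warning", {
  pred <- data.frame(park = c("A", "A", "A", "B"), species = c("x", "y", "z", "x"),
                     density = c(1, 2, 3, 1))
  obs <- pred
  expect_warning(v <- validate_cc(pred, obs), "skipped")
  expect_equal(v$per_park$park, "A")
})

test_that("rarefaction interpolates, extrapolates and flags asymptotic pools", {
  # all levels share a single species
  one <- matrix(1, nrow = 8, ncol = 1, dimnames = list(NULL, "sp1"))
  r1 <- rarefy_richness(one, target_units = 100, n_boot = 100)
  expect_equal(r1$observed_richness, 1)
  expect_equal(r1$estimate, 1)
  expect_equal(unname(diff(r1$ci)), 0)

  # interpolation matches a Monte-Carlo subsample oracle
  set.seed(6)
  inc <- matrix(rbinom(40 * 12, 1, 0.3), nrow = 40, ncol = 12)
  colnames(inc) <- sprintf("sp%02d", 1:12)
  anal <- paleocc:::richness_at(inc, 10)
  mc <- oracle_rarefaction(inc, 10, n_mc = 4000, seed = 2)
  expect_lt(abs(anal - mc), 0.15)

  # extrapolated richness never falls below the observed richness
  r2 <- rarefy_richness(inc, target_units = 200, n_boot = 100)
  expect_gte(r2$estimate, sum(colSums(inc) > 0))

  # planted pool of 20 species, p = 0.3, 100 levels: the CI covers 20
  pool20 <- data.frame(species = sprintf("sp%02d", 1:20), mass_kg = 10)
  covered <- vapply(1:20, function(i) {
    inc_i <- generate_fauna("R", pool20, 0.3, 100, seed = 40 + i)
    r <- rarefy_richness(inc_i, target_units = 100, n_boot = 200, seed = i)
    r$ci[1] <= 20 && 20 <= r$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
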