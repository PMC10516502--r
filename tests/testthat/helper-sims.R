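# Shared fixtures and memoised heavy simulations (computed once per test run)

.sim_cache <- new.env(parent = emptyenv())

memoise_sim <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- fn()
  .sim_cache[[key]]
}

toy_series <- function(values, id = "s") {
  structure(list(id = id, time_ka = seq_along(values), npp = values),
            class = "npp_series")
}

# a point-mass-like calibrated density at a given age (tight normal)
delta_density <- function(age_ka, sd_ka = 0.01) {
  grid <- seq(age_ka - 5 * sd_ka, age_ka + 5 * sd_ka, by = sd_ka / 4)
  paleocc:::new_calibrated_density(grid, dnorm(grid, age_ka, sd_ka))
}

toy_date_table <- function() {
  data.frame(
    site = sprintf("S%d", 1:6), lon = 0, lat = 45, level = "L1",
    techno = c("Mousterian", "Mousterian", "Aurignacian",
               "Aurignacian", "Mousterian", "Aurignacian"),
    method = c("radiocarbon-conventional", rep("radiocarbon-AMS-ultrafiltration", 5)),
    material = "bone",
    anthropic = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    marine = FALSE,
    age = c(40000, 40000, 40000, 41000, 39000, 42000),
    error = c(300, 2400, 300, 300, 300, 300),  # record 2 has cv 0.06
    age_units = "yr",
    contamination = FALSE, low_collagen = FALSE, burnt_bone = FALSE,
    same_sample = NA_character_,
    stringsAsFactors = FALSE
  )
}

# CC-overlap power over replicate effect worlds (criterion-level and
# generator-invariant assertions share this)
power_simulation <- function() {
  memoise_sim("power", function() {
    sig <- vapply(1:20, function(i) {
      cfg <- pipeline_config(
        world_config(n_regions = 30, sites_per_region = 10, seed = 5000 + i),
        esf_n_resamples = 100, ole = ole_config(n_resamples = 200))
      run <- run_pipeline(cfg)
      run$fc1$esf$median_p <= 0.05
    }, logical(1))
    mean(sig)
  })
}
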