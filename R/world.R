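#' Configuration of a synthetic MIS3 world
#'
#' Defines the study conditions emulated by the synthetic-data generators:
#' regions with sites on a European-like lon/lat extent, stadial/interstadial
#' oscillations in net primary productivity (NPP), regional herbivore guilds,
#' occupation intervals for the Neanderthal-affiliated (NAI) and
#' *H. sapiens*-affiliated (SAI) industries, and noisy chronometric
#' measurements. The true regional temporal overlap between the two industry
#' groups is generated as a linear function of the region's true medium-size
#' herbivore carrying capacity (slope `overlap_effect`) plus spatially
#' autocorrelated noise, so the downstream association test has a known
#' ground truth.
#'
#' @param n_regions number of biogeographic regions (>= 1).
#' @param sites_per_region number of sites (= dated levels) per region.
#' @param window analysis window `c(old_ka, young_ka)` in ka cal BP.
#' @param stadial_cycle_ka duration of one stadial (and one interstadial)
#'   phase in ka; the Dansgaard-Oeschger pacing is on the order of 1.5 ka.
#' @param npp_base mean NPP level in kg/m^2/yr; per-region base levels are
#'   drawn around this value to emulate the observed spread across Europe.
#' @param npp_amplitude peak-to-trough amplitude of the stadial/interstadial
#'   square wave, kg/m^2/yr.
#' @param noise_sd standard deviation of the autocorrelated NPP noise,
#'   kg/m^2/yr.
#' @param overlap_effect slope linking true overlap (ka) to true medium-size
#'   carrying capacity (kg/km^2/yr).
#' @param overlap_noise_sd_ka sd of the spatially autocorrelated noise added
#'   to the true overlap, in ka.
#' @param spatial_noise_range_km e-folding range of the exponential-decay
#'   spatial covariance of the overlap noise.
#' @param dates_per_site chronometric dates generated per site and industry.
#' @param detection_prob per-level detection probability of a guild species
#'   in the fossil record.
#' @param seed integer seed; every generator derives sub-seeds from it.
#' @return an object of class `world_config`.
#' @export
world_config <- function(n_regions = 16, sites_per_region = 20,
                         window = c(55, 30), stadial_cycle_ka = 1.5,
                         npp_base = 0.28, npp_amplitude = 0.05,
                         noise_sd = 0.015, overlap_effect = 0.02,
                         overlap_noise_sd_ka = 1.0,
                         spatial_noise_range_km = 500,
                         dates_per_site = 2, detection_prob = 0.6,
                         seed = 1L) {
  stop_if_not(n_regions >= 1 && sites_per_region >= 1, "counts must be >= 1")
  stop_if_not(window[1] > window[2], "window must be (old_ka, young_ka) with old > young")
  stop_if_not(npp_amplitude >= 0 && noise_sd >= 0 && overlap_noise_sd_ka >= 0,
              "variances/amplitudes must be >= 0")
  stop_if_not(stadial_cycle_ka > 0, "stadial_cycle_ka must be > 0")
  stop_if_not(detection_prob >= 0 && detection_prob <= 1,
              "detection_prob must be in [0, 1]")
  structure(list(n_regions = as.integer(n_regions),
                 sites_per_region = as.integer(sites_per_region),
                 window = as.numeric(window),
                 stadial_cycle_ka = stadial_cycle_ka,
                 npp_base = npp_base, npp_amplitude = npp_amplitude,
                 noise_sd = noise_sd, overlap_effect = overlap_effect,
                 overlap_noise_sd_ka = overlap_noise_sd_ka,
                 spatial_noise_range_km = spatial_noise_range_km,
                 dates_per_site = as.integer(dates_per_site),
                 detection_prob = detection_prob,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Default MIS3 herbivore species pool
#'
#' A compact synthetic guild spanning the small (< 20 kg), medium (20-300 kg)
#' and large (> 300 kg) body-size classes; two-sex mean masses in kg. Species
#' below 1 kg are excluded from carrying-capacity analyses and are not
#' generated.
#'
#' @return data.frame with columns `species` and `mass_kg`.
#' @export
default_species_pool <- function() {
  data.frame(
    species = c("Lepus timidus", "Marmota marmota", "Castor fiber",
                "Rupicapra rupicapra", "Capreolus capreolus", "Capra ibex",
                "Saiga tatarica", "Sus scrofa", "Rangifer tarandus",
                "Cervus elaphus", "Equus ferus", "Bos primigenius",
                "Bison priscus", "Megaloceros giganteus"),
    mass_kg = c(3.2, 5.5, 18, 35, 23, 69, 42, 85, 110, 180, 400, 700, 650, 540),
    stringsAsFactors = FALSE
  )
}

#' Generate a toy calibration curve
#'
#' Builds a strictly monotonic calendar-to-radiocarbon mapping in the
#' IntCal-style three-column dialect (cal BP, radiocarbon age, curve error),
#' with smooth sinusoidal wiggles of a given amplitude around the identity
#' line. With `wiggle_amplitude = 0` the curve is the identity line with a
#' constant error.
#'
#' @param window calendar range `c(old_ka, young_ka)` within 0-60 ka BP.
#' @param wiggle_amplitude amplitude of the wiggles in radiocarbon yr.
#' @param seed integer seed.
#' @param knot_step_yr knot spacing in calendar yr.
#' @return an object of class `calibration_curve`.
#' @export
generate_toy_calibration_curve <- function(window = c(60, 0),
                                           wiggle_amplitude = 300,
                                           seed = 1L, knot_step_yr = 20) {
  stop_if_not(window[1] > window[2], "window must be (old_ka, young_ka)")
  stop_if_not(window[2] >= 0 && window[1] <= 60, "window must lie within 0-60 ka BP")
  set.seed(sub_seed(seed, "curve"))
  cal <- seq(window[2] * 1000, window[1] * 1000, by = knot_step_yr)
  if (wiggle_amplitude > 0) {
    # periods scaled to the amplitude keep |d wiggle / d cal| < 1, hence the
    # calendar -> radiocarbon mapping strictly monotonic
    per <- stats::runif(4, 3000, 8000) * max(1, wiggle_amplitude / 300)
    phi <- stats::runif(4, 0, 2 * pi)
    amp <- stats::runif(4); amp <- amp / sum(amp)
    s <- rowSums(vapply(1:4, function(j) amp[j] * sin(2 * pi * cal / per[j] + phi[j]),
                        numeric(length(cal))))
    c14 <- cal + wiggle_amplitude * s
    err <- 30 + 0.05 * wiggle_amplitude * abs(s)
  } else {
    c14 <- cal
    err <- rep(30, length(cal))
  }
  stop_if_not(all(diff(c14) > 0), "internal: generated curve not monotonic")
  structure(list(cal_bp = cal, c14_bp = c14, error = err,
                 name = sprintf("toy-%d", seed),
                 delta_r = 0, delta_r_error = 0, marine = FALSE),
            class = "calibration_curve")
}

# linear interpolation of the curve mean / error at calendar ages (ka BP)
curve_c14_at <- function(curve, cal_ka) {
  stats::approx(curve$cal_bp, curve$c14_bp, xout = cal_ka * 1000, rule = 1)$y
}

curve_error_at <- function(curve, cal_ka) {
  stats::approx(curve$cal_bp, curve$error, xout = cal_ka * 1000, rule = 1)$y
}

# square wave with jittered change points plus AR(1) noise, >= 0 everywhere
npp_signal <- function(time_ka, base, amplitude, noise_sd, cycle_ka, seed) {
  set.seed(seed)
  old <- max(time_ka); young <- min(time_ka)
  # change points marching from old to young, alternating stadial/interstadial
  cp <- old
  repeat {
    nxt <- cp[length(cp)] - max(0.2, stats::rnorm(1, cycle_ka, 0.2 * cycle_ka))
    cp <- c(cp, nxt)
    if (nxt < young) break
  }
  phase <- findInterval(-time_ka, -cp)  # 1,2,3,... from old to young
  level <- ifelse(phase %% 2 == 0, base + amplitude / 2, base - amplitude / 2)
  n <- length(time_ka)
  eps <- numeric(n)
  if (noise_sd > 0) {
    innov <- stats::rnorm(n, 0, noise_sd * sqrt(1 - 0.8^2))
    eps[1] <- stats::rnorm(1, 0, noise_sd)
    for (i in 2:n) eps[i] <- 0.8 * eps[i - 1] + innov[i]
  }
  pmax(level + eps, 0)
}

#' Generate an NPP time series for one region
#'
#' Emulates a Dansgaard-Oeschger-style stadial/interstadial oscillation: a
#' square wave with jittered change points plus AR(1) noise, on a regular
#' time grid over the configured window. Values are truncated at zero.
#'
#' @param config a [world_config()].
#' @param region_id region identifier (used to derive the sub-seed).
#' @param base optional base NPP level overriding `config$npp_base`.
#' @param step_ka time grid step, ka.
#' @return object of class `npp_series`: list with `id`, `time_ka`, `npp`.
#' @export
generate_npp_series <- function(config, region_id, base = NULL, step_ka = 0.05) {
  stop_if_not(inherits(config, "world_config"), "config must be a world_config")
  time_ka <- seq(config$window[1], config$window[2], by = -step_ka)
  npp <- npp_signal(time_ka, base %||% config$npp_base, config$npp_amplitude,
                    config$noise_sd, config$stadial_cycle_ka,
                    sub_seed(config$seed, "npp", region_id))
  structure(list(id = region_id, time_ka = time_ka, npp = npp),
            class = "npp_series")
}

#' Generate a fauna incidence table
#'
#' One presence/absence row per archaeo-paleontological level; each pool
#' species is detected independently with probability `detection_prob`.
#'
#' @param region_id region identifier.
#' @param pool data.frame with `species` and `mass_kg` columns.
#' @param detection_prob detection probability in `[0, 1]`.
#' @param n_levels number of levels.
#' @param seed integer seed.
#' @return integer matrix `n_levels x n_species` of 0/1 incidences.
#' @export
generate_fauna <- function(region_id, pool, detection_prob, n_levels, seed = 1L) {
  stop_if_not(detection_prob >= 0 && detection_prob <= 1,
              "detection_prob must be in [0, 1]")
  if (is.null(pool) || nrow(pool) == 0) {
    m <- matrix(integer(0), nrow = n_levels, ncol = 0)
    rownames(m) <- sprintf("%s_L%02d", region_id, seq_len(n_levels))
    return(m)
  }
  set.seed(sub_seed(seed, "fauna", region_id))
  m <- matrix(stats::rbinom(n_levels * nrow(pool), 1, detection_prob),
              nrow = n_levels, ncol = nrow(pool))
  dimnames(m) <- list(sprintf("%s_L%02d", region_id, seq_len(n_levels)),
                      pool$species)
  m
}

#' Generate chronometric dates from a true occupation history
#'
#' For each site and industry, true ages are drawn uniformly inside the
#' occupation interval; radiocarbon measurements are the calibration-curve
#' value at the true age plus lab noise. Method, material and QC fields are
#' sampled so that both filtering criteria have work to do. The hidden
#' column `.true_age_ka` carries the true-age provenance for recovery tests
#' and is never consumed by the pipeline.
#'
#' @param history data.frame with one row per (region, site, class) giving
#'   `region`, `site`, `lon`, `lat`, `class` ("NAI"/"SAI"), `occ_old_ka`,
#'   `occ_young_ka`.
#' @param curve a `calibration_curve`.
#' @param config a [world_config()] (supplies `dates_per_site`).
#' @param lab_error_model function(n) returning radiocarbon 1-sigma lab
#'   errors in yr; default uniform on 200-600 yr.
#' @param seed integer seed.
#' @return data.frame of chronometric dates (ages in uncalibrated yr BP for
#'   radiocarbon methods, calendar yr BP for luminescence).
#' @export
generate_chronometric_dates <- function(history, curve, config,
                                        lab_error_model = function(n) stats::runif(n, 200, 600),
                                        seed = config$seed) {
  rng <- range(curve$cal_bp) / 1000
  stop_if_not(all(history$occ_young_ka >= rng[1] - 1e-9) &&
                all(history$occ_old_ka <= rng[2] + 1e-9),
              "occupation interval outside calibration curve support")
  set.seed(sub_seed(seed, "dates"))
  per <- config$dates_per_site
  n <- nrow(history) * per
  idx <- rep(seq_len(nrow(history)), each = per)
  true_age <- stats::runif(n, history$occ_young_ka[idx], history$occ_old_ka[idx])
  cls <- history$class[idx]
  techno <- ifelse(cls == "NAI",
                   ifelse(stats::runif(n) < 0.9, "Mousterian", "Chatelperronian"),
                   ifelse(stats::runif(n) < 0.9, "Aurignacian", "Uluzzian"))
  method <- sample(c("radiocarbon-AMS-ultrafiltration", "radiocarbon-ABOx",
                     "radiocarbon-conventional", "OSL"),
                   n, replace = TRUE, prob = c(0.78, 0.08, 0.07, 0.07))
  err_yr <- lab_error_model(n)
  radio <- grepl("^radiocarbon", method)
  age_yr <- numeric(n)
  age_yr[radio] <- curve_c14_at(curve, true_age[radio]) +
    stats::rnorm(sum(radio), 0, err_yr[radio])
  age_yr[!radio] <- true_age[!radio] * 1000 +
    stats::rnorm(sum(!radio), 0, err_yr[!radio])
  data.frame(
    site = history$site[idx],
    lon = history$lon[idx], lat = history$lat[idx],
    level = paste0(history$site[idx], "_", cls, "1"),
    techno = techno,
    method = method,
    material = sample(c("bone", "charcoal", "shell"), n, TRUE, c(0.6, 0.35, 0.05)),
    anthropic = stats::runif(n) < 0.85,
    marine = FALSE,
    age = age_yr,
    error = err_yr,
    age_units = "yr",
    contamination = stats::runif(n) < 0.03,
    low_collagen = stats::runif(n) < 0.03,
    burnt_bone = stats::runif(n) < 0.02,
    same_sample = NA_character_,
    .true_age_ka = true_age,
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic world
#'
#' Produces a ground-truth history (true NAI end, SAI start and overlap per
#' region), regional NPP series, site-level series, fauna incidence tables,
#' a chronometric date table and a modern herbivore density table. True
#' overlap durations are linear in the region's true medium-size carrying
#' capacity with slope `overlap_effect`, plus spatially autocorrelated noise
#' with exponential-decay covariance over great-circle distance.
#'
#' @param config a [world_config()].
#' @param params carrying-capacity parameters used to define the true CC;
#'   defaults to [cc_params()].
#' @return object of class `synthetic_world`.
#' @export
generate_world <- function(config, params = cc_params()) {
  stop_if_not(inherits(config, "world_config"), "config must be a world_config")
  set.seed(sub_seed(config$seed, "world"))
  nr <- config$n_regions
  # region centroids east -> west on a European-like extent
  lon <- seq(29, -9, length.out = nr) + stats::rnorm(nr, 0, 0.5)
  lat <- stats::runif(nr, 37, 53)
  region_id <- sprintf("R_%d", seq_len(nr))
  base <- config$npp_base * stats::runif(nr, 0.6, 1.3)

  pool <- default_species_pool()
  npp_regions <- lapply(seq_len(nr), function(i)
    generate_npp_series(config, region_id[i], base = base[i]))
  guilds <- lapply(seq_len(nr), function(i) {
    set.seed(sub_seed(config$seed, "guild", region_id[i]))
    keep <- stats::runif(nrow(pool)) < 0.8
    # always keep at least one species per size class
    cls <- assign_size_class(pool$mass_kg)
    for (g in unique(cls)) if (!any(keep & cls == g)) keep[which(cls == g)[1]] <- TRUE
    pool[keep, , drop = FALSE]
  })

  # true medium-size CC per region from the package's own CC model (no MC)
  cc_med <- vapply(seq_len(nr), function(i) {
    est <- estimate_cc(npp_regions[[i]], list(region = region_id[i],
                                              species = guilds[[i]]),
                       params = params, n_draws = 0)
    est$by_class$mean[est$by_class$size_class == "medium"]
  }, numeric(1))

  # spatially autocorrelated overlap noise
  D <- haversine_matrix(lon, lat)
  Sigma <- config$overlap_noise_sd_ka^2 * exp(-D / config$spatial_noise_range_km)
  set.seed(sub_seed(config$seed, "overlap-noise"))
  eps <- if (config$overlap_noise_sd_ka > 0)
    drop(t(chol(Sigma + diag(1e-8, nr))) %*% stats::rnorm(nr)) else numeric(nr)
  overlap <- 1.0 + config$overlap_effect * (cc_med - mean(cc_med)) + eps

  mid <- 41
  nai_end <- pmin(pmax(mid - overlap / 2, config$window[2] + 4), config$window[1] - 6)
  sai_start <- pmin(pmax(mid + overlap / 2, config$window[2] + 4), config$window[1] - 6)
  history_regions <- data.frame(region = region_id, lon = lon, lat = lat,
                                true_nai_end_ka = nai_end,
                                true_sai_start_ka = sai_start,
                                true_overlap_ka = sai_start - nai_end,
                                true_cc_medium = cc_med,
                                stringsAsFactors = FALSE)

  # site-level occupation intervals per industry
  occ <- do.call(rbind, lapply(seq_len(nr), function(i) {
    set.seed(sub_seed(config$seed, "sites", region_id[i]))
    ns <- config$sites_per_region
    data.frame(
      region = region_id[i],
      site = sprintf("%s_S%02d", region_id[i], seq_len(ns)),
      lon = lon[i] + stats::runif(ns, -0.8, 0.8),
      lat = lat[i] + stats::runif(ns, -0.8, 0.8),
      stringsAsFactors = FALSE
    )
  }))
  hist_nai <- occ
  hist_nai$class <- "NAI"
  hist_nai$occ_old_ka <- pmin(config$window[1] - 2, 50)
  hist_nai$occ_young_ka <- nai_end[match(hist_nai$region, region_id)]
  hist_sai <- occ
  hist_sai$class <- "SAI"
  hist_sai$occ_old_ka <- sai_start[match(hist_sai$region, region_id)]
  hist_sai$occ_young_ka <- pmax(config$window[2] + 2, 32)
  history_sites <- rbind(hist_nai, hist_sai)

  curve <- generate_toy_calibration_curve(window = c(config$window[1], 0),
                                          seed = config$seed)
  dates <- generate_chronometric_dates(history_sites, curve, config)
  dates$region <- occ$region[match(dates$site, occ$site)]

  fauna <- lapply(seq_len(nr), function(i)
    generate_fauna(region_id[i], guilds[[i]], config$detection_prob,
                   config$sites_per_region, seed = config$seed))
  names(fauna) <- region_id

  # modern density table: allometric expectation plus lognormal noise
  set.seed(sub_seed(config$seed, "modern"))
  n_parks <- 30
  modern <- do.call(rbind, lapply(seq_len(n_parks), function(p) {
    sp <- pool[sample(nrow(pool), 10), ]
    data.frame(park = sprintf("P%02d", p), species = sp$species,
               mass_kg = sp$mass_kg,
               density_ind_km2 = params$a * sp$mass_kg^params$b *
                 exp(stats::rnorm(10, 0, 0.5)),
               stringsAsFactors = FALSE)
  }))

  structure(list(config = config, curve = curve,
                 regions = history_regions, sites = occ,
                 history_sites = history_sites,
                 npp = npp_regions, guilds = guilds, fauna = fauna,
                 dates = dates, modern = modern),
            class = "synthetic_world")
}

#' Write a synthetic world to disk
#'
#' Writes the tabular dialects the pipeline reads (date table, NPP series,
#' fauna incidence, modern density table, calibration curve) plus a JSON
#' manifest recording the configuration and seed.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(world$dates, file.path(dir, "dates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  npp_wide <- data.frame(time_ka = world$npp[[1]]$time_ka)
  for (s in world$npp) npp_wide[[s$id]] <- s$npp
  utils::write.table(npp_wide, file.path(dir, "npp.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (rid in names(world$fauna)) {
    utils::write.table(world$fauna[[rid]],
                       file.path(dir, sprintf("fauna_%s.tsv", rid)),
                       sep = "\t", row.names = TRUE, quote = FALSE)
  }
  utils::write.table(world$modern, file.path(dir, "modern_density.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(cal_bp = world$curve$cal_bp, c14_bp = world$curve$c14_bp,
               error = world$curve$error),
    file.path(dir, "curve.14c"), sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(config = unclass(world$config),
                            created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
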