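#' Delta bias correction of simulated paleoclimate series
#'
#' Additive (temperature): `past + (obs - sim)`. Multiplicative
#' (precipitation): `past * obs / max(sim, floor)` with the simulated
#' reference floored at a small positive constant.
#'
#' @param past simulated past series.
#' @param sim_ref simulated present-day reference (scalar or series-length).
#' @param obs_ref observed present-day reference.
#' @param kind "additive" or "multiplicative".
#' @param floor lower bound applied to `sim_ref` in the multiplicative case.
#' @return corrected series.
#' @export
delta_bias_correct <- function(past, sim_ref, obs_ref,
                               kind = c("additive", "multiplicative"),
                               floor = 1e-6) {
  kind <- match.arg(kind)
  if (kind == "additive") return(past + (obs_ref - sim_ref))
  stop_if_not(all(obs_ref > 0), "multiplicative correction needs observed reference > 0")
  past * obs_ref / pmax(sim_ref, floor)
}

#' Assign a body-size class
#'
#' Small below 20 kg, medium 20 to 300 kg (both bounds inclusive to medium),
#' large above 300 kg. Species below 1 kg are rejected: they are excluded
#' from the analyses at ingest.
#'
#' @param mass_kg two-sex mean body mass in kg (vectorised).
#' @return character vector "small"/"medium"/"large".
#' @export
assign_size_class <- function(mass_kg) {
  stop_if_not(all(mass_kg >= 1), "species below 1 kg are excluded")
  ifelse(mass_kg < 20, "small", ifelse(mass_kg <= 300, "medium", "large"))
}

#' Carrying-capacity model parameters
#'
#' Default structural parameters of the productivity-driven herbivore
#' carrying-capacity model: individual density follows the Damuth-style
#' allometry `a * M^b` (defaults a = 91.2 ind/km^2, b = -0.73), guild
#' members share the total supportable biomass in proportion to their
#' expected biomass density `a * M^(b+1)`, and total herbivore biomass is
#' `f * 1e6 * npp_ref * (NPP / npp_ref)^beta` kg/km^2/yr (linear in NPP at
#' the default `beta = 1`; 1e6 converts kg/m^2 to kg/km^2). The transfer
#' fraction `f` is set so a reference NPP of 0.3 kg/m^2/yr supports about
#' 810 kg/km^2/yr of herbivore biomass. These are package defaults with
#' configurable 95% CIs for Monte-Carlo propagation, not published
#' calibrated values.
#'
#' @param a,b allometric density intercept (ind/km^2) and exponent.
#' @param f NPP-to-herbivore transfer fraction (in (0, 1]).
#' @param beta NPP scaling exponent.
#' @param npp_ref reference NPP, kg/m^2/yr.
#' @param n_draws Monte-Carlo draws for CI propagation.
#' @param a_ci,b_ci,f_ci 95% CIs of the uncertain parameters.
#' @return list of class `cc_params`.
#' @export
cc_params <- function(a = 91.2, b = -0.73, f = 0.0027, beta = 1,
                      npp_ref = 0.3, n_draws = 1000,
                      a_ci = c(65, 128), b_ci = c(-0.80, -0.66),
                      f_ci = c(0.0019, 0.0038)) {
  stop_if_not(f > 0 && f <= 1, "f must be in (0, 1]")
  stop_if_not(n_draws >= 0, "n_draws must be >= 0")
  structure(list(a = a, b = b, f = f, beta = beta, npp_ref = npp_ref,
                 n_draws = as.integer(n_draws),
                 a_ci = a_ci, b_ci = b_ci, f_ci = f_ci),
            class = "cc_params")
}

#' Estimate herbivore carrying capacity for a paleocommunity
#'
#' Per time step, the total supportable herbivore biomass is
#' `f * 1e6 * npp_ref * (NPP/npp_ref)^beta` (kg/km^2/yr), partitioned among
#' the guild members in proportion to each species' allometric expected
#' biomass density `a * M^(b+1)`; species values are averaged over the
#' window, and size-class values are the sums over member species. 95% CIs
#' come from Monte-Carlo draws of (a, b, f) over their CIs (log-normal for a
#' and f, normal for b), each draw time-averaged before summarising.
#'
#' @param npp an `npp_series` for the region.
#' @param pcom paleocommunity: list with `region` and `species` (data.frame
#'   with `species`, `mass_kg`), non-empty.
#' @param params a [cc_params()].
#' @param n_draws override of `params$n_draws` (0 = deterministic only).
#' @param window optional `c(old_ka, young_ka)` restriction.
#' @param seed integer seed for the Monte-Carlo draws.
#' @return list of class `cc_estimate` with data.frames `by_species` and
#'   `by_class` (columns `mean`, `lower`, `upper`, kg/km^2/yr).
#' @export
estimate_cc <- function(npp, pcom, params = cc_params(),
                        n_draws = params$n_draws, window = NULL, seed = 1L) {
  stop_if_not(!is.null(pcom$species) && nrow(pcom$species) >= 1,
              "paleocommunity must contain at least one species")
  t <- npp$time_ka; v <- npp$npp
  if (!is.null(window)) {
    keep <- t <= window[1] & t >= window[2]
    t <- t[keep]; v <- v[keep]
  }
  stop_if_not(length(v) >= 1, "zero-length analysis window")
  M <- pcom$species$mass_kg
  cls <- assign_size_class(M)

  species_cc <- function(a, b, f, beta) {
    total_t <- f * 1e6 * params$npp_ref * (v / params$npp_ref)^beta
    share <- a * M^(b + 1)
    share <- share / sum(share)
    mean(total_t) * share  # time-average x fixed guild share
  }
  central <- species_cc(params$a, params$b, params$f, params$beta)

  if (n_draws > 0) {
    set.seed(sub_seed(seed, "cc", pcom$region %||% "pcom"))
    sd_log_a <- (log(params$a_ci[2]) - log(params$a_ci[1])) / 3.92
    sd_b <- (params$b_ci[2] - params$b_ci[1]) / 3.92
    sd_log_f <- (log(params$f_ci[2]) - log(params$f_ci[1])) / 3.92
    draws <- vapply(seq_len(n_draws), function(i) {
      species_cc(stats::rlnorm(1, log(params$a), sd_log_a),
                 stats::rnorm(1, params$b, sd_b),
                 stats::rlnorm(1, log(params$f), sd_log_f),
                 params$beta)
    }, numeric(length(M)))
    draws <- matrix(draws, nrow = length(M))
    sp_lo <- apply(draws, 1, stats::quantile, 0.025)
    sp_hi <- apply(draws, 1, stats::quantile, 0.975)
    cls_draws <- rowsum(draws, cls)
    cl_lo <- apply(cls_draws, 1, stats::quantile, 0.025)
    cl_hi <- apply(cls_draws, 1, stats::quantile, 0.975)
  } else {
    sp_lo <- sp_hi <- central
    agg <- rowsum(matrix(central, ncol = 1), cls)
    cl_lo <- cl_hi <- drop(agg)
  }

  by_species <- data.frame(species = pcom$species$species, mass_kg = M,
                           size_class = cls, mean = central,
                           lower = pmin(sp_lo, central),
                           upper = pmax(sp_hi, central),
                           stringsAsFactors = FALSE)
  agg <- tapply(central, cls, sum)
  by_class <- data.frame(size_class = names(agg), mean = as.numeric(agg),
                         lower = pmin(as.numeric(cl_lo[names(agg)]), as.numeric(agg)),
                         upper = pmax(as.numeric(cl_hi[names(agg)]), as.numeric(agg)),
                         stringsAsFactors = FALSE)
  structure(list(region = pcom$region %||% NA_character_,
                 by_species = by_species, by_class = by_class,
                 n_draws = n_draws),
            class = "cc_estimate")
}

#' Validate predicted densities against modern observations
#'
#' Correlates predicted and observed population densities on a log10 scale,
#' per park and pooled across parks; parks with fewer than 3 matched species
#' are skipped with a warning.
#'
#' @param predicted data.frame with `park`, `species`, `density` (predicted
#'   ind/km^2).
#' @param observed data.frame with `park`, `species`, `density` (observed).
#' @return list with `per_park` (park, n, r, p_value), `pooled_r`,
#'   `pooled_p`, `frac_significant` (share of parks with p < 0.05).
#' @export
validate_cc <- function(predicted, observed) {
  m <- merge(predicted, observed, by = c("park", "species"),
             suffixes = c("_pred", "_obs"))
  stop_if_not(nrow(m) >= 3, "fewer than 3 matched species overall")
  parks <- split(m, m$park)
  small <- names(parks)[vapply(parks, nrow, 0L) < 3]
  if (length(small) > 0) {
    warning(sprintf("park(s) skipped with < 3 matched species: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    parks <- parks[setdiff(names(parks), small)]
  }
  per_park <- do.call(rbind, lapply(names(parks), function(p) {
    d <- parks[[p]]
    if (stats::sd(log10(d$density_pred)) == 0 || stats::sd(log10(d$density_obs)) == 0) {
      return(data.frame(park = p, n = nrow(d), r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(log10(d$density_pred), log10(d$density_obs))
    data.frame(park = p, n = nrow(d), r = unname(ct$estimate),
               p_value = ct$p.value)
  }))
  pooled <- stats::cor.test(log10(m$density_pred), log10(m$density_obs))
  list(per_park = per_park,
       pooled_r = unname(pooled$estimate), pooled_p = pooled$p.value,
       frac_significant = mean(per_park$p_value < 0.05, na.rm = TRUE))
}

#' Rarefaction / extrapolation of incidence-based species richness
#'
#' Sample-based rarefaction of an incidence (levels x species) matrix, with
#' Chao2-style extrapolation beyond the observed number of sampling units
#' and a bootstrap CI (levels resampled with replacement).
#'
#' @param incidence 0/1 matrix, rows = levels (sampling units), columns =
#'   species.
#' @param target_units number of sampling units to interpolate/extrapolate
#'   to; targets below the observed number of units interpolate only.
#' @param n_boot bootstrap replicates for the CI (default 500).
#' @param conf CI level.
#' @param seed integer seed.
#' @return list with `observed_richness`, `estimate` (richness at the
#'   target), `ci`, `observed_within_ci`, `target_units`.
#' @export
rarefy_richness <- function(incidence, target_units = 100, n_boot = 500,
                            conf = 0.95, seed = 1L) {
  incidence <- as.matrix(incidence)
  stop_if_not(nrow(incidence) >= 1, "need at least one level")
  point <- richness_at(incidence, target_units)
  set.seed(sub_seed(seed, "rarefy"))
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(incidence), replace = TRUE)
    richness_at(incidence[idx, , drop = FALSE], target_units)
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  s_obs <- sum(colSums(incidence) > 0)
  list(observed_richness = s_obs, estimate = point, ci = ci,
       observed_within_ci = s_obs >= ci[1] && s_obs <= ci[2],
       target_units = target_units)
}

# expected richness at t sampling units (analytic interpolation; Chao2
# extrapolation past the observed number of units)
richness_at <- function(incidence, t_units) {
  T_ <- nrow(incidence)
  Y <- colSums(incidence)
  Y <- Y[Y > 0]
  s_obs <- length(Y)
  if (s_obs == 0) return(0)
  if (t_units <= T_) {
    # E[S_t] = sum_j (1 - choose(T - Y_j, t) / choose(T, t))
    lch <- function(n, k) ifelse(k > n, -Inf, lchoose(n, k))
    return(sum(1 - exp(lch(T_ - Y, t_units) - lchoose(T_, t_units))))
  }
  q1 <- sum(Y == 1); q2 <- sum(Y == 2)
  q0 <- if (q2 > 0) (T_ - 1) / T_ * q1^2 / (2 * q2)
  else (T_ - 1) / T_ * q1 * (q1 - 1) / 2
  t_star <- t_units - T_
  if (q0 == 0 || q1 == 0) return(s_obs)
  s_obs + q0 * (1 - (1 - q1 / (q1 + T_ * q0))^t_star)
}
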