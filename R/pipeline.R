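#' Pipeline configuration
#'
#' @param world_config a [world_config()] for synthetic runs.
#' @param criteria filtering criteria to run ("fc1", "fc2").
#' @param toggles techno-complex attribution toggles, see
#'   [technocomplex_class()].
#' @param use_bam use the Bayesian phase model for the regional chronology
#'   (otherwise optimal linear estimation only).
#' @param bam_settings MCMC settings passed to [fit_bam()].
#' @param ole ole settings: an [ole_config()].
#' @param cc a [cc_params()].
#' @param esf_n_resamples CI resamples in the correlation tests (the default
#'   scales the 10,000-draw procedure down by a global factor for routine
#'   runs).
#' @param do_kde also build the KDE overlap stacks.
#' @param kde a [kde_config()].
#' @param out_dir optional output directory for artifact files.
#' @param seed integer seed recorded in all outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(world_config = paleocc::world_config(),
                            criteria = "fc1", toggles = list(),
                            use_bam = FALSE,
                            bam_settings = list(n_chains = 2, burn = 500,
                                                iter = 3000, thin = 3),
                            ole = ole_config(n_resamples = 500),
                            cc = cc_params(n_draws = 300),
                            esf_n_resamples = 500,
                            do_kde = FALSE, kde = kde_config(),
                            out_dir = NULL, seed = world_config$seed) {
  structure(list(world_config = world_config, criteria = criteria,
                 toggles = toggles, use_bam = use_bam,
                 bam_settings = bam_settings, ole = ole, cc = cc,
                 esf_n_resamples = esf_n_resamples, do_kde = do_kde,
                 kde = kde, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 4294967291)
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Executes filter -> calibrate -> chronology (OLE and optionally the
#' Bayesian phase model) -> temporal overlap -> carrying capacity ->
#' coexistence group comparison -> spatially filtered correlation test
#' (and optionally the KDE overlap stacks), for each requested filtering
#' criteria set. Every output table carries the config hash and seed.
#'
#' @param config a [pipeline_config()].
#' @param world optional pre-generated `synthetic_world` (otherwise
#'   generated from `config$world_config`).
#' @return list of class `pipeline_run` with one entry per criteria tag
#'   plus `world` and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), world = NULL) {
  stop_if_not(inherits(config, "pipeline_config"), "need a pipeline_config")
  if (is.null(world)) world <- generate_world(config$world_config)
  prov <- list(config_hash = config_hash(config), seed = config$seed,
               package_version = as.character(utils::packageVersion("paleocc")))
  runs <- lapply(config$criteria, function(fc)
    run_criteria(world, config, fc))
  names(runs) <- config$criteria
  out <- structure(c(runs, list(world = world, provenance = prov)),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

run_criteria <- function(world, config, fc) {
  dates <- filter_dates(world$dates, fc, config$toggles)
  if (nrow(dates) == 0) stop("stage filter: no dates survive", call. = FALSE)
  dens <- calibrate_dates(dates, world$curve)
  dates$cal_mean_ka <- vapply(dens, function(d) d$mean_ka, 0)
  dates$cal_sd_ka <- vapply(dens, function(d) d$sd_ka, 0)

  regions <- world$regions$region
  chron <- lapply(regions, function(rid) {
    est <- function(cls, direction, kind) {
      sel <- dates$region == rid & dates$class == cls
      if (sum(sel) < config$ole$min_dates) return(NULL)
      if (config$use_bam) {
        bs <- config$bam_settings
        fit <- fit_bam(dens[which(sel)],
                       window = c(max(dates$cal_mean_ka[sel]) + 3,
                                  min(dates$cal_mean_ka[sel]) - 3),
                       n_chains = bs$n_chains %||% 3, burn = bs$burn %||% 1000,
                       iter = bs$iter %||% 8000, thin = bs$thin %||% 4,
                       seed = sub_seed(config$seed, "bam", rid, cls))
        if (kind == "end") fit$end else fit$start
      } else {
        cfg <- config$ole
        cfg$direction <- direction
        cfg$seed <- sub_seed(config$seed, "ole", rid, cls)
        cfg$k <- min(cfg$k, sum(sel))
        res <- run_ole(dates$cal_mean_ka[sel], dates$cal_sd_ka[sel], cfg)
        h68 <- unname(stats::quantile(res$draws, c(0.16, 0.84)))
        list(kind = kind, mode = res$estimate,
             hpd68 = c(lower = h68[1], upper = h68[2]),
             hpd95 = c(lower = res$ci[1], upper = res$ci[2]))
      }
    }
    tryCatch(
      region_chronology(rid,
                        nai_end = est("NAI", "last-appearance", "end"),
                        sai_start = est("SAI", "first-appearance", "start"),
                        criteria = fc),
      error = function(e) stop(sprintf("stage chronology, region %s: %s",
                                       rid, conditionMessage(e)), call. = FALSE))
  })
  names(chron) <- regions
  chron <- Filter(function(ch) !is.null(ch$nai_end), chron)

  overlaps <- lapply(chron, temporal_overlap)
  overlap_df <- data.frame(
    region = vapply(overlaps, function(o) o$region, ""),
    minimal_ka = vapply(overlaps, function(o) o$minimal_ka, 0),
    central_ka = vapply(overlaps, function(o) o$central_ka, 0),
    coexistence = vapply(overlaps, function(o) as.logical(o$coexistence), NA),
    stringsAsFactors = FALSE)

  pool <- default_species_pool()
  cc_list <- lapply(regions, function(rid) {
    inc <- world$fauna[[rid]]
    present <- colnames(inc)[colSums(inc) > 0]
    if (length(present) == 0) return(NULL)
    pcom <- list(region = rid,
                 species = pool[pool$species %in% present, , drop = FALSE])
    estimate_cc(world$npp[[match(rid, regions)]], pcom, config$cc,
                seed = sub_seed(config$seed, "cc", rid))
  })
  names(cc_list) <- regions
  cc_df <- do.call(rbind, lapply(regions, function(rid) {
    e <- cc_list[[rid]]
    if (is.null(e)) return(NULL)
    cbind(region = rid, e$by_class, stringsAsFactors = FALSE)
  }))

  comparison <- NULL
  if (any(overlap_df$coexistence %in% TRUE) && any(overlap_df$coexistence %in% FALSE)) {
    no_co <- overlap_df$region[overlap_df$coexistence %in% FALSE]
    med <- cc_df[cc_df$size_class == "medium", c("region", "mean")]
    names(med)[2] <- "value"
    med <- med[med$region %in% overlap_df$region, ]
    comparison <- group_percent_difference(med, no_co, "cc_medium")
  }

  # spatially filtered correlation: medium-size CC vs temporal overlap
  esf <- NULL
  ok <- overlap_df$region[!is.na(overlap_df$central_ka)]
  if (length(ok) >= 5) {
    cen <- world$regions[match(ok, world$regions$region), c("region", "lon", "lat")]
    w <- build_weights(cen)
    ev <- moran_eigenvectors(w)
    ydf <- do.call(rbind, lapply(ok, function(rid) {
      ch <- chron[[rid]]
      ov <- overlaps[[rid]]
      # overlap = SAI start - NAI end; for independent phase posteriors the
      # interval widths combine in quadrature
      w_sai <- max(ch$sai_start$hpd95) - min(ch$sai_start$hpd95)
      w_nai <- max(ch$nai_end$hpd95) - min(ch$nai_end$hpd95)
      half <- sqrt(w_sai^2 + w_nai^2) / 2
      data.frame(region = rid, estimate = ov$central_ka,
                 ci_low = ov$central_ka - half, ci_high = ov$central_ka + half)
    }))
    xdf <- do.call(rbind, lapply(ok, function(rid) {
      cl <- cc_list[[rid]]$by_class
      m <- cl[cl$size_class == "medium", ]
      data.frame(region = rid, estimate = m$mean, ci_low = m$lower,
                 ci_high = m$upper)
    }))
    esf <- resample_correlation(ydf, xdf, ev, w,
                                n_resamples = config$esf_n_resamples,
                                seed = sub_seed(config$seed, "esf", fc))
  }

  kde <- NULL
  if (isTRUE(config$do_kde)) {
    kde <- kde_overlap(dates, dens, config$kde)
  }

  list(criteria = fc, dates = dates, chronology = chron,
       overlaps = overlap_df, cc = cc_df, cc_estimates = cc_list,
       comparison = comparison, esf = esf, kde = kde)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# config_hash=%s seed=%d paleocc=%s",
                 run$provenance$config_hash, run$provenance$seed,
                 run$provenance$package_version)
  for (fc in setdiff(names(run), c("world", "provenance"))) {
    for (what in c("overlaps", "cc")) {
      f <- file.path(dir, sprintf("%s_%s.tsv", fc, what))
      writeLines(hdr, f)
      suppressWarnings(utils::write.table(run[[fc]][[what]], f, sep = "\t",
                                          row.names = FALSE, quote = FALSE,
                                          append = TRUE))
    }
  }
  invisible(dir)
}

#' Percentile classification of a regional metric
#'
#' Low (L) below the 0.25 percentile, high (H) above the 0.75 percentile,
#' medium (M) in between; values tied with a quartile go to M, so a metric
#' equal across all regions is all-M.
#'
#' @param values numeric vector.
#' @return character vector of "L"/"M"/"H".
#' @export
classify_percentile <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.75))
  ifelse(values < q[1], "L", ifelse(values > q[2], "H", "M"))
}

#' Human-readable run report
#'
#' Tables of region chronologies, overlaps, carrying-capacity classifications
#' (low/medium/high by the 0.25/0.75 percentile rule) and correlation-test
#' summaries.
#'
#' @param run a [run_pipeline()] result.
#' @return character vector of report lines (invisibly printed tables are
#'   attached as the "tables" attribute).
#' @export
make_report <- function(run) {
  stop_if_not(inherits(run, "pipeline_run"), "need a pipeline_run")
  lines <- c(sprintf("paleocc pipeline run (config %s, seed %d)",
                     run$provenance$config_hash, run$provenance$seed), "")
  tables <- list()
  for (fc in setdiff(names(run), c("world", "provenance"))) {
    r <- run[[fc]]
    stop_if_not(!is.null(r$overlaps) && !is.null(r$cc),
                sprintf("missing artifact for criteria %s", fc))
    lines <- c(lines, sprintf("== criteria %s ==", fc))
    if (nrow(r$overlaps) == 0 || all(is.na(r$overlaps$minimal_ka))) {
      lines <- c(lines, "no overlap computed (no region with both industries)")
    } else {
      n_co <- sum(r$overlaps$coexistence %in% TRUE)
      lines <- c(lines, sprintf("%d/%d regions with temporal overlap > 0",
                                n_co, nrow(r$overlaps)))
    }
    med <- r$cc[r$cc$size_class == "medium", ]
    if (nrow(med) > 0) {
      med$class <- classify_percentile(med$mean)
      tables[[paste0(fc, "_cc_medium")]] <- med
    }
    if (!is.null(r$comparison)) {
      lines <- c(lines, sprintf(
        "medium-size CC %.0f%% lower in no-coexistence regions",
        r$comparison$percent_lower))
    }
    if (!is.null(r$esf)) {
      lines <- c(lines, sprintf(
        "CC-overlap test: median coefficient %.4f, median p %.4f, %.0f%% of resamples significant",
        r$esf$median_coefficient, r$esf$median_p, 100 * r$esf$frac_significant))
    }
    lines <- c(lines, "")
  }
  structure(lines, tables = tables)
}
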