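#' Region chronology container
#'
#' @param region region id.
#' @param nai_end `phase_estimate`-like list for the NAI disappearance
#'   (fields `mode`, `hpd68`, `hpd95`).
#' @param sai_start same for the SAI appearance, or `NULL` when the SAI is
#'   not represented in the region under the chosen filtering criteria.
#' @param criteria filtering criteria tag ("fc1"/"fc2").
#' @return list of class `region_chronology`.
#' @export
region_chronology <- function(region, nai_end, sai_start = NULL,
                              criteria = "fc1") {
  structure(list(region = region, nai_end = nai_end, sai_start = sai_start,
                 criteria = criteria),
            class = "region_chronology")
}

#' Temporal overlap between the NAI end and the SAI start
#'
#' Ages in ka BP, larger = older; overlap is positive when the SAI start is
#' older than the NAI end. The minimal overlap uses the 95% HPD bounds
#' (youngest SAI-start bound minus oldest NAI-end bound); the central
#' overlap is the difference of the posterior modes. A 68%-based variant is
#' available via `level`.
#'
#' @param chron a [region_chronology()].
#' @param level HPD level used for the minimal overlap ("95" or "68").
#' @return list of class `overlap_result` with `region`, `minimal_ka`,
#'   `central_ka`, `coexistence` (minimal overlap > 0), `sai_absent`.
#' @export
temporal_overlap <- function(chron, level = c("95", "68")) {
  level <- match.arg(level)
  if (is.null(chron$sai_start)) {
    return(structure(list(region = chron$region, minimal_ka = NA_real_,
                          central_ka = NA_real_, coexistence = NA,
                          sai_absent = TRUE),
                     class = "overlap_result"))
  }
  key <- paste0("hpd", level)
  for (side in list(chron$nai_end, chron$sai_start)) {
    stop_if_not(!is.null(side[[key]]) && all(is.finite(side[[key]])),
                sprintf("region %s: missing HPD bounds", chron$region))
  }
  sai_young <- min(chron$sai_start[[key]])
  nai_old <- max(chron$nai_end[[key]])
  minimal <- sai_young - nai_old
  central <- chron$sai_start$mode - chron$nai_end$mode
  structure(list(region = chron$region, minimal_ka = minimal,
                 central_ka = central, coexistence = minimal > 0,
                 sai_absent = FALSE),
            class = "overlap_result")
}

#' Group percent difference of a regional metric
#'
#' Unweighted group means over coexistence and no-coexistence regions;
#' percent difference is `100 * (1 - mean_no / mean_co)`, i.e. how much
#' lower the metric is in the no-coexistence group.
#'
#' @param metrics data.frame with columns `region` and `value`.
#' @param no_coexistence character vector of no-coexistence region ids; all
#'   remaining regions form the coexistence group.
#' @param metric_name label carried in the result.
#' @return list of class `group_comparison` with group means,
#'   `percent_lower` (full precision) and `percent_lower_rounded`.
#' @export
group_percent_difference <- function(metrics, no_coexistence,
                                     metric_name = "metric") {
  stop_if_not(all(c("region", "value") %in% names(metrics)),
              "metrics needs region and value columns")
  stop_if_not(!anyNA(metrics$value), "metric missing for some region")
  no <- metrics$value[metrics$region %in% no_coexistence]
  co <- metrics$value[!metrics$region %in% no_coexistence]
  stop_if_not(length(no) > 0 && length(co) > 0, "both groups must be non-empty")
  stop_if_not(mean(co) > 0, "coexistence-group mean must be positive")
  pct <- 100 * (1 - mean(no) / mean(co))
  structure(list(metric = metric_name,
                 mean_coexistence = mean(co), mean_no_coexistence = mean(no),
                 percent_lower = pct, percent_lower_rounded = round(pct)),
            class = "group_comparison")
}

#' Coefficient of variation, percent
#'
#' `100 * sample SD / mean`; the mean must be positive.
#'
#' @param x numeric series.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  stop_if_not(mean(x) > 0, "CV undefined for mean <= 0")
  100 * stats::sd(x) / mean(x)
}
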