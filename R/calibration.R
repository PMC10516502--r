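RADIOCARBON_METHODS <- c("radiocarbon-AMS-ultrafiltration",
                         "radiocarbon-ABOx",
                         "radiocarbon-conventional")
CHRONOMETRIC_METHODS <- c(RADIOCARBON_METHODS, "OSL", "TL", "U-Th")

#' Read a calibration curve in the IntCal-style dialect
#'
#' Three whitespace- or comma-delimited columns: calendar age (cal BP),
#' radiocarbon age (yr BP), curve error (yr). Lines starting with `#` are
#' comments. Knots are sorted by calendar age on read.
#'
#' @param path file path.
#' @param name curve name.
#' @param marine whether this is a marine curve (required for marine-flagged
#'   dates); the reservoir offset `delta_r` defaults to 0 with error 0.
#' @param delta_r,delta_r_error reservoir offset and its 1-sigma error, yr.
#' @return an object of class `calibration_curve`.
#' @export
read_calibration_curve <- function(path, name = basename(path), marine = FALSE,
                                   delta_r = 0, delta_r_error = 0) {
  tab <- utils::read.table(path, comment.char = "#", sep = "",
                           col.names = c("cal_bp", "c14_bp", "error"))
  tab <- tab[order(tab$cal_bp), ]
  stop_if_not(all(tab$error > 0), "curve errors must be > 0")
  structure(list(cal_bp = tab$cal_bp, c14_bp = tab$c14_bp, error = tab$error,
                 name = name, delta_r = delta_r,
                 delta_r_error = delta_r_error, marine = marine),
            class = "calibration_curve")
}

new_calibrated_density <- function(grid_ka, mass) {
  s <- sum(mass)
  stop_if_not(s > 0, "calibrated density has zero total mass")
  mass <- mass / s
  structure(list(grid_ka = grid_ka, mass = mass,
                 mode_ka = grid_ka[which.max(mass)],
                 mean_ka = sum(grid_ka * mass),
                 sd_ka = sqrt(max(0, sum(grid_ka^2 * mass) - sum(grid_ka * mass)^2))),
            class = "calibrated_density")
}

#' Calibrate a chronometric date
#'
#' Radiocarbon dates are calibrated against the curve: the posterior on the
#' calendar grid is proportional to
#' `N(measurement - delta_r; curve mean, sqrt(lab^2 + curve^2 + delta_r_err^2))`,
#' normalized to unit mass. Non-radiocarbon determinations (OSL/TL/U-Th)
#' bypass the curve as normal densities with their 1-sigma error.
#'
#' @param age measured age: uncalibrated radiocarbon yr BP for radiocarbon
#'   methods, calendar yr BP otherwise.
#' @param error 1-sigma error in yr.
#' @param curve a `calibration_curve` (ignored for non-radiocarbon methods).
#' @param method one of the supported chronometric methods.
#' @param grid_step_ka calendar grid step, ka (default 0.005 = 5 yr).
#' @param label date label used in error messages.
#' @return a `calibrated_density` (grid in ka cal BP; masses sum to 1).
#' @export
calibrate <- function(age, error, curve = NULL,
                      method = "radiocarbon-AMS-ultrafiltration",
                      grid_step_ka = 0.005, label = NULL) {
  stop_if_not(method %in% CHRONOMETRIC_METHODS,
              sprintf("unknown method '%s'", method))
  stop_if_not(error >= 0, "error must be >= 0")
  if (!method %in% RADIOCARBON_METHODS) {
    half <- max(5 * error / 1000, 5 * grid_step_ka)
    grid <- seq(age / 1000 - half, age / 1000 + half, by = grid_step_ka)
    return(new_calibrated_density(grid, stats::dnorm(grid * 1000, age, max(error, 1e-9))))
  }
  stop_if_not(inherits(curve, "calibration_curve"),
              "radiocarbon calibration needs a calibration_curve")
  m <- age - curve$delta_r
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = grid_step_ka * 1000) / 1000
  mu <- curve_c14_at(curve, grid)
  s <- sqrt(error^2 + curve_error_at(curve, grid)^2 + curve$delta_r_error^2)
  z <- abs(m - mu) / s
  if (min(z) > 5) {
    stop(sprintf("date %s (%.0f +/- %.0f BP) lies outside the curve support at 5 sigma",
                 label %||% "<unnamed>", age, error), call. = FALSE)
  }
  dens <- stats::dnorm(m, mu, s)
  dens[z > 5] <- 0  # truncate at +/- 5 sigma
  new_calibrated_density(grid, dens)
}

#' Calibrate every date in a table
#'
#' @param dates a chronometric date table (see [filter_dates()]); ages are
#'   converted from the declared `age_units` ("yr" or "ka").
#' @param curve calibration curve for terrestrial dates.
#' @param marine_curve optional marine curve for `marine`-flagged dates;
#'   required when any date is marine.
#' @param grid_step_ka calendar grid step, ka.
#' @return list of `calibrated_density`, one per row.
#' @export
calibrate_dates <- function(dates, curve, marine_curve = NULL,
                            grid_step_ka = 0.005) {
  k <- if ("age_units" %in% names(dates) && any(dates$age_units == "ka")) {
    ifelse(dates$age_units == "ka", 1000, 1)
  } else rep(1, nrow(dates))
  if (any(dates$marine %||% FALSE)) {
    stop_if_not(!is.null(marine_curve) && isTRUE(marine_curve$marine),
                "marine-flagged dates require a marine calibration curve")
  }
  lapply(seq_len(nrow(dates)), function(i) {
    cv <- if (isTRUE(dates$marine[i])) marine_curve else curve
    calibrate(dates$age[i] * k[i], dates$error[i] * k[i], cv,
              method = dates$method[i], grid_step_ka = grid_step_ka,
              label = dates$site[i])
  })
}

#' Combine radiocarbon measurements on the same sample
#'
#' Inverse-variance weighted mean with pooled error, plus a chi-square
#' consistency statistic (the standard radiocarbon date-combination
#' convention).
#'
#' @param ages,errors numeric vectors (>= 2 radiocarbon determinations on
#'   one sample), in yr BP.
#' @param methods optional method labels; mixing radiocarbon with
#'   non-radiocarbon methods is an error.
#' @param alpha significance level for the consistency flag.
#' @return list with `age`, `error`, `chisq`, `df`, `p_value`, `consistent`.
#' @export
combine_same_sample <- function(ages, errors, methods = NULL, alpha = 0.05) {
  stop_if_not(length(ages) >= 2, "need >= 2 dates on one sample")
  stop_if_not(all(errors > 0), "errors must be > 0")
  if (!is.null(methods)) {
    radio <- methods %in% RADIOCARBON_METHODS
    stop_if_not(all(radio) || all(!radio),
                "cannot combine mixed radiocarbon and non-radiocarbon methods")
  }
  w <- 1 / errors^2
  m <- sum(w * ages) / sum(w)
  s <- sqrt(1 / sum(w))
  chisq <- sum((ages - m)^2 / errors^2)
  df <- length(ages) - 1
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  list(age = m, error = s, chisq = chisq, df = df, p_value = p,
       consistent = p >= alpha)
}
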