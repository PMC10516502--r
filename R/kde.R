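#' KDE configuration
#'
#' @param bandwidth_km Gaussian kernel sigma in km (default 150, on the
#'   order of the annual migration distance of extant hunter-gatherers).
#' @param step_ka time bin width in ka.
#' @param window time window `c(old_ka, young_ka)`.
#' @param res_deg raster resolution in degrees.
#' @param extent raster extent `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return list of class `kde_config`.
#' @export
kde_config <- function(bandwidth_km = 150, step_ka = 1, window = c(50, 30),
                       res_deg = 0.5, extent = c(-11, 30, 34, 55)) {
  stop_if_not(bandwidth_km > 0 && step_ka > 0, "bandwidth and step must be > 0")
  structure(list(bandwidth_km = bandwidth_km, step_ka = step_ka,
                 window = window, res_deg = res_deg, extent = extent),
            class = "kde_config")
}

#' Spatiotemporal kernel density overlap surfaces
#'
#' For every time bin, each date contributes a weight equal to its calibrated
#' probability mass inside the bin, spread over the raster by a Gaussian
#' kernel (sigma = bandwidth) of great-circle distance from its site. One
#' raster stack is built per class (NAI, SAI); the overlap stack is their
#' elementwise product, non-zero only where both classes are present.
#'
#' @param dates filtered date table with columns `lon`, `lat`, `class`.
#' @param densities list of `calibrated_density`, parallel to `dates` rows.
#' @param config a [kde_config()].
#' @return list with 3-d arrays (lon x lat x time) `nai`, `sai`, `overlap`,
#'   plus the `lon`, `lat` and `time_bins` coordinate vectors.
#' @export
kde_overlap <- function(dates, densities, config = kde_config()) {
  stop_if_not(nrow(dates) == length(densities),
              "dates and densities must be parallel")
  stop_if_not(all(dates$lon >= config$extent[1] & dates$lon <= config$extent[2] &
                    dates$lat >= config$extent[3] & dates$lat <= config$extent[4]),
              "coordinates outside the grid extent")
  lon <- seq(config$extent[1], config$extent[2], by = config$res_deg)
  lat <- seq(config$extent[3], config$extent[4], by = config$res_deg)
  edges <- seq(config$window[1], config$window[2], by = -config$step_ka)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  nbin <- length(mids)
  grid <- expand.grid(lon = lon, lat = lat)
  shape <- c(length(lon), length(lat), nbin)
  stacks <- list(NAI = array(0, shape), SAI = array(0, shape))

  # per-bin calibrated mass for one density
  bin_mass <- function(d) {
    b <- findInterval(-d$grid_ka, -edges)  # bins indexed old -> young
    m <- numeric(nbin)
    ok <- b >= 1 & b <= nbin
    if (any(ok)) {
      agg <- tapply(d$mass[ok], b[ok], sum)
      m[as.integer(names(agg))] <- agg
    }
    m
  }

  kern_cache <- new.env()
  for (i in seq_len(nrow(dates))) {
    cls <- dates$class[i]
    if (!cls %in% names(stacks)) next
    key <- sprintf("%.4f_%.4f", dates$lon[i], dates$lat[i])
    kern <- kern_cache[[key]]
    if (is.null(kern)) {
      dist <- haversine_km(dates$lon[i], dates$lat[i], grid$lon, grid$lat)
      kern <- exp(-0.5 * (dist / config$bandwidth_km)^2)
      kern_cache[[key]] <- kern
    }
    w <- bin_mass(densities[[i]])
    nz <- which(w > 0)
    for (b in nz) {
      stacks[[cls]][, , b] <- stacks[[cls]][, , b] + w[b] * kern
    }
  }
  list(nai = stacks$NAI, sai = stacks$SAI,
       overlap = stacks$NAI * stacks$SAI,
       lon = lon, lat = lat, time_bins = mids)
}
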