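# Internal helpers shared across modules. Ages are handled internally in
# ka cal BP (BP = 1950), larger = older; distances in km on a sphere of
# radius 6371 km.

EARTH_RADIUS_KM <- 6371

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Great-circle distance matrix
#'
#' Haversine distances between points given in decimal degrees, on a sphere
#' of radius 6371 km.
#'
#' @param lon,lat numeric vectors of coordinates.
#' @return symmetric matrix of distances in km.
#' @export
haversine_matrix <- function(lon, lat) {
  n <- length(lon)
  pts <- cbind(lon, lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = EARTH_RADIUS_KM * 1000) / 1000
  }
  (d + t(d)) / 2
}

# distances (km) from one point to many
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(c(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# truncated normal draws via inverse cdf; vectorised over mean/sd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lower), upper)
}

# derive a reproducible 32-bit sub-seed from a base seed and a string tag
sub_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# shortest interval containing prob mass of a sample (highest posterior
# density interval from pooled MCMC draws)
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  width <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + m])
}

# kernel-smoothed density argmax (fixed smoothing rule: Silverman's nrd0)
posterior_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, n = 1024)
  d$x[which.max(d$y)]
}

# split-chain potential scale reduction (Gelman-Rubin style); chains is a
# list of equal-length numeric vectors
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    h <- floor(length(ch) / 2)
    list(ch[seq_len(h)], ch[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
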