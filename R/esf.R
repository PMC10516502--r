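#' Build a spatial weight matrix over region centroids
#'
#' Inverse great-circle-distance weights (or binary within a distance band),
#' zero diagonal, with a row-standardized copy attached.
#'
#' @param centroids data.frame with `region`, `lon`, `lat` (>= 3 regions).
#' @param scheme "inverse-distance" or "distance-band".
#' @param band_km band radius for the binary scheme.
#' @return list of class `spatial_weights`: `ids`, `W` (symmetric raw),
#'   `W_row` (row-standardized), `scheme`.
#' @export
build_weights <- function(centroids, scheme = c("inverse-distance", "distance-band"),
                          band_km = 1000) {
  scheme <- match.arg(scheme)
  stop_if_not(nrow(centroids) >= 3, "need at least 3 regions")
  D <- haversine_matrix(centroids$lon, centroids$lat)
  offdiag <- D[upper.tri(D)]
  stop_if_not(all(offdiag > 0), "coincident centroids")
  W <- if (scheme == "inverse-distance") 1 / D else (D <= band_km) * 1
  diag(W) <- 0
  rs <- rowSums(W)
  stop_if_not(all(rs > 0), "a region has zero total weight")
  structure(list(ids = centroids$region, W = W, W_row = W / rs,
                 scheme = scheme),
            class = "spatial_weights")
}

#' Moran's I with a permutation test
#'
#' Standard Moran coefficient with row-standardized weights; the p-value is
#' from random permutations of the values (two-sided, seeded).
#'
#' @param values numeric vector (>= 3 non-constant values).
#' @param weights a [build_weights()] object.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `I`, `expected` (-1/(n-1)), `p_value`.
#' @export
moran_i <- function(values, weights, n_perm = 999, seed = 1L) {
  n <- length(values)
  stop_if_not(n >= 3, "need >= 3 values")
  stop_if_not(stats::sd(values) > 0, "Moran's I undefined for a constant vector")
  W <- weights$W_row
  s0 <- sum(W)
  obs <- moran_stat(values, W, s0)
  set.seed(sub_seed(seed, "moran"))
  perm <- vapply(seq_len(n_perm), function(i)
    moran_stat(sample(values), W, s0), numeric(1))
  e <- -1 / (n - 1)
  p <- (1 + sum(abs(perm - e) >= abs(obs - e))) / (n_perm + 1)
  list(I = obs, expected = e, p_value = p)
}

moran_stat <- function(values, W, s0 = sum(W)) {
  z <- values - mean(values)
  (length(values) / s0) * drop(z %*% W %*% z) / sum(z^2)
}

#' Moran eigenvectors of a spatial weight matrix
#'
#' Eigen-decomposition of the doubly-centered weight matrix `M W M` with
#' `M = I - 11'/n`: the eigenvectors are orthonormal, orthogonal to the
#' constant vector, and ordered by decreasing eigenvalue (each eigenvalue is
#' proportional to the Moran coefficient of its vector). Candidates with
#' `eigenvalue / max eigenvalue` above the threshold are retained.
#'
#' @param weights a [build_weights()] object.
#' @param threshold candidate retention threshold (default 0.25).
#' @return list of class `eigenvector_set`: `vectors` (n x m), `values`,
#'   `threshold`.
#' @export
moran_eigenvectors <- function(weights, threshold = 0.25) {
  W <- (weights$W + t(weights$W)) / 2
  n <- nrow(W)
  M <- diag(n) - matrix(1 / n, n, n)
  eig <- eigen(M %*% W %*% M, symmetric = TRUE)
  keep <- eig$values / max(eig$values) > threshold & eig$values > 0
  structure(list(vectors = eig$vectors[, keep, drop = FALSE],
                 values = eig$values[keep], threshold = threshold),
            class = "eigenvector_set")
}

#' Eigenvector-spatially-filtered regression
#'
#' OLS of `y` on `x` plus forward-selected Moran eigenvectors. At each step
#' the candidate that minimizes the absolute residual Moran's I is added;
#' selection stops when the residual autocorrelation is no longer
#' significant (permutation p >= `stop_alpha`) or no candidate reduces it.
#'
#' @param y,x numeric vectors over regions.
#' @param eigvecs an [moran_eigenvectors()] set.
#' @param weights the [build_weights()] object (for residual Moran tests).
#' @param stop_alpha significance level of the residual-autocorrelation
#'   stopping rule (default 0.10).
#' @param n_perm permutations per residual Moran test.
#' @param seed integer seed.
#' @return list of class `esf_fit`: `coefficient` (on x), `p_value`
#'   (two-sided), `selected` (indices of selected eigenvectors),
#'   `residual_moran`.
#' @export
fit_esf <- function(y, x, eigvecs, weights, stop_alpha = 0.10,
                    n_perm = 199, seed = 1L) {
  n <- length(y)
  stop_if_not(length(x) == n, "y and x lengths differ")
  E <- eigvecs$vectors
  selected <- integer(0)
  max_sel <- max(0, n - 4)
  repeat {
    X <- cbind(x, E[, selected, drop = FALSE])
    fit <- stats::lm.fit(cbind(1, X), y)
    res <- fit$residuals
    if (stats::sd(res) < 1e-12) break
    mt <- moran_i(res, weights, n_perm = n_perm,
                  seed = sub_seed(seed, "esf", length(selected)))
    if (mt$p_value >= stop_alpha) break
    remaining <- setdiff(seq_len(ncol(E)), selected)
    if (length(remaining) == 0 || length(selected) >= max_sel) break
    cur <- abs(mt$I - mt$expected)
    trial <- vapply(remaining, function(j) {
      Xj <- cbind(1, x, E[, c(selected, j), drop = FALSE])
      rj <- stats::lm.fit(Xj, y)$residuals
      if (stats::sd(rj) < 1e-12) return(0)
      abs(moran_stat(rj, weights$W_row) - mt$expected)
    }, numeric(1))
    if (min(trial) >= cur) break
    selected <- c(selected, remaining[which.min(trial)])
  }
  stop_if_not(n - length(selected) - 2 >= 1,
              "more selected eigenvectors than degrees of freedom")
  df <- data.frame(y = y, x = x)
  if (length(selected) > 0) {
    ev <- E[, selected, drop = FALSE]
    colnames(ev) <- paste0("E", selected)
    df <- cbind(df, ev)
  }
  lmfit <- stats::lm(y ~ ., data = df)
  sm <- summary(lmfit)$coefficients
  res <- stats::residuals(lmfit)
  rm_i <- if (stats::sd(res) > 1e-12)
    moran_stat(res, weights$W_row) else NA_real_
  structure(list(coefficient = unname(sm["x", "Estimate"]),
                 p_value = unname(sm["x", "Pr(>|t|)"]),
                 selected = selected, residual_moran = rm_i,
                 model = lmfit),
            class = "esf_fit")
}

#' Correlation test with 95%-CI uncertainty resampling
#'
#' Draws every dependent and independent value from the distribution implied
#' by its 95% CI (two-piece normal centered at the point estimate, sd =
#' half-width / 1.96 on each side; optionally truncated to the bounds),
#' refits the spatially filtered regression for each of `n_resamples` draws,
#' and reports the coefficient and p-value distributions and the fraction of
#' resamples significant at `alpha`.
#'
#' @param y,x data.frames with columns `estimate`, `ci_low`, `ci_high`
#'   (bounds must bracket the estimates).
#' @param eigvecs an [moran_eigenvectors()] set.
#' @param weights a [build_weights()] object.
#' @param n_resamples number of CI draws (default 10,000).
#' @param alpha significance threshold (default 0.05).
#' @param truncate truncate draws to the CI bounds.
#' @param seed integer seed.
#' @return list of class `esf_resample`: `coefficients`, `p_values`,
#'   `frac_significant`, `median_coefficient`, `median_p`,
#'   `selected_count_summary`.
#' @export
resample_correlation <- function(y, x, eigvecs, weights, n_resamples = 10000,
                                 alpha = 0.05, truncate = FALSE, seed = 1L) {
  check_ci <- function(d, nm) {
    stop_if_not(all(d$ci_low <= d$ci_high), sprintf("%s: degenerate CI", nm))
    stop_if_not(all(d$ci_low <= d$estimate & d$estimate <= d$ci_high),
                sprintf("%s: CI bounds must bracket the estimates", nm))
  }
  check_ci(y, "y"); check_ci(x, "x")
  set.seed(sub_seed(seed, "resample"))
  draw <- function(d) {
    sd_lo <- (d$estimate - d$ci_low) / 1.96
    sd_hi <- (d$ci_high - d$estimate) / 1.96
    z <- stats::rnorm(nrow(d))
    v <- d$estimate + ifelse(z < 0, z * sd_lo, z * sd_hi)
    if (truncate) v <- pmin(pmax(v, d$ci_low), d$ci_high)
    v
  }
  coefs <- numeric(n_resamples)
  ps <- numeric(n_resamples)
  nsel <- integer(n_resamples)
  for (i in seq_len(n_resamples)) {
    fit <- fit_esf(draw(y), draw(x), eigvecs, weights,
                   seed = sub_seed(seed, "resample-fit", i))
    coefs[i] <- fit$coefficient
    ps[i] <- fit$p_value
    nsel[i] <- length(fit$selected)
  }
  structure(list(coefficients = coefs, p_values = ps,
                 frac_significant = mean(ps <= alpha),
                 median_coefficient = stats::median(coefs),
                 median_p = stats::median(ps),
                 selected_count_summary = summary(nsel),
                 alpha = alpha, n_resamples = n_resamples),
            class = "esf_resample")
}
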