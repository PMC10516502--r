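line_centroids <- function(n, spacing_deg = 2) {
  data.frame(region = sprintf("R_%d", seq_len(n)),
             lon = seq(0, by = spacing_deg, length.out = n), lat = 45)
}

test_that("inverse-distance weights match hand computation on a line", {
  cen <- line_centroids(4)
  w <- build_weights(cen)
  d12 <- haversine_km(cen$lon[1], 45, cen$lon[2], 45)
  d13 <- haversine_km(cen$lon[1], 45, cen$lon[3], 45)
  expect_equal(w$W[1, 2], 1 / d12, tolerance = 1e-9)
  expect_equal(w$W[1, 3], 1 / d13, tolerance = 1e-9)
  expect_equal(w$W, t(w$W))
  expect_true(all(diag(w$W) == 0))
  expect_equal(unname(rowSums(w$W_row)), rep(1, 4))

  # equidistant neighbours get equal weight
  expect_equal(w$W[2, 1], w$W[2, 3], tolerance = 1e-6)

  # doubling all distances halves all raw inverse-distance weights
  w2 <- build_weights(line_centroids(4, spacing_deg = 4))
  expect_equal(w2$W[1, 2], w$W[1, 2] / 2, tolerance = 1e-3)

  expect_error(build_weights(data.frame(region = c("a", "b", "c"),
                                        lon = c(0, 0, 1), lat = 45)),
               "coincident")
})

test_that("Moran's I agrees with an independent implementation and flags sign", {
  cen <- line_centroids(8)
  w <- build_weights(cen)
  set.seed(2)
  x <- rnorm(8)
  expect_equal(paleocc:::moran_stat(x, w$W_row), oracle_moran(x, w$W_row),
               tolerance = 1e-12)
  if (requireNamespace("ape", quietly = TRUE)) {
    expect_equal(paleocc:::moran_stat(x, w$W_row),
                 unname(ape::Moran.I(x, w$W_row, scaled = FALSE)$observed),
                 tolerance = 1e-9)
  }

  # perfect checkerboard on a line: strong negative autocorrelation
  chk <- moran_i(rep(c(1, -1), 4), w)
  expect_lt(chk$I, 0)
  expect_error(moran_i(rep(1, 8), w), "constant")
})

test_that("Moran eigenvectors are centered, orthonormal and maximise I", {
  cen <- line_centroids(10)
  w <- build_weights(cen)
  ev <- moran_eigenvectors(w, threshold = 0)
  expect_lte(ncol(ev$vectors), 9)
  expect_true(all(abs(colSums(ev$vectors)) < 1e-10))
  expect_equal(crossprod(ev$vectors), diag(ncol(ev$vectors)), tolerance = 1e-9)

  # the first eigenvector attains (numerically) the maximal Moran's I
  i1 <- paleocc:::moran_stat(ev$vectors[, 1], w$W_row)
  set.seed(3)
  i_rand <- vapply(1:200, function(i) {
    paleocc:::moran_stat(rnorm(10), w$W_row)
  }, numeric(1))
  expect_gte(i1, max(i_rand))

  # 4-node path: decomposition matches a directly constructed M W M (up to sign)
  cen4 <- line_centroids(4)
  w4 <- build_weights(cen4)
  M <- diag(4) - matrix(1 / 4, 4, 4)
  ref <- eigen(M %*% ((w4$W + t(w4$W)) / 2) %*% M, symmetric = TRUE)
  ev4 <- moran_eigenvectors(w4, threshold = 0)
  for (j in seq_len(ncol(ev4$vectors))) {
    expect_equal(abs(sum(ev4$vectors[, j] * ref$vectors[, j])), 1,
                 tolerance = 1e-9)
  }
})

test_that("spatially filtered regression recovers exact relationships", {
  set.seed(4)
  cen <- line_centroids(15)
  w <- build_weights(cen)
  ev <- moran_eigenvectors(w)
  x <- rnorm(15)
  fit0 <- suppressWarnings(fit_esf(x, x, ev, w))  # exact fit warns in lm
  expect_equal(fit0$coefficient, 1, tolerance = 1e-9)
  expect_lt(fit0$p_value, 1e-12)
  expect_equal(length(fit0$selected), 0L)

  # with zero vectors selected the coefficient equals plain OLS exactly
  y <- 2 * x + rnorm(15, 0, 0.1)
  fit1 <- fit_esf(y, x, ev, w)
  if (length(fit1$selected) == 0) {
    expect_equal(fit1$coefficient, unname(coef(lm(y ~ x))[2]), tolerance = 1e-12)
  }

  # construction oracle: y = x + first eigenvector; once the vector is
  # selected the x coefficient returns to 1
  y2 <- x + 3 * ev$vectors[, 1]
  fit2 <- suppressWarnings(fit_esf(y2, x, ev, w))
  expect_true(1 %in% fit2$selected || abs(fit2$coefficient - 1) < 0.05)
  if (1 %in% fit2$selected) expect_equal(fit2$coefficient, 1, tolerance = 1e-6)
})

test_that("CI resampling collapses for zero-width CIs and guards degenerate input", {
  set.seed(5)
  cen <- line_centroids(12)
  w <- build_weights(cen)
  ev <- moran_eigenvectors(w)
  x <- rnorm(12); y <- x + rnorm(12, 0, 0.3)
  ydf <- data.frame(region = cen$region, estimate = y, ci_low = y, ci_high = y)
  xdf <- data.frame(region = cen$region, estimate = x, ci_low = x, ci_high = x)
  rs <- resample_correlation(ydf, xdf, ev, w, n_resamples = 50)
  expect_equal(length(unique(rs$coefficients)), 1L)
  expect_equal(rs$coefficients[1], fit_esf(y, x, ev, w)$coefficient,
               tolerance = 1e-12)

  bad <- ydf; bad$ci_low[1] <- bad$ci_high[1] + 1
  expect_error(resample_correlation(bad, xdf, ev, w, n_resamples = 5),
               "degenerate|bracket")
})
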