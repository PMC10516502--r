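test_that("dCORT reproduces hand-computed values and limiting cases", {
  s1 <- toy_series(c(0, 1, 2))
  s2 <- toy_series(c(0, -1, -2))
  # CORT = -1, phi_2(-1) = 2/(1 + e^-2), d = sqrt(20)
  expect_equal(dcort_distance(s1, s2),
               2 / (1 + exp(-2)) * sqrt(20), tolerance = 1e-9)
  expect_equal(dcort_distance(s1, s1), 0)

  # orthogonal increments: CORT = 0, phi = 1, so dCORT = Euclidean distance
  a <- toy_series(c(0, 1, 1)); b <- toy_series(c(0, 0, 1))
  expect_equal(dcort_distance(a, b), sqrt(sum((a$npp - b$npp)^2)))

  # k = 0 reduces to the Euclidean distance regardless of CORT
  expect_equal(dcort_distance(s1, s2, dcort_config(k_tuning = 0)), sqrt(20))

  expect_error(dcort_distance(s1, toy_series(c(0, 1, 2, 3))), "grid")
})

test_that("dCORT is symmetric and zero only on identical series", {
  set.seed(8)
  for (i in 1:10) {
    x <- toy_series(cumsum(rnorm(20)) + 10)
    y <- toy_series(cumsum(rnorm(20)) + 10)
    expect_equal(dcort_distance(x, y), dcort_distance(y, x))
    expect_gte(dcort_distance(x, y), 0)
  }
})

test_that("hierarchical clustering recovers a planted partition deterministically", {
  set.seed(3)
  mk <- function(base, n) lapply(1:n, function(i) toy_series(base + rnorm(30, 0, 0.05)))
  g1 <- mk(sin(1:30 / 3) + 5, 4)
  g2 <- mk(-sin(1:30 / 3) + 15, 4)
  series <- c(g1, g2)
  names(series) <- sprintf("s%02d", 1:8)
  dm <- dcort_matrix(series)
  lab <- cluster_npp(dm, n_clusters = 2)
  expect_equal(unname(lab[1:4]), rep(1L, 4))
  expect_equal(unname(lab[5:8]), rep(2L, 4))

  # gap rule finds the same two clusters
  expect_equal(unname(cluster_npp(dm)), unname(lab))

  # permutation invariance
  perm <- sample(8)
  dm2 <- dm
  dm2$matrix <- dm$matrix[perm, perm]
  lab2 <- cluster_npp(dm2, n_clusters = 2)
  expect_equal(lab2[names(lab)], lab)

  # singleton and error cases
  expect_equal(sort(unique(cluster_npp(dm, n_clusters = 8))), 1:8)
  expect_error(cluster_npp(dm, n_clusters = 9), "exceeds")
})

test_that("Koppen classification follows the documented rule table", {
  warm_wet <- rep(60, 12)
  # polar: hottest month 8 C -> tundra
  expect_equal(koppen_classify(c(rep(-20, 6), rep(8, 6)), warm_wet), "ET")
  expect_equal(koppen_classify(rep(-5, 12), warm_wet), "EF")
  # Dfa boundary: coldest -5, hottest exactly 22, no dry season
  temps <- c(-5, -3, 2, 8, 14, 19, 22, 21, 16, 9, 3, -2)
  expect_equal(koppen_classify(temps, warm_wet), "Dfa")
  # drop the hottest month below 22 -> b (>= 4 months >= 10)
  temps_b <- temps; temps_b[7] <- 21.9
  expect_equal(koppen_classify(temps_b, warm_wet), "Dfb")
  # Csa: coldest 2, hottest 24, summer drought
  temps_c <- c(2, 3, 6, 10, 15, 20, 24, 23, 19, 12, 6, 3)
  precip <- c(80, 70, 60, 40, 20, 10, 5, 8, 30, 60, 80, 90)
  expect_equal(koppen_classify(temps_c, precip), "Csa")
  expect_error(koppen_classify(rep(-95, 12), warm_wet), "non-physical")
  expect_error(koppen_classify(rep(5, 12), rep(-1, 12)), "non-physical")
})

test_that("Jaccard dissimilarity is a bounded metric on sets", {
  expect_equal(jaccard_dissimilarity(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_dissimilarity(c("a"), c("b")), 1)
  expect_equal(jaccard_dissimilarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_message(z <- jaccard_dissimilarity(character(0), character(0)), "empty")
  expect_equal(z, 0)

  # triangle inequality on random triples
  set.seed(5)
  pool <- letters[1:10]
  for (i in 1:20) {
    A <- sample(pool, sample(1:8, 1)); B <- sample(pool, sample(1:8, 1))
    C <- sample(pool, sample(1:8, 1))
    expect_lte(jaccard_dissimilarity(A, C),
               jaccard_dissimilarity(A, B) + jaccard_dissimilarity(B, C) + 1e-12)
  }
})

test_that("region delimitation refines the NPP partition east to west", {
  sites <- data.frame(site = sprintf("s%d", 1:6),
                      lon = c(20, 21, 10, 11, 0, 1),
                      npp_label = c(1, 1, 2, 2, 3, 3),
                      climate = "Dfb", fauna_label = 1,
                      stringsAsFactors = FALSE)
  one <- delimit_regions(transform(sites, npp_label = 1))
  expect_equal(length(unique(one$region)), 1L)

  base <- delimit_regions(sites)
  expect_equal(length(unique(base$region)), 3L)
  # east-west naming: easternmost cluster is R_1
  expect_equal(unique(base$region[base$lon >= 20]), "R_1")
  expect_equal(unique(base$region[base$lon <= 1]), "R_3")

  # a climate split inside one NPP cluster adds exactly one region
  split_clim <- sites
  split_clim$climate[1] <- "ET"
  expect_equal(length(unique(delimit_regions(split_clim)$region)), 4L)

  # a fauna split coinciding in one of three NPP clusters: 4 regions
  split_fauna <- sites
  split_fauna$fauna_label[3] <- 2
  out <- delimit_regions(split_fauna)
  expect_equal(length(unique(out$region)), 4L)
  # refinement: sites in different NPP clusters never share a region
  agg <- table(out$npp_label, out$region)
  expect_true(all(colSums(agg > 0) == 1))

  bad <- sites; bad$climate[2] <- NA
  expect_error(delimit_regions(bad), "labelings")
})
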