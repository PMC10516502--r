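#' dCORT dissimilarity between two NPP series
#'
#' Combines the raw Euclidean distance between the series with a weight based
#' on the temporal correlation of their first differences:
#' `dCORT = phi_k(CORT(s1, s2)) * d_Euclid(s1, s2)`, where `CORT` is the
#' correlation of first differences and `phi_k(u) = 2 / (1 + exp(k * u))`.
#' With `k_tuning = 0` the index reduces to the Euclidean distance; with
#' `k_tuning > 0` series that move in opposite directions are pushed apart.
#'
#' @param s1,s2 `npp_series` objects (or plain lists with `time_ka`, `npp`)
#'   on identical time grids.
#' @param config a [dcort_config()].
#' @return non-negative scalar.
#' @export
dcort_distance <- function(s1, s2, config = dcort_config()) {
  stop_if_not(length(s1$time_ka) == length(s2$time_ka) &&
                all(abs(s1$time_ka - s2$time_ka) < 1e-9),
              "series must share an identical time grid")
  d1 <- diff(s1$npp); d2 <- diff(s2$npp)
  denom <- sqrt(sum(d1^2)) * sqrt(sum(d2^2))
  cort <- if (denom == 0) 0 else sum(d1 * d2) / denom
  phi <- 2 / (1 + exp(config$k_tuning * cort))
  phi * sqrt(sum((s1$npp - s2$npp)^2))
}

#' dCORT configuration
#'
#' @param k_tuning adaptive weight parameter (>= 0, default 2).
#' @return list of class `dcort_config`.
#' @export
dcort_config <- function(k_tuning = 2) {
  stop_if_not(k_tuning >= 0, "k_tuning must be >= 0")
  structure(list(k_tuning = k_tuning, base_distance = "euclidean"),
            class = "dcort_config")
}

#' Pairwise dCORT dissimilarity matrix
#'
#' @param series named list of `npp_series` on a common grid.
#' @param config a [dcort_config()].
#' @return object of class `dissimilarity_matrix` (symmetric, zero diagonal).
#' @export
dcort_matrix <- function(series, config = dcort_config()) {
  n <- length(series)
  ids <- names(series) %||% vapply(series, function(s) as.character(s$id), "")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    m[i, j] <- m[j, i] <- dcort_distance(series[[i]], series[[j]], config)
  }
  structure(list(ids = ids, matrix = m, metric = "dCORT"),
            class = "dissimilarity_matrix")
}

#' Agglomerative clustering of a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering with deterministic label
#' assignment: clusters are renumbered so that the cluster containing the
#' lexicographically smallest member id gets label 1, and so on. With
#' `n_clusters = NULL` the cut is chosen by the largest relative gap in the
#' merge heights.
#'
#' @param dmat a `dissimilarity_matrix` (or plain symmetric matrix).
#' @param n_clusters number of clusters, or `NULL` for the gap rule.
#' @param linkage linkage rule passed to [stats::hclust()].
#' @return named integer vector of cluster labels.
#' @export
cluster_npp <- function(dmat, n_clusters = NULL, linkage = "average") {
  m <- if (inherits(dmat, "dissimilarity_matrix")) dmat$matrix else dmat
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  stop_if_not(is.null(n_clusters) || n_clusters <= nrow(m),
              "n_clusters exceeds the number of items")
  # deterministic under input permutations: order items by id first
  ord <- order(ids)
  m <- m[ord, ord]
  ids <- ids[ord]
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  if (is.null(n_clusters)) {
    h <- hc$height
    if (length(h) < 2) {
      n_clusters <- length(ids)
    } else {
      gaps <- diff(h) / pmax(h[-length(h)], 1e-12)
      n_clusters <- length(ids) - which.max(gaps)
    }
  }
  raw <- stats::cutree(hc, k = n_clusters)
  # relabel so the cluster containing the smallest id gets label 1, etc.
  first_id <- tapply(ids, raw, min)
  new_of_old <- rank(first_id, ties.method = "first")
  out <- as.integer(new_of_old[as.character(raw)])
  names(out) <- ids
  out
}

#' Koppen-Geiger climate class from monthly normals
#'
#' Peel-style threshold rules restricted to the temperate (C), continental
#' (D) and polar (E) families with dry-season letters f/s/w and summer
#' letters a/b/c: hottest month >= 22 C gives "a", otherwise >= 4 months at
#' >= 10 C gives "b", else "c"; hottest month at or below 10 C gives the
#' polar family (tundra ET when above 0). Seasons are northern-hemisphere
#' (summer = April-September). The threshold set is shipped as a
#' machine-readable table in `extdata/koppen_rules.tsv`.
#'
#' @param temp_c 12 monthly mean temperatures, degrees C (Jan-Dec).
#' @param precip_mm 12 monthly precipitation totals, mm.
#' @return character class code (e.g. "Dfb", "Csa", "ET").
#' @export
koppen_classify <- function(temp_c, precip_mm) {
  stop_if_not(length(temp_c) == 12 && length(precip_mm) == 12,
              "need 12 monthly values each")
  stop_if_not(all(temp_c > -90) && all(precip_mm >= 0),
              "non-physical inputs")
  thot <- max(temp_c); tcold <- min(temp_c)
  if (thot <= 10) {
    return(if (thot > 0) "ET" else "EF")
  }
  family <- if (tcold > 0) "C" else "D"
  summer <- 4:9
  psdry <- min(precip_mm[summer]); pswet <- max(precip_mm[summer])
  pwdry <- min(precip_mm[-summer]); pwwet <- max(precip_mm[-summer])
  season <- if (psdry < 40 && psdry < pwwet / 3) "s"
  else if (pwdry < pswet / 10) "w"
  else "f"
  hot <- if (thot >= 22) "a" else if (sum(temp_c >= 10) >= 4) "b" else "c"
  paste0(family, season, hot)
}

#' Jaccard dissimilarity between two assemblages
#'
#' `1 - |A intersect B| / |A union B|`; two empty sets return 0 by convention
#' (with a message).
#'
#' @param a,b character vectors of species names (treated as sets).
#' @return scalar in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) {
    message("both assemblages empty; Jaccard dissimilarity 0 by convention")
    return(0)
  }
  1 - length(intersect(a, b)) / length(u)
}

#' Pairwise Jaccard dissimilarity matrix
#'
#' @param assemblages named list of species-name vectors.
#' @return a `dissimilarity_matrix`.
#' @export
jaccard_matrix <- function(assemblages) {
  n <- length(assemblages)
  ids <- names(assemblages) %||% as.character(seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    m[i, j] <- m[j, i] <- jaccard_dissimilarity(assemblages[[i]], assemblages[[j]])
  }
  structure(list(ids = ids, matrix = m, metric = "Jaccard"),
            class = "dissimilarity_matrix")
}

#' Delimit biogeographic regions
#'
#' Regions are the refinement of the NPP clusters split wherever member
#' sites differ in climate class or fauna cluster; the partition never
#' merges NPP clusters. Region ids `R_1..R_n` are assigned east to west by
#' decreasing mean longitude.
#'
#' @param sites data.frame with columns `site`, `lon`, plus per-site labels
#'   `npp_label`, `climate`, `fauna_label` (all three covering every site).
#' @return data.frame with columns `site`, `region` plus the input labels.
#' @export
delimit_regions <- function(sites) {
  need <- c("site", "lon", "npp_label", "climate", "fauna_label")
  stop_if_not(all(need %in% names(sites)), "missing site columns")
  stop_if_not(!anyNA(sites[need]), "every site must carry all three labelings")
  key <- interaction(sites$npp_label, sites$climate, sites$fauna_label, drop = TRUE)
  mean_lon <- tapply(sites$lon, key, mean)
  ord <- rank(-mean_lon, ties.method = "first")  # east (large lon) first
  sites$region <- sprintf("R_%d", ord[as.character(key)])
  sites
}
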