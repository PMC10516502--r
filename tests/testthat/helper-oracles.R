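# Independent oracle implementations, kept deliberately naive (explicit
# loops, textbook formulas) so they share no code path with the package.

# Textbook Solow-Roberts optimal linear estimator for the time of extinction,
# written for sightings in calendar years with the most recent sighting
# first. Loop-based transcription of the published estimator: shape
# v = (1/(k-1)) * sum_{i=1}^{k-2} log((t1 - tk)/(t1 - t_{i+1})),
# Lambda_ij = gamma(2v+i) gamma(v+j) / (gamma(v+i) gamma(j)) for j <= i,
# weights a = Lambda^-1 e / (e' Lambda^-1 e), TE = sum a_i t_i.
oracle_ole <- function(sightings) {
  t <- sort(sightings, decreasing = TRUE)
  k <- length(t)
  v <- 0
  for (i in 1:(k - 2)) {
    v <- v + log((t[1] - t[k]) / (t[1] - t[i + 1]))
  }
  v <- v / (k - 1)
  lam <- matrix(0, k, k)
  for (i in 1:k) {
    for (j in 1:k) {
      lo <- min(i, j); hi <- max(i, j)
      lam[i, j] <- gamma(2 * v + hi) * gamma(v + lo) / (gamma(v + hi) * gamma(lo))
    }
  }
  e <- rep(1, k)
  li <- solve(lam) %*% e
  a <- li / sum(li)
  sum(a * t)
}

# naive Moran's I (double loop) for cross-checking
oracle_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# expected interpolated incidence-based richness by brute-force enumeration
# over all subsets is infeasible; instead average over random subsets
oracle_rarefaction <- function(incidence, t_units, n_mc = 2000, seed = 1) {
  set.seed(seed)
  mean(vapply(seq_len(n_mc), function(i) {
    idx <- sample.int(nrow(incidence), t_units)
    sum(colSums(incidence[idx, , drop = FALSE]) > 0)
  }, numeric(1)))
}
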