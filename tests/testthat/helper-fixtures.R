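# Shared fixtures: small deterministic series and independent loop oracles.

random_ts <- function(n_regions = 4, n_vols = 200, tr = 2.2, seed = 1) {
  set.seed(seed)
  region_ts(matrix(rnorm(n_regions * n_vols), n_regions, n_vols), tr = tr)
}

# independent double-loop weighted Pearson correlation
loop_weighted_cor <- function(segment, weights) {
  w <- weights / sum(weights)
  R <- nrow(segment)
  out <- matrix(NA_real_, R, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    mi <- sum(w * segment[i, ]); mj <- sum(w * segment[j, ])
    cij <- sum(w * (segment[i, ] - mi) * (segment[j, ] - mj))
    cii <- sum(w * (segment[i, ] - mi)^2)
    cjj <- sum(w * (segment[j, ] - mj)^2)
    out[i, j] <- cij / sqrt(cii * cjj)
  }
  out
}

# independent discrete convolution of a rectangle with a truncated Gaussian
loop_taper <- function(L, sd) {
  K <- ceiling(3 * sd)
  g <- function(d) exp(-d^2 / (2 * sd^2))
  norm <- sum(sapply(-K:K, g))
  w <- numeric(L)
  for (i in 1:L) {
    acc <- 0
    for (d in -K:K) if (i - d >= 1 && i - d <= L) acc <- acc + g(d) / norm
    w[i] <- acc
  }
  w / sum(w)
}
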