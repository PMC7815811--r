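test_that("static FC matches brute-force Pearson and is sign-invariant", {
  set.seed(4)
  X <- matrix(rnorm(30), 3, 10)
  fc <- static_fc(region_ts(X, tr = 2.2))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(fc$values[i, j], abs(cor(X[i, ], X[j, ])), tolerance = 1e-12)
  # self-copy and negated copy both give |r| = 1
  Y <- rbind(X[1, ], X[1, ], -X[1, ])
  fc2 <- static_fc(region_ts(Y, tr = 2.2))
  expect_equal(fc2$values[1, 2], 1)
  expect_equal(fc2$values[1, 3], 1)
  expect_true(all(is.na(diag(fc$values))))
})

test_that("static FC flags zero-variance regions instead of failing", {
  X <- rbind(rnorm(10), rep(1, 10))
  expect_warning(fc <- static_fc(region_ts(X, tr = 2.2)), "zero-variance")
  expect_true(all(is.na(fc$values[2, ])))
})

test_that("weighted correlation: uniform reduction, affine invariance, loop oracle", {
  set.seed(7)
  X <- matrix(rnorm(3 * 27), 3, 27)
  expect_equal(weighted_correlation(X, rep(1, 27)), cor(t(X)),
               tolerance = 1e-12, ignore_attr = TRUE)
  w <- tapered_window_weights(window_spec())
  Y <- rbind(X[1, ], 2 * X[1, ] + 3)
  expect_equal(weighted_correlation(Y, w)[1, 2], 1, tolerance = 1e-12)
  expect_equal(weighted_correlation(X, w), loop_weighted_cor(X, w),
               tolerance = 1e-12)
})

test_that("both windowed_fc code paths agree with the single-window op", {
  w <- tapered_window_weights(window_spec())
  for (R in c(3, 50)) {   # exercises the sliding-sum and per-window paths
    ts <- random_ts(R, 120, seed = R)
    wc <- windowed_fc(ts)
    for (k in c(1, 10, dim(wc$stack)[3])) {
      s <- wc$window_starts[k]
      expect_equal(wc$stack[, , k],
                   weighted_correlation(ts$values[, (s + 1):(s + 27)], w),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("windowed_fc respects the window count and single-window edge", {
  ts <- random_ts(3, 197, seed = 2)
  expect_equal(dim(windowed_fc(ts)$stack)[3], 35L)
  ts1 <- random_ts(3, 27, seed = 3)
  wc1 <- windowed_fc(ts1)
  expect_equal(dim(wc1$stack)[3], 1L)
  expect_equal(wc1$stack[, , 1],
               weighted_correlation(ts1$values, tapered_window_weights(window_spec())),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("windowed correlations of a strongly coupled stationary pair stay high", {
  prof <- matrix(c(1, .9, .9, 1), 2)
  sim <- simulate_stationary_series(prof, 1970, 2.2, seed = 11)
  wc <- windowed_fc(sim)
  expect_true(all(wc$stack[1, 2, ] > 0.6))
})

test_that("summed-difference dFC: hand sum, loop oracle, constant stack", {
  mk_wc <- function(stack) {
    structure(list(stack = stack, window_starts = seq_len(dim(stack)[3]) - 1L,
                   spec = window_spec(), region_labels = paste0("R", seq_len(dim(stack)[1]))),
              class = "windowed_fc")
  }
  # one connection over 3 windows: 0.2, 0.5, 0.1 -> 0.7
  st <- array(0, c(2, 2, 3))
  st[1, 2, ] <- st[2, 1, ] <- c(0.2, 0.5, 0.1)
  for (k in 1:3) diag(st[, , k]) <- 1
  expect_equal(dfc_summed_difference(mk_wc(st))$matrix[1, 2], 0.7)
  # constant stack -> zero
  stc <- array(rep(st[, , 1], 4), c(2, 2, 4))
  expect_equal(dfc_summed_difference(mk_wc(stc))$matrix[1, 2], 0)
  # random 5-window stack vs loop oracle
  set.seed(9)
  rs <- array(runif(4 * 4 * 5, -1, 1), c(4, 4, 5))
  for (k in 1:5) { rs[, , k] <- (rs[, , k] + t(rs[, , k])) / 2; diag(rs[, , k]) <- 1 }
  got <- dfc_summed_difference(mk_wc(rs))$matrix
  want <- matrix(0, 4, 4)
  for (k in 1:4) want <- want + abs(rs[, , k + 1] - rs[, , k])
  diag(want) <- NA
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(dfc_summed_difference(mk_wc(rs[, , 1, drop = FALSE])), "2 windows")
})

test_that("coefficient-of-variation dFC follows the documented sd convention", {
  mk_wc <- function(stack) {
    structure(list(stack = stack, window_starts = seq_len(dim(stack)[3]) - 1L,
                   spec = window_spec(), region_labels = paste0("R", seq_len(dim(stack)[1]))),
              class = "windowed_fc")
  }
  st <- array(0, c(2, 2, 2))
  st[1, 2, ] <- st[2, 1, ] <- c(0.2, -0.4)   # absolutized: 0.2, 0.4
  for (k in 1:2) diag(st[, , k]) <- 1
  expect_equal(dfc_coefficient_of_variation(mk_wc(st))$matrix[1, 2],
               sd(c(0.2, 0.4)) / 0.3, tolerance = 1e-12)
  expect_equal(dfc_coefficient_of_variation(mk_wc(st), sd_type = "population")$matrix[1, 2],
               0.1 / 0.3, tolerance = 1e-12)
  # constant absolute stack -> 0 (signs differ, magnitudes equal)
  st2 <- st; st2[1, 2, ] <- st2[2, 1, ] <- c(0.3, -0.3)
  expect_equal(dfc_coefficient_of_variation(mk_wc(st2))$matrix[1, 2], 0)
  # random stack vs loop oracle
  set.seed(10)
  rs <- array(runif(3 * 3 * 6, -1, 1), c(3, 3, 6))
  for (k in 1:6) { rs[, , k] <- (rs[, , k] + t(rs[, , k])) / 2; diag(rs[, , k]) <- 1 }
  got <- dfc_coefficient_of_variation(mk_wc(rs))$matrix
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(got[i, j], sd(abs(rs[i, j, ])) / mean(abs(rs[i, j, ])),
                 tolerance = 1e-12)
})

test_that("dFC measures are permutation-invariant and scale as expected", {
  ts <- random_ts(5, 150, seed = 12)
  wc <- windowed_fc(ts)
  dd <- dfc_summed_difference(wc)
  dc <- dfc_coefficient_of_variation(wc)
  perm <- c(3, 1, 5, 2, 4)
  tsp <- region_ts(ts$values[perm, ], tr = ts$tr,
                   region_labels = ts$region_labels[perm])
  wcp <- windowed_fc(tsp)
  expect_equal(dfc_summed_difference(wcp)$matrix,
               dd$matrix[perm, perm], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(dfc_coefficient_of_variation(wcp)$matrix,
               dc$matrix[perm, perm], tolerance = 1e-10, ignore_attr = TRUE)
  # cv is invariant to a positive rescale of all window magnitudes
  wc2 <- wc; wc2$stack <- wc$stack * 0.5
  expect_equal(dfc_coefficient_of_variation(wc2)$matrix, dc$matrix,
               tolerance = 1e-12, ignore_attr = TRUE)
  # summed difference scales linearly
  expect_equal(dfc_summed_difference(wc2)$matrix, dd$matrix * 0.5,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("global mean averages the unique off-diagonal pairs", {
  m <- matrix(NA_real_, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1; m[1, 3] <- m[3, 1] <- 0.2; m[2, 3] <- m[3, 2] <- 0.3
  rownames(m) <- colnames(m) <- paste0("R", 1:3)
  expect_equal(global_mean(m), 0.2)
  # pair-enumeration oracle on a larger matrix
  set.seed(13)
  n <- 60
  big <- matrix(rnorm(n * n), n, n); big <- (big + t(big)) / 2; diag(big) <- NA
  acc <- 0; cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) { acc <- acc + big[i, j]; cnt <- cnt + 1 }
  expect_equal(global_mean(big), acc / cnt, tolerance = 1e-12)
  expect_equal(cnt, n * (n - 1) / 2)
})

test_that("subnetwork value matches hand enumeration and normalisation identity", {
  m <- matrix(0, 4, 4)
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  m[upper.tri(m)] <- vals; m <- m + t(m); diag(m) <- NA
  rownames(m) <- colnames(m) <- c("a1", "a2", "b1", "b2")
  sp <- subnetwork_spec(c("a1", "a2"), c("b1", "b2"))
  # upper-tri fill order: (1,2),(1,3),(2,3),(1,4),(2,4),(3,4)
  expect_equal(subnetwork_value(m, sp), mean(vals))
  sp_btw <- subnetwork_spec(c("a1", "a2"), c("b1", "b2"), mode = "between-sets-only")
  expect_equal(subnetwork_value(m, sp_btw), mean(c(0.2, 0.3, 0.4, 0.5)))
  # homogeneous matrix, normalised -> 1; normalisation identity
  h <- matrix(0.7, 4, 4); diag(h) <- NA; dimnames(h) <- dimnames(m)
  expect_equal(subnetwork_value(h, sp, normalize_by_global = TRUE), 1)
  expect_equal(subnetwork_value(m, sp) / subnetwork_value(m, sp, TRUE),
               global_mean(m), tolerance = 1e-12)
  expect_error(subnetwork_spec(c("a1"), c("a1", "b1")), "disjoint")
  expect_error(subnetwork_value(m, subnetwork_spec("a1", "zz")), "not present")
})

test_that("on stationary data dFC-cv shrinks as windows lengthen", {
  prof <- make_correlation_profile(4, 0.3, seed = 21)
  means <- sapply(c(20, 27, 40), function(L) {
    mean(sapply(1:20, function(s) {
      ts <- simulate_stationary_series(prof, 400, 2.2, seed = 100 * L + s)
      global_mean(dfc_coefficient_of_variation(windowed_fc(ts, window_spec(L, 5, 9))))
    }))
  })
  expect_true(all(diff(means) < 0))
})
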