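test_that("correlation profiles are valid and centred on the target", {
  p0 <- make_correlation_profile(2, 0, seed = 1)
  expect_lt(abs(p0[1, 2]), 0.2)
  p <- make_correlation_profile(4, 0.3, seed = 1)
  expect_equal(p, t(p))
  expect_equal(diag(p), rep(1, 4))
  expect_gte(min(eigen(p, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # marginal mean over many seeds converges to the base correlation
  offs <- sapply(1:100, function(s) {
    m <- make_correlation_profile(10, 0.3, seed = s)
    mean(m[upper.tri(m)])
  })
  expect_lt(abs(mean(offs) - 0.3), 0.05)
  expect_false(identical(make_correlation_profile(10, 0.3, seed = 1),
                         make_correlation_profile(10, 0.3, seed = 2)))
})

test_that("stationary series reproduce the profile correlations at large T", {
  pid <- diag(5)
  ts <- simulate_stationary_series(pid, 5000, 2.2, seed = 2)
  expect_lt(max(abs(cor(t(ts$values)) - pid)), 0.05)
  p2 <- matrix(c(1, .5, .5, 1), 2)
  ts2 <- simulate_stationary_series(p2, 5000, 2.2, seed = 3)
  r <- cor(ts2$values[1, ], ts2$values[2, ])
  expect_gt(r, 0.45); expect_lt(r, 0.55)
  # determinism
  expect_identical(simulate_stationary_series(p2, 100, 2.2, seed = 4)$values,
                   simulate_stationary_series(p2, 100, 2.2, seed = 4)$values)
})

test_that("modulated series track the target trajectory in windowed estimates", {
  # modulation slower than the ~59 s window so the windowed estimate can
  # resolve it (a 60 s period is averaged out by a full-period window)
  prof <- matrix(c(1, .4, .4, 1), 2)
  sim <- simulate_modulated_series(prof, 0.3, 240, 1970, 2.2, seed = 5)
  expect_equal(length(sim$ground_truth$trajectory), 1970L)
  expect_true(all(abs(sim$ground_truth$trajectory) <= 0.3 + 1e-12))
  wc <- windowed_fc(sim$ts)
  w <- tapered_window_weights(window_spec())
  target <- sapply(wc$window_starts, function(s)
    0.4 + sum(w * sim$ground_truth$trajectory[(s + 1):(s + 27)]))
  expect_gt(cor(target, wc$stack[1, 2, ]), 0.5)
  # amplitude outside the admissible range fails
  expect_error(simulate_modulated_series(prof, 0.7, 60, 100, 2.2, seed = 5),
               "outside")
})

test_that("zero amplitude reduces to a stationary draw", {
  prof <- matrix(c(1, .4, .4, 1), 2)
  sim <- simulate_modulated_series(prof, 0, 60, 2000, 2.2, seed = 6)
  expect_true(all(sim$ground_truth$trajectory == 0))
  r <- cor(sim$ts$values[1, ], sim$ts$values[2, ])
  expect_lt(abs(r - 0.4), 0.05)
})

test_that("a two-state sequence raises summed-difference dFC above stationary", {
  prof <- matrix(c(1, .4, .4, 1), 2)
  states <- rep(rep(c(-0.3, 0.3), each = 50), length.out = 1000)
  wins <- sapply(1:20, function(s) {
    dyn <- simulate_modulated_series(prof, NA, NA, 1000, 2.2,
                                     state_sequence = states, seed = 100 + s)
    stat <- simulate_stationary_series(prof, 1000, 2.2, seed = 200 + s)
    global_mean(dfc_summed_difference(windowed_fc(dyn$ts))) >
      global_mean(dfc_summed_difference(windowed_fc(stat)))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("global dFC is non-decreasing in modulation amplitude", {
  prof <- make_correlation_profile(4, 0.3, seed = 7)
  mean_dfc <- function(amp, measure) {
    mean(sapply(1:20, function(s) {
      sim <- simulate_modulated_series(prof, amp, 120, 500, 2.2, seed = 1000 * amp + s)
      wc <- windowed_fc(sim$ts)
      if (measure == "diff") global_mean(dfc_summed_difference(wc))
      else global_mean(dfc_coefficient_of_variation(wc))
    }))
  }
  for (meas in c("diff", "cv")) {
    vals <- sapply(c(0, 0.15, 0.3), mean_dfc, measure = meas)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("motion traces deliver the requested baseline and spike behaviour", {
  clean <- simulate_motion_trace(100, baseline_fd_mm = 0.1, seed = 8)
  fd <- framewise_displacement(clean)
  expect_equal(motion_exclusion(fd), "retain")
  expect_lt(abs(mean(fd) - 0.1), 0.05)
  excl <- mean(sapply(1:100, function(s) {
    tr <- simulate_motion_trace(100, baseline_fd_mm = 0.1, spike_prob = 0.5,
                                spike_fd_mm = 1.0, seed = s)
    motion_exclusion(framewise_displacement(tr)) == "exclude"
  }))
  expect_gt(excl, 0.95)
  expect_length(framewise_displacement(simulate_motion_trace(1, seed = 9)), 0L)
  expect_identical(simulate_motion_trace(50, seed = 10)$params,
                   simulate_motion_trace(50, seed = 10)$params)
})

test_that("cohorts are deterministic and encode the fatigue-dFC link", {
  cfg <- sim_config(n_regions = 14, n_volumes = 120, n_patients = 10,
                    n_controls = 6, seed = 42)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$clinical, co2$clinical)
  expect_identical(co1$subjects[[3]]$ts$values, co2$subjects[[3]]$ts$values)
  cl <- co1$clinical
  expect_true(all(cl$cis20r_total >= 20 & cl$cis20r_total <= 140))
  expect_true(all(cl$age >= 18 & cl$age <= 65))
  expect_true(all(is.na(cl$edss[cl$group == "control"])))
  expect_true(all(cl$edss[cl$group == "patient"] %in% seq(1, 6, 0.5)))
  # negative dFC-fatigue association in patients (the generative link)
  pt <- cl[cl$group == "patient", ]
  expect_lt(cor(pt$true_driver, pt$cis20r_total, method = "spearman"), 0)
})

test_that("a zero fatigue slope breaks the dFC-fatigue association", {
  rhos <- sapply(1:5, function(s) {
    cfg <- sim_config(n_regions = 14, n_volumes = 120, n_patients = 12,
                      n_controls = 6, fatigue_effect_slope = 0, edss_effect = 0,
                      seed = 300 + s)
    cl <- simulate_cohort(cfg)$clinical
    pt <- cl[cl$group == "patient", ]
    cor(pt$true_driver, pt$cis20r_total, method = "spearman")
  })
  expect_lt(abs(mean(rhos)), 0.3)
})

test_that("TSV and motion round trips preserve the data", {
  ts <- random_ts(3, 20, seed = 13)
  ts$subject_id <- "S001"
  f <- file.path(tempdir(), "ts.tsv")
  write_region_ts(ts, f)
  back <- read_region_ts(f)
  expect_equal(back$values, ts$values, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(back$tr, ts$tr)
  expect_equal(back$subject_id, "S001")
  mt <- simulate_motion_trace(20, seed = 14)
  fm <- file.path(tempdir(), "mot.tsv")
  write_motion_trace(mt, fm)
  expect_equal(read_motion_trace(fm)$params, mt$params,
               tolerance = 1e-10, ignore_attr = TRUE)
})
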