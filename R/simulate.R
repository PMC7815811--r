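#' Simulation configuration
#'
#' Collects every knob of the cohort generator. Defaults emulate the kind of
#' resting-state acquisition the pipeline targets — 202 volumes at TR 2.2 s
#' (197 usable after discarding 5) — at a reduced region count that keeps
#' whole-cohort simulation tractable while preserving the subnetwork
#' structure (6 basal-ganglia-like and 6 DMN-like regions plus cortical
#' filler).
#'
#' @param n_regions Number of regions (>= 12 so the two subnetwork sets fit).
#' @param n_volumes Volumes per subject before discarding (default 202).
#' @param tr_seconds Repetition time (default 2.2 s).
#' @param n_patients,n_controls Group sizes (defaults 35 and 19).
#' @param base_correlation Mean off-diagonal coupling of the static profile,
#'   in [0, 1) (default 0.25).
#' @param modulation_amplitude Amplitude of the sinusoidal correlation
#'   modulation applied to the subnetwork pairs in the high-dynamics
#'   (patient) group (default 0.3); the low-dynamics (control) group uses
#'   half this amplitude.
#' @param modulation_period_seconds Period of the modulation (default 60 s).
#' @param fatigue_effect_slope Fatigue points per standard deviation of the
#'   true subnetwork dFC driver; the sign convention is negative (higher
#'   dynamics, lower fatigue), so a positive slope yields a negative
#'   dFC-fatigue association (default 15).
#' @param edss_effect Fatigue points per EDSS step in patients (default 6).
#' @param fatigue_noise_sd Residual fatigue noise, CIS-20r points
#'   (default 12).
#' @param noise_sd Observation noise added to the BOLD-like series
#'   (default 0.2).
#' @param seed Integer master seed; per-subject sub-seeds are derived from it
#'   by a fixed counter scheme.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_regions = 30L, n_volumes = 202L, tr_seconds = 2.2,
                       n_patients = 35L, n_controls = 19L,
                       base_correlation = 0.25, modulation_amplitude = 0.3,
                       modulation_period_seconds = 60,
                       fatigue_effect_slope = 15, edss_effect = 6,
                       fatigue_noise_sd = 12, noise_sd = 0.2, seed = 1L) {
  if (n_regions < 12L) stop("need at least 12 regions for the subnetwork sets")
  if (base_correlation < 0 || base_correlation >= 1)
    stop("base correlation must lie in [0, 1)")
  if (modulation_amplitude < 0) stop("modulation amplitude must be >= 0")
  if (base_correlation + modulation_amplitude >= 1)
    stop("base + amplitude must stay inside (-1, 1)")
  if (noise_sd <= 0) stop("noise sd must be positive")
  structure(list(n_regions = as.integer(n_regions),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 base_correlation = base_correlation,
                 modulation_amplitude = modulation_amplitude,
                 modulation_period_seconds = modulation_period_seconds,
                 fatigue_effect_slope = fatigue_effect_slope,
                 edss_effect = edss_effect,
                 fatigue_noise_sd = fatigue_noise_sd,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic counter scheme: subject k of a cohort seeded with s
sub_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 1000003 * counter) %% 2147483629)
}

nearest_psd <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 0) return(m)
  v <- pmax(e$values, eps)
  m2 <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor(m2)
}

#' Random static correlation profile
#'
#' Builds a symmetric, unit-diagonal, positive semi-definite correlation
#' matrix whose off-diagonal entries are centred near
#' \code{base_correlation} with Gaussian jitter, projected to the nearest
#' PSD correlation matrix when the jitter breaks definiteness.
#'
#' @param n_regions Number of regions (>= 2).
#' @param base_correlation Target mean off-diagonal correlation in [0, 1).
#' @param jitter_sd Standard deviation of the off-diagonal jitter
#'   (default 0.05).
#' @param seed Optional integer seed.
#' @return An \code{n_regions} x \code{n_regions} correlation matrix.
#' @export
make_correlation_profile <- function(n_regions, base_correlation,
                                     jitter_sd = 0.05, seed = NULL) {
  if (n_regions < 2L) stop("need at least 2 regions")
  if (base_correlation < 0 || base_correlation >= 1)
    stop("base correlation must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n_regions, n_regions)
  off <- base_correlation + stats::rnorm(n_regions * (n_regions - 1) / 2, 0, jitter_sd)
  off <- pmin(pmax(off, -0.99), 0.99)
  m[upper.tri(m)] <- off
  m <- m + t(m)
  diag(m) <- 1
  m <- nearest_psd(m)
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("correlation profile is not positive semi-definite after projection")
  m
}

#' Stationary multivariate Gaussian series
#'
#' Draws zero-mean Gaussian volumes with the given instantaneous correlation
#' matrix, independent across time (stationary by construction). Additive
#' white observation noise can be layered on top, which shrinks the effective
#' correlations toward zero by a known factor \code{1 / (1 + noise_sd^2)}.
#'
#' @param profile Correlation matrix from
#'   \code{\link{make_correlation_profile}}.
#' @param n_vols Number of volumes.
#' @param tr Repetition time in seconds.
#' @param noise_sd Additive white-noise standard deviation (default 0: the
#'   sample correlations converge to the profile itself).
#' @param seed Optional integer seed.
#' @param region_labels Optional labels.
#' @return A \code{\link{region_ts}}.
#' @export
simulate_stationary_series <- function(profile, n_vols, tr, noise_sd = 0,
                                       seed = NULL, region_labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- nrow(profile)
  cf <- chol(profile + diag(1e-10, R))
  Z <- matrix(stats::rnorm(R * n_vols), R, n_vols)
  X <- crossprod(cf, Z)
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(R * n_vols, 0, noise_sd), R, n_vols)
  region_ts(X, tr = tr, region_labels = region_labels)
}

#' Time-varying (modulated) multivariate Gaussian series
#'
#' Generates Gaussian volumes whose instantaneous correlation for a chosen
#' set of region pairs follows a sinusoid around the static profile:
#' \eqn{r_{ij}(t) = r_{ij} + A \sin(2\pi t \cdot TR / P)}. Alternatively a
#' piecewise-constant state sequence of offsets may be supplied. All
#' modulated per-volume targets must stay strictly inside (-1, 1).
#'
#' @param profile Static correlation matrix.
#' @param modulation_amplitude Sinusoid amplitude A (ignored when
#'   \code{state_sequence} is given).
#' @param modulation_period Sinusoid period P in seconds.
#' @param n_vols,tr Series length and repetition time.
#' @param pairs Optional 2-column index matrix of modulated region pairs;
#'   default all off-diagonal pairs.
#' @param state_sequence Optional per-volume vector of correlation offsets
#'   replacing the sinusoid.
#' @param noise_sd Additive white observation noise (default 0).
#' @param seed Optional integer seed.
#' @param region_labels Optional labels.
#' @return List with \code{ts} (a \code{\link{region_ts}}) and
#'   \code{ground_truth} (list: \code{trajectory} of per-volume offsets,
#'   \code{amplitude}, \code{pairs}).
#' @export
simulate_modulated_series <- function(profile, modulation_amplitude,
                                      modulation_period, n_vols, tr,
                                      pairs = NULL, state_sequence = NULL,
                                      noise_sd = 0, seed = NULL,
                                      region_labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- nrow(profile)
  if (is.null(pairs)) {
    pairs <- which(upper.tri(profile), arr.ind = TRUE)
  }
  traj <- if (!is.null(state_sequence)) {
    if (length(state_sequence) != n_vols)
      stop("state sequence must have one offset per volume")
    state_sequence
  } else {
    modulation_amplitude * sin(2 * pi * (seq_len(n_vols) - 1L) * tr / modulation_period)
  }
  base_vals <- profile[pairs]
  rng <- range(outer(base_vals, range(traj), `+`))
  if (rng[1] <= -1 || rng[2] >= 1)
    stop("modulation pushes a target correlation outside (-1, 1)")

  X <- matrix(0, R, n_vols)
  ord <- order(traj)          # group equal targets so Cholesky is reused
  runs <- split(ord, traj[ord])
  for (grp in runs) {
    Ct <- profile
    Ct[pairs] <- base_vals + traj[grp[1L]]
    Ct[pairs[, c(2L, 1L), drop = FALSE]] <- Ct[pairs]
    cf <- tryCatch(chol(Ct + diag(1e-10, R)),
                   error = function(e) chol(nearest_psd(Ct) + diag(1e-8, R)))
    Z <- matrix(stats::rnorm(R * length(grp)), R)
    X[, grp] <- crossprod(cf, Z)
  }
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(R * n_vols, 0, noise_sd), R, n_vols)
  list(ts = region_ts(X, tr = tr, region_labels = region_labels),
       ground_truth = list(trajectory = traj,
                           amplitude = if (is.null(state_sequence)) modulation_amplitude else NA_real_,
                           pairs = pairs))
}

#' Simulated motion trace
#'
#' Produces a 6-parameter rigid-body trace whose implied framewise
#' displacement fluctuates around \code{baseline_fd_mm}, with independent
#' per-transition spikes of magnitude \code{spike_fd_mm} occurring with
#' probability \code{spike_prob}. Each transition's displacement is split
#' randomly across the three translations and three rotations (rotations
#' converted back from arc length at 50 mm).
#'
#' @param n_vols Number of volumes.
#' @param baseline_fd_mm Typical framewise displacement (default 0.1 mm).
#' @param spike_prob Per-transition spike probability (default 0).
#' @param spike_fd_mm Spike displacement (default 1 mm).
#' @param seed Optional integer seed.
#' @return A \code{\link{motion_trace}} with \code{n_vols} rows.
#' @export
simulate_motion_trace <- function(n_vols, baseline_fd_mm = 0.1,
                                  spike_prob = 0, spike_fd_mm = 1,
                                  seed = NULL) {
  if (spike_prob < 0 || spike_prob > 1) stop("spike probability must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(0, n_vols, 6L)
  if (n_vols >= 2L) {
    nt <- n_vols - 1L
    fd <- abs(stats::rnorm(nt, baseline_fd_mm, baseline_fd_mm / 4))
    spikes <- stats::runif(nt) < spike_prob
    fd[spikes] <- spike_fd_mm * stats::runif(sum(spikes), 0.9, 1.1)
    for (t in seq_len(nt)) {
      # split the target FD over the 6 parameters with random signs
      share <- stats::runif(6L); share <- share / sum(share)
      delta <- fd[t] * share * sample(c(-1, 1), 6L, replace = TRUE)
      delta[4:6] <- delta[4:6] / 50       # arc length at 50 mm -> radians
      p[t + 1L, ] <- p[t, ] + delta
    }
  }
  motion_trace(p)
}

default_region_labels <- function(n_regions) {
  bg <- c("Caudate_L", "Caudate_R", "Putamen_L", "Putamen_R",
          "Pallidum_L", "Pallidum_R")
  dmn <- c("mPFC_L", "mPFC_R", "PCC_L", "PCC_R", "Precuneus_L", "Precuneus_R")
  extra <- if (n_regions > 12L) paste0("Cortex_", seq_len(n_regions - 12L)) else character(0)
  c(bg, dmn, extra)
}

#' Default basal ganglia-DMN subnetwork spec for simulated cohorts
#' @return A \code{\link{subnetwork_spec}} matching
#'   \code{\link{default_region_labels}}.
#' @export
default_subnetwork <- function() {
  subnetwork_spec(
    set_a = c("Caudate_L", "Caudate_R", "Putamen_L", "Putamen_R",
              "Pallidum_L", "Pallidum_R"),
    set_b = c("mPFC_L", "mPFC_R", "PCC_L", "PCC_R", "Precuneus_L",
              "Precuneus_R"))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a full cohort
#'
#' Generates a two-group cohort (patients = high-dynamics, controls =
#' low-dynamics) of modulated region time series, motion traces, and clinical
#' records in which fatigue is linked to each subject's measured subnetwork
#' dFC. Per subject: (1) a time-varying series is drawn with sinusoidal
#' modulation of the basal ganglia-DMN pairs at an amplitude jittered around
#' the group level; (2) the normalised subnetwork dFC coefficient of
#' variation is computed with the supplied window spec and standardised
#' within group — this is the true fatigue driver; (3) the CIS-20r total is
#' generated as \code{intercept - slope * driver (+ EDSS effect in patients)
#' + noise}, clipped to [20, 140], and 20 item responses consistent with
#' that total are drawn and rescored.
#'
#' @param config A \code{\link{sim_config}}.
#' @param spec Window spec used to compute the true dFC driver.
#' @param n_discard Leading volumes removed before computing the driver
#'   (default 5, mirroring the preprocessing stage).
#' @return List of class \code{sim_cohort}: \code{subjects} (list with
#'   \code{ts}, \code{motion}, \code{ground_truth} per subject),
#'   \code{clinical} (one data frame row per subject: group, age, sex,
#'   education, EDSS, disease duration, medication, HADS, CIS-20r items,
#'   subscales and total), \code{config}, \code{subnetwork}.
#' @export
simulate_cohort <- function(config = sim_config(), spec = window_spec(),
                            n_discard = 5L) {
  n <- config$n_patients + config$n_controls
  group <- c(rep("patient", config$n_patients),
             rep("control", config$n_controls))
  labels <- default_region_labels(config$n_regions)
  sn <- default_subnetwork()
  pairs_all <- subnetwork_pairs(sn, labels)

  set.seed(config$seed)
  profile <- make_correlation_profile(config$n_regions,
                                      config$base_correlation,
                                      seed = sub_seed(config$seed, 0L))
  subjects <- vector("list", n)
  driver <- numeric(n)
  for (i in seq_len(n)) {
    s <- sub_seed(config$seed, i)
    set.seed(s)
    grp_amp <- if (group[i] == "patient") config$modulation_amplitude
               else config$modulation_amplitude / 2
    amp_i <- grp_amp * stats::runif(1, 0.6, 1.4)
    sim <- simulate_modulated_series(profile, amp_i,
                                     config$modulation_period_seconds,
                                     config$n_volumes, config$tr_seconds,
                                     pairs = pairs_all,
                                     noise_sd = config$noise_sd,
                                     region_labels = labels)
    sim$ts$subject_id <- sprintf("S%03d", i)
    motion <- simulate_motion_trace(config$n_volumes)
    usable <- discard_initial_volumes(sim$ts, n_discard)
    wc <- windowed_fc(usable, spec)
    cv <- dfc_coefficient_of_variation(wc)
    driver[i] <- subnetwork_value(cv, sn, normalize_by_global = TRUE)
    subjects[[i]] <- list(ts = sim$ts, motion = motion,
                          ground_truth = c(sim$ground_truth,
                                           list(group_label = if (group[i] == "patient")
                                             "high-dynamics" else "low-dynamics",
                                             amplitude_subject = amp_i)))
  }

  set.seed(sub_seed(config$seed, n + 1L))
  age <- rtrunc_norm(n, 42, 10, 18, 65)
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.7, 0.3))
  education <- sample(1:7, n, replace = TRUE)
  edss <- ifelse(group == "patient",
                 sample(seq(1, 6, by = 0.5), n, replace = TRUE), NA_real_)
  disease_duration <- ifelse(group == "patient",
                             round(rtrunc_norm(n, 8, 4, 0.5, 30), 1), NA_real_)
  medication <- ifelse(group == "patient",
                       sample(c("first-line", "second-line"), n, replace = TRUE),
                       NA_character_)
  hads_anxiety <- pmin(pmax(round(stats::rnorm(n, ifelse(group == "patient", 5.5, 4), 3)), 0), 21)
  hads_depression <- pmin(pmax(round(stats::rnorm(n, ifelse(group == "patient", 3, 1), 2.5)), 0), 21)

  z <- numeric(n)
  for (g in unique(group)) {
    idx <- group == g
    z[idx] <- as.numeric(scale(driver[idx]))
  }
  intercept <- ifelse(group == "patient", 75, 47)
  fat <- intercept - config$fatigue_effect_slope * z +
    ifelse(group == "patient", config$edss_effect * (edss - 3), 0) +
    stats::rnorm(n, 0, config$fatigue_noise_sd)
  fat <- pmin(pmax(fat, 20), 140)

  items <- matrix(NA_integer_, n, 20L)
  scores <- vector("list", n)
  for (i in seq_len(n)) {
    target_item <- fat[i] / 20
    it <- pmin(pmax(round(target_item + stats::rnorm(20L, 0, 0.8)), 1L), 7L)
    # nudge items until the rescored total matches the target within rounding
    gap <- round(fat[i]) - sum(it)
    while (gap != 0) {
      j <- sample.int(20L, 1L)
      step <- sign(gap)
      if (it[j] + step >= 1L && it[j] + step <= 7L) {
        it[j] <- it[j] + step
        gap <- gap - step
      }
    }
    items[i, ] <- it
    scores[[i]] <- score_cis20r(it)
  }

  clinical <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group, age = age, sex = sex, education = education,
    edss = edss, disease_duration = disease_duration, medication = medication,
    hads_anxiety = hads_anxiety, hads_depression = hads_depression,
    cis20r_subjective = vapply(scores, `[[`, numeric(1), "subjective_complaints"),
    cis20r_motivation = vapply(scores, `[[`, numeric(1), "motivation"),
    cis20r_physical = vapply(scores, `[[`, numeric(1), "physical_activity"),
    cis20r_concentration = vapply(scores, `[[`, numeric(1), "concentration"),
    cis20r_total = vapply(scores, `[[`, numeric(1), "total"),
    true_driver = driver,
    stringsAsFactors = FALSE)
  clinical <- cbind(clinical,
                    stats::setNames(as.data.frame(items),
                                    paste0("cis20r_item_", 1:20)))

  structure(list(subjects = subjects, clinical = clinical, config = config,
                 subnetwork = sn, profile = profile),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d patients + %d controls, %d regions x %d volumes\n",
              x$config$n_patients, x$config$n_controls,
              x$config$n_regions, x$config$n_volumes))
  invisible(x)
}

#' Synthetic 4D image + label fixture
#'
#' Paints \code{n_regions} disjoint rectangular blocks into a voxel grid,
#' injects a per-region time series into every voxel of its block (plus
#' optional voxel noise), and optionally zeroes a fraction of voxels to
#' exercise the robust-range intensity mask. Intensities ride on a baseline
#' offset so the robust range is well defined.
#'
#' A background margin (the last two planes along y) is left unlabelled at
#' zero intensity, as in a real field of view, so the robust intensity range
#' spans background to tissue.
#'
#' @param grid_shape Integer length-3 voxel grid dimensions (y >= 3).
#' @param n_regions Number of regions (blocks along the x axis).
#' @param n_vols Number of volumes.
#' @param tr Repetition time (seconds), stored in the NIfTI header when
#'   written.
#' @param voxel_noise_sd Per-voxel additive noise (default 0).
#' @param dropout_fraction Fraction of each region's voxels set to near-zero
#'   intensity (default 0); \code{dropout_regions} restricts this to chosen
#'   region ids.
#' @param dropout_regions Integer region ids subject to dropout (default all).
#' @param baseline Intensity offset (default 100).
#' @param seed Optional integer seed.
#' @param image_path,labels_path Optional paths; when given, the image and
#'   labels are also written as NIfTI files.
#' @return List: \code{image} (4D array), \code{labels} (3D integer array),
#'   \code{series} (the injected regions x volumes matrix), \code{tr}.
#' @export
make_image_fixture <- function(grid_shape, n_regions, n_vols, tr = 2.2,
                               voxel_noise_sd = 0, dropout_fraction = 0,
                               dropout_regions = seq_len(n_regions),
                               baseline = 100, seed = NULL,
                               image_path = NULL, labels_path = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L) stop("grid shape must have 3 dimensions")
  if (grid_shape[1] < n_regions) stop("grid too small for the requested regions")
  if (!is.null(seed)) set.seed(seed)

  if (grid_shape[2] < 3L) stop("grid must have at least 3 voxels along y")
  labels <- array(0L, grid_shape)
  bounds <- floor(seq(0, grid_shape[1], length.out = n_regions + 1L))
  ny <- grid_shape[2]
  for (r in seq_len(n_regions))
    labels[(bounds[r] + 1L):bounds[r + 1L], seq_len(ny - 2L), ] <- r

  series <- matrix(stats::rnorm(n_regions * n_vols), n_regions, n_vols)
  lab_vec <- as.vector(labels)
  nvox <- prod(grid_shape)
  mat <- matrix(baseline, nvox, n_vols)
  mat[lab_vec == 0L, ] <- 0
  for (r in seq_len(n_regions))
    mat[lab_vec == r, ] <- rep(baseline + series[r, ], each = sum(lab_vec == r))
  if (voxel_noise_sd > 0)
    mat <- mat + matrix(stats::rnorm(nvox * n_vols, 0, voxel_noise_sd), nvox, n_vols)
  if (dropout_fraction > 0) {
    for (r in dropout_regions) {
      vox <- which(lab_vec == r)
      nzero <- round(dropout_fraction * length(vox))
      if (nzero > 0L) mat[sample(vox, nzero), ] <- stats::rnorm(nzero * n_vols, 0, 0.01)
    }
  }
  img <- array(mat, c(grid_shape, n_vols))

  if (!is.null(image_path)) {
    nif <- RNifti::asNifti(img)
    RNifti::pixdim(nif) <- c(1, 1, 1, tr)
    RNifti::writeNifti(nif, image_path)
  }
  if (!is.null(labels_path)) RNifti::writeNifti(RNifti::asNifti(labels), labels_path)
  list(image = img, labels = labels, series = series, tr = tr)
}

#' Write a motion trace as 6-column TSV
#' @param motion A \code{\link{motion_trace}}.
#' @param path Output path.
#' @export
write_motion_trace <- function(motion, path) {
  utils::write.table(motion$params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a motion trace from 6-column TSV
#' @param path Input path.
#' @return A \code{\link{motion_trace}}.
#' @export
read_motion_trace <- function(path) {
  motion_trace(as.matrix(utils::read.delim(path)))
}
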