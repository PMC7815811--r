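#' Discard initial volumes
#'
#' Removes the first \code{n_discard} volumes (e.g. dummy scans acquired
#' before magnetisation reaches steady state). TR and labels are unchanged.
#'
#' @param ts A \code{\link{region_ts}}.
#' @param n_discard Number of leading volumes to drop (default 5); must be
#'   strictly less than the volume count.
#' @return A \code{region_ts} with \code{n_discard} fewer volumes.
#' @export
discard_initial_volumes <- function(ts, n_discard = 5L) {
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("'n_discard' must be non-negative")
  if (n_discard >= ncol(ts$values))
    stop("cannot discard all volumes: n_discard >= volume count")
  if (n_discard == 0L) return(ts)
  region_ts(ts$values[, -seq_len(n_discard), drop = FALSE], tr = ts$tr,
            region_labels = ts$region_labels, subject_id = ts$subject_id)
}

#' Motion trace container
#'
#' Per-volume rigid-body realignment parameters: three translations in mm
#' and three rotations in radians.
#'
#' @param params Numeric volumes x 6 matrix; columns 1-3 translations (mm),
#'   columns 4-6 rotations (radians).
#' @return A \code{motion_trace} object.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion parameters must have 6 columns")
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(list(params = params), class = "motion_trace")
}

#' Framewise displacement
#'
#' Summarises frame-to-frame head motion as the sum of absolute deltas of the
#' three translations plus the three rotation deltas converted to arc length
#' on a sphere of radius \code{head_radius_mm} (default 50 mm).
#'
#' @param motion A \code{\link{motion_trace}}.
#' @param head_radius_mm Head radius used to convert rotations to mm.
#' @return Numeric vector of length \code{volumes - 1} (mm); empty for a
#'   single-volume trace.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  p <- motion$params
  if (nrow(p) < 2L) return(numeric(0))
  d <- abs(diff(p))
  rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' Motion-based subject exclusion
#'
#' Applies the scrubbing-free exclusion rule: a subject is excluded when the
#' fraction of frame-to-frame transitions with framewise displacement above
#' \code{threshold_mm} reaches \code{max_fraction}. The boundary is
#' inclusive: exactly 20\% supra-threshold transitions excludes.
#'
#' @param fd Framewise-displacement sequence (non-empty).
#' @param threshold_mm Displacement threshold in mm (default 0.5).
#' @param max_fraction Maximum tolerated fraction of supra-threshold
#'   transitions (default 0.20).
#' @return \code{"retain"} or \code{"exclude"}.
#' @export
motion_exclusion <- function(fd, threshold_mm = 0.5, max_fraction = 0.20) {
  if (length(fd) == 0L) stop("empty framewise-displacement sequence")
  frac <- mean(fd > threshold_mm)
  if (frac >= max_fraction) "exclude" else "retain"
}

#' Nuisance regression
#'
#' Replaces each region's series by the residuals of an ordinary
#' least-squares fit on an intercept plus the supplied nuisance signals
#' (e.g. mean white-matter and CSF series).
#'
#' @param ts A \code{\link{region_ts}}.
#' @param nuisance Numeric signals x volumes matrix (volumes must match
#'   \code{ts}); the signals together with the intercept must be linearly
#'   independent.
#' @return A \code{region_ts} of residual series (mean-centred).
#' @export
regress_nuisance <- function(ts, nuisance) {
  nuisance <- as.matrix(nuisance)
  if (ncol(nuisance) != ncol(ts$values))
    stop("nuisance volume count must match the time series")
  X <- cbind(1, t(nuisance))
  if (qr(X)$rank < ncol(X))
    stop("nuisance design is rank deficient (collinear signals)")
  fit <- stats::lm.fit(X, t(ts$values))
  region_ts(t(fit$residuals), tr = ts$tr, region_labels = ts$region_labels,
            subject_id = ts$subject_id)
}

dct_drift_basis <- function(nvol, tr, cutoff_hz) {
  # DCT-II regressors whose frequency k / (2 * T * TR) lies below the cutoff
  kmax <- floor(2 * nvol * tr * cutoff_hz)
  if (kmax < 1L) return(NULL)
  t_idx <- seq_len(nvol)
  sapply(seq_len(kmax), function(k) cos(pi * (2 * t_idx - 1) * k / (2 * nvol)))
}

#' High-pass filter (discrete-cosine drift removal)
#'
#' Removes slow drifts by regressing out a discrete-cosine basis spanning all
#' periods longer than \code{1 / cutoff_hz}, plus the mean. This is a
#' deterministic projection (no recursive filter), so it is exactly
#' reproducible and free of edge transients; frequencies above the cutoff
#' pass essentially unchanged. Output is mean-centred.
#'
#' @param ts A \code{\link{region_ts}} with known TR.
#' @param cutoff_hz High-pass cutoff in Hz (default 0.01); must be below the
#'   Nyquist frequency \code{1 / (2 TR)}.
#' @return A filtered, mean-centred \code{region_ts}.
#' @export
highpass_filter <- function(ts, cutoff_hz = 0.01) {
  nyquist <- 1 / (2 * ts$tr)
  if (cutoff_hz >= nyquist)
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff_hz, nyquist))
  B <- dct_drift_basis(ncol(ts$values), ts$tr, cutoff_hz)
  X <- if (is.null(B)) matrix(1, ncol(ts$values), 1L) else cbind(1, B)
  fit <- stats::lm.fit(X, t(ts$values))
  region_ts(t(fit$residuals), tr = ts$tr, region_labels = ts$region_labels,
            subject_id = ts$subject_id)
}

#' Extract region time series from a 4D image and label volume
#'
#' Masks out low-intensity voxels and averages the surviving voxels of each
#' labelled region per volume. The voxel mask keeps voxels whose temporal-mean
#' intensity exceeds \code{robust_min + robust_fraction * (robust_max -
#' robust_min)}, where the robust range is the 2nd-98th percentile of the
#' temporal-mean image. Regions whose fraction of surviving voxels falls
#' below \code{min_coverage} are dropped with a warning (insufficient
#' coverage, e.g. signal dropout).
#'
#' @param image 4D numeric array (x, y, z, time) or path to a NIfTI file.
#' @param labels 3D integer array of region labels (0 = background) on the
#'   same grid, or path to a NIfTI file.
#' @param tr Repetition time in seconds for the output series (read from the
#'   NIfTI header when \code{image} is a file path and \code{tr} is missing).
#' @param robust_fraction Fraction of the robust intensity range below which
#'   voxels are excluded (default 0.25).
#' @param min_coverage Minimum fraction of a region's voxels that must
#'   survive masking for the region to be retained (default 0.5).
#' @param region_labels Optional character names for the integer labels.
#' @return A \code{\link{region_ts}} of per-region mean series, with an
#'   attribute \code{"dropped_regions"} listing regions removed for
#'   insufficient coverage.
#' @export
extract_region_timeseries <- function(image, labels, tr = NULL,
                                      robust_fraction = 0.25,
                                      min_coverage = 0.5,
                                      region_labels = NULL) {
  if (is.character(image)) {
    img <- RNifti::readNifti(image)
    if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
    image <- as.array(img)
  }
  if (is.character(labels)) labels <- as.array(RNifti::readNifti(labels))
  if (is.null(tr)) stop("'tr' must be supplied when 'image' is an array")
  dimg <- dim(image)
  if (length(dimg) != 4L) stop("'image' must be a 4D array")
  if (!identical(dim(labels), dimg[1:3]))
    stop("image and label volumes are on different grids")

  nvox <- prod(dimg[1:3])
  nvol <- dimg[4]
  mat <- matrix(image, nrow = nvox, ncol = nvol)   # voxels x time
  lab <- as.integer(round(as.vector(labels)))
  mean_img <- rowMeans(mat)

  rr <- stats::quantile(mean_img, c(0.02, 0.98), names = FALSE, type = 7)
  thr <- rr[1] + robust_fraction * (rr[2] - rr[1])
  keep <- mean_img > thr

  ids <- sort(unique(lab[lab > 0L]))
  if (is.null(region_labels)) region_labels <- paste0("region_", ids)
  if (length(region_labels) != length(ids))
    stop("one name per label id is required")

  series <- list()
  out_labels <- character(0)
  dropped <- character(0)
  for (i in seq_along(ids)) {
    vox <- lab == ids[i]
    surv <- vox & keep
    coverage <- sum(surv) / sum(vox)
    if (coverage < min_coverage) {
      dropped <- c(dropped, region_labels[i])
      next
    }
    series[[length(series) + 1L]] <-
      if (sum(surv) == 1L) mat[surv, ] else colMeans(mat[surv, , drop = FALSE])
    out_labels <- c(out_labels, region_labels[i])
  }
  if (length(dropped) > 0L)
    warning("regions dropped for insufficient coverage: ",
            paste(dropped, collapse = ", "))
  if (length(series) == 0L) stop("no region retained after masking")
  ts <- region_ts(do.call(rbind, series), tr = tr, region_labels = out_labels)
  attr(ts, "dropped_regions") <- dropped
  ts
}

#' Per-subject motion QC report
#'
#' Convenience wrapper combining \code{\link{framewise_displacement}} and
#' \code{\link{motion_exclusion}}.
#'
#' @param motion A \code{\link{motion_trace}}.
#' @param threshold_mm,max_fraction Passed to \code{\link{motion_exclusion}}.
#' @return List with mean/max FD, supra-threshold fraction, and the decision.
#' @export
motion_qc <- function(motion, threshold_mm = 0.5, max_fraction = 0.20) {
  fd <- framewise_displacement(motion)
  list(mean_fd = mean(fd), max_fd = max(fd),
       frac_above = mean(fd > threshold_mm),
       decision = motion_exclusion(fd, threshold_mm, max_fraction))
}
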