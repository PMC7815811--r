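#' Sliding-window specification
#'
#' Defines the tapered sliding window used for windowed connectivity:
#' a rectangular window of \code{length_volumes} volumes convolved with a
#' Gaussian kernel of standard deviation \code{taper_sd_volumes} volumes,
#' advanced by \code{step_volumes} volumes between successive windows.
#' Defaults correspond to a 27-volume (59.4 s at TR 2.2 s) window with a
#' 5-volume (11 s) shift and a 9-TR taper.
#'
#' @param length_volumes Window length in volumes (>= 2).
#' @param step_volumes Shift between consecutive window starts, in volumes
#'   (1 <= step <= length; overlapping windows when step < length).
#' @param taper_sd_volumes Standard deviation of the Gaussian taper kernel,
#'   in volumes (> 0).
#' @return A \code{window_spec} object.
#' @export
window_spec <- function(length_volumes = 27L, step_volumes = 5L,
                        taper_sd_volumes = 9) {
  length_volumes <- as.integer(length_volumes)
  step_volumes <- as.integer(step_volumes)
  if (length_volumes < 2L) stop("window length must be at least 2 volumes")
  if (step_volumes < 1L || step_volumes > length_volumes)
    stop("window step must satisfy 1 <= step <= length")
  if (!is.numeric(taper_sd_volumes) || taper_sd_volumes <= 0)
    stop("taper standard deviation must be positive")
  structure(list(length_volumes = length_volumes,
                 step_volumes = step_volumes,
                 taper_sd_volumes = taper_sd_volumes),
            class = "window_spec")
}

#' Tapered window weights
#'
#' Convolves a rectangular window of ones with a discretised Gaussian kernel
#' (support truncated at +/- 3 standard deviations), evaluates the result at
#' the in-window positions (same-length convolution), and normalises the
#' weights to sum to one. The weights are symmetric, strictly positive, and
#' maximal at the window centre; as the taper standard deviation grows they
#' approach the uniform weights 1/L.
#'
#' @param spec A \code{\link{window_spec}}.
#' @return Numeric vector of length \code{spec$length_volumes} summing to 1.
#' @export
tapered_window_weights <- function(spec = window_spec()) {
  L <- spec$length_volumes
  K <- as.integer(ceiling(3 * spec$taper_sd_volumes))
  offs <- seq.int(-K, K)
  kern <- exp(-offs^2 / (2 * spec$taper_sd_volumes^2))
  kern <- kern / sum(kern)
  # w[i] = sum over kernel offsets d with i - d inside the rectangle
  w <- vapply(seq_len(L), function(i) {
    keep <- (i - offs) >= 1L & (i - offs) <= L
    sum(kern[keep])
  }, numeric(1))
  w / sum(w)
}

#' Window start indices
#'
#' Enumerates the 0-based start indices of the sliding windows: starts are
#' 0, step, 2*step, ... while a full window still fits
#' (start + length <= n_volumes). Windows are half-open
#' \code{[start, start + length)}; trailing volumes not covered by a full
#' window are dropped. The window count equals
#' \code{floor((T - L) / S) + 1}.
#'
#' @param nvol Total number of volumes (>= window length).
#' @param spec A \code{\link{window_spec}}.
#' @return Integer vector of 0-based start indices.
#' @export
window_start_indices <- function(nvol, spec = window_spec()) {
  nvol <- as.integer(nvol)
  if (nvol < spec$length_volumes)
    stop("time series shorter than one window")
  seq.int(0L, nvol - spec$length_volumes, by = spec$step_volumes)
}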