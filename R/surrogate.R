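#' Phase-randomized surrogate time series
#'
#' Builds a surrogate series by randomising Fourier phases while keeping the
#' amplitude spectrum of every region. One random phase sequence is drawn per
#' surrogate and added identically to every region's spectrum (the
#' multivariate, common-phase construction): this preserves each region's
#' amplitude spectrum and autocorrelation AND the full cross-correlation
#' structure (static connectivity), destroying only time-localised changes in
#' coupling. Conjugate symmetry is enforced and the zero-frequency (and
#' Nyquist, for even length) bins are left untouched, so the output is
#' real-valued with the original per-region means.
#'
#' @param ts A \code{\link{region_ts}} with at least 4 volumes.
#' @param seed Optional integer seed for the phase draw.
#' @return A surrogate \code{region_ts} of identical dimensions.
#' @export
phase_randomized_surrogate <- function(ts, seed = NULL) {
  X <- ts$values
  N <- ncol(X)
  if (N < 4L) stop("phase randomization requires at least 4 volumes")
  if (!is.null(seed)) set.seed(seed)
  out <- surrogate_from_spectrum(stats::mvfft(t(X)), N)
  region_ts(out, tr = ts$tr, region_labels = ts$region_labels,
            subject_id = ts$subject_id)
}

# one surrogate draw given the precomputed volumes x regions spectrum
surrogate_from_spectrum <- function(Xf, N) {
  half <- if (N %% 2L == 0L) N %/% 2L - 1L else (N - 1L) %/% 2L
  phi <- stats::runif(half, 0, 2 * pi)
  rot <- rep(1 + 0i, N)
  rot[2L:(half + 1L)] <- exp(1i * phi)
  rot[N:(N - half + 1L)] <- exp(-1i * phi)   # conjugate-symmetric mirror
  Xs <- Xf * rot                         # common phase rotation per frequency
  t(Re(stats::mvfft(Xs, inverse = TRUE)) / N)
}

dfc_value <- function(ts, spec, measure, subnetwork = NULL) {
  wc <- windowed_fc(ts, spec)
  res <- switch(measure,
                diff = dfc_summed_difference(wc),
                cv = dfc_coefficient_of_variation(wc),
                stop("unknown dFC measure: ", measure))
  if (is.null(subnetwork)) global_mean(res)
  else subnetwork_value(res, subnetwork, normalize_by_global = FALSE)
}

# Batched surrogate dFC values: all surrogates pass through one FFT and one
# sliding-sum sweep. Draws phases in the same RNG order as the sequential
# path, so results are identical for a given seed.
batched_surrogate_values <- function(ts, spec, measure, subnetwork, nsur) {
  X <- ts$values
  N <- ncol(X)
  R <- nrow(X)
  half <- if (N %% 2L == 0L) N %/% 2L - 1L else (N - 1L) %/% 2L
  phi <- matrix(stats::runif(half * nsur, 0, 2 * pi), half, nsur)
  rot <- matrix(1 + 0i, N, nsur)
  rot[2L:(half + 1L), ] <- exp(1i * phi)
  rot[N:(N - half + 1L), ] <- exp(-1i * phi)
  Xf <- stats::mvfft(t(X))
  Xs <- Xf[, rep(seq_len(R), nsur), drop = FALSE] *
    rot[, rep(seq_len(nsur), each = R), drop = FALSE]
  XS <- t(Re(stats::mvfft(Xs, inverse = TRUE)) / N)   # (R*nsur) x N

  w <- tapered_window_weights(spec)
  starts <- window_start_indices(N, spec)
  L <- spec$length_volumes
  nw <- length(starts)
  wsum <- function(Y) {
    S <- matrix(0, nrow(Y), nw)
    for (l in seq_len(L)) S <- S + w[l] * Y[, starts + l, drop = FALSE]
    S
  }
  idx <- which(upper.tri(diag(R), diag = TRUE), arr.ind = TRUE)
  npr <- nrow(idx)
  i1 <- rep(idx[, 1L], nsur) + rep((seq_len(nsur) - 1L) * R, each = npr)
  i2 <- rep(idx[, 2L], nsur) + rep((seq_len(nsur) - 1L) * R, each = npr)
  M <- wsum(XS)
  S <- wsum(XS[i1, , drop = FALSE] * XS[i2, , drop = FALSE])
  covp <- S - M[i1, , drop = FALSE] * M[i2, , drop = FALSE]
  # rows of dd follow the global region index r + (s-1)*R, same space as i1/i2
  dd <- sqrt(pmax(covp[rep(idx[, 1L] == idx[, 2L], nsur), , drop = FALSE], 0))
  rp <- covp / (dd[i1, , drop = FALSE] * dd[i2, , drop = FALSE])
  rp[rp > 1] <- 1
  rp[rp < -1] <- -1

  offdiag <- idx[, 1L] != idx[, 2L]
  sel <- if (is.null(subnetwork)) offdiag else {
    pr <- subnetwork_pairs(subnetwork, ts$region_labels)
    key <- paste(pmin(pr[, 1L], pr[, 2L]), pmax(pr[, 1L], pr[, 2L]))
    paste(idx[, 1L], idx[, 2L]) %in% key
  }
  per_conn <- if (measure == "diff") {
    rowSums(abs(rp[, -1L, drop = FALSE] - rp[, -nw, drop = FALSE]))
  } else {
    a <- abs(rp)
    mu <- rowMeans(a)
    sqrt(rowSums((a - mu)^2) / (nw - 1L)) / mu
  }
  colMeans(matrix(per_conn, npr, nsur)[sel, , drop = FALSE])
}

#' Surrogate dFC ensemble for one subject
#'
#' Computes the observed dFC value (global, or subnetwork without global
#' normalisation) and the distribution of the same quantity over
#' \code{n_surrogates} independent phase-randomized surrogates, all with the
#' identical window specification.
#'
#' @param ts A \code{\link{region_ts}}.
#' @param spec A \code{\link{window_spec}}.
#' @param measure \code{"diff"} (summed difference) or \code{"cv"}
#'   (coefficient of variation).
#' @param subnetwork Optional \code{\link{subnetwork_spec}}; when given the
#'   raw (un-normalised) subnetwork mean is used instead of the global mean.
#' @param n_surrogates Number of surrogates (default 100).
#' @param seed Optional integer seed.
#' @return A \code{surrogate_ensemble}: \code{real_value},
#'   \code{surrogate_values} (length \code{n_surrogates}), plus metadata.
#' @export
surrogate_dfc <- function(ts, spec = window_spec(),
                          measure = c("diff", "cv"),
                          subnetwork = NULL, n_surrogates = 100L,
                          seed = NULL) {
  measure <- match.arg(measure)
  if (!is.null(seed)) set.seed(seed)
  real_value <- dfc_value(ts, spec, measure, subnetwork)
  N <- ncol(ts$values)
  R <- nrow(ts$values)
  npr <- R * (R + 1) / 2
  nw <- length(window_start_indices(N, spec))
  if (npr * n_surrogates * N <= 6e7 && nw > 8L) {
    surrogate_values <- batched_surrogate_values(ts, spec, measure,
                                                 subnetwork, n_surrogates)
  } else {
    Xf <- stats::mvfft(t(ts$values))     # shared across all surrogates
    surrogate_values <- vapply(seq_len(n_surrogates), function(i) {
      sts <- region_ts(surrogate_from_spectrum(Xf, N), tr = ts$tr,
                       region_labels = ts$region_labels,
                       subject_id = ts$subject_id)
      dfc_value(sts, spec, measure, subnetwork)
    }, numeric(1))
  }
  structure(list(subject_id = ts$subject_id, measure = measure,
                 real_value = real_value, surrogate_values = surrogate_values,
                 n_surrogates = n_surrogates),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %s: real %.4g vs %d surrogates (mean %.4g, sd %.3g)\n",
              x$measure, x$real_value, x$n_surrogates,
              mean(x$surrogate_values), stats::sd(x$surrogate_values)))
  invisible(x)
}

#' Paired test of real versus surrogate dFC
#'
#' Paired-sample t-test of each subject's observed dFC against the mean of
#' that subject's surrogate distribution. A significantly positive mean
#' difference indicates dFC beyond what static connectivity plus
#' autocorrelation alone (the surrogate null) would produce.
#'
#' @param ensembles List of \code{surrogate_ensemble} objects (>= 2 subjects,
#'   one measure).
#' @return List with \code{t}, \code{df}, \code{p}, and \code{mean_diff}
#'   (real minus surrogate mean).
#' @export
real_vs_surrogate_test <- function(ensembles) {
  if (length(ensembles) < 2L) stop("paired test requires at least 2 subjects")
  meas <- unique(vapply(ensembles, `[[`, character(1), "measure"))
  if (length(meas) != 1L) stop("all ensembles must use the same dFC measure")
  real <- vapply(ensembles, `[[`, numeric(1), "real_value")
  surr <- vapply(ensembles, function(e) mean(e$surrogate_values), numeric(1))
  d <- real - surr
  if (stats::sd(d) == 0) {
    return(list(measure = meas, t = 0, df = length(d) - 1L, p = 1,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(real, surr, paired = TRUE)
  list(measure = meas, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}
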