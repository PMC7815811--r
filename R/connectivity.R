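#' Static functional connectivity
#'
#' Absolute Pearson correlation between every pair of regions over the entire
#' time series, yielding a symmetric regions x regions matrix. The diagonal is
#' set to \code{NA} and excluded from all summaries. Zero-variance regions
#' produce \code{NA} entries with a warning rather than an error.
#'
#' @param ts A \code{\link{region_ts}} with at least 3 volumes.
#' @return A \code{conn_matrix} object (fields \code{values}, \code{measure},
#'   \code{region_labels}).
#' @export
static_fc <- function(ts) {
  X <- ts$values
  if (ncol(X) < 3L) stop("static FC requires at least 3 volumes")
  v <- apply(X, 1L, stats::var)
  bad <- v <= 0 | !is.finite(v)
  r <- suppressWarnings(abs(stats::cor(t(X))))
  if (any(bad)) {
    warning(sprintf("%d zero-variance region(s); their connectivity set to NA",
                    sum(bad)))
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
  }
  diag(r) <- NA_real_
  conn_matrix(r, measure = "sFC", region_labels = ts$region_labels)
}

conn_matrix <- function(values, measure, region_labels) {
  dimnames(values) <- list(region_labels, region_labels)
  structure(list(values = values, measure = measure,
                 region_labels = region_labels),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s, %d regions\n", x$measure,
              length(x$region_labels)))
  invisible(x)
}

#' Weighted Pearson correlation of a windowed segment
#'
#' Computes the weighted Pearson correlation between all pairs of regions for
#' one window, using the tapered-window weights: weighted means
#' \eqn{m_x = \sum_t w_t x_t}, weighted covariance
#' \eqn{c_{xy} = \sum_t w_t (x_t - m_x)(y_t - m_y)}, correlation
#' \eqn{c_{xy} / \sqrt{c_{xx} c_{yy}}}. With uniform weights this reduces to
#' the ordinary (population-normalised) Pearson coefficient.
#'
#' @param segment Numeric regions x length matrix (one window of data).
#' @param weights Positive weights of matching length (normalised internally).
#' @return Symmetric signed correlation matrix with unit diagonal; entries for
#'   regions with zero weighted variance are \code{NA} (with a warning).
#' @export
weighted_correlation <- function(segment, weights) {
  segment <- as.matrix(segment)
  if (length(weights) != ncol(segment))
    stop("weights must match the segment length")
  if (any(weights <= 0)) stop("weights must be strictly positive")
  w <- weights / sum(weights)
  m <- drop(segment %*% w)
  cen <- segment - m
  cov <- tcrossprod(cen * rep(w, each = nrow(segment)), cen)
  v <- diag(cov)
  bad <- v <= 0 | !is.finite(v)
  if (any(bad)) warning(sprintf("%d region(s) with zero weighted variance", sum(bad)))
  d <- sqrt(pmax(v, 0))
  r <- cov / outer(d, d)
  r[bad, ] <- NA_real_
  r[, bad] <- NA_real_
  diag(r)[!bad] <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Windowed (sliding-window) connectivity
#'
#' Splits the series into overlapping tapered windows per the
#' \code{\link{window_spec}} and computes the weighted Pearson correlation
#' matrix for each window. Two numerically identical code paths are used: for
#' small region counts a vectorised all-windows formulation based on sliding
#' weighted sums (fast when windows are many), otherwise a per-window
#' accumulation (fast when regions are many).
#'
#' @param ts A \code{\link{region_ts}}.
#' @param spec A \code{\link{window_spec}}.
#' @return A \code{windowed_fc} object: \code{stack} is a
#'   regions x regions x windows array of signed weighted correlations,
#'   \code{window_starts} the 0-based start indices, \code{spec} the spec.
#' @export
windowed_fc <- function(ts, spec = window_spec()) {
  X <- ts$values
  Tn <- ncol(X)
  R <- nrow(X)
  w <- tapered_window_weights(spec)
  starts <- window_start_indices(Tn, spec)
  nw <- length(starts)
  L <- spec$length_volumes

  if (R <= 40L && nw > 8L) {
    # sliding-sum path: accumulate weighted sums over the L in-window
    # offsets (the window matrix is sparse; dense products would waste work)
    wsum <- function(Y) {
      S <- matrix(0, nrow(Y), nw)
      for (l in seq_len(L)) S <- S + w[l] * Y[, starts + l, drop = FALSE]
      S
    }
    M <- wsum(X)                                   # R x nw weighted means
    idx <- which(upper.tri(diag(R), diag = TRUE), arr.ind = TRUE)
    npr <- nrow(idx)
    P <- X[idx[, 1L], , drop = FALSE] * X[idx[, 2L], , drop = FALSE]
    S <- wsum(P)                                   # weighted second moments
    covp <- S - M[idx[, 1L], , drop = FALSE] * M[idx[, 2L], , drop = FALSE]
    vrow <- covp[idx[, 1L] == idx[, 2L], , drop = FALSE]  # R x nw variances
    dd <- sqrt(pmax(vrow, 0))
    rp <- covp / (dd[idx[, 1L], , drop = FALSE] * dd[idx[, 2L], , drop = FALSE])
    rp[rp > 1] <- 1
    rp[rp < -1] <- -1
    bad <- vrow <= 0 | !is.finite(vrow)
    stack <- array(NA_real_, c(R, R, nw))
    base_up <- idx[, 1L] + (idx[, 2L] - 1L) * R
    base_lo <- idx[, 2L] + (idx[, 1L] - 1L) * R
    off <- rep((seq_len(nw) - 1L) * R * R, each = npr)
    v <- as.vector(rp)
    stack[rep(base_up, nw) + off] <- v
    stack[rep(base_lo, nw) + off] <- v
    if (any(bad)) {
      warning("zero weighted variance in some window(s); entries set to NA")
      for (k in which(colSums(bad) > 0L)) {
        b <- bad[, k]
        stack[b, , k] <- NA_real_
        stack[, b, k] <- NA_real_
      }
    }
  } else {
    stack <- array(NA_real_, c(R, R, nw))
    for (k in seq_len(nw)) {
      seg <- X[, (starts[k] + 1L):(starts[k] + L), drop = FALSE]
      stack[, , k] <- weighted_correlation(seg, w)
    }
  }
  dimnames(stack) <- list(ts$region_labels, ts$region_labels, NULL)
  structure(list(stack = stack, window_starts = starts, spec = spec,
                 region_labels = ts$region_labels),
            class = "windowed_fc")
}

#' @export
print.windowed_fc <- function(x, ...) {
  cat(sprintf("<windowed_fc> %d windows x %d regions (L=%d, step=%d, taper sd=%g)\n",
              dim(x$stack)[3], dim(x$stack)[1], x$spec$length_volumes,
              x$spec$step_volumes, x$spec$taper_sd_volumes))
  invisible(x)
}

dfc_result <- function(matrix, measure, region_labels, n_windows) {
  dimnames(matrix) <- list(region_labels, region_labels)
  structure(list(matrix = matrix, measure = measure,
                 region_labels = region_labels, n_windows = n_windows),
            class = "dfc_result")
}

#' @export
print.dfc_result <- function(x, ...) {
  cat(sprintf("<dfc_result> %s over %d windows, %d regions; global mean %.4g\n",
              x$measure, x$n_windows, length(x$region_labels),
              global_mean(x)))
  invisible(x)
}

#' dFC by summed successive difference
#'
#' For every connection, sums the absolute change in the signed windowed
#' correlation between consecutive windows:
#' \eqn{\sum_w |r_{w+1} - r_w|}. Signed window correlations are used by
#' default (only the differences are absolutised); set
#' \code{absolutize_windows = TRUE} to absolutise the window matrices first.
#'
#' @param wc A \code{\link{windowed_fc}} with at least 2 windows.
#' @param absolutize_windows Absolutise window correlations before
#'   differencing (default \code{FALSE}).
#' @return A \code{dfc_result} with non-negative per-connection values.
#' @export
dfc_summed_difference <- function(wc, absolutize_windows = FALSE) {
  nw <- dim(wc$stack)[3]
  if (nw < 2L) stop("summed-difference dFC requires at least 2 windows")
  s <- wc$stack
  if (absolutize_windows) s <- abs(s)
  R <- dim(s)[1]
  m <- matrix(s, R * R, nw)
  out <- matrix(rowSums(abs(m[, -1L, drop = FALSE] - m[, -nw, drop = FALSE])),
                R, R)
  diag(out) <- NA_real_
  dfc_result(out, "summed-difference", wc$region_labels, nw)
}

#' dFC by coefficient of variation
#'
#' Absolutises every window's correlation matrix, then computes per
#' connection the coefficient of variation across windows,
#' \eqn{cv(i) = \sigma_i / \mu_i}, where \eqn{\mu} is the mean absolute
#' connection strength over windows and \eqn{\sigma} its standard deviation
#' (sample, i.e. divisor W-1, by default; set \code{sd_type = "population"}
#' for divisor W). Connections with zero mean strength are undefined
#' (\code{NA}, with a warning).
#'
#' @param wc A \code{\link{windowed_fc}} with at least 2 windows.
#' @param sd_type \code{"sample"} (default) or \code{"population"}.
#' @return A \code{dfc_result} with non-negative per-connection values.
#' @export
dfc_coefficient_of_variation <- function(wc, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  nw <- dim(wc$stack)[3]
  if (nw < 2L) stop("coefficient-of-variation dFC requires at least 2 windows")
  R <- dim(wc$stack)[1]
  a <- matrix(abs(wc$stack), R * R, nw)
  muv <- rowMeans(a)
  sgv <- sqrt(rowSums((a - muv)^2) / (nw - 1L))
  if (sd_type == "population") sgv <- sgv * sqrt((nw - 1) / nw)
  mu <- matrix(muv, R, R)
  out <- matrix(sgv / muv, R, R)
  zero <- !is.na(mu) & mu == 0
  if (any(zero[upper.tri(zero)])) {
    warning("connections with zero mean strength are undefined (NA)")
    out[zero] <- NA_real_
  }
  diag(out) <- NA_real_
  dfc_result(out, if (sd_type == "sample") "cv" else "cv-population",
             wc$region_labels, nw)
}

extract_values <- function(x) {
  if (inherits(x, "dfc_result")) x$matrix
  else if (inherits(x, "conn_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a dfc_result, conn_matrix, or matrix")
}

#' Global mean over unique region pairs
#'
#' Averages a connectivity or dFC matrix over the unique off-diagonal pairs
#' (upper triangle). Undefined (\code{NA}) cells are skipped; their count is
#' reported via a message.
#'
#' @param x A \code{dfc_result}, \code{conn_matrix}, or square matrix.
#' @return Scalar mean.
#' @export
global_mean <- function(x) {
  m <- extract_values(x)
  v <- m[upper.tri(m)]
  nna <- sum(is.na(v))
  if (nna == length(v)) stop("all off-diagonal cells are undefined")
  if (nna > 0L) message(sprintf("global mean skipped %d undefined cell(s)", nna))
  mean(v, na.rm = TRUE)
}

#' Subnetwork specification
#'
#' Names the two region sets whose interconnectivity is summarised: here
#' typically the bilateral basal ganglia (caudate nucleus, putamen, globus
#' pallidus) versus default-mode cortical regions (medial prefrontal cortex,
#' posterior cingulate cortex, precuneus). \code{mode} selects whether
#' within-set pairs are included alongside between-set pairs.
#'
#' @param set_a,set_b Disjoint, non-empty character vectors of region labels.
#' @param mode \code{"between-sets-plus-within"} (all unique pairs among the
#'   union of both sets; default) or \code{"between-sets-only"}.
#' @return A \code{subnetwork_spec} object.
#' @export
subnetwork_spec <- function(set_a, set_b,
                            mode = c("between-sets-plus-within", "between-sets-only")) {
  mode <- match.arg(mode)
  set_a <- as.character(set_a); set_b <- as.character(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("both subnetwork sets must be non-empty")
  if (length(intersect(set_a, set_b)) > 0L)
    stop("subnetwork sets must be disjoint")
  structure(list(set_a = set_a, set_b = set_b, mode = mode),
            class = "subnetwork_spec")
}

subnetwork_pairs <- function(spec, labels) {
  miss <- setdiff(c(spec$set_a, spec$set_b), labels)
  if (length(miss) > 0L)
    stop("subnetwork labels not present in matrix: ", paste(miss, collapse = ", "))
  ia <- match(spec$set_a, labels)
  ib <- match(spec$set_b, labels)
  if (spec$mode == "between-sets-plus-within") {
    all_idx <- c(ia, ib)
    pr <- t(utils::combn(all_idx, 2L))
  } else {
    pr <- as.matrix(expand.grid(ia, ib))
  }
  pr
}

#' Subnetwork connectivity value
#'
#' Averages the matrix over the pairs selected by the
#' \code{\link{subnetwork_spec}}, optionally dividing by the global mean of
#' the same matrix to correct for between-subject differences in overall
#' connectivity strength.
#'
#' @param x A \code{dfc_result}, \code{conn_matrix}, or square labelled matrix.
#' @param spec A \code{\link{subnetwork_spec}}.
#' @param normalize_by_global Divide by \code{\link{global_mean}} (default
#'   \code{FALSE}).
#' @return Scalar subnetwork value.
#' @export
subnetwork_value <- function(x, spec, normalize_by_global = FALSE) {
  m <- extract_values(x)
  labels <- rownames(m)
  if (is.null(labels)) stop("matrix must carry region labels")
  pr <- subnetwork_pairs(spec, labels)
  if (nrow(pr) == 0L) stop("empty subnetwork pair set")
  vals <- m[pr]
  out <- mean(vals, na.rm = TRUE)
  if (normalize_by_global) out <- out / global_mean(x)
  out
}
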