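#' Default CIS-20r item-to-subscale map
#'
#' The revised Checklist of Individual Strength has 20 items scored 1-7 on
#' four subscales: subjective fatigue complaints (8 items), motivation
#' (4 items), physical activity (3 items), and concentration (5 items).
#' The published instrument's exact item order and reverse keying are not
#' fixed here; this default assigns items in order (1-8, 9-12, 13-15, 16-20)
#' with no reversal, and is a documented stand-in that can be replaced by a
#' study-specific map.
#'
#' @return Named list of integer item indices per subscale.
#' @export
cis20r_default_map <- function() {
  list(subjective_complaints = 1:8,
       motivation = 9:12,
       physical_activity = 13:15,
       concentration = 16:20)
}

#' Score the CIS-20r fatigue questionnaire
#'
#' Sums item responses into the four subscale scores and a total score
#' (total = sum of subscales, range 20-140). Items must be complete and in
#' range; no imputation is performed.
#'
#' @param items Numeric vector of 20 item responses, each in 1-7.
#' @param map Item-to-subscale map (see \code{\link{cis20r_default_map}}).
#' @param reverse_items Integer indices of reverse-keyed items, recoded as
#'   \code{8 - response} before summing (default none).
#' @return Named list with the four subscale scores and \code{total}.
#' @export
score_cis20r <- function(items, map = cis20r_default_map(),
                         reverse_items = integer(0)) {
  if (length(items) != 20L) stop("CIS-20r requires exactly 20 item responses")
  if (anyNA(items)) stop("missing item responses are not allowed")
  if (any(items < 1 | items > 7)) stop("item responses must lie in [1, 7]")
  if (length(reverse_items) > 0L) items[reverse_items] <- 8 - items[reverse_items]
  sub <- lapply(map, function(idx) sum(items[idx]))
  sub$total <- sum(unlist(sub))
  sub
}

#' Classify severe fatigue from the CIS-20r total
#'
#' @param total CIS-20r total score in [20, 140].
#' @param cutoff Severe-fatigue cutoff (default 76); scores at or above the
#'   cutoff are classified severe.
#' @return \code{"severe"} or \code{"non-severe"}.
#' @export
classify_severe_fatigue <- function(total, cutoff = 76) {
  if (any(total < 20 | total > 140)) stop("CIS-20r total must lie in [20, 140]")
  ifelse(total >= cutoff, "severe", "non-severe")
}

#' Normality assessment (Kolmogorov-Smirnov)
#'
#' One-sample KS test of the sample against a normal distribution with the
#' sample's own mean and standard deviation (the common statistics-package
#' behaviour; note the estimated parameters make the test conservative).
#' Classified non-normal when p < alpha. Degenerate (constant) samples are
#' classified non-normal.
#'
#' @param x Numeric sample, n >= 4.
#' @param alpha Decision level (default 0.05).
#' @return \code{"normal"} or \code{"non-normal"}.
#' @export
assess_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 4L) stop("normality assessment requires n >= 4")
  s <- stats::sd(x)
  if (s == 0) return("non-normal")
  p <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s))$p.value
  if (p < alpha) "non-normal" else "normal"
}

#' Normality-gated two-group comparison
#'
#' If both samples are classified normal by \code{\link{assess_normality}},
#' a two-sample t-test is used (pooled variance by default, switching to
#' Welch when the variance ratio exceeds \code{welch_ratio}); otherwise a
#' Mann-Whitney U test.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param force \code{"auto"} (gate on normality), \code{"t"}, or
#'   \code{"mann-whitney"}.
#' @param welch_ratio Variance ratio above which Welch's correction replaces
#'   the pooled t-test (default 4).
#' @return List: \code{test} name, \code{statistic}, \code{df} (t only),
#'   \code{p}.
#' @export
two_group_compare <- function(x, y, force = c("auto", "t", "mann-whitney"),
                              welch_ratio = 4) {
  force <- match.arg(force)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("both groups need n >= 2")
  use_t <- switch(force,
                  t = TRUE, `mann-whitney` = FALSE,
                  auto = length(x) >= 4L && length(y) >= 4L &&
                    assess_normality(x) == "normal" &&
                    assess_normality(y) == "normal")
  if (use_t) {
    vr <- stats::var(x) / stats::var(y)
    welch <- !is.finite(vr) || vr > welch_ratio || vr < 1 / welch_ratio
    tt <- stats::t.test(x, y, var.equal = !welch)
    list(test = if (welch) "welch-t" else "pooled-t",
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         df = NA_real_, p = wt$p.value)
  }
}

#' Normality-gated paired comparison
#'
#' Longitudinal within-subject comparison: the normality of the paired
#' differences gates a paired t-test versus a Wilcoxon signed-rank test.
#' All-zero differences return statistic 0, p = 1 (no change).
#'
#' @param before,after Paired numeric vectors of equal length (n >= 2).
#' @return List: \code{test}, \code{statistic}, \code{df} (t only), \code{p}.
#' @export
paired_compare <- function(before, after) {
  if (length(before) != length(after)) stop("paired samples must have equal length")
  ok <- stats::complete.cases(before, after)
  before <- before[ok]; after <- after[ok]
  if (length(before) < 2L) stop("paired comparison needs n >= 2 complete pairs")
  d <- after - before
  if (all(d == 0)) return(list(test = "paired-t", statistic = 0,
                               df = length(d) - 1L, p = 1))
  normal <- length(d) >= 4L && assess_normality(d) == "normal"
  if (normal) {
    tt <- stats::t.test(after, before, paired = TRUE)
    list(test = "paired-t", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE,
                                              exact = FALSE))
    list(test = "wilcoxon-signed-rank", statistic = unname(wt$statistic),
         df = NA_real_, p = wt$p.value)
  }
}

#' Hierarchical forward regression
#'
#' Blockwise forward selection for a continuous outcome. Blocks are processed
#' in order (e.g. 1: demographic/clinical covariates; 2: volumetrics; 3: dFC
#' predictors); within each block the candidate with the smallest partial-t
#' p-value is entered repeatedly while that p-value is below \code{p_enter}.
#' Entered predictors are never removed (pure forward). Listwise deletion is
#' applied over the outcome and all candidates before fitting.
#'
#' @param data Data frame with the outcome and all candidate predictors.
#'   Two-level factors/characters are recoded 0/1 internally.
#' @param outcome Name of the outcome column.
#' @param blocks List of character vectors of predictor names, in entry order;
#'   blocks must be disjoint.
#' @param p_enter Entry threshold on the partial-t p-value (default 0.05).
#' @return List of class \code{forward_regression}: \code{selected} (entry
#'   order), \code{steps} (data frame with per-entry R-squared, adjusted
#'   R-squared, delta R-squared and its F-test), \code{coefficients} (final
#'   standardized beta, t, p per predictor), \code{model} (final R-squared,
#'   adjusted R-squared, F, df, p), \code{n} (complete cases used).
#' @export
hierarchical_forward_regression <- function(data, outcome, blocks,
                                            p_enter = 0.05) {
  cand <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(cand)) stop("regression blocks must be disjoint")
  miss <- setdiff(c(outcome, cand), names(data))
  if (length(miss) > 0L) stop("columns not found: ", paste(miss, collapse = ", "))
  d <- data[, c(outcome, cand), drop = FALSE]
  for (nm in cand) {
    if (is.character(d[[nm]]) || is.factor(d[[nm]])) {
      lev <- sort(unique(as.character(d[[nm]])))
      if (length(lev) > 2L) stop("predictor '", nm, "' has more than 2 levels")
      d[[nm]] <- as.numeric(as.character(d[[nm]]) == lev[length(lev)])
    }
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(cand))
    stop("need more complete cases than candidate predictors")
  y <- d[[outcome]]

  selected <- character(0)
  steps <- list()
  r2_prev <- 0
  for (block in blocks) {
    remaining <- setdiff(block, selected)
    repeat {
      if (length(remaining) == 0L) break
      pvals <- vapply(remaining, function(v) {
        f <- stats::reformulate(c(selected, v), response = outcome)
        fit <- stats::lm(f, data = d)
        cf <- summary(fit)$coefficients
        if (!v %in% rownames(cf)) return(1)  # aliased
        cf[v, "Pr(>|t|)"]
      }, numeric(1))
      best <- names(which.min(pvals))
      if (pvals[best] >= p_enter) break
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
      fit <- stats::lm(stats::reformulate(selected, response = outcome), data = d)
      sm <- summary(fit)
      dr2 <- sm$r.squared - r2_prev
      df2 <- fit$df.residual
      f_change <- dr2 / (1 - sm$r.squared) * df2
      steps[[length(steps) + 1L]] <- data.frame(
        predictor = best, r_squared = sm$r.squared,
        adj_r_squared = sm$adj.r.squared, delta_r_squared = dr2,
        f_change = f_change,
        p_change = stats::pf(f_change, 1, df2, lower.tail = FALSE))
      r2_prev <- sm$r.squared
    }
  }

  if (length(selected) == 0L) {
    warning("no predictor met the entry criterion; intercept-only model")
    return(structure(list(selected = character(0),
                          steps = data.frame(),
                          coefficients = data.frame(),
                          model = list(r_squared = 0, adj_r_squared = 0,
                                       f = NA_real_, df1 = 0, df2 = n - 1L,
                                       p = NA_real_),
                          n = n),
                     class = "forward_regression"))
  }

  fit <- stats::lm(stats::reformulate(selected, response = outcome), data = d)
  sm <- summary(fit)
  cf <- sm$coefficients[selected, , drop = FALSE]
  sdy <- stats::sd(y)
  beta_std <- vapply(selected, function(v) {
    unname(stats::coef(fit)[v]) * stats::sd(d[[v]]) / sdy
  }, numeric(1))
  fstat <- sm$fstatistic
  structure(list(
    selected = selected,
    steps = do.call(rbind, steps),
    coefficients = data.frame(predictor = selected,
                              std_beta = beta_std,
                              t = cf[, "t value"],
                              p = cf[, "Pr(>|t|)"],
                              row.names = NULL),
    model = list(r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 f = unname(fstat[1]), df1 = unname(fstat[2]),
                 df2 = unname(fstat[3]),
                 p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = n), class = "forward_regression")
}

#' @export
print.forward_regression <- function(x, ...) {
  cat(sprintf("<forward_regression> n = %d, R^2 = %.3f (adj %.3f)\n",
              x$n, x$model$r_squared, x$model$adj_r_squared))
  if (length(x$selected) > 0L) print(x$coefficients)
  invisible(x)
}

#' Spearman correlation profile of fatigue predictors
#'
#' Rank correlations between each predictor and each fatigue score (total
#' and subscales), uncorrected for multiple testing (exploratory post-hoc
#' usage).
#'
#' @param predictors Data frame of predictor columns.
#' @param fatigue Data frame of fatigue scores (total and subscales), same
#'   rows.
#' @return Data frame: predictor, fatigue_score, n, rho, p.
#' @export
spearman_profile <- function(predictors, fatigue) {
  if (nrow(predictors) != nrow(fatigue)) stop("row counts must match")
  out <- list()
  for (pn in names(predictors)) for (fn in names(fatigue)) {
    ok <- stats::complete.cases(predictors[[pn]], fatigue[[fn]])
    if (sum(ok) < 5L) stop("Spearman profile requires n >= 5 per pair")
    ct <- suppressWarnings(stats::cor.test(predictors[[pn]][ok],
                                           fatigue[[fn]][ok],
                                           method = "spearman", exact = FALSE))
    out[[length(out) + 1L]] <- data.frame(
      predictor = pn, fatigue_score = fn, n = sum(ok),
      rho = unname(ct$estimate), p = ct$p.value)
  }
  do.call(rbind, out)
}

#' Three-group comparison (Kruskal-Wallis with pairwise follow-up)
#'
#' Omnibus Kruskal-Wallis test across groups (e.g. healthy controls,
#' non-fatigued patients, fatigued patients) followed by uncorrected pairwise
#' Mann-Whitney U tests.
#'
#' @param values Numeric vector.
#' @param group Factor/character of group membership (>= 2 per group).
#' @return List: \code{h}, \code{df}, \code{p} (omnibus), \code{pairwise}
#'   data frame (group1, group2, u, p).
#' @export
three_group_compare <- function(values, group) {
  group <- as.factor(group)
  if (any(table(group) < 2L)) stop("each group needs at least 2 subjects")
  kw <- stats::kruskal.test(values, group)
  levs <- levels(group)
  pw <- list()
  for (i in seq_along(levs)) for (j in seq_along(levs)) {
    if (j <= i) next
    wt <- suppressWarnings(stats::wilcox.test(values[group == levs[i]],
                                              values[group == levs[j]],
                                              exact = FALSE))
    pw[[length(pw) + 1L]] <- data.frame(group1 = levs[i], group2 = levs[j],
                                        u = unname(wt$statistic),
                                        p = wt$p.value)
  }
  list(h = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value,
       pairwise = do.call(rbind, pw))
}
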