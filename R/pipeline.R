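pipeline_defaults <- function() {
  list(
    simulate = TRUE,
    n_regions = 30L, n_volumes = 202L, tr_seconds = 2.2,
    n_patients = 12L, n_controls = 8L,
    base_correlation = 0.25, modulation_amplitude = 0.3,
    modulation_period_seconds = 60,
    fatigue_effect_slope = 15, edss_effect = 6, fatigue_noise_sd = 12,
    noise_sd = 0.2,
    n_discard = 5L,
    fd_threshold_mm = 0.5, fd_max_fraction = 0.20,
    highpass_hz = 0.01,
    window_length = 27L, window_step = 5L, window_taper_sd = 9,
    n_surrogates = 100L,
    fatigue_cutoff = 76,
    p_enter = 0.05,
    seed = 1L,
    out_dir = "dynfc-output"
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Fills in every default (27/5/9 window, 0.5 mm / 20\% motion rule, 0.01 Hz
#' high-pass, 100 surrogates, fatigue cutoff 76, entry p 0.05) and validates
#' values. Unknown keys are rejected by name.
#'
#' @param config Named list of overrides, or a path to a JSON (or YAML, when
#'   the yaml package is available) config file.
#' @return The resolved configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the yaml package is required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(config)) config <- list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (cfg$window_step < 1L) stop("window step must be at least 1")
  if (cfg$window_length < 2L) stop("window length must be at least 2")
  if (cfg$window_taper_sd <= 0) stop("window taper sd must be positive")
  if (cfg$n_volumes - cfg$n_discard < cfg$window_length)
    stop("usable volume count is shorter than one window")
  if (cfg$n_surrogates < 1L) stop("at least one surrogate is required")
  if (cfg$fd_threshold_mm <= 0) stop("FD threshold must be positive")
  if (cfg$highpass_hz >= 1 / (2 * cfg$tr_seconds))
    stop("high-pass cutoff must be below Nyquist")
  cfg
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the full workflow on a simulated cohort: per subject, motion
#' QC, volume discarding, high-pass filtering, static FC, windowed FC, both
#' dFC measures with global and basal ganglia-DMN subnetwork values (raw and
#' normalised); at cohort level, the surrogate-null paired test, group
#' comparisons (patients vs controls), hierarchical forward regression of
#' fatigue, Spearman post-hoc profile, and the cutoff-based three-group
#' comparison. All tables are written to \code{config$out_dir} along with the
#' resolved configuration; the run is reproducible from config + seed.
#'
#' @param config A named list of overrides or config-file path for
#'   \code{\link{validate_config}}.
#' @return Invisibly, a list with the cohort table (per-subject connectivity
#'   summaries merged with clinical data), the surrogate test results, the
#'   group-comparison table, the regression fit, and output paths.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  if (!isTRUE(cfg$simulate))
    stop("only simulated input is supported by run_pipeline in this release")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- window_spec(cfg$window_length, cfg$window_step, cfg$window_taper_sd)
  sn <- default_subnetwork()

  sim_cfg <- sim_config(
    n_regions = cfg$n_regions, n_volumes = cfg$n_volumes,
    tr_seconds = cfg$tr_seconds, n_patients = cfg$n_patients,
    n_controls = cfg$n_controls, base_correlation = cfg$base_correlation,
    modulation_amplitude = cfg$modulation_amplitude,
    modulation_period_seconds = cfg$modulation_period_seconds,
    fatigue_effect_slope = cfg$fatigue_effect_slope,
    edss_effect = cfg$edss_effect, fatigue_noise_sd = cfg$fatigue_noise_sd,
    noise_sd = cfg$noise_sd, seed = cfg$seed)
  cohort <- simulate_cohort(sim_cfg, spec, n_discard = cfg$n_discard)

  n <- nrow(cohort$clinical)
  qc <- vector("list", n)
  rows <- vector("list", n)
  ens_diff <- list(); ens_cv <- list()
  for (i in seq_len(n)) {
    sub <- cohort$subjects[[i]]
    qc[[i]] <- c(list(subject_id = sub$ts$subject_id),
                 motion_qc(sub$motion, cfg$fd_threshold_mm, cfg$fd_max_fraction))
    ts <- discard_initial_volumes(sub$ts, cfg$n_discard)
    ts <- highpass_filter(ts, cfg$highpass_hz)
    sfc <- static_fc(ts)
    wc <- windowed_fc(ts, spec)
    dd <- dfc_summed_difference(wc)
    dc <- dfc_coefficient_of_variation(wc)
    rows[[i]] <- data.frame(
      subject_id = sub$ts$subject_id,
      qc_decision = qc[[i]]$decision,
      global_sfc = global_mean(sfc),
      global_dfc_diff = global_mean(dd),
      global_dfc_cv = global_mean(dc),
      bd_sfc = subnetwork_value(sfc, sn, normalize_by_global = TRUE),
      bd_dfc_diff = subnetwork_value(dd, sn, normalize_by_global = TRUE),
      bd_dfc_cv = subnetwork_value(dc, sn, normalize_by_global = TRUE),
      stringsAsFactors = FALSE)
    seed_i <- sub_seed(cfg$seed, 500000L + i)
    ens_diff[[i]] <- surrogate_dfc(ts, spec, "diff",
                                   n_surrogates = cfg$n_surrogates,
                                   seed = seed_i)
    ens_cv[[i]] <- surrogate_dfc(ts, spec, "cv",
                                 n_surrogates = cfg$n_surrogates,
                                 seed = seed_i + 1L)
  }
  conn <- do.call(rbind, rows)
  tab <- merge(cohort$clinical, conn, by = "subject_id")

  surrogate_tests <- list(diff = real_vs_surrogate_test(ens_diff),
                          cv = real_vs_surrogate_test(ens_cv))

  measures <- c("global_sfc", "global_dfc_diff", "global_dfc_cv",
                "bd_sfc", "bd_dfc_diff", "bd_dfc_cv")
  cmp <- do.call(rbind, lapply(measures, function(m) {
    r <- two_group_compare(tab[[m]][tab$group == "patient"],
                           tab[[m]][tab$group == "control"])
    data.frame(measure = m, test = r$test, statistic = r$statistic,
               df = r$df, p = r$p)
  }))

  pt <- tab[tab$group == "patient", ]
  reg <- tryCatch(hierarchical_forward_regression(
    pt, outcome = "cis20r_total",
    blocks = list(c("age", "sex", "education", "medication",
                    "disease_duration", "edss"),
                  c("global_dfc_diff", "global_dfc_cv",
                    "bd_dfc_diff", "bd_dfc_cv")),
    p_enter = cfg$p_enter),
    error = function(e) {
      warning("regression stage skipped: ", conditionMessage(e))
      structure(list(selected = character(0), steps = data.frame(),
                     coefficients = data.frame(),
                     model = list(error = conditionMessage(e)),
                     n = nrow(pt)),
                class = "forward_regression")
    })

  spearman <- if (length(reg$selected) > 0L) {
    spearman_profile(pt[, reg$selected, drop = FALSE],
                     pt[, c("cis20r_total", "cis20r_subjective",
                            "cis20r_motivation", "cis20r_physical",
                            "cis20r_concentration")])
  } else NULL

  fat_class <- classify_severe_fatigue(tab$cis20r_total, cfg$fatigue_cutoff)
  grp3 <- ifelse(tab$group == "control", "control",
                 ifelse(fat_class == "severe", "fatigued", "non-fatigued"))
  three_group <- if (all(table(grp3) >= 2L))
    three_group_compare(tab$bd_dfc_cv, grp3) else NULL

  # ---- write the report bundle ----
  utils::write.csv(tab, file.path(cfg$out_dir, "cohort_table.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp, file.path(cfg$out_dir, "group_comparisons.csv"),
                   row.names = FALSE)
  jsonlite::write_json(qc, file.path(cfg$out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(surrogate_tests,
                       file.path(cfg$out_dir, "surrogate_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(selected = reg$selected,
                            coefficients = reg$coefficients,
                            model = reg$model, n = reg$n),
                       file.path(cfg$out_dir, "regression.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(spearman))
    utils::write.csv(spearman, file.path(cfg$out_dir, "spearman_posthoc.csv"),
                     row.names = FALSE)
  if (!is.null(three_group)) {
    jsonlite::write_json(three_group,
                         file.path(cfg$out_dir, "three_group.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(table = tab, qc = qc, surrogate_tests = surrogate_tests,
                 group_comparisons = cmp, regression = reg,
                 spearman = spearman, three_group = three_group,
                 out_dir = cfg$out_dir))
}
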