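#' Default pipeline configuration
#'
#' All stage parameters of the analysis pipeline in one place, with defaults
#' equal to the study's printed acquisition and analysis values: 3.47 Hz
#' sampling, 760/850 nm, band-pass 0.01-0.08 Hz (orders 3 low-pass / 5
#' high-pass), wavelet IQR factor 0.1, z cut-off 3.29, block window -2 to
#' 45 s, RT bounds 200/2000 ms, and the binomial inclusion criterion
#' (26 trials, p = 0.5, 99% quantile).
#'
#' @param n_per_group named group sizes
#' @param seed global seed
#' @param out_dir output directory for intermediates (`NULL` = keep in memory)
#' @param simulate_behavior,simulate_nirs,run_stats stage toggles
#' @param ... overrides for any listed parameter
#' @return list of class `pipeline_config`
#' @export
default_config <- function(n_per_group = c(experimental = 19, control = 23),
                           seed = 1, out_dir = NULL,
                           simulate_behavior = TRUE, simulate_nirs = TRUE,
                           run_stats = TRUE, ...) {
  cfg <- list(
    n_per_group = n_per_group, seed = seed, out_dir = out_dir,
    simulate_behavior = simulate_behavior, simulate_nirs = simulate_nirs,
    run_stats = run_stats,
    fs = 3.47, wavelengths = c(760, 850),
    low = 0.01, high = 0.08, lp_order = 3, hp_order = 5,
    iqr_factor = 0.1, z_cutoff = 3.29, window = c(-2, 45),
    rt_min = 200, rt_max = 2000,
    inclusion_n = 26, inclusion_p = 0.5, inclusion_quantile = 0.99,
    age_mean = 69.18, age_sd = 3.92, age_range = c(64, 79),
    rcs_rho = 0.8, qc = TRUE, motion_correction = TRUE, bandpass = TRUE
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full simulate -> preprocess -> score -> analyze pipeline
#'
#' Simulates a cohort (behavioral sessions and fNIRS recordings), runs the
#' preprocessing chain on every recording, scores the behavioral sessions
#' into rate-correct scores with all exclusion rules, pools channels to ROI
#' activations, and runs the inference stage (mixed repeated-measures ANOVA
#' on RCS and on HBdiff, planned pre-vs-post contrasts per group, and
#' forced-entry regressions of RCS on group + ROI HBdiff + MMSE per time
#' point). Identical configuration and seed reproduce the run exactly.
#'
#' @param config a [default_config()]
#' @return list of class `run_report`: result tables per stage, exclusion
#'   counts attributable to named rules, and the parameter echo
#' @export
run_pipeline <- function(config = default_config()) {
  set.seed(config$seed)
  tps <- c("pre", "post15", "post30", "post45")
  montage <- default_montage()
  mapping <- map_channels_to_rois(montage)

  meta <- list()
  pid <- 0
  for (g in names(config$n_per_group)) {
    for (i in seq_len(config$n_per_group[[g]])) {
      pid <- pid + 1
      age <- min(max(round(stats::rnorm(1, config$age_mean, config$age_sd)),
                     config$age_range[1]), config$age_range[2])
      meta[[pid]] <- data.frame(participant_id = sprintf("P%03d", pid),
                                group = g, age = age,
                                mmse = min(30, round(stats::rnorm(1, 29.2, 1.0))),
                                stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)

  report <- list(config = config, meta = meta,
                 version = as.character(utils::packageVersion("fnirswm")))

  # --- behavioral stage -----------------------------------------------
  if (config$simulate_behavior) {
    trials <- list()
    for (i in seq_len(nrow(meta))) {
      acc_shift <- stats::rnorm(1, 0, 0.5)
      rt_shift <- stats::rnorm(1, 0, 0.15)
      for (tp in tps) {
        trials[[length(trials) + 1]] <- generate_behavioral_session(
          group = meta$group[i], time_point = tp,
          participant_id = meta$participant_id[i],
          acc_shift = acc_shift, rt_shift = rt_shift)
      }
    }
    trials <- do.call(rbind, trials)
    filtered <- filter_trials(trials, rt_min = config$rt_min,
                              rt_max = config$rt_max)
    scores <- score_trials(filtered)
    thr <- inclusion_threshold(config$inclusion_n, config$inclusion_p,
                               config$inclusion_quantile)
    scores <- apply_exclusions(scores, threshold = thr,
                               z_cutoff = config$z_cutoff)
    report$trials_per_cell <- sum(!filtered$discarded &
                                    filtered$participant_id == meta$participant_id[1] &
                                    filtered$time_point == "pre" &
                                    filtered$condition == "2-back")
    report$n_discarded_trials <- sum(filtered$discarded)
    report$scores <- scores
    report$exclusions <- table(scores$excluded_reason)
  }

  # --- fNIRS stage ----------------------------------------------------
  if (config$simulate_nirs) {
    sim_cfg <- sim_config(fs = config$fs, wavelengths = config$wavelengths)
    acts <- list()
    drop_rates <- numeric(0)
    for (i in seq_len(nrow(meta))) {
      for (tp in tps) {
        gen <- generate_nirs_recording(sim_cfg, montage,
                                       participant_id = meta$participant_id[i],
                                       group = meta$group[i], time_point = tp,
                                       age = meta$age[i])
        pp <- preprocess_recording(gen$recording, qc = config$qc,
                                   motion_correction = config$motion_correction,
                                   bandpass = config$bandpass,
                                   iqr_factor = config$iqr_factor,
                                   low = config$low, high = config$high,
                                   window = config$window)
        drop_rates <- c(drop_rates, pp$qc_drop_rate)
        vals <- pp$summary[, "2-back"]
        names(vals) <- montage$label
        vals[montage$roi == "excluded"] <- NA
        keep <- !is.na(vals)
        if (sum(keep) >= 3)
          vals[keep][channel_outlier_filter(vals[keep],
                                            cutoff = config$z_cutoff)] <- NA
        pooled <- pool_roi(vals, mapping, level = "region")
        pooled$participant_id <- meta$participant_id[i]
        pooled$group <- meta$group[i]
        pooled$time_point <- tp
        acts[[length(acts) + 1]] <- pooled
      }
    }
    activations <- do.call(rbind, acts)
    report$activations <- activations
    report$qc_drop_rate <- mean(drop_rates, na.rm = TRUE)
  }

  # --- inference stage ------------------------------------------------
  if (config$run_stats && config$simulate_behavior) {
    rcs2 <- report$scores[report$scores$condition == "2-back" &
                            report$scores$included, ]
    rcs2 <- merge(rcs2, meta, by = "participant_id")
    report$rcs_anova <- mixed_rm_anova(rcs2, dv = "rcs",
                                       subject = "participant_id",
                                       between = "group",
                                       within = "time_point")
    report$rcs_contrasts <- planned_contrasts(rcs2, dv = "rcs",
                                              subject = "participant_id",
                                              group = "group",
                                              time = "time_point")
  }
  if (config$run_stats && config$simulate_nirs) {
    act <- report$activations
    act <- act[!is.na(act$hbdiff_mean), ]
    report$hbdiff_anova <- mixed_rm_anova(act, dv = "hbdiff_mean",
                                          subject = "participant_id",
                                          between = "group",
                                          within = c("time_point", "region",
                                                     "hemisphere"))
    if (config$simulate_behavior) {
      report$regressions <- list()
      rcs2 <- report$scores[report$scores$condition == "2-back" &
                              report$scores$included, ]
      for (tp in tps) {
        roi_tp <- act[act$time_point == tp, ]
        roi_wide <- stats::aggregate(
          hbdiff_mean ~ participant_id + region + hemisphere, roi_tp, mean)
        roi_wide$key <- paste(roi_wide$region, roi_wide$hemisphere, sep = "_")
        rw <- stats::reshape(roi_wide[, c("participant_id", "key", "hbdiff_mean")],
                             idvar = "participant_id", timevar = "key",
                             direction = "wide")
        names(rw) <- sub("^hbdiff_mean\\.", "", names(rw))
        df <- merge(merge(rcs2[rcs2$time_point == tp,
                               c("participant_id", "rcs")], rw,
                          by = "participant_id"),
                    meta, by = "participant_id")
        df$group_eg <- as.integer(df$group == "experimental")
        preds <- c("group_eg", "mmse", "frontal_left", "frontal_right",
                   "parietal_left", "parietal_right")
        if (all(preds %in% names(df)) && nrow(df) > length(preds) + 1) {
          report$regressions[[tp]] <- forced_entry_regression(df, "rcs", preds)
        }
      }
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(report$scores))
      utils::write.table(report$scores,
                         file.path(config$out_dir, "scores.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report$activations))
      utils::write.table(report$activations,
                         file.path(config$out_dir, "roi_activations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report$rcs_anova))
      utils::write.table(as.data.frame(report$rcs_anova),
                         file.path(config$out_dir, "rcs_anova.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  class(report) <- "run_report"
  report
}
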