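#' Configuration for an end-to-end analysis run
#'
#' Bundles every knob of the pipeline: cohort size and group parameters,
#' task list, analysis windows (the 2-4 s epoch-time CMC window, the
#' 1-3 s post-trigger burst scoring window, the 13-30 Hz beta band),
#' permutation settings and the master seed.
#'
#' @param n_per_group participants per group.
#' @param tasks list of [task_spec()]s.
#' @param params_hc,params_als group parameter sets.
#' @param n_perm permutations for all permutation tests.
#' @param cluster_alpha cluster-forming alpha.
#' @param cmc_window CMC analysis window, epoch-relative seconds.
#' @param burst_window burst scoring window, trigger-relative seconds.
#' @param beta_band beta band in Hz.
#' @param seed master seed.
#' @param reject_epochs run GESD bad-epoch rejection.
#' @param compute_power compute Morlet power / probability time courses
#'   and their cluster tests (the slowest stage; switch off for quick
#'   direction-only runs).
#' @param timecourse_stride subsample factor of the epoch grid used in
#'   time-resolved cluster tests.
#' @param n_extra_parcels extra task-inactive parcels in the simulation.
#' @return a `run_config` list.
#' @export
run_config <- function(n_per_group = 10,
                       tasks = list(task_spec("bilateral", n_trials = 60)),
                       params_hc = group_params(),
                       params_als = group_params_als(),
                       n_perm = 1000, cluster_alpha = 0.05,
                       cmc_window = c(2, 4), burst_window = c(1, 3),
                       beta_band = c(13, 30), seed = 1,
                       reject_epochs = TRUE, compute_power = TRUE,
                       timecourse_stride = 8L, n_extra_parcels = 0) {
  stopifnot(cmc_window[1] >= 0, cmc_window[2] <= 6,
            burst_window[1] >= -1, burst_window[2] <= 5)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or accept a supplied cohort) -> epoch rejection ->
#' behavioural metrics -> motor CMC spectra and beta CMC topography ->
#' beta power and burst analyses -> group statistics (cluster permutation
#' tests on CMC spectra and time courses, max-t permutation GLM with
#' age/sex/missing-MRI confounds on burst metrics, Welch t with
#' Bonferroni on behaviour, Pearson correlations of contralateral beta
#' CMC with clinical covariates), plus signed direction flags of the
#' patient-vs-control group mean differences.
#'
#' @param config a [run_config()].
#' @param cohort optional precomputed cohort from [simulate_cohort()];
#'   simulated from `config` when NULL.
#' @param out_dir optional directory for CSV outputs and the JSON
#'   manifest.
#' @return a report list (see Details in the vignette): per-participant
#'   tables, group statistics, `directions` (signed ALS-minus-HC group
#'   mean differences) and a manifest.
#' @export
run_analysis <- function(config, cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort))
    cohort <- simulate_cohort(config$params_hc, config$params_als,
                              config$n_per_group, config$tasks,
                              master_seed = config$seed,
                              n_extra_parcels = config$n_extra_parcels)
  parts <- cohort$participants
  task_labels <- vapply(config$tasks, `[[`, "", "task_label")
  cmc_rows <- list(); metric_rows <- list(); behav_rows <- list()
  spectra <- list()     # [[task]][[hemi]] matrix subjects x freq bins
  power_tc <- list(); prob_tc <- list()
  for (i in seq_len(nrow(parts))) {
    pid <- parts$participant_id[i]
    for (tk in task_labels) {
      ep <- cohort$sessions[[pid]][[tk]]
      if (config$reject_epochs) ep <- reject_bad_epochs(ep)
      # behaviour
      br <- behavioural_metrics(ep)
      bs <- behaviour_summary(br)
      behav_rows[[length(behav_rows) + 1]] <-
        cbind(participant_id = pid, task = tk, bs)
      # CMC
      prep <- prepare_cmc_epochs(ep)
      mc <- motor_cmc(prep, window_s = config$cmc_window)
      for (nm in names(mc)) {
        cs <- mc[[nm]]
        hemi <- sub("_.*", "", nm)
        pairing <- sub(".*_", "", nm)
        cmc_rows[[length(cmc_rows) + 1]] <- data.frame(
          participant_id = pid, task = tk, hemisphere = hemi,
          pairing = pairing,
          beta_cmc = band_mean_coherence(cs, config$beta_band))
        if (pairing == "contra") {
          key <- paste(tk, hemi, sep = ".")
          spectra[[key]] <- rbind(spectra[[key]], cs$coh)
        }
      }
      # bursts on the two motor parcels (raw data)
      fo <- dur <- amp <- prob <- list()
      for (mch in c("left_motor", "right_motor")) {
        bev <- detect_bursts(channel_matrix(ep, mch), ep$fs,
                             band = config$beta_band,
                             t_start = ep$time[1])
        bm <- burst_metrics(bev, config$burst_window)
        fo[[mch]] <- bm$fractional_occupancy
        dur[[mch]] <- bm$mean_duration_s
        amp[[mch]] <- bm$mean_amplitude
        if (config$compute_power)
          prob[[mch]] <- burst_probability_timecourse(bev,
                                                      baseline_correct = TRUE)
      }
      row <- data.frame(participant_id = pid, task = tk,
                        fo = mean(unlist(fo)),
                        duration = mean(unlist(dur), na.rm = TRUE),
                        amplitude = mean(unlist(amp), na.rm = TRUE))
      if (config$compute_power) {
        zs <- zscore_epochs(ep, c("left_motor", "right_motor"))
        ub <- unbaselined_beta_power(zs, c("left_motor", "right_motor"))
        row$ub_power_whole <- ub[["whole"]]
        row$ub_power_pre <- ub[["pre"]]
        key <- tk
        zse <- subtract_evoked(zs, c("left_motor", "right_motor"))
        ptc <- (beta_power_timecourse(zse, "left_motor",
                                      baseline_correct = TRUE) +
                beta_power_timecourse(zse, "right_motor",
                                      baseline_correct = TRUE)) / 2
        power_tc[[key]] <- rbind(power_tc[[key]], ptc)
        prob_tc[[key]] <- rbind(prob_tc[[key]],
                                (prob$left_motor + prob$right_motor) / 2)
      }
      metric_rows[[length(metric_rows) + 1]] <- row
    }
  }
  cmc_tab <- do.call(rbind, cmc_rows)
  metric_tab <- do.call(rbind, metric_rows)
  behav_tab <- do.call(rbind, behav_rows)
  grp <- parts$group[match(unique(parts$participant_id), parts$participant_id)]
  is_als <- parts$group == "ALS"
  # --- group statistics ---------------------------------------------------
  n_corr <- length(task_labels) * 2  # tasks x hemispheres
  cmc_tests <- list()
  for (key in names(spectra)) {
    M <- spectra[[key]]
    if (nrow(M) != nrow(parts)) next
    ct <- cluster_permutation_test(M[!is_als, , drop = FALSE],
                                   M[is_als, , drop = FALSE],
                                   n_perm = config$n_perm,
                                   cluster_alpha = config$cluster_alpha,
                                   seed = config$seed)
    ct$clusters$p_adjusted <- bonferroni_adjust(ct$clusters$p_value, n_corr)
    cmc_tests[[key]] <- ct
  }
  tc_tests <- list()
  if (config$compute_power) {
    stride <- config$timecourse_stride
    for (kind in c("power", "prob")) {
      tcs <- if (kind == "power") power_tc else prob_tc
      for (tk in names(tcs)) {
        M <- tcs[[tk]][, seq(1, ncol(tcs[[tk]]), by = stride), drop = FALSE]
        tc_tests[[paste(kind, tk, sep = ".")]] <-
          cluster_permutation_test(M[!is_als, , drop = FALSE],
                                   M[is_als, , drop = FALSE],
                                   n_perm = config$n_perm,
                                   cluster_alpha = config$cluster_alpha,
                                   seed = config$seed)
      }
    }
  }
  # burst/power metric GLM with confounds, max-t across metrics
  design <- cbind(intercept = 1, group_als = as.numeric(is_als),
                  age = parts$age, sex_m = as.numeric(parts$sex == "M"),
                  missing_mri = as.numeric(parts$missing_mri))
  # confounds with no variance in a small cohort carry no information and
  # would make the design rank deficient
  keep_col <- c(TRUE, TRUE, apply(design[, -(1:2), drop = FALSE], 2,
                                  stats::var) > 0)
  design <- design[, keep_col, drop = FALSE]
  contrast <- as.numeric(colnames(design) == "group_als")
  glm_tests <- list()
  for (tk in task_labels) {
    sub <- metric_tab[metric_tab$task == tk, ]
    sub <- sub[match(parts$participant_id, sub$participant_id), ]
    Y <- as.matrix(sub[, setdiff(names(sub), c("participant_id", "task"))])
    glm_tests[[tk]] <- permutation_glm_maxt(Y, design, contrast,
                                            n_perm = config$n_perm,
                                            seed = config$seed)
  }
  # behaviour: Welch t per task x metric, Bonferroni across the family
  behav_stats <- list()
  bmetrics <- c("median_rt_s", "mean_grip_length_s", "mean_excess_force_N",
                "prop_correct")
  for (tk in task_labels) {
    sub <- behav_tab[behav_tab$task == tk, ]
    sub <- sub[match(parts$participant_id, sub$participant_id), ]
    for (m in bmetrics) {
      wt <- welch_t(sub[[m]][is_als], sub[[m]][!is_als])
      behav_stats[[paste(tk, m, sep = ".")]] <-
        data.frame(task = tk, metric = m, t = wt$t, df = wt$df, p = wt$p)
    }
  }
  behav_stats <- do.call(rbind, behav_stats)
  behav_stats$p_adjusted <- bonferroni_adjust(behav_stats$p,
                                              length(task_labels) * length(bmetrics))
  # clinical correlations in the patient group
  contra <- stats::aggregate(beta_cmc ~ participant_id,
                             cmc_tab[cmc_tab$pairing == "contra", ], mean)
  contra <- contra[match(parts$participant_id, contra$participant_id), ]
  correlations <- list()
  for (cv in c("alsfrs_r", "ecas")) {
    x <- contra$beta_cmc[is_als]; y <- parts[[cv]][is_als]
    correlations[[cv]] <- tryCatch(pearson_corr(x, y),
                                   error = function(e) NULL)
  }
  # signed group mean differences (ALS - HC)
  mean_by <- function(v) mean(v[is_als], na.rm = TRUE) - mean(v[!is_als], na.rm = TRUE)
  met_aligned <- metric_tab[match(parts$participant_id, metric_tab$participant_id), ]
  directions <- c(
    contra_beta_cmc = mean_by(contra$beta_cmc),
    fo = mean_by(met_aligned$fo),
    amplitude = mean_by(met_aligned$amplitude),
    duration = mean_by(met_aligned$duration))
  report <- list(
    participants = parts, cmc = cmc_tab, burst_metrics = metric_tab,
    behaviour = behav_tab, cmc_cluster_tests = cmc_tests,
    timecourse_tests = tc_tests, glm_tests = glm_tests,
    behaviour_stats = behav_stats, correlations = correlations,
    directions = directions,
    manifest = list(seed = config$seed, n_per_group = config$n_per_group,
                    tasks = task_labels, n_perm = config$n_perm,
                    config_hash = config_hash(config)))
  if (!is.null(out_dir)) write_report(report, out_dir)
  invisible(report)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

#' Write the report bundle as CSV files plus a JSON manifest
#'
#' @param report output of [run_analysis()].
#' @param out_dir destination directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$participants, file.path(out_dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cmc, file.path(out_dir, "cmc_spectra.csv"),
                   row.names = FALSE)
  utils::write.csv(report$burst_metrics, file.path(out_dir, "burst_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$behaviour, file.path(out_dir, "behaviour_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$behaviour_stats, file.path(out_dir, "stats_behaviour.csv"),
                   row.names = FALSE)
  glm_tab <- do.call(rbind, lapply(names(report$glm_tests), function(tk)
    cbind(task = tk, as.data.frame(report$glm_tests[[tk]]))))
  utils::write.csv(glm_tab, file.path(out_dir, "stats_glm.csv"),
                   row.names = FALSE)
  cl_tab <- do.call(rbind, lapply(names(report$cmc_cluster_tests), function(k)
    cbind(test = k, report$cmc_cluster_tests[[k]]$clusters)))
  if (!is.null(cl_tab))
    utils::write.csv(cl_tab, file.path(out_dir, "stats_clusters.csv"),
                     row.names = FALSE)
  writeLines(jsonlite::toJSON(c(report$manifest,
                                list(directions = as.list(report$directions))),
                              auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
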