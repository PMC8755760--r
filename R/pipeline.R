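# Orchestration: one call runs simulate -> behaviour -> PLS -> timecourse
# -> MVPA -> BMS on a synthetic study and emits a structured report. All
# randomness flows from the single config seed via named substreams, so a
# fixed seed gives a bit-identical report.

#' Default study configuration
#'
#' Stage toggles and per-stage parameter blocks for [run_pipeline()].
#' Resample counts default to desk-scale values (500 permutations /
#' bootstraps, 50 voxel subsets); the full-scale analysis uses 5000 and up
#' to 2000 respectively.
#'
#' @param seed Master seed.
#' @param n_subjects Number of subjects (default 24).
#' @param out Output directory (NULL = nothing written).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1, n_subjects = 24, out = NULL) {
  structure(list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects),
    out = out,
    stages = list(behavior = TRUE, pls = TRUE, timecourse = TRUE,
                  mvpa = TRUE, bms = TRUE),
    race = race_params(),
    target_corr = -0.5,
    n_perm = 500, n_boot = 500, n_subsets = 50, subset_frac = 0.9,
    bms_samples = 1e5), class = "study_config")
}

validate_config <- function(config) {
  known <- names(study_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  config
}

#' Run the full synthetic-study pipeline
#'
#' Generates a synthetic study (population, stop-signal trials, recall
#' tables, ROI patterns, time-courses, evidence matrices), then runs every
#' enabled analysis stage and collects the results into a report list. If
#' `config$out` is set, stage outputs and a JSON report are written there
#' along with the resolved configuration.
#'
#' @param config A `study_config`.
#' @return A list of class `study_report`.
#' @export
run_pipeline <- function(config = study_config()) {
  config <- validate_config(config)
  seed <- config$seed
  report <- list(config = unclass(config)[setdiff(names(config), "out")],
                 warnings = character(0))
  truth <- make_population(config$n_subjects, config$target_corr,
                           seed = substream_seed(seed, 0L, 100L))
  trials <- simulate_stop_signal(truth, config$race,
                                 seed = substream_seed(seed, 0L, 101L))
  recall <- simulate_tnt_recall(truth,
                                seed = substream_seed(seed, 0L, 102L))
  patterns <- simulate_roi_patterns(n_subjects = config$n_subjects,
                                    truth = truth,
                                    tie_decline_to_sif = TRUE,
                                    seed = substream_seed(seed, 0L, 103L))
  tc <- simulate_roi_timecourse(default_modulation(),
                                n_subjects = config$n_subjects,
                                seed = substream_seed(seed, 0L, 104L))
  space <- build_model_space()
  ev <- simulate_log_evidences(config$n_subjects, space,
                               true_family = "direction:bidirectional",
                               effect_lnB = 3,
                               seed = substream_seed(seed, 0L, 105L))
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write_events_tsv(trials, file.path(config$out, "stop_events.tsv"))
    write_recall_tsv(recall, file.path(config$out, "recall.tsv"))
    write_timecourse_tsv(tc, file.path(config$out, "timecourse.tsv"))
    write_pattern_set(patterns, file.path(config$out, "patterns"))
    write_evidence_matrix(ev, file.path(config$out, "evidence.tsv"))
  }

  behav <- NULL
  if (config$stages$behavior) {
    ss <- stop_summary_by_subject(trials)
    sif <- sif_by_subject(recall)
    behav <- merge(ss, sif, by = "subject")
    sif_test <- group_one_sample_test(behav$sif, tail = "one")
    ssrt_sif <- select_and_correlate(behav$ssrt_ms, behav$sif)
    slope <- go_rt_run_slope(trials)
    report$behavior <- list(per_subject = behav,
                            mean_ssrt_ms = mean(behav$ssrt_ms),
                            mean_sif = mean(behav$sif),
                            sif_test = sif_test,
                            ssrt_sif_correlation = unclass(ssrt_sif),
                            go_rt_slope = slope[c("slope_ms_per_run", "t",
                                                  "p")])
  }
  if (config$stages$pls) {
    # Inhibit > Respond contrast per subject over the prefrontal source
    # ROIs (run-averaged), behaviours = SSRT and SIF
    X <- do.call(cbind, lapply(c("rDLPFC", "rVLPFC"), function(roi) {
      t(vapply(patterns[[roi]], function(p) {
        inh <- apply(p$betas[p$run_mask, c("Stop", "NoThink"), ,
                             drop = FALSE], 3, mean)
        rsp <- apply(p$betas[p$run_mask, c("Go", "Think"), ,
                             drop = FALSE], 3, mean)
        inh - rsp
      }, numeric(dim(patterns[[roi]][[1]]$betas)[3])))
    }))
    Y <- cbind(ssrt = behav$ssrt_ms, sif = behav$sif)
    fit <- fit_behavioural_pls(X, Y)
    perm <- pls_permutation_test(X, Y, n_perm = config$n_perm,
                                 seed = substream_seed(seed, 0L, 106L))
    boot <- pls_bootstrap_saliences(X, Y, n_boot = config$n_boot,
                                    seed = substream_seed(seed, 0L, 107L))
    report$pls <- list(pct_covariance = fit$pct_covariance,
                       perm_p = perm,
                       n_salient_voxels =
                         colSums(abs(boot$bootstrap_ratios) > 1.96),
                       behaviour_corr_profile = fit$behaviour_corr_profile)
  }
  if (config$stages$timecourse) {
    mt <- modulation_table(tc)
    report$timecourse <- interaction_anova(mt)
  }
  if (config$stages$mvpa) {
    rois <- names(patterns)
    acc_cross <- vapply(rois, function(roi) {
      vapply(patterns[[roi]], function(p) {
        cross_task_accuracy(p, n_subsets = config$n_subsets,
                            subset_frac = config$subset_frac,
                            seed = substream_seed(seed, p$subject,
                                                  108L))$accuracy
      }, numeric(1))
    }, numeric(config$n_subjects))
    acc_between <- vapply(rois, function(roi) {
      vapply(patterns[[roi]], function(p) {
        between_task_accuracy(p, n_subsets = config$n_subsets,
                              subset_frac = config$subset_frac,
                              seed = substream_seed(seed, p$subject,
                                                    109L))$accuracy
      }, numeric(1))
    }, numeric(config$n_subjects))
    per_run <- t(vapply(patterns$rDLPFC, per_run_cross_accuracy,
                        numeric(dim(patterns$rDLPFC[[1]]$betas)[1])))
    trend <- linear_trend_and_slope_correlations(
      per_run, list(ssrt = behav$ssrt_ms, sif = behav$sif))
    report$mvpa <- list(
      cross_task = group_decoding_inference(acc_cross),
      between_task = group_decoding_inference(acc_between),
      per_run_group_mean = colMeans(per_run, na.rm = TRUE),
      conflict_reduction = trend[c("trend", "correlations")])
  }
  if (config$stages$bms) {
    fam <- family_bms(ev, space, "direction",
                      n_samples = config$bms_samples,
                      seed = substream_seed(seed, 0L, 110L))
    report$bms <- list(direction_families = list(
      expected_prob = fam$expected_prob,
      exceedance_prob = fam$exceedance_prob))
  }
  class(report) <- "study_report"
  if (!is.null(config$out)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(config$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# flatten a report into JSON-serialisable primitives
report_to_json <- function(report) {
  strip <- function(x) {
    if (is.data.frame(x)) return(as.list(x))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(report))
}
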