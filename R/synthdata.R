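# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of (parameters, seed): the RNG runs in a local scope and a
# master seed spawns per-subject substreams by fixed arithmetic.

#' Generate a subject population with a shared latent inhibition ability
#'
#' Draws per-subject true stop-signal reaction times (SSRT) and
#' suppression-induced forgetting (SIF) scores from a bivariate normal
#' construction so that their population correlation equals `target_corr`.
#' A shared latent ability underlies both: subjects with faster SSRTs show
#' larger SIF when `target_corr` is negative. Means are anchored near the
#' typical group values of 348 ms (SSRT) and 0.05 (SIF).
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param target_corr Target population correlation between true SSRT and
#'   true SIF, in \[-1, 1\].
#' @param seed Integer seed.
#' @param ssrt_mean,ssrt_sd Population mean and SD of true SSRT (ms).
#' @param sif_mean,sif_sd Population mean and SD of true SIF (proportion).
#' @return An object of class `population_truth`: a list with `n_subjects`,
#'   `latent_ability`, `true_mean_ssrt`, `true_sif`, `target_corr`, `seed`.
#' @export
make_population <- function(n_subjects, target_corr = -0.5, seed = 1,
                            ssrt_mean = 348, ssrt_sd = 50,
                            sif_mean = 0.05, sif_sd = 0.09) {
  stopifnot(n_subjects >= 0)
  if (abs(target_corr) > 1) stop("target_corr must lie in [-1, 1]")
  if (n_subjects == 0) {
    out <- list(n_subjects = 0L, latent_ability = numeric(0),
                true_mean_ssrt = numeric(0), true_sif = numeric(0),
                target_corr = target_corr, seed = as.integer(seed))
    class(out) <- "population_truth"
    return(out)
  }
  with_local_seed(seed, {
    z1 <- rnorm(n_subjects)
    z2 <- rnorm(n_subjects)
    ssrt_z <- z1
    sif_z <- target_corr * z1 + sqrt(1 - target_corr^2) * z2
    out <- list(
      n_subjects = as.integer(n_subjects),
      latent_ability = -z1,          # high ability = fast SSRT
      true_mean_ssrt = ssrt_mean + ssrt_sd * ssrt_z,
      true_sif = pmin(1, pmax(-1, sif_mean + sif_sd * sif_z)),
      target_corr = target_corr,
      seed = as.integer(seed))
    class(out) <- "population_truth"
    out
  })
}

#' Race-model parameters for the stop-signal generator
#'
#' Go finishing times are ex-Gaussian (the standard race-model choice);
#' trial-level SSRTs are truncated normal (> 0) around each subject's true
#' mean SSRT. The stop-signal delay staircase moves in `ssd_step` = 50 ms
#' steps starting at 250 or 300 ms.
#'
#' @param go_mu,go_sigma,go_tau Ex-Gaussian parameters of the go finishing
#'   time (ms); defaults give a correct go RT near 600 ms.
#' @param ssrt_sd Trial-level SD of the stop process (ms).
#' @param ssd_start Starting stop-signal delay (250 or 300 ms).
#' @param ssd_step Staircase step (ms), 50 by convention.
#' @param p_trigger_failure Probability the stop process never starts
#'   (default 0; trigger-failure correction is an extension hook).
#' @param p_go_omission,p_go_choice_error Go omission and choice-error rates.
#' @return A list of class `race_params`.
#' @export
race_params <- function(go_mu = 530, go_sigma = 40, go_tau = 70,
                        ssrt_sd = 30, ssd_start = 250, ssd_step = 50,
                        p_trigger_failure = 0,
                        p_go_omission = 0.002, p_go_choice_error = 0.04) {
  stopifnot(go_mu > 0, go_sigma > 0, go_tau > 0, ssrt_sd > 0,
            ssd_step > 0, p_trigger_failure >= 0, p_trigger_failure < 1)
  structure(list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
                 ssrt_sd = ssrt_sd, ssd_start = ssd_start,
                 ssd_step = ssd_step, p_trigger_failure = p_trigger_failure,
                 p_go_omission = p_go_omission,
                 p_go_choice_error = p_go_choice_error),
            class = "race_params")
}

rexgauss <- function(n, mu, sigma, tau) rnorm(n, mu, sigma) + rexp(n, 1 / tau)

rtnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate stop-signal trials under an independent race with a staircase
#'
#' For each subject, generates go and stop trials over 8 runs. On a stop
#' trial the subject responds iff the sampled go finishing time is shorter
#' than SSD + sampled SSRT (or on a trigger failure). The SSD moves up
#' `ssd_step` after a successful stop and down after a failed stop, floored
#' at 0, holding the respond rate near 50%. Go omissions and choice errors
#' are injected at the configured low rates.
#'
#' @param truth A `population_truth` object.
#' @param params A `race_params` object.
#' @param n_trials Total trials per subject (default 384).
#' @param prop_stop Proportion of stop trials in (0, 1).
#' @param seed Integer seed.
#' @param n_runs Number of runs (default 8).
#' @return A data.frame (the trial table) with columns `subject`, `run`,
#'   `trial_index`, `trial_type`, `ssd_ms`, `rt_ms`, `response`, `correct`.
#' @export
simulate_stop_signal <- function(truth, params = race_params(),
                                 n_trials = 384, prop_stop = 0.32,
                                 seed = 1, n_runs = 8) {
  stopifnot(inherits(truth, "population_truth"), n_trials > 0,
            prop_stop > 0, prop_stop < 1)
  per_run <- n_trials %/% n_runs
  out <- vector("list", truth$n_subjects)
  for (i in seq_len(truth$n_subjects)) {
    out[[i]] <- with_local_seed(substream_seed(seed, i, 1L), {
      ssd <- if (is.na(params$ssd_start)) sample(c(250, 300), 1) else
        params$ssd_start
      n_stop_total <- round(n_trials * prop_stop)
      rows <- vector("list", n_runs)
      idx <- 0L
      for (r in seq_len(n_runs)) {
        n_stop_run <- round(n_stop_total / n_runs)
        is_stop <- rep(FALSE, per_run)
        is_stop[sample(per_run, n_stop_run)] <- TRUE
        run_rows <- data.frame(
          subject = i, run = r, trial_index = idx + seq_len(per_run),
          trial_type = ifelse(is_stop, "stop", "go"),
          ssd_ms = NA_real_, rt_ms = NA_real_,
          response = NA_character_, correct = NA,
          stringsAsFactors = FALSE)
        for (k in seq_len(per_run)) {
          go_t <- rexgauss(1, params$go_mu, params$go_sigma, params$go_tau)
          if (is_stop[k]) {
            run_rows$ssd_ms[k] <- ssd
            ssrt_t <- rtnorm_pos(1, truth$true_mean_ssrt[i], params$ssrt_sd)
            trig_fail <- runif(1) < params$p_trigger_failure
            respond <- trig_fail || (go_t < ssd + ssrt_t)
            if (respond) {
              run_rows$rt_ms[k] <- go_t
              run_rows$response[k] <- "button"
              run_rows$correct[k] <- FALSE
              ssd <- max(0, ssd - params$ssd_step)
            } else {
              run_rows$correct[k] <- TRUE
              ssd <- ssd + params$ssd_step
            }
          } else {
            if (runif(1) < params$p_go_omission) {
              run_rows$correct[k] <- FALSE       # omission: no response
            } else {
              run_rows$rt_ms[k] <- go_t
              run_rows$response[k] <- "button"
              run_rows$correct[k] <- runif(1) >= params$p_go_choice_error
            }
          }
        }
        idx <- idx + per_run
        rows[[r]] <- run_rows
      }
      do.call(rbind, rows)
    })
  }
  do.call(rbind, out)
}

#' Simulate Think/No-Think final recall with planted forgetting
#'
#' Each subject receives `n_pairs_per_condition` word pairs in each of the
#' Think, NoThink and Baseline conditions. Learning status is
#' Bernoulli(`learning_rate`); final recall is Bernoulli(`baseline_recall`)
#' for Baseline and Think pairs and Bernoulli(`baseline_recall` - true SIF)
#' for NoThink pairs, drawn independently for the same-probe and
#' independent-probe tests.
#'
#' @param truth A `population_truth` object.
#' @param n_pairs_per_condition Pairs per condition (default 20).
#' @param learning_rate Probability a pair is learned at criterion.
#' @param baseline_recall Baseline final recall probability.
#' @param seed Integer seed.
#' @param n_fillers Number of filler pairs per subject (never scored).
#' @return A data.frame with columns `subject`, `pair_id`, `condition`,
#'   `learned`, `sp_correct`, `ip_correct`.
#' @export
simulate_tnt_recall <- function(truth, n_pairs_per_condition = 20,
                                learning_rate = 0.71, baseline_recall = 0.77,
                                seed = 1, n_fillers = 0) {
  stopifnot(inherits(truth, "population_truth"),
            learning_rate >= 0, learning_rate <= 1,
            baseline_recall >= 0, baseline_recall <= 1)
  if (truth$n_subjects > 0 &&
      baseline_recall - max(truth$true_sif) < 0) {
    stop("baseline_recall minus the largest true SIF is negative")
  }
  out <- vector("list", truth$n_subjects)
  conds <- c("Think", "NoThink", "Baseline")
  for (i in seq_len(truth$n_subjects)) {
    out[[i]] <- with_local_seed(substream_seed(seed, i, 2L), {
      cond <- c(rep(conds, each = n_pairs_per_condition),
                rep("filler", n_fillers))
      n <- length(cond)
      p <- ifelse(cond == "NoThink",
                  pmin(1, pmax(0, baseline_recall - truth$true_sif[i])),
                  baseline_recall)
      data.frame(
        subject = i, pair_id = seq_len(n), condition = cond,
        learned = runif(n) < learning_rate,
        sp_correct = runif(n) < p,
        ip_correct = runif(n) < p,
        stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, out)
}

#' ROI design for the pattern generator
#'
#' Encodes the signal structure of an ROI: a domain-general inhibition
#' component of amplitude `g_shared` along a voxel direction shared by the
#' two stopping tasks, a domain-specific task component of amplitude
#' `s_specific` along a per-task direction, and white voxel noise. The
#' shared component of the NoThink condition decays across runs by
#' `decline_rate` per run, emulating a conflict-reduction benefit.
#'
#' @param name ROI label.
#' @param n_voxels Number of voxels (>= 2).
#' @param g_shared Domain-general amplitude (arbitrary units, >= 0).
#' @param s_specific Domain-specific amplitude (>= 0).
#' @param decline_rate Per-run multiplicative decay of the NoThink shared
#'   component, in \[0, 1\] (1 = no decline).
#' @param noise_sd Voxel noise SD.
#' @return A list of class `roi_design`.
#' @export
roi_design <- function(name, n_voxels = 40, g_shared = 1, s_specific = 1,
                       decline_rate = 1, noise_sd = 1) {
  stopifnot(g_shared >= 0, s_specific >= 0,
            decline_rate >= 0, decline_rate <= 1, noise_sd >= 0)
  if (n_voxels < 2) stop("n_voxels must be at least 2")
  structure(list(name = name, n_voxels = as.integer(n_voxels),
                 g_shared = g_shared, s_specific = s_specific,
                 decline_rate = decline_rate, noise_sd = noise_sd),
            class = "roi_design")
}

#' Default four-ROI design set
#'
#' Prefrontal source ROIs (rDLPFC, rVLPFC) carry both domain-general and
#' domain-specific components, with a run-wise decline of the NoThink shared
#' component; target ROIs (hippocampus, M1) carry only domain-specific
#' signal, so cross-task decoding is at chance there.
#'
#' @return A named list of `roi_design` objects.
#' @export
default_roi_designs <- function() {
  list(
    rDLPFC = roi_design("rDLPFC", n_voxels = 40, g_shared = 2.0,
                        s_specific = 1.6, decline_rate = 0.82),
    rVLPFC = roi_design("rVLPFC", n_voxels = 40, g_shared = 2.1,
                        s_specific = 2.2, decline_rate = 0.88),
    hippocampus = roi_design("hippocampus", n_voxels = 40, g_shared = 0,
                             s_specific = 1.8, decline_rate = 1),
    M1 = roi_design("M1", n_voxels = 40, g_shared = 0,
                    s_specific = 2.0, decline_rate = 1)
  )
}

roi_conditions <- c("Stop", "Go", "NoThink", "Think")

#' Simulate run-wise ROI activity patterns
#'
#' For each ROI and subject, generates a run x condition x voxel beta array.
#' The inhibition conditions (Stop, NoThink) load on a unit voxel direction
#' `u` shared across tasks within a subject (what makes cross-task transfer
#' possible); all conditions of a task load on a task-specific direction.
#' The NoThink shared loading decays by `decline_rate` per run. Optionally
#' the per-subject decline is tied to true SIF so that better forgetters
#' show steeper decline.
#'
#' @param designs Named list of `roi_design` objects.
#' @param n_subjects Number of subjects.
#' @param n_runs Number of runs (default 8).
#' @param seed Integer seed.
#' @param truth Optional `population_truth`; required if
#'   `tie_decline_to_sif` is TRUE.
#' @param tie_decline_to_sif If TRUE, each subject's NoThink decline rate is
#'   `decline_rate - decline_sif_slope * (true_sif - 0.05)`, clamped to
#'   \[0, 1\].
#' @param decline_sif_slope Slope tying decline to SIF (default 1.5).
#' @param run_mask Optional logical matrix (subjects x runs) of available
#'   runs; defaults to all available.
#' @return A named list (per ROI) of per-subject lists, each with `betas`
#'   (array runs x 4 conditions x voxels) and `run_mask`.
#' @export
simulate_roi_patterns <- function(designs = default_roi_designs(),
                                  n_subjects = 24, n_runs = 8, seed = 1,
                                  truth = NULL, tie_decline_to_sif = FALSE,
                                  decline_sif_slope = 1.5, run_mask = NULL) {
  if (tie_decline_to_sif && is.null(truth)) {
    stop("tie_decline_to_sif requires truth")
  }
  if (is.null(run_mask)) {
    run_mask <- matrix(TRUE, n_subjects, n_runs)
  }
  out <- lapply(seq_along(designs), function(d) {
    des <- designs[[d]]
    subj <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      subj[[i]] <- with_local_seed(substream_seed(seed, i, 10L + d), {
        V <- des$n_voxels
        unit <- function(v) v / sqrt(sum(v^2))
        u <- unit(rnorm(V))
        v_stop <- unit(rnorm(V))
        v_tnt <- unit(rnorm(V))
        dec <- des$decline_rate
        if (tie_decline_to_sif) {
          dec <- min(1, max(0, dec - decline_sif_slope *
                              (truth$true_sif[i] - 0.05)))
        }
        betas <- array(rnorm(n_runs * 4 * V, sd = des$noise_sd),
                       dim = c(n_runs, 4, V),
                       dimnames = list(NULL, roi_conditions, NULL))
        for (r in seq_len(n_runs)) {
          betas[r, "Stop", ] <- betas[r, "Stop", ] +
            des$g_shared * u + des$s_specific * v_stop
          betas[r, "Go", ] <- betas[r, "Go", ] + des$s_specific * v_stop
          betas[r, "NoThink", ] <- betas[r, "NoThink", ] +
            des$g_shared * dec^(r - 1) * u + des$s_specific * v_tnt
          betas[r, "Think", ] <- betas[r, "Think", ] + des$s_specific * v_tnt
        }
        list(betas = betas, run_mask = run_mask[i, ], roi = des$name,
             subject = i)
      })
    }
    subj
  })
  names(out) <- names(designs)
  out
}

#' Simulate ROI peristimulus time-courses
#'
#' Each subject x ROI x condition series is the canonical double-gamma HRF
#' sampled on the peristimulus grid 0 to 12 s at `tr_s`, scaled by the
#' signed modulation amplitude, plus white noise. The onset value is ~0 by
#' construction of the HRF.
#'
#' @param modulation Numeric matrix (ROIs x conditions, dimnames required)
#'   of signed amplitudes.
#' @param n_subjects Number of subjects.
#' @param tr_s Sampling interval in seconds (default 2).
#' @param seed Integer seed.
#' @param noise_sd Sample noise SD (default 0.15).
#' @param subject_sd Between-subject amplitude SD (default 0.2).
#' @return A data.frame with columns `subject`, `roi`, `condition`,
#'   `time_s`, `bold`.
#' @export
simulate_roi_timecourse <- function(modulation, n_subjects = 24, tr_s = 2,
                                    seed = 1, noise_sd = 0.15,
                                    subject_sd = 0.2) {
  stopifnot(is.matrix(modulation), !is.null(rownames(modulation)),
            !is.null(colnames(modulation)))
  times <- seq(0, 12, by = tr_s)
  h <- hrf_canonical(times)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    out[[i]] <- with_local_seed(substream_seed(seed, i, 3L), {
      rows <- expand.grid(roi = rownames(modulation),
                          condition = colnames(modulation),
                          stringsAsFactors = FALSE)
      do.call(rbind, lapply(seq_len(nrow(rows)), function(k) {
        amp <- modulation[rows$roi[k], rows$condition[k]] +
          rnorm(1, 0, subject_sd)
        data.frame(subject = i, roi = rows$roi[k],
                   condition = rows$condition[k], time_s = times,
                   bold = amp * h + rnorm(length(times), 0, noise_sd),
                   stringsAsFactors = FALSE)
      }))
    })
  }
  do.call(rbind, out)
}

#' Default crossover modulation matrix for the time-course generator
#'
#' M1 is down-regulated by action stopping and up-regulated by going;
#' hippocampus is down-regulated by thought suppression and up-regulated by
#' retrieval, planting the region x modality crossover interaction.
#'
#' @return A 2 x 4 numeric matrix (rows M1, hippocampus).
#' @export
default_modulation <- function() {
  m <- rbind(M1 = c(Stop = -0.5, Go = 0.5, NoThink = -0.1, Think = 0.1),
             hippocampus = c(Stop = -0.1, Go = 0.1,
                             NoThink = -0.4, Think = 0.4))
  m
}

#' Simulate subjects x models log-evidence matrices
#'
#' Each subject's log evidences are i.i.d. Gaussian noise, with
#' `effect_lnB` added to every model inside the designated true family.
#'
#' @param n_subjects Number of subjects.
#' @param space A `model_space` from [build_model_space()].
#' @param true_family Family label as "partition:level", e.g.
#'   "targets:preferred"; use NULL for a pure-noise matrix.
#' @param effect_lnB Log-evidence advantage (nats, >= 0).
#' @param seed Integer seed.
#' @param noise_sd SD of the evidence noise (default 1).
#' @return A list of class `evidence_matrix` with `log_evidence`
#'   (subjects x models) and `model_ids`.
#' @export
simulate_log_evidences <- function(n_subjects, space, true_family = NULL,
                                   effect_lnB = 0, seed = 1, noise_sd = 1) {
  stopifnot(effect_lnB >= 0)
  m <- length(space$models)
  ids <- vapply(space$models, function(x) x$id, integer(1))
  fam_cols <- integer(0)
  if (!is.null(true_family)) {
    parts <- strsplit(true_family, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.null(space$family_partitions[[parts[1]]]) ||
        is.null(space$family_partitions[[parts[1]]][[parts[2]]])) {
      stop("unknown family label: ", true_family)
    }
    fam_ids <- space$family_partitions[[parts[1]]][[parts[2]]]
    fam_cols <- which(ids %in% fam_ids)
  }
  ev <- with_local_seed(seed, {
    e <- matrix(rnorm(n_subjects * m, sd = noise_sd), n_subjects, m)
    if (length(fam_cols)) e[, fam_cols] <- e[, fam_cols] + effect_lnB
    e
  })
  structure(list(log_evidence = ev, model_ids = ids),
            class = "evidence_matrix")
}

#' Boxcar condition inputs for the network simulator
#'
#' Builds alternating 30 s Stop-signal and Think/No-Think task blocks at
#' repetition time `tr_s`, with 4 s rests between blocks. Returns modulatory
#' condition regressors (Stop, NoThink: on during the respective task
#' blocks) and driving task inputs delivered to both prefrontal nodes.
#'
#' @param n_blocks Total task blocks (default 16, alternating).
#' @param tr_s Repetition time in seconds (default 2).
#' @return A list with `u_mod` (T x 2 matrix, columns Stop and NoThink) and
#'   `u_drive` (T x 2 matrix, columns stop-task and tnt-task).
#' @export
default_network_inputs <- function(n_blocks = 16, tr_s = 2) {
  block_scans <- round(30 / tr_s)
  rest_scans <- round(4 / tr_s)
  u_stop <- u_nt <- numeric(0)
  for (b in seq_len(n_blocks)) {
    on_stop <- rep(as.numeric(b %% 2 == 1), block_scans)
    u_stop <- c(u_stop, on_stop, rep(0, rest_scans))
    u_nt <- c(u_nt, 1 - on_stop, rep(0, rest_scans))
  }
  u_mod <- cbind(Stop = u_stop, NoThink = u_nt)
  u_drive <- u_mod
  colnames(u_drive) <- c("stop_task", "tnt_task")
  list(u_mod = u_mod, u_drive = u_drive, tr_s = tr_s)
}

#' Simulate four-node BOLD series from a bilinear network model
#'
#' Discrete-time bilinear dynamics
#' `x(t+1) = A x(t) + sum_j u_j(t) B_j x(t) + C u(t)` over the nodes
#' rDLPFC, rVLPFC, hippocampus, M1, with the modulatory matrices `B_j`
#' constructed from a model's condition-specific edge sets. States are
#' convolved with the canonical HRF and white noise is added.
#'
#' @param model A `ModelSpec` from [build_model_space()].
#' @param coupling List with `a_self` (self coupling), `a_between`
#'   (intrinsic between-node coupling), `b_mod` (modulatory increment,
#'   negative = inhibitory), `c_drive` (driving strength).
#' @param inputs As returned by [default_network_inputs()].
#' @param tr_s Repetition time (seconds).
#' @param seed Integer seed.
#' @param noise_sd Observation noise SD (default 0.05).
#' @return A T x 4 matrix of BOLD series (columns named by node).
#' @export
simulate_network_timeseries <- function(model,
                                        coupling = list(a_self = 0.5,
                                                        a_between = 0.15,
                                                        b_mod = -0.45,
                                                        c_drive = 0.5),
                                        inputs = default_network_inputs(),
                                        tr_s = 2, seed = 1,
                                        noise_sd = 0.05) {
  nodes <- dcm_nodes()
  A <- intrinsic_matrix(coupling$a_self, coupling$a_between)
  if (max(abs(eigen(A, only.values = TRUE)$values)) >= 1) {
    stop("unstable coupling: spectral radius of A must be < 1")
  }
  Bs <- lapply(c("Stop", "NoThink"), function(cond) {
    B <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
    ed <- model$modulatory_edges[[cond]]
    if (length(ed)) {
      for (e in ed) B[e[2], e[1]] <- coupling$b_mod  # row = to, col = from
    }
    B
  })
  Tn <- nrow(inputs$u_mod)
  C <- matrix(0, 4, 2, dimnames = list(nodes, colnames(inputs$u_drive)))
  C["rDLPFC", ] <- coupling$c_drive
  C["rVLPFC", ] <- coupling$c_drive
  x <- matrix(0, Tn, 4, dimnames = list(NULL, nodes))
  for (t in seq_len(Tn - 1)) {
    M <- A + inputs$u_mod[t, 1] * Bs[[1]] + inputs$u_mod[t, 2] * Bs[[2]]
    x[t + 1, ] <- M %*% x[t, ] + C %*% inputs$u_drive[t, ]
  }
  h <- hrf_canonical(seq(0, 24, by = tr_s))
  y <- apply(x, 2, function(col) {
    convolve(col, rev(h), type = "open")[seq_len(Tn)]
  })
  with_local_seed(seed, y + matrix(rnorm(Tn * 4, sd = noise_sd), Tn, 4))
}
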