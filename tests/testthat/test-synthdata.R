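test_that("population generator hits the target SSRT-SIF correlation", {
  pop <- make_population(0, -0.5, seed = 1)
  expect_equal(pop$n_subjects, 0L)
  expect_length(pop$true_mean_ssrt, 0)

  big <- make_population(10000, -0.5, seed = 1)
  expect_equal(cor(big$true_mean_ssrt, big$true_sif), -0.5,
               tolerance = 0.02)
  expect_true(all(abs(big$true_sif) <= 1))

  # small-sample correlations are unbiased around the target
  rs <- vapply(1:60, function(k) {
    p <- make_population(24, -0.5, seed = k)
    cor(p$true_mean_ssrt, p$true_sif)
  }, numeric(1))
  expect_equal(mean(rs), -0.5, tolerance = 0.06)

  expect_error(make_population(5, -1.5), "target_corr")
})

test_that("generators are pure functions of parameters and seed", {
  pop <- make_population(4, -0.5, seed = 9)
  expect_identical(make_population(4, -0.5, seed = 9), pop)
  expect_identical(simulate_stop_signal(pop, seed = 2),
                   simulate_stop_signal(pop, seed = 2))
  expect_identical(simulate_tnt_recall(pop, seed = 2),
                   simulate_tnt_recall(pop, seed = 2))
  sp <- build_model_space()
  m <- sp$models[[13]]
  expect_identical(simulate_network_timeseries(m, seed = 3),
                   simulate_network_timeseries(m, seed = 3))
  # the generator must not disturb the caller's RNG stream
  set.seed(42)
  before <- .Random.seed
  invisible(simulate_stop_signal(pop, seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("staircase keeps the stop respond rate near 50%", {
  pop <- make_population(8, -0.5, seed = 7)
  tr <- simulate_stop_signal(pop, n_trials = 384, prop_stop = 0.32,
                             seed = 7)
  ss <- stop_summary_by_subject(tr)
  expect_true(all(abs(ss$p_respond_stop - 0.5) <= 0.05))
  # SSDs are non-negative multiples of the 50 ms step
  ssd <- tr$ssd_ms[tr$trial_type == "stop"]
  expect_true(all(ssd >= 0))
  expect_true(all(ssd %% 50 == 0))
  # respond rate stays within the observed empirical range across seeds
  for (s in 1:5) {
    t2 <- simulate_stop_signal(make_population(4, -0.5, seed = s),
                               seed = s)
    p <- stop_summary_by_subject(t2)$p_respond_stop
    expect_true(all(p >= 0.36 & p <= 0.69))
  }
})

test_that("integration-method SSRT recovers the planted stopping speed", {
  est <- vapply(1:40, function(s) {
    pop <- make_population(2, 0, seed = s, ssrt_mean = 280, ssrt_sd = 0)
    mean(stop_summary_by_subject(
      simulate_stop_signal(pop, seed = s))$ssrt_ms)
  }, numeric(1))
  expect_equal(mean(est), 280, tolerance = 15)
})

test_that("recall generator plants the forgetting effect", {
  pop0 <- make_population(24, 0, seed = 3, sif_mean = 0, sif_sd = 0)
  rec0 <- simulate_tnt_recall(pop0, seed = 3)
  sifs <- vapply(1:30, function(s) {
    mean(sif_by_subject(simulate_tnt_recall(pop0, seed = s))$sif)
  }, numeric(1))
  expect_equal(mean(sifs), 0, tolerance = 0.01)

  # learning_rate = 1: conditionalization removes nothing
  rec_all <- simulate_tnt_recall(pop0, learning_rate = 1, seed = 5)
  expect_true(all(rec_all$learned))

  pop_hi <- make_population(4, 0, seed = 1, sif_mean = 0.9, sif_sd = 0)
  expect_error(simulate_tnt_recall(pop_hi, baseline_recall = 0.5),
               "negative")
})

test_that("roi pattern generator respects its design contract", {
  expect_error(roi_design("x", n_voxels = 1), "at least 2")
  des <- list(a = roi_design("a", n_voxels = 12, g_shared = 1,
                             s_specific = 1))
  pats <- simulate_roi_patterns(des, n_subjects = 3, seed = 2)
  expect_equal(dim(pats$a[[1]]$betas), c(8, 4, 12))
  expect_identical(simulate_roi_patterns(des, n_subjects = 3, seed = 2),
                   pats)
})

test_that("time-course generator plants signed HRF modulations", {
  mod0 <- matrix(0, 1, 4,
                 dimnames = list("M1", c("Stop", "Go", "NoThink", "Think")))
  tc0 <- simulate_roi_timecourse(mod0, n_subjects = 20, seed = 1,
                                 subject_sd = 0)
  mt0 <- modulation_table(tc0)
  expect_equal(mean(mt0$index), 0, tolerance = 0.05)

  mod <- matrix(c(-1, 0, 0, 0), 1, 4,
                dimnames = list("M1", c("Stop", "Go", "NoThink", "Think")))
  signs <- vapply(1:40, function(s) {
    tc <- simulate_roi_timecourse(mod, n_subjects = 8, seed = s,
                                  subject_sd = 0.1)
    d <- tc[tc$condition == "Stop", ]
    mean(vapply(split(d, d$subject), function(x) {
      modulation_index(x$time_s, x$bold)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(signs < 0), 0.95)
})

test_that("evidence generator plants a winning family", {
  sp <- build_model_space()
  expect_error(simulate_log_evidences(5, sp, "targets:bogus", 1),
               "unknown family")
  ev1 <- simulate_log_evidences(1, sp, seed = 4)
  expect_equal(dim(ev1$log_evidence), c(1, 73))
  expect_s3_class(rfx_bms(ev1, n_samples = 5000, seed = 1), "bms_result")

  # planted advantage wins the family comparison on most seeds
  wins <- vapply(1:10, function(s) {
    ev <- simulate_log_evidences(24, sp, "targets:preferred",
                                 effect_lnB = 3, seed = s)
    fb <- family_bms(ev, sp, "targets", n_samples = 2e4, seed = s)
    fb$exceedance_prob[["preferred"]] > 0.9
  }, logical(1))
  expect_gte(mean(wins), 0.9)

  # no advantage: roughly uniform family mass
  ev0 <- simulate_log_evidences(24, sp, "targets:preferred",
                                effect_lnB = 0, seed = 11, noise_sd = 0.1)
  fb0 <- family_bms(ev0, sp, "targets", n_samples = 2e4, seed = 11)
  expect_true(all(fb0$exceedance_prob > 0.05))
})

test_that("network simulator obeys stability and isolation contracts", {
  sp <- build_model_space()
  m12 <- sp$models[[13]]
  expect_error(
    simulate_network_timeseries(m12, coupling = list(a_self = 1.2,
                                                     a_between = 0.3,
                                                     b_mod = 0,
                                                     c_drive = 0.5)),
    "unstable")
  # zero coupling, driving only into the prefrontal nodes: target nodes
  # carry nothing but observation noise
  null_model <- sp$models[[1]]
  y <- simulate_network_timeseries(
    null_model, coupling = list(a_self = 0, a_between = 0, b_mod = 0,
                                c_drive = 0.5), seed = 2, noise_sd = 0.05)
  expect_lt(sd(y[, "hippocampus"]), 0.07)
  expect_lt(sd(y[, "M1"]), 0.07)
  expect_gt(sd(y[, "rDLPFC"]), 0.2)
})
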