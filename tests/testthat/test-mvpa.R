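sim_one_pattern <- function(g = 0, s = 1.5, seed = 1, V = 16,
                            decline = 1, noise = 1) {
  des <- list(roi = roi_design("roi", n_voxels = V, g_shared = g,
                               s_specific = s, decline_rate = decline,
                               noise_sd = noise))
  simulate_roi_patterns(des, n_subjects = 1, seed = seed)$roi[[1]]
}

test_that("prewhitening matches its closed-form special cases", {
  with_local_seed(2, X <- matrix(rnorm(40), 8, 5))
  expect_equal(prewhiten(X, diag(5), shrinkage = 0), X,
               ignore_attr = TRUE)
  expect_equal(prewhiten(X, diag(4, 5), shrinkage = 0), X / 2,
               ignore_attr = TRUE)
  # whitening a known SPD covariance moves the residual covariance
  # toward the identity
  with_local_seed(3, {
    A <- matrix(rnorm(25), 5, 5)
    S <- crossprod(A) + diag(5)
    R <- MASS::mvrnorm(400, rep(0, 5), S)
  })
  W <- prewhiten(R, S, shrinkage = 0)
  d_before <- norm(cov(R) - diag(5), "F")
  d_after <- norm(cov(W) - diag(5), "F")
  expect_lt(d_after, d_before)
  expect_error(prewhiten(X, -diag(5), shrinkage = 0), "positive definite")
})

test_that("cross-task z-scoring and subset bookkeeping hold exactly", {
  p <- sim_one_pattern(g = 1, seed = 4)
  st <- stopsuite:::task_stack(p, c("Stop", "Go"))
  Z <- stopsuite:::zscore_cols(st$X)
  expect_equal(colMeans(Z), rep(0, ncol(Z)), tolerance = 1e-12)
  expect_equal(apply(Z, 2, sd), rep(1, ncol(Z)), tolerance = 1e-12)
  # subset_frac = 1 with a single subset equals the full-ROI classifier
  a1 <- cross_task_accuracy(p, n_subsets = 1, subset_frac = 1, seed = 1)
  a2 <- cross_task_accuracy(p, n_subsets = 5, subset_frac = 1, seed = 2)
  expect_equal(a1$accuracy, a2$accuracy)
  expect_equal(a2$n_subsets_used, 1)     # only one unique subset exists
})

test_that("separable patterns decode perfectly, null patterns at chance", {
  p <- noise_free_pattern()
  expect_equal(cross_task_accuracy(p, n_subsets = 1, subset_frac = 1,
                                   seed = 1)$accuracy, 1)
  accs <- vapply(1:30, function(s) {
    cross_task_accuracy(sim_one_pattern(g = 0, seed = s), n_subsets = 10,
                        seed = s)$accuracy
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.04)
  bt <- vapply(1:30, function(s) {
    between_task_accuracy(sim_one_pattern(g = 0, s = 0, seed = s),
                          n_subsets = 10, seed = s)$accuracy
  }, numeric(1))
  expect_equal(mean(bt), 0.5, tolerance = 0.05)
})

test_that("between-task folds match a closed-form LDA oracle exactly", {
  # fixed 4-voxel, 4-run fixture
  base <- c(0.3, -0.2, 0.1, 0.4)
  betas <- array(0, c(4, 4, 4),
                 dimnames = list(NULL, c("Stop", "Go", "NoThink", "Think"),
                                 NULL))
  vals <- matrix(c(
    1.2, 0.1, -0.4, 0.9,
    0.8, -0.3, 0.2, 1.1,
    1.0, 0.4, -0.1, 0.7,
    1.4, -0.2, 0.3, 0.8), 4, 4, byrow = TRUE)
  for (r in 1:4) {
    betas[r, "NoThink", ] <- vals[r, ] + base
    betas[r, "Stop", ] <- rev(vals[r, ])
    betas[r, "Go", ] <- base
    betas[r, "Think", ] <- base / 2
  }
  p <- list(betas = betas, run_mask = rep(TRUE, 4), subject = 1,
            roi = "toy")
  got <- between_task_accuracy(p, n_subsets = 1, subset_frac = 1,
                               seed = 1)$accuracy
  # oracle: row z-scoring + leave-one-run-out shrinkage LDA, written
  # independently with explicit loops
  X <- do.call(rbind, lapply(1:4, function(r) {
    rbind(betas[r, "NoThink", ], betas[r, "Stop", ])
  }))
  X <- t(apply(X, 1, function(v) (v - mean(v)) / sd(v)))
  y <- rep(c("nothink", "stop"), 4)
  fold <- rep(1:4, each = 2)
  acc <- mean(vapply(1:4, function(r) {
    pred <- oracle_lda_predict(X[fold != r, ], y[fold != r],
                               X[fold == r, , drop = FALSE])
    mean(pred == y[fold == r])
  }, numeric(1)))
  expect_identical(got, acc)
})

test_that("between-task accuracy ignores univariate level differences", {
  p <- sim_one_pattern(g = 0, s = 1.5, seed = 6)
  p2 <- p
  p2$betas[, "NoThink", ] <- p2$betas[, "NoThink", ] + 50
  a1 <- between_task_accuracy(p, n_subsets = 3, seed = 3)$accuracy
  a2 <- between_task_accuracy(p2, n_subsets = 3, seed = 3)$accuracy
  expect_equal(a1, a2)
})

test_that("per-run curves honour the run mask and recover decline", {
  p <- sim_one_pattern(g = 2, seed = 7, decline = 1)
  p$run_mask[8] <- FALSE
  acc <- per_run_cross_accuracy(p)
  expect_length(acc, 8)
  expect_true(is.na(acc[8]))
  expect_true(all(!is.na(acc[1:7])))

  # planted decline: negative mean slope across seeds
  slopes <- vapply(1:15, function(s) {
    pr <- per_run_cross_accuracy(sim_one_pattern(g = 2.5, seed = s,
                                                 decline = 0.75,
                                                 noise = 0.7))
    w <- 1:8 - mean(1:8)
    sum(w * pr) / sum(w^2)
  }, numeric(1))
  expect_lt(mean(slopes), 0)
  # no planted decline: slopes near zero on average
  slopes0 <- vapply(1:15, function(s) {
    pr <- per_run_cross_accuracy(sim_one_pattern(g = 2.5, seed = 100 + s,
                                                 decline = 1,
                                                 noise = 0.7))
    w <- 1:8 - mean(1:8)
    sum(w * pr) / sum(w^2)
  }, numeric(1))
  expect_lt(abs(mean(slopes0)), abs(mean(slopes)))
})

test_that("slopes and the linear contrast match closed-form values", {
  per_run <- rbind(c(0.9, 0.8, 0.7, 0.6),
                   c(0.6, 0.6, 0.6, 0.6),
                   c(0.5, 0.6, 0.7, 0.8))
  # pad so >= 10 subjects remain even after one exclusion
  with_local_seed(5, {
    per_run <- rbind(per_run,
                     matrix(runif(8 * 4, 0.4, 0.8), 8, 4))
    behaviour <- list(ssrt = rnorm(11, 348, 50),
                      sif = rnorm(11, 0.05, 0.09))
  })
  res <- linear_trend_and_slope_correlations(per_run, behaviour)
  expect_equal(res$slopes[1], -0.1, tolerance = 1e-12)
  expect_equal(res$slopes[2], 0, tolerance = 1e-12)
  expect_equal(res$slopes[3], 0.1, tolerance = 1e-12)
  expect_s3_class(res$correlations$sif, "correlation_result")
  # subjects with fewer than 3 runs are excluded with a warning
  per_run[4, 2:4] <- NA
  expect_warning(linear_trend_and_slope_correlations(per_run, behaviour),
                 "excluded")
})

test_that("group inference applies Bonferroni and fills Bayes factors", {
  acc <- cbind(roiA = rep(0.5, 12), roiB = seq(0.55, 0.77, length.out = 12))
  res <- group_decoding_inference(acc)
  a <- res[res$roi == "roiA", ]
  expect_equal(a$t, 0)
  expect_equal(a$p_adj, 1)
  expect_false(is.na(a$b01))          # chance-level ROI gets a BF
  b <- res[res$roi == "roiB", ]
  expect_true(is.na(b$b01))
  expect_equal(b$p_adj, pmin(1, b$p * 2))
  expect_equal(b$d, b$t / sqrt(12))
})
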