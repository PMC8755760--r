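# Run-wise LDA pattern classification: cross-task (domain-general) and
# between-task (domain-specific) decoding, random 90% voxel subsets,
# per-run conflict-reduction curves, and group inference.

#' Noise-normalise (pre-whiten) activity patterns
#'
#' Multiplies patterns by the inverse square root of a shrinkage-regularised
#' residual covariance. With an identity covariance the patterns are
#' unchanged.
#'
#' @param patterns Patterns x voxels matrix of raw betas.
#' @param residual_cov Voxel covariance estimate (voxels x voxels).
#' @param shrinkage Shrinkage weight toward the scaled identity, in
#'   \[0, 1\] (default 0.1).
#' @return The whitened patterns matrix.
#' @export
prewhiten <- function(patterns, residual_cov, shrinkage = 0.1) {
  patterns <- as.matrix(patterns)
  S <- as.matrix(residual_cov)
  nu <- mean(diag(S))
  Ss <- (1 - shrinkage) * S + shrinkage * nu * diag(nrow(S))
  e <- eigen(Ss, symmetric = TRUE)
  if (any(e$values <= 0)) stop("covariance not positive definite after ",
                               "shrinkage")
  W <- e$vectors %*% diag(1 / sqrt(e$values), nrow(S)) %*% t(e$vectors)
  patterns %*% W
}

# Two-class LDA with a Ledoit-Wolf-style shrinkage covariance (voxels can
# outnumber the 16 training patterns). Returns a linear readout.
lda_train <- function(X, y) {
  X <- as.matrix(X)
  cls <- sort(unique(y))
  stopifnot(length(cls) == 2)
  m0 <- colMeans(X[y == cls[1], , drop = FALSE])
  m1 <- colMeans(X[y == cls[2], , drop = FALSE])
  Z <- X
  Z[y == cls[1], ] <- sweep(X[y == cls[1], , drop = FALSE], 2, m0)
  Z[y == cls[2], ] <- sweep(X[y == cls[2], , drop = FALSE], 2, m1)
  n <- nrow(Z)
  p <- ncol(Z)
  S <- crossprod(Z) / n
  mu <- sum(diag(S)) / p
  s2 <- sum(S^2)
  d2 <- (s2 - 2 * mu * sum(diag(S)) + p * mu^2) / p
  # sum_t ||z_t z_t' - S||_F^2 = sum_t ||z_t||^4 - n ||S||_F^2
  b2bar <- (sum(rowSums(Z^2)^2) - n * s2) / (n^2 * p)
  b2 <- min(max(b2bar, 0), d2)
  lambda <- if (d2 > 0) b2 / d2 else 1
  Sh <- lambda * mu * diag(p) + (1 - lambda) * S
  if (mu == 0) Sh <- diag(p)  # zero within-class scatter (noise-free)
  w <- solve(Sh, m1 - m0)
  list(w = w, threshold = sum(w * (m0 + m1)) / 2, classes = cls)
}

lda_predict <- function(fit, X) {
  scores <- as.matrix(X) %*% fit$w
  ifelse(scores > fit$threshold, fit$classes[2], fit$classes[1])
}

# z-score each voxel (column) across patterns; constant voxels -> 0.
# Columnwise, so z-scoring commutes with voxel subsetting.
zscore_cols <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  Xc <- X - rep(m, each = n)
  s <- sqrt(colSums(Xc^2) / (n - 1))
  s[s == 0] <- 1
  Xc / rep(s, each = n)
}

# z-score each pattern (row) across voxels
zscore_rows <- function(X) t(apply(X, 1, function(v) {
  s <- sd(v)
  if (s == 0) s <- 1
  (v - mean(v)) / s
}))

# unique random voxel subsets of size k out of V (sorted index keys)
draw_subsets <- function(V, k, n_subsets) {
  max_unique <- suppressWarnings(choose(V, k))
  m <- min(n_subsets, floor(max_unique))
  seen <- character(0)
  out <- vector("list", m)
  i <- 0L
  while (i < m) {
    s <- sort(sample.int(V, k))
    key <- paste(s, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    i <- i + 1L
    out[[i]] <- s
  }
  out
}

task_stack <- function(pattern, conds) {
  runs <- which(pattern$run_mask)
  X <- do.call(rbind, lapply(runs, function(r) pattern$betas[r, conds, ]))
  y <- rep(c("inhibit", "respond"), length(runs))
  list(X = X, y = y, runs = rep(runs, each = 2))
}

#' Cross-task classification accuracy for one subject x ROI
#'
#' Trains a two-class LDA to distinguish the Inhibit from the Respond
#' condition in one task (e.g. Stop vs Go) and tests it on the other task
#' (NoThink vs Think), and vice versa. Each voxel is z-scored across the
#' training set's activation estimates and, separately, across the test
#' set's, so only the relative Inhibit-vs-Respond contribution remains.
#' Accuracy is averaged over both train/test directions and over
#' `n_subsets` unique random subsets of `subset_frac` of the voxels.
#'
#' @param pattern A per-subject pattern element from
#'   [simulate_roi_patterns()] (list with `betas`, `run_mask`).
#' @param n_subsets Number of random voxel subsets (default 50; capped at
#'   the number of unique subsets).
#' @param subset_frac Fraction of voxels per subset (default 0.9).
#' @param seed Integer seed.
#' @return A list with `accuracy`, `scheme = "cross_task"`,
#'   `n_subsets_used`.
#' @export
cross_task_accuracy <- function(pattern, n_subsets = 50, subset_frac = 0.9,
                                seed = 1) {
  V <- dim(pattern$betas)[3]
  if (V < 2) stop("need at least 2 voxels")
  stop_set <- task_stack(pattern, c("Stop", "Go"))
  tnt_set <- task_stack(pattern, c("NoThink", "Think"))
  # columnwise z-scoring commutes with subsetting, so do it once
  Zstop <- zscore_cols(stop_set$X)
  Ztnt <- zscore_cols(tnt_set$X)
  with_local_seed(seed, {
    k <- ceiling(subset_frac * V)
    subsets <- draw_subsets(V, k, n_subsets)
    accs <- vapply(subsets, function(sub) {
      a <- 0
      for (dir in 1:2) {
        Xtr <- if (dir == 1) Zstop[, sub, drop = FALSE] else
          Ztnt[, sub, drop = FALSE]
        Xte <- if (dir == 1) Ztnt[, sub, drop = FALSE] else
          Zstop[, sub, drop = FALSE]
        ytr <- if (dir == 1) stop_set$y else tnt_set$y
        yte <- if (dir == 1) tnt_set$y else stop_set$y
        fit <- lda_train(Xtr, ytr)
        a <- a + mean(lda_predict(fit, Xte) == yte)
      }
      a / 2
    }, numeric(1))
    list(accuracy = mean(accs), scheme = "cross_task",
         n_subsets_used = length(subsets))
  })
}

#' Between-task classification accuracy for one subject x ROI
#'
#' Trains and tests a within-subject LDA to distinguish NoThink from Stop
#' patterns with leave-one-run-out cross-validation over the available
#' runs. Each pattern is z-scored across voxels first, removing univariate
#' intensity differences between the two tasks.
#'
#' @inheritParams cross_task_accuracy
#' @return A list with `accuracy`, `scheme = "between_task"`,
#'   `n_subsets_used`.
#' @export
between_task_accuracy <- function(pattern, n_subsets = 50,
                                  subset_frac = 0.9, seed = 1) {
  V <- dim(pattern$betas)[3]
  if (V < 2) stop("need at least 2 voxels")
  runs <- which(pattern$run_mask)
  if (length(runs) < 4) stop("need at least 4 available runs")
  X <- do.call(rbind, lapply(runs, function(r) {
    pattern$betas[r, c("NoThink", "Stop"), ]
  }))
  X <- zscore_rows(X)
  y <- rep(c("nothink", "stop"), length(runs))
  fold <- rep(runs, each = 2)
  with_local_seed(seed, {
    k <- ceiling(subset_frac * V)
    subsets <- draw_subsets(V, k, n_subsets)
    accs <- vapply(subsets, function(sub) {
      mean(vapply(runs, function(r) {
        tr <- fold != r
        fit <- lda_train(X[tr, sub, drop = FALSE], y[tr])
        mean(lda_predict(fit, X[!tr, sub, drop = FALSE]) == y[!tr])
      }, numeric(1)))
    }, numeric(1))
    list(accuracy = mean(accs), scheme = "between_task",
         n_subsets_used = length(subsets))
  })
}

#' Per-run cross-task accuracy (conflict-reduction curve)
#'
#' Trains the action-stopping classifier on all Stop/Go patterns and tests
#' it separately on each run's NoThink/Think pair (NoThink scored as Stop,
#' Think as Go), honouring the run mask. A declining curve indicates a
#' shrinking domain-general component across thought-suppression runs.
#'
#' @param pattern A per-subject pattern element.
#' @param seed Integer seed (kept for interface symmetry; the computation
#'   is deterministic on the full ROI).
#' @return Numeric vector of length `n_runs` with per-run accuracies (NA
#'   for masked runs).
#' @export
per_run_cross_accuracy <- function(pattern, seed = 1) {
  n_runs <- dim(pattern$betas)[1]
  stop_set <- task_stack(pattern, c("Stop", "Go"))
  tnt_set <- task_stack(pattern, c("NoThink", "Think"))
  Xtr <- zscore_cols(stop_set$X)
  Xte <- zscore_cols(tnt_set$X)
  fit <- lda_train(Xtr, stop_set$y)
  pred <- lda_predict(fit, Xte)
  acc <- rep(NA_real_, n_runs)
  for (r in which(pattern$run_mask)) {
    sel <- tnt_set$runs == r
    acc[r] <- mean(pred[sel] == tnt_set$y[sel])
  }
  acc
}

#' Linear decline of per-run accuracies and slope-behaviour correlations
#'
#' Group linear-trend test on per-run accuracies (ANOVA linear contrast
#' with weights proportional to centred run indices, using each subject's
#' available runs), per-subject least-squares accuracy slopes, and robust
#' correlations of the slopes with SSRT and SIF via
#' [select_and_correlate()].
#'
#' @param per_run Subjects x runs accuracy matrix (NA for missing runs).
#' @param behaviour Data frame or list with per-subject `ssrt` and `sif`.
#' @return A list with `trend` (F, df, p), `slopes`, and `correlations`.
#' @export
linear_trend_and_slope_correlations <- function(per_run, behaviour) {
  n <- nrow(per_run)
  contrast <- numeric(n)
  slopes <- rep(NA_real_, n)
  excluded <- integer(0)
  for (i in seq_len(n)) {
    ok <- which(!is.na(per_run[i, ]))
    if (length(ok) < 3) {
      excluded <- c(excluded, i)
      next
    }
    w <- ok - mean(ok)
    contrast[i] <- sum(w * per_run[i, ok])
    slopes[i] <- sum(w * per_run[i, ok]) / sum(w^2)  # OLS slope
  }
  if (length(excluded)) {
    warning("excluded subjects with <3 runs: ",
            paste(excluded, collapse = ", "))
  }
  keep <- setdiff(seq_len(n), excluded)
  tt <- group_one_sample_test(contrast[keep], tail = "two")
  corrs <- list(
    ssrt = select_and_correlate(slopes[keep], behaviour$ssrt[keep]),
    sif = select_and_correlate(slopes[keep], behaviour$sif[keep]))
  list(trend = list(F = tt$t^2, df1 = 1, df2 = tt$df, p = tt$p),
       slopes = slopes, correlations = corrs)
}

#' Group inference on decoding accuracies
#'
#' Per ROI, a one-tailed one-sample t-test of subject accuracies against
#' the 50% chance level, Bonferroni corrected over the number of ROIs; for
#' ROIs not significant after correction, the one-tailed JZS Bayes factor
#' (B01) quantifies the evidence for chance-level decoding.
#'
#' @param acc Subjects x ROIs accuracy matrix (column names = ROI labels).
#' @param alpha Significance level after correction (default 0.05).
#' @return A data.frame with one row per ROI: `mean_acc`, `t`, `df`, `p`,
#'   `p_adj`, `d`, `b01` (NA where significant).
#' @export
group_decoding_inference <- function(acc, alpha = 0.05) {
  acc <- as.matrix(acc)
  n_roi <- ncol(acc)
  out <- do.call(rbind, lapply(seq_len(n_roi), function(j) {
    v <- acc[, j]
    v <- v[!is.na(v)]
    tt <- group_one_sample_test(v, tail = "one", mu0 = 0.5)
    data.frame(roi = colnames(acc)[j], mean_acc = mean(v), t = tt$t,
               df = tt$df, p = tt$p, d = tt$d)
  }))
  out$p_adj <- pmin(1, out$p * n_roi)
  out$b01 <- NA_real_
  ns <- which(out$p_adj >= alpha)
  for (j in ns) {
    out$b01[j] <- jzs_bf_one_sample(out$t[j], out$df[j] + 1,
                                    tail = "one")$b01
  }
  out
}
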