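# Behavioural partial least squares: SVD of the brain-behaviour correlation
# matrix, permutation inference on singular values, and bootstrap salience
# ratios. Bootstrap ratios are computed on singular-value-weighted
# saliences (the projection of R onto the behaviour weights): the unit
# normalisation of the raw salience vector couples voxels through its
# norm, which deflates bootstrap SEs and inflates the ratios.

pls_prepare <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal row counts")
  if (nrow(X) < 3) stop("need at least 3 subjects")
  if (ncol(X) < 2) stop("need at least 2 voxels")
  zx <- which(apply(X, 2, sd) == 0)
  zy <- which(apply(Y, 2, sd) == 0)
  if (length(zx)) stop("zero-variance voxel column: ", zx[1])
  if (length(zy)) stop("zero-variance behaviour column: ", zy[1])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  rs <- sqrt(rowSums(Xc^2))
  rs[rs == 0] <- 1
  Xn <- Xc / rs                       # each row to unit sum of squares
  list(Xn = Xn, Yc = Yc)
}

pls_corr_svd <- function(Xn, Yc) {
  R <- cor(Xn, Yc)                    # voxels x behaviours
  sv <- svd(R)
  list(R = R, u = sv$u, d = sv$d, v = sv$v)
}

#' Fit a behavioural PLS model
#'
#' Mean-centres X (subjects x voxels) and Y (subjects x behaviours)
#' columnwise, scales each X row to unit sum of squares, correlates every
#' voxel with every behaviour across subjects, and decomposes the resulting
#' correlation matrix R by SVD. Latent variables (LVs) carry a singular
#' value (covariance share s_k^2 / sum s^2), voxel saliences, behaviour
#' weights, per-subject brain scores (raw X times salience), and the
#' correlation profile of brain scores with each behaviour.
#'
#' @param X Subjects x voxels contrast matrix.
#' @param Y Subjects x behaviours matrix (e.g. SSRT and SIF).
#' @return A list of class `pls_result`.
#' @export
fit_behavioural_pls <- function(X, Y) {
  prep <- pls_prepare(X, Y)
  sv <- pls_corr_svd(prep$Xn, prep$Yc)
  X <- as.matrix(X)
  brain_scores <- X %*% sv$u
  Y <- as.matrix(Y)
  profile <- suppressWarnings(cor(Y, brain_scores))
  out <- list(singular_values = sv$d,
              pct_covariance = sv$d^2 / sum(sv$d^2),
              saliences = sv$u,
              behaviour_weights = sv$v,
              brain_scores = brain_scores,
              behaviour_corr_profile = profile,
              R = sv$R)
  class(out) <- "pls_result"
  out
}

#' Permutation test of PLS singular values
#'
#' Permutes the rows of Y, refits the decomposition, and reports the
#' per-LV p-value (1 + #\{perm s_k >= observed s_k\}) / (1 + n_perm) — the
#' add-one estimator, so p is never zero.
#'
#' @param X,Y As in [fit_behavioural_pls()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return Numeric vector of per-LV p-values.
#' @export
pls_permutation_test <- function(X, Y, n_perm = 5000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  prep <- pls_prepare(X, Y)
  obs <- pls_corr_svd(prep$Xn, prep$Yc)$d
  n <- nrow(prep$Yc)
  counts <- with_local_seed(seed, {
    cnt <- numeric(length(obs))
    for (b in seq_len(n_perm)) {
      Yp <- prep$Yc[sample(n), , drop = FALSE]
      dperm <- svd(cor(prep$Xn, Yp))$d
      cnt <- cnt + (dperm >= obs)
    }
    cnt
  })
  (1 + counts) / (1 + n_perm)
}

#' Bootstrap salience ratios and behaviour-correlation intervals
#'
#' Resamples subjects with replacement, refits the decomposition, sign
#' aligns each resample's saliences to the original LV by the dot-product
#' rule, and reports the bootstrap ratio (original salience / bootstrap
#' SE, read as a z-score; |ratio| > 1.96 corresponds to p < 0.05
#' two-tailed) and percentile 95% intervals of the behaviour correlation
#' profile. Ratios are formed on singular-value-weighted saliences, whose
#' bootstrap SEs are free of the unit-norm coupling of the raw salience
#' vector.
#'
#' @param X,Y As in [fit_behavioural_pls()].
#' @param n_boot Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param max_retries Redraws allowed for zero-variance resamples.
#' @return A list with `bootstrap_ratios` (voxels x LVs),
#'   `behaviour_corr_ci` (behaviours x LVs x 2), `salience_se`.
#' @export
pls_bootstrap_saliences <- function(X, Y, n_boot = 5000, seed = 1,
                                    max_retries = 100) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  fit <- fit_behavioural_pls(X, Y)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  L <- length(fit$singular_values)
  with_local_seed(seed, {
    sal <- array(NA_real_, c(nrow(fit$saliences), L, n_boot))
    prof <- array(NA_real_, c(ncol(Y), L, n_boot))
    for (b in seq_len(n_boot)) {
      ok <- FALSE
      for (r in seq_len(max_retries)) {
        idx <- sample(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        if (any(apply(Xb, 2, sd) == 0) || any(apply(Yb, 2, sd) == 0)) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not draw a non-degenerate bootstrap resample")
      fb <- fit_behavioural_pls(Xb, Yb)
      signs <- vapply(seq_len(L), function(k) {
        s <- sum(fb$saliences[, k] * fit$saliences[, k])
        if (s >= 0) 1 else -1
      }, numeric(1))
      sal[, , b] <- sweep(fb$saliences %*% diag(fb$singular_values, L),
                          2, signs, "*")
      prof[, , b] <- sweep(fb$behaviour_corr_profile, 2, signs, "*")
    }
    se <- apply(sal, c(1, 2), sd)
    se[se == 0] <- NA_real_
    ci <- apply(prof, c(1, 2), quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    orig <- fit$saliences %*% diag(fit$singular_values, L)
    list(bootstrap_ratios = orig / se,
         behaviour_corr_ci = aperm(ci, c(2, 3, 1)),
         salience_se = se)
  })
}
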