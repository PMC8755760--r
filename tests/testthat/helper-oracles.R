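# Independent oracles and fixture builders used across the test files.

# hand-buildable stop-signal trial table
toy_stop_table <- function(go_rts, stop_ssds, stop_rts,
                           go_correct = rep(TRUE, length(go_rts))) {
  n_go <- length(go_rts)
  n_st <- length(stop_ssds)
  data.frame(
    subject = 1, run = 1, trial_index = seq_len(n_go + n_st),
    trial_type = c(rep("go", n_go), rep("stop", n_st)),
    ssd_ms = c(rep(NA_real_, n_go), stop_ssds),
    rt_ms = c(go_rts, stop_rts),
    response = ifelse(c(!is.na(go_rts), !is.na(stop_rts)), "b",
                      NA_character_),
    correct = c(go_correct & !is.na(go_rts), is.na(stop_rts)),
    stringsAsFactors = FALSE)
}

# exact Tukey halfspace depth by exhaustive halfplane check over all
# boundary directions defined by point pairs (O(n^3), fixtures only)
brute_halfspace_depth <- function(xy) {
  n <- nrow(xy)
  vapply(seq_len(n), function(i) {
    best <- n
    for (j in seq_len(n)) {
      d <- xy[j, ] - xy[i, ]
      if (all(d == 0)) next
      for (u in list(c(d[2], -d[1]), c(-d[2], d[1]))) {
        proj <- as.matrix(sweep(xy, 2, xy[i, ])) %*% u
        best <- min(best, sum(proj >= -1e-9), sum(proj >= 1e-9) + 1)
      }
    }
    best
  }, numeric(1))
}

# straightforward two-class shrinkage LDA written independently of the
# package implementation (explicit loops, textbook formulas)
oracle_lda_predict <- function(Xtr, ytr, Xte) {
  cls <- sort(unique(ytr))
  m0 <- colMeans(Xtr[ytr == cls[1], , drop = FALSE])
  m1 <- colMeans(Xtr[ytr == cls[2], , drop = FALSE])
  n <- nrow(Xtr)
  p <- ncol(Xtr)
  Z <- Xtr
  for (r in seq_len(n)) {
    Z[r, ] <- Xtr[r, ] - (if (ytr[r] == cls[1]) m0 else m1)
  }
  S <- matrix(0, p, p)
  for (r in seq_len(n)) S <- S + Z[r, ] %*% t(Z[r, ])
  S <- S / n
  mu <- mean(diag(S))
  d2 <- sum((S - mu * diag(p))^2) / p
  b2bar <- 0
  for (r in seq_len(n)) b2bar <- b2bar + sum((Z[r, ] %*% t(Z[r, ]) - S)^2)
  b2bar <- b2bar / (n^2 * p)
  lam <- if (d2 > 0) min(max(b2bar, 0), d2) / d2 else 1
  Sh <- lam * mu * diag(p) + (1 - lam) * S
  w <- solve(Sh) %*% (m1 - m0)
  thr <- sum(w * (m0 + m1)) / 2
  ifelse(Xte %*% w > thr, cls[2], cls[1])
}

# Gibbs sampler for the random-effects model-frequency posterior
gibbs_bms_expected <- function(E, alpha0 = 1, n_iter = 20000,
                               burn = 2000, seed = 99) {
  n <- nrow(E)
  m <- ncol(E)
  with_local_seed(seed, {
    r <- rep(1 / m, m)
    acc <- numeric(m)
    kept <- 0
    for (it in seq_len(n_iter)) {
      z <- vapply(seq_len(n), function(s) {
        w <- log(r) + E[s, ]
        w <- exp(w - max(w))
        sample.int(m, 1, prob = w)
      }, integer(1))
      counts <- tabulate(z, nbins = m)
      g <- rgamma(m, shape = alpha0 + counts)
      r <- g / sum(g)
      if (it > burn) {
        acc <- acc + r
        kept <- kept + 1
      }
    }
    acc / kept
  })
}

# per-subject pattern with a perfectly separable shared inhibition axis
noise_free_pattern <- function(n_runs = 8, V = 6) {
  u <- rep(1 / sqrt(V), V)
  betas <- array(0, c(n_runs, 4, V),
                 dimnames = list(NULL, c("Stop", "Go", "NoThink", "Think"),
                                 NULL))
  for (r in seq_len(n_runs)) {
    betas[r, "Stop", ] <- u
    betas[r, "NoThink", ] <- u
  }
  list(betas = betas, run_mask = rep(TRUE, n_runs), subject = 1,
       roi = "toy")
}
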