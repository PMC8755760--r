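# Effective-connectivity model space (73 models over four nodes), random
# effects Bayesian model selection with exceedance probabilities, family
# inference, and a least-squares + BIC evidence proxy for synthetic
# four-node series.

dcm_nodes <- function() c("rDLPFC", "rVLPFC", "hippocampus", "M1")

# intrinsic coupling: bidirectional between all node pairs except no
# connection between M1 and hippocampus; row = to, column = from
intrinsic_matrix <- function(a_self = 0.5, a_between = 0.15) {
  nodes <- dcm_nodes()
  A <- matrix(a_between, 4, 4, dimnames = list(nodes, nodes))
  diag(A) <- a_self
  A["M1", "hippocampus"] <- 0
  A["hippocampus", "M1"] <- 0
  A
}

# modulatory edge sets of one model; returns list(Stop = ..., NoThink = ...)
# where each element is a list of c(from, to) node pairs
build_modulatory_edges <- function(direction, pathway, interaction,
                                   targets) {
  target_of <- if (targets == "preferred") {
    c(Stop = "M1", NoThink = "hippocampus")
  } else {
    c(Stop = "hippocampus", NoThink = "M1")
  }
  sources_of <- function(cond) {
    switch(pathway,
           independent = if (cond == "Stop") "rVLPFC" else "rDLPFC",
           dlpfc_only = "rDLPFC",
           vlpfc_only = "rVLPFC",
           both = c("rDLPFC", "rVLPFC"))
  }
  inter_edges <- switch(interaction,
                        none = list(),
                        v_to_d = list(c("rVLPFC", "rDLPFC")),
                        d_to_v = list(c("rDLPFC", "rVLPFC")),
                        bidirectional = list(c("rVLPFC", "rDLPFC"),
                                             c("rDLPFC", "rVLPFC")))
  edges <- lapply(c("Stop", "NoThink"), function(cond) {
    tgt <- target_of[[cond]]
    e <- list()
    for (src in sources_of(cond)) {
      if (direction %in% c("bidirectional", "top_down")) {
        e <- c(e, list(c(src, tgt)))
      }
      if (direction %in% c("bidirectional", "bottom_up")) {
        e <- c(e, list(c(tgt, src)))
      }
    }
    c(e, inter_edges)
  })
  names(edges) <- c("Stop", "NoThink")
  edges
}

#' Build the 73-model effective-connectivity space
#'
#' One null model (no modulatory connections) plus 72 modulatory models
#' over the nodes rDLPFC, rVLPFC, hippocampus and M1, organised into four
#' family dimensions: Direction (bidirectional / top-down / bottom-up
#' source-target modulation; 24 models each), Pathways (independent,
#' rDLPFC-only, rVLPFC-only, or parallel modulation by both), Interactions
#' (how Stop and NoThink modulate the rDLPFC-rVLPFC connections), and
#' Targets (preferred: Stop modulates M1 and NoThink the hippocampus;
#' non-preferred: the swap). Within each direction x target half the local
#' composition is: independent with 4 interaction variants, parallel with
#' 4, rDLPFC-only with 2 (none / bidirectional), rVLPFC-only with 2 —
#' 12 models, so 24 per direction family. Within the bidirectional family
#' the parallel models are ids 9-12 (preferred) and 21-24 (non-preferred).
#'
#' @return A list of class `model_space` with `models` (list of model
#'   specs) and `family_partitions` (named partitions of model ids for
#'   direction, pathway, interaction and targets).
#' @export
build_model_space <- function() {
  directions <- c("bidirectional", "top_down", "bottom_up")
  combos <- list(
    list(pathway = "independent",
         interactions = c("none", "v_to_d", "d_to_v", "bidirectional")),
    list(pathway = "dlpfc_only", interactions = c("none", "bidirectional")),
    list(pathway = "vlpfc_only", interactions = c("none", "bidirectional")),
    list(pathway = "both",
         interactions = c("none", "v_to_d", "d_to_v", "bidirectional")))
  models <- list(list(id = 0L, direction = "none", pathway = "none",
                      interaction = "none", targets = "none",
                      modulatory_edges = list(Stop = list(),
                                              NoThink = list())))
  id <- 0L
  for (dir in directions) {
    for (tgt in c("preferred", "non_preferred")) {
      for (cmb in combos) {
        for (intr in cmb$interactions) {
          id <- id + 1L
          models[[length(models) + 1]] <- list(
            id = id, direction = dir, pathway = cmb$pathway,
            interaction = intr, targets = tgt,
            modulatory_edges = build_modulatory_edges(dir, cmb$pathway,
                                                      intr, tgt))
        }
      }
    }
  }
  ids_where <- function(field, value) {
    vapply(Filter(function(m) m[[field]] == value, models),
           function(m) m$id, integer(1))
  }
  partitions <- list(
    direction = lapply(setNames(nm = directions), ids_where,
                       field = "direction"),
    pathway = lapply(setNames(nm = c("independent", "dlpfc_only",
                                     "vlpfc_only", "both")),
                     ids_where, field = "pathway"),
    interaction = lapply(setNames(nm = c("none", "v_to_d", "d_to_v",
                                         "bidirectional")),
                         ids_where, field = "interaction"),
    targets = lapply(setNames(nm = c("preferred", "non_preferred")),
                     ids_where, field = "targets"))
  structure(list(models = models, family_partitions = partitions),
            class = "model_space")
}

#' Random-effects Bayesian model selection
#'
#' Variational estimation of the Dirichlet posterior over model frequencies
#' from a subjects x models log-evidence matrix (iterating subject-wise
#' model posteriors with digamma-corrected evidences until the Dirichlet
#' counts change by less than `tol`), followed by Monte-Carlo exceedance
#' probabilities (argmax frequencies over Dirichlet samples).
#'
#' @param ev An `evidence_matrix` or a plain subjects x models matrix.
#' @param prior_alpha Dirichlet prior count per model (default 1).
#' @param n_samples Dirichlet samples for the exceedance computation
#'   (default 1e5).
#' @param seed Integer seed for the sampling step.
#' @param tol Convergence tolerance on the alpha update (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @return A list of class `bms_result` with `alpha`, `expected_prob`,
#'   `exceedance_prob`, `n_samples`.
#' @export
rfx_bms <- function(ev, prior_alpha = 1, n_samples = 1e5, seed = 1,
                    tol = 1e-6, max_iter = 500) {
  E <- if (inherits(ev, "evidence_matrix")) ev$log_evidence else as.matrix(ev)
  if (!all(is.finite(E))) stop("non-finite log evidences")
  stopifnot(prior_alpha > 0, nrow(E) >= 1)
  m <- ncol(E)
  alpha <- rep(prior_alpha, m)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lg <- sweep(E, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    g <- exp(lg - apply(lg, 1, max))
    g <- g / rowSums(g)
    alpha_new <- prior_alpha + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("BMS did not converge after ", max_iter,
         " iterations (last alpha change ", format(delta), ")")
  }
  xp <- exceedance_from_alpha(alpha, n_samples = n_samples, seed = seed)
  out <- list(alpha = alpha, expected_prob = alpha / sum(alpha),
              exceedance_prob = xp, n_samples = n_samples)
  class(out) <- "bms_result"
  out
}

# Monte-Carlo exceedance probabilities from Dirichlet counts; optional
# `groups` sums sampled mass within families before the argmax.
exceedance_from_alpha <- function(alpha, groups = NULL, n_samples = 1e5,
                                  seed = 1, chunk = 50000L) {
  m <- length(alpha)
  k <- if (is.null(groups)) m else length(groups)
  wins <- numeric(k)
  with_local_seed(seed, {
    done <- 0L
    while (done < n_samples) {
      nb <- min(chunk, n_samples - done)
      g <- matrix(rgamma(nb * m, shape = rep(alpha, each = nb)), nb, m)
      if (!is.null(groups)) {
        g <- vapply(groups, function(ix) rowSums(g[, ix, drop = FALSE]),
                    numeric(nb))
      }
      best <- max.col(g, ties.method = "first")
      wins <- wins + tabulate(best, nbins = k)
      done <- done + nb
    }
  })
  if (!is.null(groups)) names(wins) <- names(groups)
  wins / n_samples
}

#' Family-level Bayesian model selection
#'
#' Restricts the comparison to the models covered by a named partition
#' (mirroring staged family comparisons: direction, pathway, interaction,
#' targets), runs [rfx_bms()] on those columns, and computes family
#' exceedance probabilities by summing sampled Dirichlet mass within each
#' family before the argmax. Expected family probabilities are the summed
#' expected model probabilities.
#'
#' @param ev An `evidence_matrix` (column order = model ids of `space`).
#' @param space The `model_space` the evidence columns refer to.
#' @param partition Either the name of a family dimension (e.g. "targets")
#'   or a named list of disjoint model-id vectors.
#' @param restrict_to Optional vector of model ids to restrict the staged
#'   comparison to (default: all ids covered by the partition).
#' @inheritParams rfx_bms
#' @return A list of class `bms_result` with per-family `alpha`,
#'   `expected_prob` and `exceedance_prob`.
#' @export
family_bms <- function(ev, space, partition, restrict_to = NULL,
                       prior_alpha = 1, n_samples = 1e5, seed = 1) {
  stopifnot(inherits(space, "model_space"))
  if (is.character(partition) && length(partition) == 1) {
    partition <- space$family_partitions[[partition]]
    if (is.null(partition)) stop("unknown partition name")
  }
  all_ids <- sort(unlist(partition, use.names = FALSE))
  if (anyDuplicated(all_ids)) stop("overlapping partition")
  if (!is.null(restrict_to)) {
    partition <- lapply(partition, intersect, restrict_to)
    partition <- partition[vapply(partition, length, integer(1)) > 0]
    all_ids <- sort(unlist(partition, use.names = FALSE))
  }
  ids <- if (inherits(ev, "evidence_matrix")) ev$model_ids else
    vapply(space$models, function(m) m$id, integer(1))
  E <- if (inherits(ev, "evidence_matrix")) ev$log_evidence else
    as.matrix(ev)
  cols <- match(all_ids, ids)
  if (anyNA(cols)) stop("evidence matrix lacks some partition models")
  fit <- rfx_bms(E[, cols, drop = FALSE], prior_alpha = prior_alpha,
                 n_samples = n_samples, seed = seed)
  groups <- lapply(partition, function(fam) match(fam, all_ids))
  xp <- exceedance_from_alpha(fit$alpha, groups = groups,
                              n_samples = n_samples, seed = seed)
  exp_prob <- vapply(groups, function(ix) sum(fit$expected_prob[ix]),
                     numeric(1))
  out <- list(alpha = vapply(groups, function(ix) sum(fit$alpha[ix]),
                             numeric(1)),
              expected_prob = exp_prob, exceedance_prob = xp,
              n_samples = n_samples, model_level = fit)
  class(out) <- "bms_result"
  out
}

# Regularised Wiener deconvolution of a BOLD series by the canonical HRF.
# The FFT is zero-padded to twice the series length so the operation is an
# exact linear (non-circular) filter; without padding the wrap-around
# mismatch is amplified by the inverse filter and leaks block-locked
# structure into the recovered states.
wiener_deconvolve <- function(y, tr_s = 2, reg = 0.005) {
  Tn <- length(y)
  L <- 2 * Tn
  h <- hrf_canonical(seq(0, 24, by = tr_s))
  hp <- c(h, rep(0, L - length(h)))
  H <- fft(hp)
  Y <- fft(c(y, rep(0, Tn)))
  X <- Conj(H) * Y / (Mod(H)^2 + reg * max(Mod(H)^2))
  Re(fft(X, inverse = TRUE))[seq_len(Tn)] / L
}

#' Least-squares + BIC log-evidence proxy for a network model
#'
#' Stands in for full variational model inversion on synthetic data only:
#' deconvolves each node's BOLD series by regularised Wiener filtering,
#' then fits the discrete-time bilinear system restricted to the model's
#' intrinsic and modulatory edges by ordinary least squares, node by node.
#' The log evidence is approximated by -BIC/2 summed over nodes. Labelled
#' a proxy in all outputs; not a substitute inference for real data.
#'
#' @param series T x 4 BOLD matrix (columns rDLPFC, rVLPFC, hippocampus,
#'   M1).
#' @param model A model spec from [build_model_space()].
#' @param inputs Condition inputs as from [default_network_inputs()].
#' @param tr_s Repetition time (seconds).
#' @param ridge Ridge fallback penalty if the design is singular.
#' @return The proxy log evidence (scalar).
#' @export
evidence_proxy_fit <- function(series, model,
                               inputs = default_network_inputs(),
                               tr_s = 2, ridge = 1e-6) {
  if (!all(is.finite(series))) stop("series must be finite")
  nodes <- dcm_nodes()
  Tn <- nrow(series)
  X <- apply(series, 2, wiener_deconvolve, tr_s = tr_s)
  colnames(X) <- nodes
  # the deconvolved states carry the net convolve-then-deconvolve filter;
  # exogenous driving regressors must pass through the same filter or its
  # residue leaks into the condition-specific terms
  h <- hrf_canonical(seq(0, 24, by = tr_s))
  filt_u <- apply(inputs$u_drive, 2, function(u) {
    wiener_deconvolve(convolve(u, rev(h), type = "open")[seq_len(Tn)],
                      tr_s = tr_s)
  })
  A <- intrinsic_matrix()
  # drop the samples distorted by the circular-deconvolution boundary
  # (one HRF length at the start, the filter tail at the end); the wrap
  # artifact otherwise falls inside the first task block and is absorbed
  # by that condition's modulatory regressors
  keep <- (length(h) + 1):(Tn - 2)
  total <- 0
  for (i in seq_along(nodes)) {
    to <- nodes[i]
    resp <- X[keep + 1, i]
    regs <- list(intercept = rep(1, length(keep)))
    for (j in seq_along(nodes)) {
      if (A[i, j] != 0) regs[[paste0("a_", nodes[j])]] <- X[keep, j]
    }
    for (cond in c("Stop", "NoThink")) {
      for (e in model$modulatory_edges[[cond]]) {
        if (e[2] == to) {
          regs[[paste(cond, e[1], sep = "_")]] <-
            inputs$u_mod[keep, cond] * X[keep, match(e[1], nodes)]
        }
      }
    }
    if (to %in% c("rDLPFC", "rVLPFC")) {
      regs$drive_stop <- filt_u[keep, 1]
      regs$drive_tnt <- filt_u[keep, 2]
    }
    D <- do.call(cbind, regs)
    k <- ncol(D)
    fit <- tryCatch(lm.fit(D, resp), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) {
      beta <- solve(crossprod(D) + ridge * diag(k), crossprod(D, resp))
      res <- resp - D %*% beta
    } else {
      res <- fit$residuals
    }
    n <- length(resp)
    rss <- sum(res^2)
    total <- total + (n * log(rss / n) + k * log(n))
  }
  -total / 2
}
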