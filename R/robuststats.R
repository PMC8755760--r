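# Outlier detection, the correlation-method decision tree, and the JZS
# one-sample Bayes factor.

#' Univariate boxplot outliers
#'
#' Indices of values outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\]. A constant
#' vector has zero IQR and, by convention, no outliers.
#'
#' @param x Numeric vector, length >= 4.
#' @return Integer vector of outlier indices (possibly empty).
#' @export
boxplot_outliers <- function(x) {
  if (length(x) < 4) stop("need at least 4 values")
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  which(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
}

# Tukey halfspace depth of each row of xy. For each point, the minimum over
# closed halfplanes through it of the number of points contained; the
# minimum is attained at a normal perpendicular to some point difference,
# so those (slightly perturbed) directions are the candidate set.
halfspace_depth <- function(xy) {
  n <- nrow(xy)
  vapply(seq_len(n), function(i) {
    d <- sweep(xy, 2, xy[i, ])
    nz <- rowSums(abs(d)) > 0
    m <- sum(nz)
    if (m == 0) return(as.numeric(n))  # all points coincide
    dd <- d[nz, , drop = FALSE]
    ang <- atan2(dd[, 2], dd[, 1])
    cand <- as.vector(outer(c(ang + pi / 2, ang - pi / 2),
                            c(-1e-7, 0, 1e-7), "+"))
    U <- cbind(cos(cand), sin(cand))
    counts <- rowSums(U %*% t(dd) >= -1e-9)
    min(counts) + (n - m)              # coincident points (incl. self)
  }, numeric(1))
}

#' Bivariate bagplot outliers
#'
#' Flags points outside the fence obtained by inflating the 50%
#' halfspace-depth bag by a factor of 3 about the depth median (the
#' classical fence factor). Collinear data fall back to the univariate
#' boxplot rule on the principal axis, flagged via the `degenerate`
#' attribute.
#'
#' @param xy Two-column numeric matrix, n >= 10.
#' @param factor Fence inflation factor (default 3).
#' @return Integer vector of outlier indices, with attribute `degenerate`.
#' @export
bagplot_outliers <- function(xy, factor = 3) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 10) stop("need at least 10 points")
  ctr <- scale(xy, scale = FALSE)
  sv <- svd(ctr)$d
  if (sv[2] < 1e-10 * max(sv[1], 1)) {
    # collinear: project on the principal axis and use the boxplot rule
    proj <- ctr %*% svd(ctr)$v[, 1]
    out <- boxplot_outliers(as.numeric(proj))
    if (length(out) == 0 && sv[1] > 0) {
      # zero-IQR projections: flag any point off the common location
      med <- median(proj)
      if (median(abs(proj - med)) == 0) out <- which(abs(proj - med) > 0)
    }
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  n <- nrow(xy)
  depth <- halfspace_depth(xy)
  med_pt <- colMeans(xy[depth == max(depth), , drop = FALSE])
  # bag: the ceil(n/2) deepest points; depth ties broken by closeness to
  # the depth median so boundary ties cannot drag far points into the bag
  ord <- order(-depth, rowSums(sweep(xy, 2, med_pt)^2))
  bag_idx <- ord[seq_len(ceiling(n / 2))]
  bag <- xy[bag_idx, , drop = FALSE]
  # symmetrise about the depth median so the discrete bag hull is not
  # one-sided in small samples
  bc <- sweep(bag, 2, med_pt)
  bc <- rbind(bc, -bc)
  infl <- sweep(bc * factor, 2, med_pt, "+")
  hull <- infl[grDevices::chull(infl), , drop = FALSE]
  inside <- mgcv::in.out(rbind(hull, hull[1, ]), xy)
  out <- setdiff(which(!inside), bag_idx)
  attr(out, "degenerate") <- FALSE
  out
}

#' Percentile-bend correlation
#'
#' Robust correlation that down-weights extreme marginal values via a bend
#' constant (default beta = 0.2, the "20% bend"). The p-value uses the
#' Student-t approximation with n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors.
#' @param beta Bend constant in (0, 0.5).
#' @return A list with `estimate`, `p_value`, `n`.
#' @export
percentile_bend_cor <- function(x, y, beta = 0.2) {
  n <- length(x)
  stopifnot(n == length(y), n >= 4)
  pb_scores <- function(v) {
    m <- floor((1 - beta) * n + 0.5)
    w <- sort(abs(v - median(v)))[m]
    if (w == 0) return(rep(0, n))
    i1 <- sum(v < median(v) - w)
    i2 <- sum(v > median(v) + w)
    sv <- sum(v[v >= median(v) - w & v <= median(v) + w])
    phi <- (w * (i2 - i1) + sv) / (n - i1 - i2)
    u <- (v - phi) / w
    pmin(1, pmax(-1, u))
  }
  a <- pb_scores(x)
  b <- pb_scores(y)
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(estimate = r, p_value = 2 * (1 - pt(abs(tstat), n - 2)), n = n)
}

#' MCD-skipped Spearman correlation
#'
#' Flags bivariate outliers by robust Mahalanobis distance under the
#' minimum covariance determinant (MCD) estimator (h = ceiling((n+3)/2),
#' chi-square(2, 0.975) cut-off), removes them, and computes Spearman's
#' correlation with its p-value on the clean subset. For n <= 30 the MCD
#' search is exhaustive, so the estimate is order-invariant; larger n uses
#' a fixed internal seed.
#'
#' @param x,y Paired numeric vectors, n >= 10.
#' @return A list with `estimate`, `p_value`, `n_used`, `outliers_removed`.
#' @export
skipped_spearman_mcd <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 10)
  xy <- cbind(x, y)
  h <- ceiling((n + 3) / 2)
  mcd <- tryCatch(
    with_local_seed(20210112, {
      MASS::cov.mcd(xy, quantile.used = h,
                    nsamp = if (n <= 30) "exact" else 5000)
    }),
    error = function(e) NULL)
  if (is.null(mcd)) {
    # (near-)collinear data: robust distances along the principal axis
    ctr <- scale(xy, scale = FALSE)
    proj <- as.numeric(ctr %*% svd(ctr)$v[, 1])
    s <- mad(proj)
    if (s == 0) s <- max(abs(proj - median(proj)), 1)
    d2 <- ((proj - median(proj)) / s)^2
    flagged <- which(d2 > qchisq(0.975, df = 1))
  } else {
    d2 <- mahalanobis(xy, mcd$center, mcd$cov)
    flagged <- which(d2 > qchisq(0.975, df = 2))
  }
  keep <- setdiff(seq_len(n), flagged)
  ct <- suppressWarnings(cor.test(x[keep], y[keep], method = "spearman"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n_used = length(keep), outliers_removed = flagged)
}

#' Robust correlation with automatic method selection
#'
#' Implements the decision tree used for all brain-behaviour correlations:
#' with no outliers and normal marginals (Shapiro-Wilk at alpha = 0.05),
#' Pearson; with univariate outliers or non-normality but no bivariate
#' outliers, the 20% percentile-bend correlation; with bivariate outliers
#' (bagplot rule), the MCD-skipped Spearman correlation.
#'
#' @param x,y Paired numeric vectors, n >= 10.
#' @param alpha Normality-test level (default 0.05).
#' @return A list of class `correlation_result` with `method`, `estimate`,
#'   `p_value`, `n_used`, `outliers_removed`.
#' @export
select_and_correlate <- function(x, y, alpha = 0.05) {
  n <- length(x)
  if (n < 10) stop("need at least 10 pairs for the decision tree")
  stopifnot(n == length(y))
  uni <- union(boxplot_outliers(x), boxplot_outliers(y))
  biv <- bagplot_outliers(cbind(x, y))
  normal_ok <- function(v) {
    if (sd(v) == 0) return(FALSE)
    shapiro.test(v)$p.value >= alpha
  }
  if (length(biv) > 0) {
    r <- skipped_spearman_mcd(x, y)
    out <- list(method = "skipped_spearman_mcd", estimate = r$estimate,
                p_value = r$p_value, n_used = r$n_used,
                outliers_removed = r$outliers_removed)
  } else if (length(uni) == 0 && normal_ok(x) && normal_ok(y)) {
    ct <- cor.test(x, y, method = "pearson")
    out <- list(method = "pearson", estimate = unname(ct$estimate),
                p_value = ct$p.value, n_used = n,
                outliers_removed = integer(0))
  } else {
    r <- percentile_bend_cor(x, y)
    out <- list(method = "percentile_bend_20", estimate = r$estimate,
                p_value = r$p_value, n_used = n,
                outliers_removed = integer(0))
  }
  class(out) <- "correlation_result"
  out
}

#' JZS one-sample Bayes factor (null over alternative)
#'
#' Default Bayes factor for the one-sample t-test with a Cauchy(0, scale)
#' prior on the standardized effect delta. `tail = "one"` restricts the
#' alternative prior to delta > 0 (folded Cauchy). B01 > 1 favours the
#' null. Posterior median and central 95% interval of delta are computed on
#' a dense grid.
#'
#' @param t Observed t statistic (finite).
#' @param n Sample size (>= 2).
#' @param scale Cauchy prior scale (default 0.707, "medium").
#' @param tail "one" or "two".
#' @return A list of class `bf_result` with `b01`,
#'   `posterior_median_delta`, `posterior_ci95`.
#' @export
jzs_bf_one_sample <- function(t, n, scale = 0.707,
                              tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (!is.finite(t)) stop("t must be finite")
  stopifnot(n >= 2, scale > 0)
  df <- n - 1
  lik0 <- dt(t, df)
  # the non-central t density warns about final-digit precision far in
  # the tails; accuracy at the integral level is checked in the tests
  dens <- function(d) {
    suppressWarnings(dt(t, df, ncp = d * sqrt(n))) * dcauchy(d, 0, scale)
  }
  if (tail == "one") {
    m1 <- integrate(function(d) 2 * dens(d), 0, Inf,
                    rel.tol = 1e-8)$value
  } else {
    m1 <- integrate(dens, -Inf, Inf, rel.tol = 1e-8)$value
  }
  # posterior of delta on a dense grid (bounds wide enough for n >= 2)
  hi <- max(3, abs(t) / sqrt(n) + 8 / sqrt(n))
  lo <- if (tail == "one") 0 else -hi
  grid <- seq(lo, hi, length.out = 20001)
  post <- dens(grid)
  cdf <- cumsum(post)
  cdf <- cdf / cdf[length(cdf)]
  qfun <- function(p) grid[which.max(cdf >= p)]
  out <- list(b01 = lik0 / m1,
              posterior_median_delta = qfun(0.5),
              posterior_ci95 = c(qfun(0.025), qfun(0.975)))
  class(out) <- "bf_result"
  out
}
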