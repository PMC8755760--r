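# Peristimulus time-course summarisation and the region x modality
# repeated-measures interaction analysis.

#' Modulation index of one peristimulus time-course
#'
#' Mean of the samples at 2, 4 and 6 s post-onset minus the onset (0 s)
#' sample, accounting for pretrial variability. The grid must contain the
#' onset and the full 2-6 s window.
#'
#' @param time_s Peristimulus times in seconds.
#' @param bold BOLD values at those times.
#' @return A single number (BOLD difference units).
#' @export
modulation_index <- function(time_s, bold) {
  need <- c(0, 2, 4, 6)
  if (!all(need %in% time_s)) {
    stop("time grid must contain the onset and the 2-6 s window samples")
  }
  mean(bold[time_s %in% c(2, 4, 6)]) - bold[time_s == 0][1]
}

#' Modulation table from a time-course set
#'
#' Computes the per-condition modulation index for every subject x ROI and
#' forms the two stopping contrasts Stop - Go and NoThink - Think.
#'
#' @param tc Data frame with columns `subject`, `roi`, `condition`,
#'   `time_s`, `bold` (as produced by [simulate_roi_timecourse()]).
#' @return A data.frame with columns `subject`, `roi`, `contrast`, `index`,
#'   one row per subject x roi x contrast.
#' @export
modulation_table <- function(tc) {
  key <- interaction(tc$subject, tc$roi, tc$condition, drop = TRUE)
  pieces <- split(tc, key)
  mi <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(subject = d$subject[1], roi = d$roi[1],
               condition = d$condition[1],
               index = modulation_index(d$time_s, d$bold),
               stringsAsFactors = FALSE)
  }))
  wide <- reshape(mi, idvar = c("subject", "roi"), timevar = "condition",
                  direction = "wide")
  out <- rbind(
    data.frame(subject = wide$subject, roi = wide$roi, contrast = "StopGo",
               index = wide$index.Stop - wide$index.Go),
    data.frame(subject = wide$subject, roi = wide$roi,
               contrast = "NoThinkThink",
               index = wide$index.NoThink - wide$index.Think))
  rownames(out) <- NULL
  out
}

#' Region x modality repeated-measures ANOVA on modulation indices
#'
#' 2 x 2 within-subject ANOVA of the modulation table (two target ROIs by
#' two stopping contrasts). For a 2 x 2 within design each F equals the
#' squared paired t on the corresponding contrast, which is how the F
#' statistics are computed here (and cross-checked in the test-suite against
#' a sums-of-squares oracle). Also reports Bonferroni-corrected post-hoc
#' paired comparisons between ROIs within each modality and one-tailed
#' one-sample tests of each cell against zero (hypothesised direction:
#' below baseline).
#'
#' @param table Modulation table from [modulation_table()].
#' @param rois Character pair of ROI labels (default the two target ROIs
#'   found in the table).
#' @param contrasts Character pair of contrast labels.
#' @return A list with `anova` (data.frame of effect, F, df1, df2, p),
#'   `posthoc_paired`, `cell_tests`.
#' @export
interaction_anova <- function(table,
                              rois = sort(unique(table$roi)),
                              contrasts = c("StopGo", "NoThinkThink")) {
  stopifnot(length(rois) == 2, length(contrasts) == 2)
  subs <- sort(unique(table$subject))
  cell <- function(r, cst) {
    d <- table[table$roi == r & table$contrast == cst, ]
    d <- d[order(d$subject), ]
    if (!identical(sort(d$subject), subs)) {
      miss <- setdiff(subs, d$subject)
      stop("missing cell (", r, ", ", cst, ") for subjects: ",
           paste(miss, collapse = ", "))
    }
    d$index
  }
  y11 <- cell(rois[1], contrasts[1]); y12 <- cell(rois[1], contrasts[2])
  y21 <- cell(rois[2], contrasts[1]); y22 <- cell(rois[2], contrasts[2])
  n <- length(subs)
  eff <- function(v) {
    tt <- group_one_sample_test(v, tail = "two")
    c(F = tt$t^2, df1 = 1, df2 = n - 1, p = tt$p)
  }
  a <- eff(((y11 + y12) - (y21 + y22)) / 2)      # region main effect
  b <- eff(((y11 + y21) - (y12 + y22)) / 2)      # modality main effect
  ab <- eff((y11 - y12) - (y21 - y22))           # interaction
  an <- data.frame(effect = c("region", "modality", "interaction"),
                   rbind(a, b, ab), row.names = NULL)
  ph <- do.call(rbind, lapply(1:2, function(j) {
    d <- list(y11, y12)[[j]] - list(y21, y22)[[j]]
    tt <- group_one_sample_test(d, tail = "two")
    data.frame(contrast = contrasts[j],
               comparison = paste(rois[1], "vs", rois[2]),
               t = tt$t, df = tt$df, p = tt$p, d = tt$d)
  }))
  ph$p_adj <- pmin(1, ph$p * nrow(ph))
  cells <- expand.grid(roi = rois, contrast = contrasts,
                       stringsAsFactors = FALSE)
  ct <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    v <- cell(cells$roi[k], cells$contrast[k])
    tt <- group_one_sample_test(-v, tail = "one")  # below-baseline direction
    data.frame(roi = cells$roi[k], contrast = cells$contrast[k],
               mean = mean(v), t = -tt$t, df = tt$df, p = tt$p, d = -tt$d)
  }))
  ct$p_adj <- pmin(1, ct$p * nrow(ct))
  list(anova = an, posthoc_paired = ph, cell_tests = ct)
}
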