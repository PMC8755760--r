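# Readers and writers for the pipeline's plain-text formats: events-style
# TSV trial tables ("n/a" encodes missing SSD/RT), recall and time-course
# TSV, delimited pattern and evidence matrices with JSON sidecars. Every
# writer round-trips losslessly through its paired reader.

events_columns <- c("subject", "run", "trial_index", "trial_type",
                    "ssd_ms", "rt_ms", "response", "correct")

na_encode <- function(x) ifelse(is.na(x), "n/a", as.character(x))

parse_numeric <- function(x, col, lines) {
  x[x == "n/a"] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop("malformed numeric in column '", col, "' at line ",
         lines[bad[1]])
  }
  out
}

#' Read an events-style stop-signal trial TSV
#'
#' Tab-delimited with a header; "n/a" encodes absent SSD (go trials) and
#' absent RT (omissions and successful stops).
#'
#' @param path File path.
#' @return A trial-table data.frame.
#' @export
read_events_tsv <- function(path) {
  d <- read.delim(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL)
  miss <- setdiff(events_columns, names(d))
  if (length(miss)) stop("missing column: ", miss[1])
  lines <- seq_len(nrow(d)) + 1L
  out <- data.frame(
    subject = parse_numeric(d$subject, "subject", lines),
    run = parse_numeric(d$run, "run", lines),
    trial_index = parse_numeric(d$trial_index, "trial_index", lines),
    trial_type = d$trial_type,
    ssd_ms = parse_numeric(d$ssd_ms, "ssd_ms", lines),
    rt_ms = parse_numeric(d$rt_ms, "rt_ms", lines),
    response = ifelse(d$response == "n/a", NA_character_, d$response),
    correct = d$correct == "TRUE",
    stringsAsFactors = FALSE)
  out
}

#' Write an events-style stop-signal trial TSV
#'
#' @param table Trial-table data.frame.
#' @param path File path.
#' @export
write_events_tsv <- function(table, path) {
  d <- table[, events_columns]
  for (col in c("ssd_ms", "rt_ms", "response")) d[[col]] <- na_encode(d[[col]])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write recall tables as TSV
#'
#' @param path File path.
#' @return `read_recall_tsv`: a recall-table data.frame.
#' @export
read_recall_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject", "pair_id", "condition", "learned",
                    "sp_correct", "ip_correct"), names(d))
  if (length(miss)) stop("missing column: ", miss[1])
  d
}

#' @rdname read_recall_tsv
#' @param table Recall-table data.frame.
#' @export
write_recall_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a pattern set as delimited matrices with JSON sidecars
#'
#' One file per subject x ROI: a tab-delimited matrix with rows in
#' run-major order (run 1 conditions Stop, Go, NoThink, Think; then run 2,
#' ...) and voxels as columns, plus a JSON sidecar recording the condition
#' labels, run count and run mask.
#'
#' @param patterns A pattern set (per-ROI list of per-subject lists).
#' @param dir Output directory (created if needed).
#' @return `write_pattern_set`: the directory, invisibly.
#' @export
write_pattern_set <- function(patterns, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (roi in names(patterns)) {
    for (i in seq_along(patterns[[roi]])) {
      p <- patterns[[roi]][[i]]
      nr <- dim(p$betas)[1]
      flat <- do.call(rbind, lapply(seq_len(nr), function(r) p$betas[r, , ]))
      stem <- file.path(dir, sprintf("sub-%02d_roi-%s", i, roi))
      write.table(flat, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(
        list(subject = i, roi = roi, n_runs = nr,
             conditions = roi_conditions, run_mask = p$run_mask),
        paste0(stem, ".json"), auto_unbox = TRUE)
    }
  }
  invisible(dir)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "_roi-.*\\.json$",
                              full.names = TRUE))
  out <- list()
  for (sc in sidecars) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    flat <- as.matrix(read.delim(sub("\\.json$", ".tsv", sc), header = FALSE))
    nr <- meta$n_runs
    nc <- length(meta$conditions)
    betas <- array(NA_real_, c(nr, nc, ncol(flat)),
                   dimnames = list(NULL, meta$conditions, NULL))
    for (r in seq_len(nr)) betas[r, , ] <- flat[(r - 1) * nc + seq_len(nc), ]
    out[[meta$roi]][[meta$subject]] <-
      list(betas = betas, run_mask = meta$run_mask, roi = meta$roi,
           subject = meta$subject)
  }
  out
}

#' Write / read an evidence matrix with a model-space manifest
#'
#' @param ev An `evidence_matrix`.
#' @param path TSV path; a `.json` manifest with the model ids is written
#'   alongside.
#' @export
write_evidence_matrix <- function(ev, path) {
  write.table(ev$log_evidence, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(model_ids = ev$model_ids),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_evidence_matrix
#' @export
read_evidence_matrix <- function(path) {
  E <- as.matrix(read.delim(path, header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(log_evidence = unname(E),
                 model_ids = as.integer(meta$model_ids)),
            class = "evidence_matrix")
}

#' Read / write time-course TSV
#'
#' @param path File path.
#' @export
read_timecourse_tsv <- function(path) read.delim(path,
                                                 stringsAsFactors = FALSE)

#' @rdname read_timecourse_tsv
#' @param tc Time-course data.frame.
#' @export
write_timecourse_tsv <- function(tc, path) {
  write.table(tc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
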