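CONTAINER_SCHEMA <- "phasegate-container-1"

#' Write a trial container to disk
#'
#' Plain-text directory format: `signals.tsv` (one row per trial x channel,
#' full double precision) plus a `meta.json` sidecar carrying the sampling
#' rate, movement-onset index, identifiers, planted truth, optional labels
#' and any extra metadata. The round trip is lossless.
#'
#' @param trials a [trial_set()].
#' @param path directory to create/overwrite.
#' @param labels optional [label_set()] stored alongside.
#' @param extra optional named list of additional metadata, preserved
#'   verbatim.
#' @return `path`, invisibly.
#' @export
write_trial_container <- function(trials, path, labels = NULL, extra = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(trials$data)
  m <- aperm(trials$data, c(2, 1, 3)) # channel fastest, then trial
  dim(m) <- c(d[1] * d[2], d[3])
  idx <- cbind(
    trial = rep(seq_len(d[1]), each = d[2]),
    channel = rep(seq_len(d[2]), d[1])
  )
  lines <- c(
    paste(c("trial", "channel", paste0("s", seq_len(d[3]))), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(idx[i, 1], idx[i, 2], sprintf("%.17g", m[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, file.path(path, "signals.tsv"))
  meta <- list(
    schema = CONTAINER_SCHEMA,
    fs = trials$fs,
    t0_index = trials$t0_index,
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    channel_ids = trials$channel_ids,
    trial_ids = trials$trial_ids,
    truth = trials$truth,
    extra = extra
  )
  if (!is.null(labels)) {
    meta$labels <- as.list(as.data.frame(labels))
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trial container from disk
#'
#' @param path a directory written by [write_trial_container()].
#' @return list with `trials` (a [trial_set()]), `labels` (a [label_set()]
#'   or NULL) and `extra` metadata.
#' @export
read_trial_container <- function(path) {
  meta_file <- file.path(path, "meta.json")
  sig_file <- file.path(path, "signals.tsv")
  if (!file.exists(meta_file) || !file.exists(sig_file)) {
    stop_cfg("not a trial container: ", path)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (!identical(meta$schema, CONTAINER_SCHEMA)) {
    stop_cfg("container schema mismatch: found '", meta$schema %||% "<none>",
             "', expected '", CONTAINER_SCHEMA, "'")
  }
  tab <- tryCatch(
    read.table(sig_file, header = TRUE, sep = "\t", colClasses = "numeric"),
    error = function(e) stop_cfg("corrupt container signals: ", conditionMessage(e))
  )
  nt <- meta$n_trials; nc <- meta$n_channels; ns <- meta$n_samples
  if (nrow(tab) != nt * nc || ncol(tab) != ns + 2L) {
    stop_cfg("truncated or inconsistent container: expected ", nt * nc, " x ",
             ns + 2L, " table, found ", nrow(tab), " x ", ncol(tab))
  }
  data <- array(0, dim = c(nt, nc, ns))
  for (i in seq_len(nrow(tab))) {
    data[tab[i, 1], tab[i, 2], ] <- as.numeric(tab[i, -(1:2)])
  }
  truth <- meta$truth
  ts <- trial_set(
    data, as.numeric(meta$fs), meta$t0_index,
    channel_ids = meta$channel_ids, trial_ids = meta$trial_ids,
    truth = if (length(truth)) truth else NULL
  )
  labels <- NULL
  if (!is.null(meta$labels)) {
    lb <- as.data.frame(meta$labels, stringsAsFactors = FALSE)
    labels <- label_set(lb$label, trial = lb$trial,
                        rating = lb$rating, delay = lb$delay)
    if (!is.null(lb$outcome)) labels$outcome <- lb$outcome
  }
  list(trials = ts, labels = labels, extra = meta$extra)
}

#' Write a spike table as TSV
#'
#' Columns `unit`, `trial`, `time_s` (seconds relative to movement onset).
#'
#' @param spikes a `spike_train_set` or data.frame with those columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(spikes, path) {
  stopifnot(all(c("unit", "trial", "time_s") %in% names(spikes)))
  lines <- c(
    "unit\ttrial\ttime_s",
    sprintf("%d\t%d\t%.17g", as.integer(spikes$unit),
            as.integer(spikes$trial), spikes$time_s)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a spike table
#'
#' @param path TSV written by [write_spike_table()].
#' @return a `spike_train_set` data.frame.
#' @export
read_spike_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("unit", "trial", "time_s") %in% names(tab))) {
    stop_cfg("not a spike table: ", path)
  }
  class(tab) <- c("spike_train_set", "data.frame")
  tab
}
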