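#' Trial-epoched multichannel time series
#'
#' Container for epoched recordings: a `trials x channels x samples` array of
#' real-valued signals (microvolts) with its sampling rate and the sample
#' index of movement onset (t = 0). All trials share one time axis; negative
#' times are pre-movement.
#'
#' @param data numeric array `trials x channels x samples`.
#' @param fs sampling rate in Hz (> 0).
#' @param t0_index sample index (1-based) of movement onset.
#' @param channel_ids,trial_ids optional identifiers; defaults are generated.
#' @param truth optional list of planted ground-truth metadata carried along
#'   by the synthetic generators (frequency, locked phase per trial, seed, ...).
#' @return an object of class `trial_set`.
#' @seealso [make_phase_coded_trials()], [trial_times()]
#' @export
trial_set <- function(data, fs, t0_index, channel_ids = NULL, trial_ids = NULL,
                      truth = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_cfg("`data` must be a trials x channels x samples array")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_cfg("`fs` must be a positive scalar")
  }
  ns <- dim(data)[3]
  if (t0_index < 1L || t0_index > ns) {
    stop_cfg("`t0_index` must index a sample inside the epoch")
  }
  structure(
    list(
      data = data,
      fs = fs,
      t0_index = as.integer(t0_index),
      channel_ids = channel_ids %||% paste0("ch", seq_len(dim(data)[2])),
      trial_ids = trial_ids %||% seq_len(dim(data)[1]),
      truth = truth
    ),
    class = "trial_set"
  )
}

#' Time axis of a trial set
#'
#' @param x a `trial_set`.
#' @return times in seconds relative to movement onset (t = 0).
#' @export
trial_times <- function(x) {
  (seq_len(dim(x$data)[3]) - x$t0_index) / x$fs
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  tt <- trial_times(x)
  cat(sprintf(
    "<trial_set> %d trials x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
    d[1], d[2], d[3], x$fs, tt[1], tt[length(tt)]
  ))
  if (!is.null(x$truth)) cat("  planted truth:", paste(names(x$truth), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$data)

#' Per-trial behavioural labels
#'
#' @param label character/factor vector of `"high"`, `"low"` or `"excluded"`.
#' @param trial optional trial ids (defaults to sequence).
#' @param rating optional raw ratings (e.g. 1-9 agency scale).
#' @param delay optional go-cue to movement delay in seconds.
#' @return a `data.frame` of class `label_set`.
#' @export
label_set <- function(label, trial = seq_along(label), rating = NULL, delay = NULL) {
  label <- as.character(label)
  bad <- setdiff(unique(label), c("high", "low", "excluded"))
  if (length(bad)) stop_cfg("unknown labels: ", paste(bad, collapse = ", "))
  out <- data.frame(trial = trial, label = label, stringsAsFactors = FALSE)
  if (!is.null(rating)) out$rating <- rating
  if (!is.null(delay)) out$delay <- delay
  class(out) <- c("label_set", "data.frame")
  out
}

# Normalise labels (label_set, factor or character vector) to a character
# vector of length n with values high/low/excluded.
as_label_vector <- function(labels, n = NULL) {
  v <- if (inherits(labels, "label_set") || is.data.frame(labels)) {
    as.character(labels$label)
  } else {
    as.character(labels)
  }
  if (!is.null(n) && length(v) != n) {
    stop_cfg("labels have length ", length(v), " but ", n, " trials are present")
  }
  v
}
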