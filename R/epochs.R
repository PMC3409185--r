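#' Construct an epoch set
#'
#' The unit of all signal processing: a 3-d array of sensor data split into
#' stimulus-locked epochs, with its time axis and per-epoch condition labels.
#'
#' @param data Numeric array, epochs x channels x samples (tesla).
#' @param sfreq Sampling rate, Hz.
#' @param time_ms Time axis in ms relative to stimulus onset; strictly
#'   increasing, length = dim(data)[3].
#' @param labels Condition label per epoch (character or factor).
#' @param rejected Logical per-epoch rejection mask (default none).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sfreq, time_ms, labels = NULL, rejected = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n_ep <- dim(data)[1]
  if (!is.numeric(sfreq) || sfreq <= 0) stop("epoch_set: sfreq must be > 0")
  if (length(time_ms) != dim(data)[3])
    stop("epoch_set: time axis length != sample count")
  if (any(diff(time_ms) <= 0)) stop("epoch_set: time axis must be strictly increasing")
  if (is.null(labels)) labels <- rep("all", n_ep)
  if (length(labels) != n_ep) stop("epoch_set: one label per epoch required")
  if (is.null(rejected)) rejected <- rep(FALSE, n_ep)
  if (length(rejected) != n_ep) stop("epoch_set: rejected mask length mismatch")
  structure(list(data = data, sfreq = as.numeric(sfreq),
                 time_ms = as.numeric(time_ms),
                 labels = as.character(labels),
                 rejected = as.logical(rejected)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %.2f Hz, %d rejected\n",
              d[1], d[2], d[3], x$sfreq, sum(x$rejected)))
  invisible(x)
}

#' Indices of the time axis inside a window
#' @param epochs An `epoch_set` (or anything with `time_ms`).
#' @param window Length-2 ms pair (inclusive).
#' @return Integer sample indices.
#' @export
window_samples <- function(epochs, window) {
  idx <- which(epochs$time_ms >= window[1] & epochs$time_ms <= window[2])
  if (!length(idx)) stop("window_samples: window outside the epoch time axis")
  idx
}

#' Keep only epochs with given condition labels
#' @param epochs An `epoch_set`.
#' @param conditions Character vector of labels to keep.
#' @return An `epoch_set` restricted to those epochs.
#' @export
subset_conditions <- function(epochs, conditions) {
  keep <- epochs$labels %in% conditions
  if (!any(keep)) stop("subset_conditions: no epochs with the requested labels")
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$sfreq, epochs$time_ms,
            epochs$labels[keep], epochs$rejected[keep])
}

#' Drop rejected epochs
#' @param epochs An `epoch_set`.
#' @return An `epoch_set` containing only surviving epochs, in order.
#' @export
surviving_epochs <- function(epochs) {
  keep <- !epochs$rejected
  if (!any(keep)) stop("surviving_epochs: all epochs are rejected")
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$sfreq, epochs$time_ms,
            epochs$labels[keep], rep(FALSE, sum(keep)))
}

#' Analysis windows and bands
#'
#' Bundles the pre-stimulus baseline window, the post-stimulus active
#' windows, and the frequency bands of interest. Defaults follow the
#' standard face-viewing protocol: passive -300 to -100 ms; three 200 ms
#' active windows at 50-250, 250-450 and 450-650 ms; gamma 30-80 Hz and a
#' control lower band 3-30 Hz.
#'
#' @param passive ms pair, entirely pre-stimulus.
#' @param actives List of ms pairs, each 200 ms long.
#' @param bands Named list of Hz pairs.
#' @return An object of class `analysis_windows`.
#' @export
analysis_windows <- function(passive = c(-300, -100),
                             actives = list(c(50, 250), c(250, 450), c(450, 650)),
                             bands = list(lower = c(3, 30), gamma = c(30, 80))) {
  if (passive[2] > 0) stop("analysis_windows: passive window must be pre-stimulus")
  for (a in actives)
    if (abs(diff(a) - diff(passive)) > 1e-9)
      stop("analysis_windows: active windows must match the passive window length")
  for (b in bands)
    if (b[1] <= 0 || b[2] <= b[1]) stop("analysis_windows: bad band edges")
  structure(list(passive = passive, actives = actives, bands = bands),
            class = "analysis_windows")
}
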