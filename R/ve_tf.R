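#' Virtual-electrode site
#'
#' @param mni_coord MNI mm coordinate.
#' @param mode How the site was chosen: "between_group_peak",
#'   "within_group_mean_peak" or "theory_driven".
#' @param label Site label.
#' @return An object of class `ve_site`.
#' @export
ve_site <- function(mni_coord, mode = "theory_driven", label = NULL) {
  stopifnot(length(mni_coord) == 3)
  if (is.null(label))
    label <- paste0("(", paste(round(mni_coord, 1), collapse = ", "), ")")
  structure(list(mni_coord = as.numeric(mni_coord), mode = mode,
                 label = label), class = "ve_site")
}

#' Select virtual-electrode sites
#'
#' Three selection modes, any subset of which may be requested:
#' the peak |t| voxel of a between-groups map; the coordinate-wise mean of
#' the significant maxima of the within-group maps, snapped to the nearest
#' grid point; and user-supplied theory-driven MNI coordinates (passed
#' through unchanged).
#'
#' @param between_map Optional thresholded between-groups `stat_map`.
#' @param within_maps Optional list of within-group `stat_map`s (thresholded,
#'   common grid).
#' @param theory_sites Optional list of MNI coordinates (length-3 vectors).
#' @param k Peaks per map considered in the within-group mode.
#' @return List of `ve_site`s.
#' @export
select_ve_sites <- function(between_map = NULL, within_maps = NULL,
                            theory_sites = NULL, k = 5) {
  sites <- list()
  if (!is.null(between_map)) {
    v <- between_map$values
    v[between_map$degenerate] <- NA
    i <- which.max(abs(v))
    sites <- c(sites, list(ve_site(between_map$grid$points[i, ],
                                   mode = "between_group_peak",
                                   label = "between-groups peak")))
  }
  if (!is.null(within_maps)) {
    peaks <- do.call(rbind, lapply(within_maps, function(m) {
      p <- find_peaks(m, k = k)
      p[p$sign == "max", c("x", "y", "z"), drop = FALSE]
    }))
    if (is.null(peaks) || !nrow(peaks))
      stop("select_ve_sites: no significant maxima in the within-group maps")
    ctr <- colMeans(peaks)
    g <- within_maps[[1]]$grid$points
    i <- which.min(colSums((t(g) - ctr)^2))
    sites <- c(sites, list(ve_site(g[i, ], mode = "within_group_mean_peak",
                                   label = "mean of within-group maxima")))
  }
  for (s in theory_sites)
    sites <- c(sites, list(ve_site(s, mode = "theory_driven")))
  sites
}

#' Beamformer weights for a virtual electrode
#'
#' Maps the MNI site into the subject's space with their affine, evaluates
#' the analytic lead field at the mapped point (not the nearest grid point),
#' and computes minimum-variance weights against the supplied covariance.
#'
#' @param site A `ve_site` (MNI mm).
#' @param affine The subject's MNI-to-subject 4x4 transform.
#' @param sensors A `sensor_array`.
#' @param head A `head_model`.
#' @param cov The subject's `cov_matrix`.
#' @return As [compute_weights()], plus `point` (subject-space mm).
#' @export
place_ve <- function(site, affine, sensors, head, cov) {
  stopifnot(inherits(site, "ve_site"))
  p <- warp_point(site$mni_coord, affine)
  if (sqrt(sum((p - head$center)^2)) >= head$radius)
    stop("place_ve: mapped site lies outside the head sphere")
  lf <- lead_field_point(p, sensors, head)
  w <- compute_weights(lf$L, cov)
  w$point <- p
  w
}

#' Reconstruct the virtual-electrode time series
#'
#' The VE trace is the weighted sum of the sensor data in every epoch —
#' a linear, deterministic spatial filter.
#'
#' @param w Weight vector (or a [place_ve()] / [compute_weights()] result).
#' @param epochs An `epoch_set` (rejected epochs skipped).
#' @return A `ve_trace`: `trace` (epochs x samples matrix), `time_ms`,
#'   `sfreq`.
#' @export
reconstruct_trace <- function(w, epochs) {
  if (is.list(w)) w <- w$w
  if (!all(is.finite(w))) stop("reconstruct_trace: non-finite weights")
  epochs <- surviving_epochs(epochs)
  d <- dim(epochs$data)
  X <- matrix(aperm(epochs$data, c(2, 3, 1)), nrow = d[2])  # ch x (T*ep)
  tr <- matrix(as.numeric(w %*% X), nrow = d[1], byrow = TRUE)
  structure(list(trace = tr, time_ms = epochs$time_ms, sfreq = epochs$sfreq),
            class = "ve_trace")
}

#' Stockwell transform of a single trace
#'
#' Frequency-domain S-transform: for each analyzed frequency k (in DFT
#' bins), the inverse transform of the spectrum shifted by k and windowed
#' by the Gaussian voice exp(-2 pi^2 m^2 / k^2). Time resolution therefore
#' scales with frequency. Requested frequencies are snapped to DFT bins.
#' The time-marginal identity holds: the mean over time of row k equals the
#' (normalized) DFT coefficient at k.
#'
#' @param x Numeric signal (length >= 16).
#' @param sfreq Sampling rate, Hz.
#' @param fmin,fmax Analysis range, Hz (`fmax` below Nyquist). `fmin = 0`
#'   yields a DC row equal to the signal mean (flagged via attribute
#'   `"dc_row"`).
#' @param fstep Frequency step, Hz.
#' @param decimate Keep every `decimate`-th time sample.
#' @param output "power" (|S|^2) or "complex".
#' @return A matrix (frequencies x time) with attributes `freqs` (actual
#'   bin frequencies, Hz) and `time_index` (kept sample indices).
#' @export
stockwell <- function(x, sfreq, fmin = 1, fmax = 100, fstep = 1,
                      decimate = 1, output = c("power", "complex")) {
  output <- match.arg(output)
  n <- length(x)
  if (n < 16) stop("stockwell: signal length must be >= 16")
  if (fmax >= sfreq / 2) stop("stockwell: fmax must be below Nyquist")
  if (fmin > fmax) stop("stockwell: fmin must be <= fmax")
  X <- stats::fft(x) / n
  want <- seq(fmin, fmax, by = fstep)
  bins <- unique(round(want * n / sfreq))
  bins <- bins[bins >= 0 & bins <= floor((n - 1) / 2)]
  dc_row <- bins[1] == 0
  m <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]  # signed bins
  keep <- seq(1, n, by = decimate)
  S <- matrix(0 + 0i, length(bins), length(keep))
  for (i in seq_along(bins)) {
    k <- bins[i]
    if (k == 0) { S[i, ] <- mean(x); next }
    Xs <- X[(((0:(n - 1)) + k) %% n) + 1]
    voice <- exp(-2 * pi^2 * m^2 / k^2)
    row <- stats::fft(Xs * voice, inverse = TRUE)   # no 1/n: X already scaled
    S[i, ] <- row[keep]
  }
  out <- if (output == "power") Re(S * Conj(S)) else S
  attr(out, "freqs") <- bins * sfreq / n
  attr(out, "time_index") <- keep
  attr(out, "dc_row") <- dc_row
  out
}

.tf_map <- function(values, freqs, time_ms, kind, mask = NULL, windows = NULL) {
  structure(list(values = values, freqs = freqs, time_ms = time_ms,
                 kind = kind, mask = mask, windows = windows),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map:%s> %d freqs x %d time bins (%.1f-%.1f Hz)%s\n",
              x$kind, nrow(x$values), ncol(x$values), min(x$freqs),
              max(x$freqs),
              if (!is.null(x$mask)) sprintf(", %d significant bins",
                                            sum(x$mask)) else ""))
  invisible(x)
}

# per-epoch Stockwell power: epochs x freqs x time array
.epoch_tf_power <- function(ve, fmin, fmax, fstep, decimate) {
  first <- stockwell(ve$trace[1, ], ve$sfreq, fmin, fmax, fstep, decimate)
  freqs <- attr(first, "freqs"); keep <- attr(first, "time_index")
  n_ep <- nrow(ve$trace)
  P <- array(NA_real_, c(n_ep, nrow(first), ncol(first)))
  P[1, , ] <- first
  if (n_ep > 1)
    for (e in 2:n_ep)
      P[e, , ] <- stockwell(ve$trace[e, ], ve$sfreq, fmin, fmax, fstep, decimate)
  list(P = P, freqs = freqs, time_ms = ve$time_ms[keep])
}

#' Evoked (phase-locked) time-frequency power
#'
#' Averages the VE traces across epochs first, then takes the Stockwell
#' power of the average: only activity with a consistent phase across
#' epochs survives the averaging.
#'
#' @param ve A `ve_trace` (>= 2 epochs for a meaningful decomposition).
#' @param fmin,fmax,fstep,decimate Passed to [stockwell()] (time decimated
#'   x4 by default for tractability).
#' @return A `tf_map` of kind "evoked".
#' @export
evoked_tf <- function(ve, fmin = 1, fmax = 100, fstep = 1, decimate = 4) {
  stopifnot(inherits(ve, "ve_trace"))
  avg <- colMeans(ve$trace)
  S <- stockwell(avg, ve$sfreq, fmin, fmax, fstep, decimate)
  .tf_map(unclass(S)[, , drop = FALSE], attr(S, "freqs"),
          ve$time_ms[attr(S, "time_index")], "evoked")
}

#' Induced (total, non-phase-locked) time-frequency power
#'
#' Stockwell power of every epoch, then the average across epochs — the
#' operational definition of induced power used here (total power; phase
#' alignment is irrelevant because power is taken before averaging). An
#' evoked-subtraction variant (`subtract_evoked = TRUE`) removes the
#' epoch-average trace before the per-epoch transform.
#'
#' @inheritParams evoked_tf
#' @param subtract_evoked Subtract the phase-locked average first.
#' @return A `tf_map` of kind "induced".
#' @export
induced_tf <- function(ve, fmin = 1, fmax = 100, fstep = 1, decimate = 4,
                       subtract_evoked = FALSE) {
  stopifnot(inherits(ve, "ve_trace"))
  if (subtract_evoked)
    ve$trace <- sweep(ve$trace, 2, colMeans(ve$trace))
  tp <- .epoch_tf_power(ve, fmin, fmax, fstep, decimate)
  .tf_map(apply(tp$P, c(2, 3), mean), tp$freqs, tp$time_ms, "induced")
}

#' First-level time-frequency t-map
#'
#' For every time-frequency bin in the active span, a paired t-test across
#' epochs between that bin's power and the same-frequency mean power over
#' the passive window (the per-epoch, per-frequency baseline).
#'
#' @param ve A `ve_trace`.
#' @param windows An [analysis_windows()]; the active span is the union of
#'   its active windows, the baseline its passive window.
#' @param fmin,fmax,fstep,decimate Passed to [stockwell()].
#' @param span Optional ms pair overriding the active span.
#' @return A `tf_map` of kind "first_level_t" restricted to the active
#'   span; degenerate-variance bins get t = 0.
#' @export
tf_first_level <- function(ve, windows = analysis_windows(), fmin = 1,
                           fmax = 100, fstep = 1, decimate = 4, span = NULL) {
  stopifnot(inherits(ve, "ve_trace"))
  tp <- .epoch_tf_power(ve, fmin, fmax, fstep, decimate)
  if (is.null(span))
    span <- range(unlist(windows$actives))
  it_base <- which(tp$time_ms >= windows$passive[1] &
                     tp$time_ms <= windows$passive[2])
  it_act <- which(tp$time_ms >= span[1] & tp$time_ms <= span[2])
  if (!length(it_base) || !length(it_act))
    stop("tf_first_level: windows outside the decimated time axis")
  n_ep <- dim(tp$P)[1]
  base <- apply(tp$P[, , it_base, drop = FALSE], c(1, 2), mean)  # ep x freq
  tmat <- matrix(0, dim(tp$P)[2], length(it_act))
  for (j in seq_along(it_act)) {
    D <- tp$P[, , it_act[j]] - base                              # ep x freq
    mu <- colMeans(D)
    sdv <- sqrt(pmax(colSums(D^2) - n_ep * mu^2, 0) / (n_ep - 1))
    tmat[, j] <- ifelse(sdv > 0, mu / (sdv / sqrt(n_ep)), 0)
  }
  out <- .tf_map(tmat, tp$freqs, tp$time_ms[it_act], "first_level_t",
                 windows = windows)
  attr(out, "df") <- n_ep - 1
  out
}

#' Group time-frequency permutation test
#'
#' One-sample t across subjects at every time-frequency bin of the
#' first-level t-maps, with sign-flip permutation and maximum statistics
#' (the same engine as the volumetric group test).
#'
#' @param tmaps List of first-level `tf_map`s (congruent axes).
#' @param n_permutations,alpha,seed As [sign_flip_engine()].
#' @return A `tf_map` of kind "group_t" with the two-sided significance
#'   mask, plus attribute `"perm"` (the `perm_result`).
#' @export
tf_group_permutation <- function(tmaps, n_permutations = 1000, alpha = 0.05,
                                 seed = 1L) {
  stopifnot(length(tmaps) >= 2)
  dims <- dim(tmaps[[1]]$values)
  M <- do.call(rbind, lapply(tmaps, function(m) {
    stopifnot(all(dim(m$values) == dims))
    as.vector(m$values)
  }))
  res <- sign_flip_engine(M, n_permutations = n_permutations, alpha = alpha,
                          seed = seed)
  out <- .tf_map(matrix(res$observed, dims[1], dims[2]), tmaps[[1]]$freqs,
                 tmaps[[1]]$time_ms, "group_t",
                 mask = matrix(res$mask, dims[1], dims[2]))
  attr(out, "perm") <- res
  out
}

#' Heatmap of a time-frequency map
#'
#' Base-graphics rendering with the significance mask outlined by contour
#' lines (the usual "significant bins within dotted lines" display).
#'
#' @param x A `tf_map`.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.tf_map <- function(x, main = x$kind, ...) {
  graphics::image(x$time_ms, x$freqs, t(x$values), xlab = "time (ms)",
                  ylab = "frequency (Hz)", main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  if (!is.null(x$mask) && any(x$mask))
    graphics::contour(x$time_ms, x$freqs, t(x$mask * 1), levels = 0.5,
                      add = TRUE, drawlabels = FALSE, lty = 3)
  invisible(x)
}
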