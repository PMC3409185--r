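#' Band-limited sensor covariance with diagonal loading
#'
#' Sample covariance of band-filtered data pooled over one or more epoch
#' windows across all surviving epochs, regularized by diagonal loading
#' (`regularization` x mean diagonal added to the diagonal).
#'
#' @param epochs An `epoch_set` (rejected epochs are skipped).
#' @param band Hz pair; `NULL` to skip filtering (data already filtered).
#' @param windows List of ms pairs pooled into the estimate.
#' @param regularization Diagonal-loading fraction (default 0.02; with the
#'   long pooled windows used here the covariance is well estimated and
#'   heavier loading blurs the spatial filter).
#' @return An object of class `cov_matrix`: `C` (channels x channels,
#'   tesla^2), `n_samples`, `regularization`, `band`, `windows`.
#' @export
covariance <- function(epochs, band = NULL, windows = list(), regularization = 0.02) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs <- surviving_epochs(epochs)
  if (dim(epochs$data)[1] < 2) stop("covariance: need >= 2 surviving epochs")
  if (!is.null(band)) epochs <- bandpass(epochs, band)
  idx <- if (length(windows)) sort(unique(unlist(lapply(windows, window_samples,
                                                        epochs = epochs))))
         else seq_along(epochs$time_ms)
  d <- dim(epochs$data)
  # channels x pooled samples
  M <- matrix(aperm(epochs$data[, , idx, drop = FALSE], c(2, 3, 1)), nrow = d[2])
  n <- ncol(M)
  M <- M - rowMeans(M)
  C <- tcrossprod(M) / (n - 1)
  load <- regularization * mean(diag(C))
  if (regularization == 0 && rcond(C) < 1e-14)
    stop("covariance: matrix is rank-deficient and regularization is 0")
  C <- C + diag(load, d[2])
  structure(list(C = C, n_samples = n, regularization = regularization,
                 band = band, windows = windows), class = "cov_matrix")
}

#' Minimum-variance beamformer weights at one location
#'
#' Scalar LCMV weights: the source orientation is the tangential direction
#' maximizing beamformer output power — the eigenvector of L' C^-1 L with
#' the smallest eigenvalue — and the weights are
#' w = C^-1 l / (l' C^-1 l), which pass the lead field with unit gain while
#' minimizing output variance.
#'
#' @param L n_channels x 2 tangential lead field at the location.
#' @param cov A `cov_matrix`.
#' @param max_condition Condition-number limit of L' C^-1 L above which the
#'   point is flagged degenerate.
#' @return List: `w` (weights), `orientation` (angle, radians, in the
#'   tangential basis), `degenerate` flag.
#' @export
compute_weights <- function(L, cov, max_condition = 1e8) {
  Ci_L <- solve(cov$C, L)
  A <- crossprod(L, Ci_L)       # 2x2, symmetric positive (semi)definite
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (!all(is.finite(e$values)) || e$values[2] <= 0 ||
      e$values[1] / e$values[2] > max_condition) {
    return(list(w = rep(NA_real_, nrow(L)), orientation = NA_real_,
                degenerate = TRUE))
  }
  v <- e$vectors[, 2]           # smallest eigenvalue -> max output power
  w <- as.numeric(Ci_L %*% v) / e$values[2]
  list(w = w, orientation = atan2(v[2], v[1]), degenerate = FALSE)
}

# weights for all grid points; returns P x N matrix + flags + orientations
.weights_matrix <- function(lf, cov, max_condition = 1e8) {
  n_pts <- dim(lf$L)[3]
  n_ch <- dim(lf$L)[1]
  W <- matrix(NA_real_, n_pts, n_ch)
  degenerate <- logical(n_pts)
  orientation <- numeric(n_pts)
  valid <- if (is.null(lf$valid)) rep(TRUE, n_pts) else lf$valid
  Lflat <- matrix(lf$L, nrow = n_ch)          # N x (2P)
  Lflat[, rep(!valid, each = 2)] <- 0
  CiL <- solve(cov$C, Lflat)
  for (p in seq_len(n_pts)) {
    if (!valid[p]) { degenerate[p] <- TRUE; next }
    j <- c(2 * p - 1, 2 * p)
    A <- crossprod(Lflat[, j], CiL[, j])
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    if (!all(is.finite(e$values)) || e$values[2] <= 0 ||
        e$values[1] / e$values[2] > max_condition) {
      degenerate[p] <- TRUE
      next
    }
    v <- e$vectors[, 2]
    W[p, ] <- as.numeric(CiL[, j] %*% v) / e$values[2]
    orientation[p] <- atan2(v[2], v[1])
  }
  list(W = W, degenerate = degenerate, orientation = orientation)
}

#' Per-epoch active/passive power contrast at one location
#'
#' Projects band-filtered epochs through the weights, computes per-epoch
#' mean squared amplitude in the active and passive windows, and tests the
#' paired difference (active - passive) with a t-test across epochs.
#' Positive t = activation increase.
#'
#' @param w Beamformer weight vector.
#' @param epochs Band-filtered `epoch_set`.
#' @param active,passive ms pairs.
#' @return List: `t`, `df`, `power_active`, `power_passive` (per-epoch
#'   vectors), `degenerate` (TRUE when the difference has zero variance;
#'   then t = 0).
#' @export
voxel_power_contrast <- function(w, epochs, active, passive) {
  epochs <- surviving_epochs(epochs)
  n_ep <- dim(epochs$data)[1]
  if (n_ep < 2) stop("voxel_power_contrast: need >= 2 epochs")
  ia <- window_samples(epochs, active)
  ip <- window_samples(epochs, passive)
  pa <- pp <- numeric(n_ep)
  for (e in seq_len(n_ep)) {
    v <- as.numeric(w %*% epochs$data[e, , ])
    pa[e] <- mean(v[ia]^2)
    pp[e] <- mean(v[ip]^2)
  }
  d <- pa - pp
  sd_d <- stats::sd(d)
  degen <- !is.finite(sd_d) || sd_d == 0
  t <- if (degen) 0 else mean(d) / (sd_d / sqrt(n_ep))
  list(t = t, df = n_ep - 1, power_active = pa, power_passive = pp,
       degenerate = degen)
}

#' Volumetric active/passive power scan
#'
#' Runs the minimum-variance beamformer at every grid point: band-filters
#' the data, estimates the covariance over the passive plus active windows,
#' computes weights, and forms the per-epoch active-vs-passive paired
#' t-contrast at each voxel.
#'
#' @param epochs An `epoch_set`.
#' @param lf A `lead_field` for the (possibly warped) grid.
#' @param band Hz pair.
#' @param active,passive ms pairs.
#' @param regularization Diagonal-loading fraction.
#' @param cov_windows Windows pooled for the covariance; default the passive
#'   and active windows of this contrast.
#' @return A `stat_map` (kind "t") with per-voxel t values, df, degenerate
#'   mask, and per-voxel subject-level summaries `power_active` /
#'   `power_passive` (mean over epochs of the per-epoch window power).
#' @export
scan_volume <- function(epochs, lf, band, active, passive,
                        regularization = 0.02, cov_windows = NULL) {
  stopifnot(inherits(lf, "lead_field"))
  epochs <- surviving_epochs(epochs)
  fe <- bandpass(epochs, band)
  if (is.null(cov_windows)) cov_windows <- list(passive, active)
  cov <- covariance(fe, band = NULL, windows = cov_windows,
                    regularization = regularization)
  wm <- .weights_matrix(lf, cov)
  n_ep <- dim(fe$data)[1]
  ia <- window_samples(fe, active)
  ip <- window_samples(fe, passive)
  n_pts <- nrow(wm$W)
  pa <- pp <- matrix(NA_real_, n_ep, n_pts)
  ok <- !wm$degenerate
  Wok <- wm$W[ok, , drop = FALSE]
  for (e in seq_len(n_ep)) {
    Va <- Wok %*% fe$data[e, , ia]
    Vp <- Wok %*% fe$data[e, , ip]
    pa[e, ok] <- rowMeans(Va^2)
    pp[e, ok] <- rowMeans(Vp^2)
  }
  d <- pa - pp
  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  t <- ifelse(is.finite(sdv) & sdv > 0, mu / (sdv / sqrt(n_ep)), 0)
  t[!ok] <- NA_real_
  stat_map(values = t, grid = lf$grid, kind = "t", df = n_ep - 1,
           band = band, windows = list(active = active, passive = passive),
           degenerate = !ok,
           power_active = colMeans(pa), power_passive = colMeans(pp))
}

#' Construct a volumetric statistic map
#'
#' @param values Per-grid-point statistic.
#' @param grid The `source_grid` (MNI space for group maps).
#' @param kind "t", "z" or "t_diff".
#' @param df Degrees of freedom (NA for difference maps).
#' @param band,windows Provenance.
#' @param threshold Significance threshold on |value| (NA = unthresholded).
#' @param mask Logical significance mask.
#' @param degenerate Logical mask of unstable voxels (excluded).
#' @param ... Extra fields stored on the object (e.g. power summaries).
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, grid, kind = "t", df = NA_real_, band = NULL,
                     windows = NULL, threshold = NA_real_, mask = NULL,
                     degenerate = NULL, ...) {
  stopifnot(inherits(grid, "source_grid"), length(values) == nrow(grid$points))
  if (is.null(mask)) mask <- rep(FALSE, length(values))
  if (is.null(degenerate)) degenerate <- rep(FALSE, length(values))
  structure(c(list(values = as.numeric(values), grid = grid, kind = kind,
                   df = df, band = band, windows = windows,
                   threshold = threshold, mask = mask,
                   degenerate = degenerate), list(...)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map:%s> %d voxels, band %s, threshold %s, %d significant\n",
              x$kind, length(x$values),
              if (is.null(x$band)) "-" else paste(x$band, collapse = "-"),
              format(x$threshold, digits = 3), sum(x$mask)))
  invisible(x)
}

#' Convert a t map to a z map
#'
#' Probit transform of the t cumulative distribution,
#' z = qnorm(pt(t, df)), computed on log scale so extreme tails keep their
#' ordering; |z| is clamped at 8 (flagged via attribute "clamped").
#'
#' @param map A `stat_map` of kind "t" (or a numeric vector with `df`).
#' @param df Degrees of freedom (taken from the map when omitted).
#' @return The map with z values (kind "z"). Monotone and sign-preserving.
#' @export
t_to_z <- function(map, df = NULL) {
  if (inherits(map, "stat_map")) {
    if (is.null(df)) df <- map$df
    z <- t_to_z(map$values, df)
    map$values <- as.numeric(z)
    map$kind <- "z"
    attr(map, "clamped") <- attr(z, "clamped")
    return(map)
  }
  t <- map
  if (is.null(df) || !all(df >= 1)) stop("t_to_z: df must be >= 1")
  # two-tailed-symmetric probit transform, stable in the tails
  z <- ifelse(t <= 0,
              stats::qnorm(stats::pt(t, df, log.p = TRUE), log.p = TRUE),
              -stats::qnorm(stats::pt(-t, df, log.p = TRUE), log.p = TRUE))
  clamped <- abs(z) > 8 & !is.na(z)
  z <- pmin(pmax(z, -8), 8)
  attr(z, "clamped") <- clamped
  z
}

#' Group one-sample permutation test over a volume
#'
#' One-sample t across subjects at every voxel, with family-wise error
#' control by sign-flip permutation and the maximum statistic: each
#' permutation inverts the polarity of a random subset of subjects' maps
#' and records the largest |t| over voxels; the significance threshold is
#' the (1 - alpha) quantile of those maxima (two-sided).
#'
#' @param maps List of subject `stat_map`s (identical grids) or a
#'   subjects x voxels matrix.
#' @param n_permutations Number of sign-flip permutations (>= 100 advised;
#'   < 10 is an error). All 2^n flips are enumerated when feasible.
#' @param alpha Family-wise error rate.
#' @param seed Integer seed.
#' @return A `perm_result` whose `map` is the observed group t `stat_map`
#'   with threshold and mask set.
#' @export
group_onesample <- function(maps, n_permutations = 1000, alpha = 0.05,
                            seed = 1L) {
  if (is.list(maps) && inherits(maps[[1]], "stat_map")) {
    grid <- maps[[1]]$grid
    M <- do.call(rbind, lapply(maps, function(m) {
      stopifnot(nrow(m$grid$points) == nrow(grid$points))
      m$values
    }))
    degen <- Reduce(`|`, lapply(maps, `[[`, "degenerate"))
  } else {
    M <- as.matrix(maps)
    grid <- NULL
    degen <- rep(FALSE, ncol(M))
  }
  degen <- degen | apply(!is.finite(M), 2, any)
  M[, degen] <- 0
  res <- sign_flip_engine(M, n_permutations = n_permutations, alpha = alpha,
                          seed = seed)
  out_map <- if (!is.null(grid))
    stat_map(res$observed, grid, kind = "t", df = nrow(M) - 1,
             threshold = res$threshold, mask = res$mask, degenerate = degen)
  else res$observed
  res$map <- out_map
  res
}

#' Between-groups contrast of contrasts
#'
#' The two-stage group-difference procedure: (1) an unpaired two-sample t
#' per voxel between groups on the subject-level mean active-window band
#' power, with its own label-exchange maximum-statistic cutoff at
#' `alpha`; (2) the same on passive-window power (the baseline difference);
#' (3) the reported map is t_active - t_passive; (4) the significance
#' cutoff is whichever of the two permutation tests required the higher
#' value, applied two-sided to the difference map.
#'
#' @param scansA,scansB Lists of per-subject `stat_map`s from
#'   [scan_volume()] (carrying `power_active`/`power_passive`), one group
#'   each, on a common grid.
#' @param n_permutations Label-exchange permutations per test (default 300).
#' @param alpha Significance level (default 0.001).
#' @param seed Integer seed.
#' @return A `stat_map` of kind "t_diff" with fields `t_active`,
#'   `t_passive`, `cutoff_active`, `cutoff_passive`, and attributes of the
#'   two permutation results.
#' @export
between_groups_contrast <- function(scansA, scansB, n_permutations = 300,
                                    alpha = 0.001, seed = 1L) {
  if (length(scansA) < 2 || length(scansB) < 2)
    stop("between_groups_contrast: each group needs >= 2 subjects")
  grid <- scansA[[1]]$grid
  getm <- function(scans, fld) do.call(rbind, lapply(scans, `[[`, fld))
  Aa <- getm(scansA, "power_active"); Ap <- getm(scansA, "power_passive")
  Ba <- getm(scansB, "power_active"); Bp <- getm(scansB, "power_passive")
  degen <- Reduce(`|`, lapply(c(scansA, scansB), `[[`, "degenerate")) |
    apply(!is.finite(rbind(Aa, Ap, Ba, Bp)), 2, any)
  Aa[, degen] <- 0; Ap[, degen] <- 0; Ba[, degen] <- 0; Bp[, degen] <- 0
  res_a <- label_exchange_engine(Aa, Ba, n_permutations = n_permutations,
                                 alpha = alpha, seed = seed)
  res_p <- label_exchange_engine(Ap, Bp, n_permutations = n_permutations,
                                 alpha = alpha, seed = seed + 1L)
  diff_t <- res_a$observed - res_p$observed
  cutoff <- max(res_a$threshold, res_p$threshold)
  df <- length(scansA) + length(scansB) - 2
  out <- stat_map(diff_t, grid, kind = "t_diff", df = df,
                  band = scansA[[1]]$band, windows = scansA[[1]]$windows,
                  threshold = cutoff, mask = abs(diff_t) >= cutoff & !degen,
                  degenerate = degen,
                  t_active = res_a$observed, t_passive = res_p$observed,
                  cutoff_active = res_a$threshold,
                  cutoff_passive = res_p$threshold)
  # parametric p<.001 cutoff logged for comparison with the permutation one
  attr(out, "parametric_cutoff") <- stats::qt(1 - alpha / 2, df)
  attr(out, "perm_active") <- res_a
  attr(out, "perm_passive") <- res_p
  out
}

#' Ranked significant maxima and minima of a statistic map
#'
#' @param map A thresholded `stat_map`.
#' @param k Number of peaks per sign.
#' @return data.frame (x, y, z, value, sign) of up to `k` significant
#'   positive and `k` significant negative voxels, sorted by |value|
#'   descending, ties broken lexicographically by coordinate. Empty when
#'   nothing is significant.
#' @export
find_peaks <- function(map, k = 5) {
  stopifnot(inherits(map, "stat_map"))
  sel <- which(map$mask & !map$degenerate & is.finite(map$values))
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      value = numeric(0), sign = character(0))
  if (!length(sel)) return(empty)
  p <- map$grid$points[sel, , drop = FALSE]
  v <- map$values[sel]
  pick <- function(idx) {
    if (!length(idx)) return(empty)
    o <- order(-abs(v[idx]), p[idx, 1], p[idx, 2], p[idx, 3])
    idx <- idx[o][seq_len(min(k, length(idx)))]
    data.frame(x = p[idx, 1], y = p[idx, 2], z = p[idx, 3],
               value = v[idx], sign = ifelse(v[idx] > 0, "max", "min"))
  }
  out <- rbind(pick(which(v > 0)), pick(which(v < 0)))
  rownames(out) <- NULL
  out
}
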