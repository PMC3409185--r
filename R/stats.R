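#' Pooled-variance two-sample t-test
#'
#' Classic equal-variance two-sample t with df = n1 + n2 - 2. Works either
#' from raw samples (`x`, `y`) or from printed summary statistics alone
#' (n, mean, SD per group) — the latter is how published group comparisons
#' are recomputed.
#'
#' @param x,y Raw samples, or NULL when summaries are given.
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summaries.
#' @return A `t_test_result`: statistic, df, p (two-sided), variant,
#'   group summaries, degenerate flag.
#' @export
pooled_t <- function(x = NULL, y = NULL, n1 = NULL, mean1 = NULL, sd1 = NULL,
                     n2 = NULL, mean2 = NULL, sd2 = NULL) {
  if (!is.null(x)) { n1 <- length(x); mean1 <- mean(x); sd1 <- stats::sd(x) }
  if (!is.null(y)) { n2 <- length(y); mean2 <- mean(y); sd2 <- stats::sd(y) }
  if (any(vapply(list(n1, mean1, sd1, n2, mean2, sd2), is.null, TRUE)))
    stop("pooled_t: supply raw samples or complete summaries")
  if (n1 < 2 || n2 < 2) stop("pooled_t: each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("pooled_t: SDs must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  degenerate <- se == 0
  stat <- if (degenerate) 0 else (mean1 - mean2) / se
  .t_test_result(stat, df, variant = "pooled",
                 groups = data.frame(n = c(n1, n2), mean = c(mean1, mean2),
                                     sd = c(sd1, sd2)),
                 degenerate = degenerate)
}

#' Welch two-sample t-test (unequal variances)
#'
#' Welch statistic with Satterthwaite degrees of freedom (fractional when
#' the variances differ).
#'
#' @param x,y Raw samples (each n >= 2).
#' @return A `t_test_result`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("welch_t: each group needs n >= 2")
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  se <- sqrt(v1 + v2)
  degenerate <- se == 0
  df <- if (degenerate) length(x) + length(y) - 2 else
    (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  stat <- if (degenerate) 0 else (mean(x) - mean(y)) / se
  .t_test_result(stat, df, variant = "welch",
                 groups = data.frame(n = c(length(x), length(y)),
                                     mean = c(mean(x), mean(y)),
                                     sd = c(stats::sd(x), stats::sd(y))),
                 degenerate = degenerate)
}

.t_test_result <- function(statistic, df, variant, groups, degenerate = FALSE) {
  structure(list(statistic = statistic, df = df,
                 p = 2 * stats::pt(-abs(statistic), df),
                 variant = variant, groups = groups, degenerate = degenerate),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t = %.3f, df = %.3f, p = %.4g%s\n", x$variant, x$statistic,
              x$df, x$p, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Bonferroni-adjusted per-test alpha
#' @param alpha Family-wise level.
#' @param m Number of tests (>= 1).
#' @return alpha / m.
#' @export
bonferroni_adjust <- function(alpha, m) {
  if (m < 1) stop("bonferroni_adjust: m must be >= 1")
  alpha / m
}

#' Trim outliers beyond k cell SDs
#'
#' Single-pass trimming rule for response times: within each cell, values
#' more than `k` standard deviations from the cell mean are removed.
#'
#' @param values Numeric vector.
#' @param cell Factor (or vector) defining the trimming cells; default one
#'   cell.
#' @param k SD multiple (default 2).
#' @return List: `values` (survivors), `kept` (logical over input),
#'   `log` data.frame of removals (index, value, cell, cell_mean, cell_sd).
#' @export
trim_outliers <- function(values, cell = NULL, k = 2) {
  if (is.null(cell)) cell <- rep(1, length(values))
  cell <- as.factor(cell)
  kept <- rep(TRUE, length(values))
  logs <- list()
  for (lv in levels(cell)) {
    idx <- which(cell == lv)
    if (length(idx) < 3) stop("trim_outliers: each cell needs n >= 3")
    m <- mean(values[idx]); s <- stats::sd(values[idx])
    bad <- idx[abs(values[idx] - m) > k * s]
    kept[bad] <- FALSE
    if (length(bad))
      logs[[lv]] <- data.frame(index = bad, value = values[bad], cell = lv,
                               cell_mean = m, cell_sd = s)
  }
  if (!any(kept)) stop("trim_outliers: trimming removed every value")
  log_df <- if (length(logs)) do.call(rbind, c(logs, make.row.names = FALSE))
            else data.frame(index = integer(0), value = numeric(0),
                            cell = character(0), cell_mean = numeric(0),
                            cell_sd = numeric(0))
  list(values = values[kept], kept = kept, log = log_df)
}

#' Log10 transform for right-skewed response times
#' @param values Positive numeric vector.
#' @return log10(values).
#' @export
log10_transform <- function(values) {
  bad <- which(!(values > 0))
  if (length(bad))
    stop("log10_transform: nonpositive value at index ", bad[1])
  log10(values)
}

# vectorized one-sample t over columns given a sign-flip vector f (+-1):
# the column second moments are invariant under flips, so each permutation
# costs one matrix-vector product.
.onesample_t_cols <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  ss <- colSums(M^2)
  s2 <- pmax((ss - n * mu^2) / (n - 1), 0)
  ifelse(s2 > 0, mu / sqrt(s2 / n), 0)
}

#' Sign-flip permutation engine with maximum statistics
#'
#' Generic group-level engine shared by the volumetric and time-frequency
#' one-sample tests. The observed statistic is the per-column one-sample t
#' (or a user statistic); the null is built by inverting the polarity of a
#' uniformly random subset of rows (subjects) per permutation and recording
#' the maximum |statistic| over columns. When all 2^n sign patterns number
#' no more than `n_permutations` they are enumerated exhaustively.
#'
#' @param maps subjects x variables matrix of first-level values.
#' @param statistic Optional function(matrix) -> vector of per-column
#'   statistics; default the one-sample t.
#' @param n_permutations Number of permutations (< 10 is an error, < 100
#'   warns).
#' @param alpha Family-wise error rate; threshold is the (1 - alpha)
#'   quantile (linear interpolation) of the null maxima.
#' @param seed Integer seed (recorded in the result).
#' @return A `perm_result`: observed statistics, `null_max`, `threshold`,
#'   `mask` (|observed| >= threshold), `n_permutations`, `alpha`, `seed`,
#'   `exhaustive` flag.
#' @export
sign_flip_engine <- function(maps, statistic = NULL, n_permutations = 1000,
                             alpha = 0.05, seed = 1L) {
  M <- as.matrix(maps)
  n <- nrow(M)
  if (n < 2) stop("sign_flip_engine: need >= 2 subjects")
  if (n_permutations < 10) stop("sign_flip_engine: need >= 10 permutations")
  if (n_permutations < 100)
    warning("sign_flip_engine: fewer than 100 permutations")
  default_stat <- is.null(statistic)
  if (default_stat) statistic <- .onesample_t_cols
  observed <- statistic(M)
  exhaustive <- 2^n <= n_permutations
  flips <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    withr::with_seed(seed, matrix(sample(c(-1, 1), n * n_permutations,
                                         replace = TRUE),
                                  ncol = n))
  }
  if (default_stat) {
    # mean under flips via one matrix product; second moments are invariant
    nss <- colSums(M^2)
    mu_all <- (flips %*% M) / n
    s2 <- pmax(sweep(-n * mu_all^2, 2, nss, "+") / (n - 1), 0)
    tmat <- ifelse(s2 > 0, mu_all / sqrt(s2 / n), 0)
    null_max <- apply(abs(tmat), 1, max)
  } else {
    null_max <- apply(flips, 1, function(f) max(abs(statistic(M * f))))
  }
  threshold <- stats::quantile(null_max, 1 - alpha, names = FALSE, type = 7)
  structure(list(observed = observed, null_max = null_max,
                 threshold = threshold, mask = abs(observed) >= threshold,
                 n_permutations = nrow(flips), alpha = alpha, seed = seed,
                 exhaustive = exhaustive),
            class = "perm_result")
}

# vectorized pooled two-sample t over columns for a given index set of
# group-A rows within the stacked matrix
.twosample_t_cols <- function(X, idxA) {
  nA <- length(idxA); nB <- nrow(X) - nA
  A <- X[idxA, , drop = FALSE]
  B <- X[-idxA, , drop = FALSE]
  mA <- colMeans(A); mB <- colMeans(B)
  sA2 <- (colSums(A^2) - nA * mA^2) / (nA - 1)
  sB2 <- (colSums(B^2) - nB * mB^2) / (nB - 1)
  sp2 <- pmax(((nA - 1) * sA2 + (nB - 1) * sB2) / (nA + nB - 2), 0)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  ifelse(se > 0, (mA - mB) / se, 0)
}

#' Label-exchange permutation engine with maximum statistics
#'
#' Two-sample analogue of [sign_flip_engine()]: permutes group labels,
#' recomputes the per-column pooled two-sample t (or a user statistic with
#' signature `function(stacked, idxA)`), and records the maximum |t| over
#' columns per permutation. Distinct assignments are enumerated exhaustively
#' when they number no more than `n_permutations`.
#'
#' @param groupA,groupB subjects x variables matrices.
#' @param statistic Optional `function(stacked_matrix, idxA)` -> vector.
#' @param n_permutations Number of permutations (default 300).
#' @param alpha Family-wise error rate.
#' @param seed Integer seed.
#' @return A `perm_result` (as in [sign_flip_engine()]).
#' @export
label_exchange_engine <- function(groupA, groupB, statistic = NULL,
                                  n_permutations = 300, alpha = 0.05,
                                  seed = 1L) {
  A <- as.matrix(groupA); B <- as.matrix(groupB)
  if (nrow(A) < 2 || nrow(B) < 2)
    stop("label_exchange_engine: each group needs >= 2 subjects")
  if (is.null(statistic)) statistic <- .twosample_t_cols
  X <- rbind(A, B)
  n <- nrow(X); nA <- nrow(A)
  observed <- statistic(X, seq_len(nA))
  n_distinct <- choose(n, nA)
  exhaustive <- n_distinct <= n_permutations
  idx_sets <- if (exhaustive) {
    asplit(utils::combn(n, nA), 2)
  } else {
    withr::with_seed(seed,
      lapply(seq_len(n_permutations), function(i) sample.int(n, nA)))
  }
  null_max <- vapply(idx_sets, function(ix) max(abs(statistic(X, ix))),
                     numeric(1))
  threshold <- stats::quantile(null_max, 1 - alpha, names = FALSE, type = 7)
  structure(list(observed = observed, null_max = null_max,
                 threshold = threshold, mask = abs(observed) >= threshold,
                 n_permutations = length(idx_sets), alpha = alpha,
                 seed = seed, exhaustive = exhaustive),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %d permutations%s, alpha %.4g, threshold %.3f, %d significant\n",
              x$n_permutations, if (x$exhaustive) " (exhaustive)" else "",
              x$alpha, x$threshold, sum(x$mask)))
  invisible(x)
}

#' Backward-elimination linear regression with standardized coefficients
#'
#' Starts with all candidate predictors, iteratively removes the predictor
#' with the largest p-value above `removal_alpha`, refits, and stops when
#' every retained predictor has p <= `removal_alpha`. Response and
#' predictors are z-scored, so the coefficients are standardized betas.
#'
#' @param y Response vector.
#' @param X data.frame or matrix of candidate predictors (named columns).
#' @param removal_alpha Removal criterion (default 0.10).
#' @return A `regression_result`: retained predictor names, standardized
#'   betas, their t and p, R-squared, overall F with df, and the removal
#'   trail (predictor, p at removal, step).
#' @export
backward_regression <- function(y, X, removal_alpha = 0.10) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    stop("backward_regression: predictors must be named")
  n <- length(y)
  if (n <= ncol(X) + 2)
    stop("backward_regression: need n > candidates + 2")
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  Xz <- as.data.frame(lapply(X, zs))
  yz <- zs(y)
  if (ncol(Xz) > 1 && kappa(cbind(1, as.matrix(Xz)), exact = TRUE) > 1e10)
    stop("backward_regression: predictors are collinear")
  retained <- names(Xz)
  trail <- data.frame(predictor = character(0), p_at_removal = numeric(0),
                      step = integer(0))
  step <- 0L
  fit <- NULL
  while (length(retained)) {
    fit <- stats::lm(yz ~ ., data = cbind(yz = yz, Xz[retained]))
    ps <- summary(fit)$coefficients[-1, 4]
    worst <- which.max(ps)
    if (ps[worst] <= removal_alpha) break
    step <- step + 1L
    trail <- rbind(trail, data.frame(predictor = retained[worst],
                                     p_at_removal = ps[worst], step = step))
    retained <- retained[-worst]
    fit <- NULL
  }
  if (!length(retained)) {
    return(structure(list(retained = character(0), betas = numeric(0),
                          t = numeric(0), p = numeric(0), r_squared = 0,
                          f = NA_real_, df = c(0, n - 1), trail = trail,
                          removal_alpha = removal_alpha),
                     class = "regression_result"))
  }
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  structure(list(retained = retained,
                 betas = stats::setNames(co[, 1], retained),
                 t = stats::setNames(co[, 3], retained),
                 p = stats::setNames(co[, 4], retained),
                 r_squared = sm$r.squared,
                 f = unname(sm$fstatistic[1]),
                 df = unname(sm$fstatistic[2:3]),
                 trail = trail, removal_alpha = removal_alpha),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  if (!length(x$retained)) {
    cat("<regression_result> intercept-only model (all predictors removed)\n")
    return(invisible(x))
  }
  cat(sprintf("<regression_result> R^2 = %.3f, F(%g, %g) = %.3f\n",
              x$r_squared, x$df[1], x$df[2], x$f))
  for (nm in x$retained)
    cat(sprintf("  %s: beta = %.3f, t = %.3f, p = %.4g\n", nm, x$betas[nm],
                x$t[nm], x$p[nm]))
  invisible(x)
}
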