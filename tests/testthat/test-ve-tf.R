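test_that("Stockwell transform satisfies tone, impulse and marginal identities", {
  sfreq <- 200; n <- 256
  tt <- (0:(n - 1)) / sfreq
  # pure tone concentrates at its frequency row
  S <- stockwell(sin(2 * pi * 40 * tt), sfreq, 5, 80, 1)
  fpk <- attr(S, "freqs")[which.max(rowMeans(S))]
  expect_lt(abs(fpk - 40), 1.5)
  # time-marginal identity: mean over time of row k = DFT coefficient at k
  withr::with_seed(31, x <- stats::rnorm(n))
  Sc <- stockwell(x, sfreq, 1, 80, 1, output = "complex")
  bins <- round(attr(Sc, "freqs") * n / sfreq)
  expect_lt(max(Mod(rowMeans(Sc) - (stats::fft(x) / n)[bins + 1])), 1e-10)
  # impulse: energy at every frequency, localized around t0, width ~ 1/f
  imp <- numeric(n); t0 <- 100; imp[t0] <- 1
  Si <- stockwell(imp, sfreq, 5, 80, 5)
  peaks <- apply(Si, 1, which.max)
  expect_true(all(abs(peaks - t0) <= 2))
  width <- apply(Si, 1, function(r) sum(r > max(r) / 2))
  expect_true(width[1] > width[length(width)])  # low freq wider than high
  expect_error(stockwell(x, sfreq, 1, 150), "Nyquist")
  expect_error(stockwell(x[1:8], sfreq, 1, 40), "length")
})

test_that("virtual electrodes apply the subject affine and keep unit gain", {
  head <- fix_head(); sens <- fix_sensors(32)
  ep <- simulate_epoch_set(list(gamma_source()), sens, head, n_epochs = 10,
                           seed = 41)
  cov <- covariance(bandpass(ep, c(30, 80)))
  site <- ve_site(c(36, -86, 2))
  # identity affine equals direct computation at the MNI point
  w_id <- place_ve(site, diag(4), sens, head, cov)
  lf <- lead_field_point(c(36, -86, 2), sens, head)
  w_direct <- compute_weights(lf$L, cov)
  expect_equal(w_id$w, w_direct$w)
  # translated subject: different weights, unit gain preserved
  tr <- diag(4); tr[1:3, 4] <- c(4, -3, 2)
  w_tr <- place_ve(site, tr, sens, head, cov)
  lf_tr <- lead_field_point(warp_point(c(36, -86, 2), tr), sens, head)
  lt <- lf_tr$L %*% c(cos(w_tr$orientation), sin(w_tr$orientation))
  expect_equal(sum(w_tr$w * lt), 1, tolerance = 1e-9)
  expect_gt(max(abs(w_tr$w - w_id$w)), 0)
  # mapped outside the head -> error
  far <- diag(4); far[1:3, 4] <- c(0, -200, 0)
  expect_error(place_ve(site, far, sens, head, cov), "outside")
  # trace equals an explicit matrix-product oracle
  ve <- reconstruct_trace(w_id, ep)
  man <- t(vapply(seq_len(10), function(e)
    as.numeric(w_id$w %*% ep$data[e, , ]), numeric(dim(ep$data)[3])))
  expect_lt(max(abs(ve$trace - man)), 1e-12 * max(abs(man)))
  expect_equal(reconstruct_trace(w_id$w, ep)$trace, ve$trace)
})

test_that("subjects with different affines recover the same planted source", {
  head <- fix_head(); sens <- fix_sensors(32)
  site <- ve_site(c(36, -86, 2))
  for (shift in list(c(0, 0, 0), c(5, -4, 3))) {
    A <- diag(4); A[1:3, 4] <- shift
    src <- source_spec(warp_point(c(36, -86, 2), A), orientation = 0.4,
                       components = list(source_component(
                         "evoked", freq = 10, onset = 40, offset = 400,
                         amplitude = 30)))
    ep <- simulate_epoch_set(list(src), sens, head, n_epochs = 4,
                             n_background = 2, sensor_noise_sd = 1e-14,
                             seed = 17)
    w <- place_ve(site, A, sens, head, covariance(ep))
    ve <- reconstruct_trace(w, ep)
    # ground-truth source time course: the planted Gabor
    t_s <- ve$time_ms / 1000
    gab <- exp(-(t_s - 0.22)^2 / (2 * 0.06^2)) * cos(2 * pi * 10 * (t_s - 0.22))
    expect_gt(abs(stats::cor(colMeans(ve$trace), gab)), 0.99)
  }
})

test_that("evoked/induced decomposition separates phase-locked from total power", {
  head <- fix_head(); sens <- fix_sensors(16)
  loc <- c(36, -86, 2)
  get_ratio <- function(jit, n_ep = 200) {
    ep <- simulate_epoch_set(list(gamma_source(loc, carrier = "sine",
                                               phase_jitter = jit)),
                             sens, head, n_epochs = n_ep, n_background = 2,
                             seed = 51)
    cov <- covariance(ep, c(30, 80), list(c(-300, -100), c(50, 650)))
    ve <- reconstruct_trace(place_ve(ve_site(loc), diag(4), sens, head, cov), ep)
    ev <- evoked_tf(ve, 40, 80, 2)
    ind <- induced_tf(ve, 40, 80, 2)
    i60 <- which.min(abs(ev$freqs - 60))
    sel <- ev$time_ms >= 200 & ev$time_ms <= 600
    mean(ev$values[i60, sel]) / mean(ind$values[i60, sel])
  }
  # phase-locking dial: ratio decreases monotonically with jitter
  ratios <- vapply(c(0, 0.25, 0.5, 0.75, 1), get_ratio, numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_gt(ratios[1], 0.9)
  expect_lt(ratios[5], 0.05)
})

test_that("decomposition degenerates for single epochs and bounds evoked power", {
  withr::with_seed(52, tr <- matrix(stats::rnorm(6 * 400), 6, 400))
  ve <- structure(list(trace = tr, time_ms = seq(-295, by = 1000 / 678.17,
                                                 length.out = 400) ,
                       sfreq = 678.17), class = "ve_trace")
  ve1 <- ve; ve1$trace <- tr[1, , drop = FALSE]
  ev1 <- evoked_tf(ve1, 5, 60, 5); in1 <- induced_tf(ve1, 5, 60, 5)
  expect_equal(ev1$values, in1$values, tolerance = 1e-12)
  # identical epochs: evoked equals single-epoch power
  vesame <- ve; vesame$trace <- tr[rep(1, 6), ]
  expect_equal(evoked_tf(vesame, 5, 60, 5)$values, ev1$values,
               tolerance = 1e-12)
  # Jensen bound: evoked power <= induced (total) power at every bin
  ev <- evoked_tf(ve, 5, 60, 5); ind <- induced_tf(ve, 5, 60, 5)
  expect_true(all(ev$values <= ind$values + 1e-12 * max(ind$values)))
})

test_that("first-level TF t-maps match a per-bin oracle and find planted bursts", {
  head <- fix_head(); sens <- fix_sensors(16)
  src <- source_spec(c(36, -86, 2), orientation = 0.4, components = list(
    source_component("induced", freq = 60, bandwidth = 10, onset = 250,
                     offset = 450, amplitude = 25)))
  ep <- simulate_epoch_set(list(src), sens, head, n_epochs = 40,
                           n_background = 2, seed = 61)
  cov <- covariance(ep, c(30, 80), list(c(-300, -100), c(50, 650)))
  ve <- reconstruct_trace(place_ve(ve_site(c(36, -86, 2)), diag(4), sens,
                                   head, cov), ep)
  fl <- tf_first_level(ve, analysis_windows(), fmin = 20, fmax = 90,
                       fstep = 2, decimate = 4)
  # positive t cluster at 50-70 Hz in the burst window
  sel_f <- fl$freqs >= 50 & fl$freqs <= 70
  sel_t <- fl$time_ms >= 275 & fl$time_ms <= 425
  expect_gt(mean(fl$values[sel_f, sel_t]), 2)
  # oracle: recompute the t at one bin from per-epoch Stockwell power
  i_f <- which(sel_f)[2]; i_t <- which(sel_t)[3]
  P <- vapply(seq_len(40), function(e) {
    S <- stockwell(ve$trace[e, ], ve$sfreq, 20, 90, 2, decimate = 4)
    base_idx <- attr(S, "time_index")
    tms <- ve$time_ms[base_idx]
    c(S[i_f, which(tms >= 50 & tms <= 650)[i_t]],
      mean(S[i_f, tms >= -300 & tms <= -100]))
  }, numeric(2))
  d <- P[1, ] - P[2, ]
  expect_equal(fl$values[i_f, i_t], mean(d) / (stats::sd(d) / sqrt(40)),
               tolerance = 1e-8)
  # stationary noise: t-field centered on zero
  withr::with_seed(62, trn <- matrix(stats::rnorm(30 * 1356), 30, 1356))
  ven <- structure(list(trace = trn,
                        time_ms = -1000 + (0:1355) / 678.17 * 1000,
                        sfreq = 678.17), class = "ve_trace")
  fln <- tf_first_level(ven, analysis_windows(), 20, 90, 5, 8)
  expect_lt(abs(mean(fln$values)), 0.5)
})

test_that("group TF permutation matches the exhaustive engine and masks planted bins", {
  withr::with_seed(63, {
    tmaps <- lapply(1:8, function(i) {
      v <- matrix(stats::rnorm(10 * 12), 10, 12)
      v[3:4, 5:7] <- v[3:4, 5:7] + 4
      megbeam:::.tf_map(v, 1:10, 1:12, "first_level_t")
    })
  })
  g <- tf_group_permutation(tmaps, n_permutations = 256, alpha = 0.05, seed = 2)
  expect_true(attr(g, "perm")$exhaustive)
  expect_true(all(g$mask[3:4, 5:7]))
  expect_false(any(g$mask[8:10, ]))
  # all-zero maps -> empty mask
  zmaps <- lapply(1:4, function(i)
    megbeam:::.tf_map(matrix(0, 5, 6), 1:5, 1:6, "first_level_t"))
  gz <- suppressWarnings(
    tf_group_permutation(zmaps, n_permutations = 16, alpha = 0.05, seed = 2))
  expect_false(any(gz$mask & gz$values != 0))
})

test_that("VE site selection covers all three modes with a recomputation oracle", {
  g <- fix_roi(10)$grid
  n <- nrow(g$points)
  withr::with_seed(64, v <- stats::rnorm(n))
  v[17] <- 9
  between <- stat_map(v, g, "t_diff", threshold = 5, mask = abs(v) >= 5)
  within1 <- stat_map(v, g, "t", threshold = 5, mask = abs(v) >= 5)
  v2 <- v; v2[23] <- 7
  within2 <- stat_map(v2, g, "t", threshold = 5, mask = abs(v2) >= 5)
  sites <- select_ve_sites(between, list(within1, within2),
                           theory_sites = list(c(32, -57, -3)))
  expect_length(sites, 3)
  expect_equal(sites[[1]]$mni_coord, unname(g$points[17, ]))
  # mean-of-maxima oracle from the peak tables, snapped to the grid
  pk <- rbind(find_peaks(within1), find_peaks(within2))
  ctr <- colMeans(as.matrix(pk[pk$sign == "max", c("x", "y", "z")]))
  snap <- g$points[which.min(colSums((t(g$points) - ctr)^2)), ]
  expect_equal(sites[[2]]$mni_coord, unname(snap))
  # theory site passes through unchanged
  expect_equal(sites[[3]]$mni_coord, c(32, -57, -3))
  # single significant voxel: modes 1 and 2 coincide
  s1 <- select_ve_sites(between, list(within1))
  expect_equal(s1[[1]]$mni_coord, s1[[2]]$mni_coord)
  nothing <- stat_map(v, g, "t")
  expect_error(select_ve_sites(within_maps = list(nothing)), "maxima")
})
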