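test_that("covariance matches a naive two-pass oracle and loads the diagonal", {
  ep <- noise_epochs(6, 5, 300, seed = 2)
  cv0 <- covariance(ep, band = NULL, windows = list(), regularization = 0)
  # brute-force oracle: stack samples, base-R covariance
  M <- matrix(aperm(ep$data, c(2, 3, 1)), nrow = 5)
  expect_lt(max(abs(cv0$C - stats::cov(t(M)))), 1e-12 * max(abs(cv0$C)))
  # white noise: diagonal ~ sigma^2, off-diagonal ~ 0
  big <- noise_epochs(20, 4, 500, sd = 2, seed = 3)
  cvb <- covariance(big, regularization = 0)
  expect_equal(diag(cvb$C), rep(4, 4), tolerance = 0.2)
  expect_lt(max(abs(cvb$C[upper.tri(cvb$C)])), 0.2)
  # loading identity: diag increased by exactly reg * mean(diag)
  cv5 <- covariance(ep, regularization = 0.05)
  expect_equal(diag(cv5$C), diag(cv0$C) + 0.05 * mean(diag(cv0$C)),
               tolerance = 1e-12)
  expect_equal(cv5$C[lower.tri(cv5$C)], cv0$C[lower.tri(cv0$C)])
})

test_that("beamformer weights satisfy unit gain and reduce to a matched filter", {
  head <- fix_head(); sens <- fix_sensors(32)
  lf <- lead_field_point(c(36, -86, 2), sens, head)
  # identity covariance -> weights proportional to the lead field
  cid <- structure(list(C = diag(32)), class = "cov_matrix")
  w <- compute_weights(lf$L, cid)
  l_theta <- lf$L %*% c(cos(w$orientation), sin(w$orientation))
  expect_equal(sum(w$w * l_theta), 1, tolerance = 1e-9)     # unit gain
  expect_gt(abs(stats::cor(w$w, as.numeric(l_theta))), 1 - 1e-9)
  # unit gain holds at every non-degenerate scanned point
  ep <- simulate_epoch_set(list(gamma_source()), sens, head, n_epochs = 10,
                           seed = 6)
  cov <- covariance(bandpass(ep, c(30, 80)))
  roi <- fix_roi(10)
  wm <- megbeam:::.weights_matrix(roi$lf, cov)
  for (p in which(!wm$degenerate)[c(1, 5, 20)]) {
    lt <- roi$lf$L[, , p] %*% c(cos(wm$orientation[p]), sin(wm$orientation[p]))
    expect_equal(sum(wm$W[p, ] * lt), 1, tolerance = 1e-9)
  }
})

test_that("a noiseless planted source is reconstructed with correlation > 0.999", {
  head <- fix_head(); sens <- fix_sensors(32)
  src <- source_spec(c(35, -85, 0), orientation = 0.4, components = list(
    source_component("evoked", freq = 10, onset = 40, offset = 400,
                     amplitude = 30)))
  ep <- simulate_epoch_set(list(src), sens, head, n_epochs = 3,
                           n_background = 0, sensor_noise_sd = 0, seed = 1)
  cov <- covariance(ep)
  lf <- lead_field_point(c(35, -85, 0), sens, head)
  w <- compute_weights(lf$L, cov)
  ve <- reconstruct_trace(w, ep)
  # true time course via the known lead field (sensor with max projection)
  truth <- ep$data[1, which.max(abs(lf$L[, 1])), ]
  expect_gt(abs(stats::cor(ve$trace[1, ], truth)), 0.999)
})

test_that("power contrasts recover sign, planted location, and the t formula", {
  head <- fix_head(); sens <- fix_sensors(32)
  roi <- fix_roi(5)
  # planted increase localizes within one grid spacing
  ep <- simulate_epoch_set(list(gamma_source()), sens, head, n_epochs = 60,
                           seed = 3)
  m <- scan_volume(ep, roi$lf, c(30, 80), c(250, 450), c(-300, -100))
  i <- which.max(m$values)
  expect_lte(sqrt(sum((roi$grid$points[i, ] - c(35, -85, 0))^2)), 5)
  expect_gt(m$values[i], 5)
  # formula oracle at the peak voxel using the stored per-epoch machinery
  fe <- bandpass(ep, c(30, 80))
  cov <- covariance(fe, windows = list(c(-300, -100), c(250, 450)))
  wpk <- compute_weights(roi$lf$L[, , i], cov)
  vc <- voxel_power_contrast(wpk$w, fe, c(250, 450), c(-300, -100))
  d <- vc$power_active - vc$power_passive
  expect_equal(vc$t, mean(d) / (stats::sd(d) / sqrt(length(d))),
               tolerance = 1e-10)
  expect_equal(vc$t, m$values[i], tolerance = 1e-8)
  expect_equal(vc$df, 59)
  # identical windows give t = 0
  same <- voxel_power_contrast(wpk$w, fe, c(-300, -100), c(-300, -100))
  expect_equal(same$t, 0)
  expect_true(same$degenerate)
})

test_that("a planted beta desynchronization yields a negative lower-band t", {
  head <- fix_head(); sens <- fix_sensors(32)
  src <- source_spec(c(0, -96, -6), orientation = 2.0, components = list(
    source_component("desync", freq = 20, bandwidth = 16, onset = 150,
                     offset = 1000, amplitude = 25, factor = 0.5)))
  ep <- simulate_epoch_set(list(src), sens, head, n_epochs = 40, seed = 8)
  g <- crop_grid(build_source_grid(10, head, 5, 20),
                 c(-20, -105, -25), c(20, -75, 15))
  lf <- lead_field_matrix(g, sens, head)
  m <- scan_volume(ep, lf, c(3, 30), c(250, 450), c(-300, -100))
  iv <- which.min(colSums((t(g$points) - c(0, -96, -6))^2))
  expect_lt(m$values[iv], -3)
})

test_that("t-to-z conversion is monotone, sign-preserving, and matches quadrature", {
  expect_equal(as.numeric(t_to_z(0, df = 10)), 0)
  ts <- seq(-6, 6, by = 0.5)
  zs <- as.numeric(t_to_z(ts, df = 7))
  expect_true(all(diff(zs) > 0))
  expect_equal(sign(zs), sign(ts))
  # quadrature oracle at t = 2, df = 299
  p <- stats::integrate(function(x) stats::dt(x, 299), -Inf, 2,
                        rel.tol = 1e-12)$value
  expect_equal(as.numeric(t_to_z(2, df = 299)), stats::qnorm(p),
               tolerance = 1e-6)
  # tail saturation clamps at |z| = 8 and flags it
  z_big <- t_to_z(80, df = 299)
  expect_equal(as.numeric(z_big), 8)
  expect_true(attr(z_big, "clamped"))
})

test_that("peak tables rank significant extremes like an exhaustive sort", {
  g <- fix_roi(10)$grid
  withr::with_seed(12, v <- stats::rnorm(nrow(g$points)))
  m <- stat_map(v, g, threshold = 1, mask = abs(v) >= 1)
  pk <- find_peaks(m, k = 5)
  # full-sort oracle
  sig <- which(abs(v) >= 1)
  pos <- sig[v[sig] > 0]; pos <- pos[order(-v[pos])][1:min(5, sum(v[sig] > 0))]
  expect_equal(pk$value[pk$sign == "max"], v[pos])
  expect_equal(as.matrix(pk[pk$sign == "max", c("x", "y", "z")]),
               g$points[pos, , drop = FALSE], ignore_attr = TRUE)
  # nothing significant -> empty table; k-truncation respected
  expect_equal(nrow(find_peaks(stat_map(v, g))), 0)
  one <- stat_map(v, g, threshold = max(abs(v)) - 1e-9,
                  mask = abs(v) >= max(abs(v)) - 1e-9)
  expect_equal(nrow(find_peaks(one, k = 5)), 1)
  expect_lte(nrow(find_peaks(m, k = 2)), 4)
})
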