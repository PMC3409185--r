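test_that("epoch simulation is deterministic and respects amplitude zero", {
  head <- fix_head(); sens <- fix_sensors(16)
  src <- gamma_source(amplitude = 20)
  a <- simulate_epoch_set(list(src), sens, head, n_epochs = 5, seed = 4)
  b <- simulate_epoch_set(list(src), sens, head, n_epochs = 5, seed = 4)
  expect_identical(a$data, b$data)
  # zero-amplitude sources leave pure sensor noise with mean ~ 0
  z <- simulate_epoch_set(list(gamma_source(amplitude = 0)), sens, head,
                          n_epochs = 20, n_background = 0,
                          sensor_noise_sd = 1e-14, seed = 4)
  expect_lt(abs(mean(z$data)) / stats::sd(z$data), 0.01)
  # aliasing guard
  bad <- source_spec(c(35, -85, 0), components = list(
    source_component("induced", freq = 400)))
  expect_error(simulate_epoch_set(list(bad), sens, head, n_epochs = 2, seed = 1),
               "Nyquist")
})

test_that("phase-locked sources average coherently, random-phase ones as 1/sqrt(n)", {
  head <- fix_head(); sens <- fix_sensors(16)
  # phase-locked: trial average equals any single trial
  locked <- source_spec(c(35, -85, 0), orientation = 0.4, components = list(
    source_component("evoked", freq = 10, onset = 40, offset = 160,
                     amplitude = 30)))
  ep <- simulate_epoch_set(list(locked), sens, head, n_epochs = 8,
                           n_background = 0, sensor_noise_sd = 0, seed = 2)
  avg <- apply(ep$data, c(2, 3), mean)
  expect_lt(max(abs(avg - ep$data[1, , ])), 1e-9 * max(abs(avg)))
  # random-phase sine: average RMS shrinks as 1/sqrt(n) (factor-2 band)
  rnd <- gamma_source(carrier = "sine", phase_jitter = 1)
  n <- 300
  ep2 <- simulate_epoch_set(list(rnd), sens, head, n_epochs = n,
                            n_background = 0, sensor_noise_sd = 0, seed = 2)
  ch <- which.max(apply(ep2$data[1, , ], 1, stats::sd))
  rms1 <- sqrt(mean(ep2$data[1, ch, ]^2))
  rms_avg <- sqrt(mean(apply(ep2$data[, ch, ], 2, mean)^2))
  ratio <- rms_avg / (rms1 / sqrt(n))
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
})

test_that("cohort generation reproduces the AQ group structure", {
  spec <- cohort_spec(n_sensors = 16)
  cohort <- simulate_cohort(spec, seed = 11, signals = FALSE)
  expect_length(cohort, 25)
  groups <- vapply(cohort, `[[`, "", "group")
  aq <- vapply(cohort, function(s) s$covariates$AQ, 0)
  # group means within 2 SE of the configured 12.33 / 38.62
  expect_lt(abs(mean(aq[groups == "td"]) - 12.33), 2 * 6.47 / sqrt(13))
  expect_lt(abs(mean(aq[groups == "asd"]) - 38.62), 2 * 6.16 / sqrt(12))
  # determinism: bitwise-identical cohorts from the same seed
  expect_identical(simulate_cohort(spec, seed = 11, signals = FALSE), cohort)
  # equal gains across groups -> no planted between-group effect
  null_spec <- cohort_spec(gamma_gain = c(td = 1, asd = 1), n_sensors = 16)
  nc <- simulate_cohort(null_spec, seed = 5, signals = FALSE)
  g <- vapply(nc, function(s) s$truth$gamma_gain, 0)
  ng <- vapply(nc, `[[`, "", "group")
  expect_lt(abs(mean(g[ng == "td"]) - mean(g[ng == "asd"])),
            2 * stats::sd(g) * sqrt(1 / 13 + 1 / 12))
  expect_error(simulate_cohort(cohort_spec(n_td = 1, n_sensors = 16), seed = 1),
               "2 subjects")
})

test_that("AQ-gain copula attains the requested within-group correlation", {
  # r = -0.5, one group of 200: Monte-Carlo CI derived from the copula
  spec <- cohort_spec(n_td = 200, n_asd = 2, n_sensors = 16)
  cohort <- simulate_cohort(spec, seed = 42, signals = FALSE)
  td <- cohort[vapply(cohort, `[[`, "", "group") == "td"]
  r <- stats::cor(vapply(td, function(s) s$covariates$AQ, 0),
                  vapply(td, function(s) s$truth$gamma_gain, 0))
  expect_gt(r, -0.65); expect_lt(r, -0.35)
})

test_that("behavioral tables plant RT structure recoverable by a pooled t", {
  spec <- cohort_spec(n_sensors = 16)
  cohort <- simulate_cohort(spec, seed = 1, signals = FALSE)
  groups <- vapply(cohort, `[[`, "", "group")
  # no planted outliers -> less than 5% beyond 2 cell SDs expected
  beh0 <- simulate_behavioral(cohort, rt_model = list(
    mean = c(td = 900, asd = 900), sdlog = 0.15,
    condition_offset = rep(0, 6), outlier_rate = 0,
    accuracy = c(td = 0.9, asd = 0.9)), seed = 3)
  cell <- interaction(beh0$group, beh0$condition)
  frac_out <- mean(!trim_outliers(beh0$rt_ms, cell)$kept)
  expect_lt(frac_out, 0.05)
  # equal group means -> group t near zero
  rt0 <- tapply(log10_transform(beh0$rt_ms), beh0$subject, mean)
  gm <- groups[match(names(rt0), vapply(cohort, `[[`, "", "subject_id"))]
  expect_lt(abs(pooled_t(rt0[gm == "td"], rt0[gm == "asd"])$statistic), 3)
  # planted 200 ms difference recovered with sign in >= 80% of 100 seeds
  hits <- vapply(1:100, function(s) {
    b <- simulate_behavioral(cohort, rt_model = list(
      mean = c(td = 850, asd = 1050), sdlog = 0.15,
      condition_offset = rep(0, 6), outlier_rate = 0.02,
      accuracy = c(td = 0.9, asd = 0.85)), seed = s)
    rt <- tapply(b$rt_ms, b$subject, mean)
    gmm <- groups[match(names(rt), vapply(cohort, `[[`, "", "subject_id"))]
    tt <- pooled_t(rt[gmm == "asd"], rt[gmm == "td"])
    tt$statistic > 0 && tt$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  expect_error(simulate_behavioral(cohort, rt_model = list(
    mean = c(td = -1, asd = 900), sdlog = 0.15,
    condition_offset = rep(0, 6), outlier_rate = 0,
    accuracy = c(td = 0.9, asd = 0.9))), "positive")
})
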