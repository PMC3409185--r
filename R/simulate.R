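#' Define one simulated dipolar source
#'
#' @param location MNI mm coordinate (length 3), interior to the head sphere.
#' @param orientation Tangential orientation angle in radians (direction in
#'   the 2-d tangential basis at the location).
#' @param components List of [source_component()]s.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(location, orientation = 0, components = list()) {
  stopifnot(length(location) == 3, length(components) >= 1)
  structure(list(location = as.numeric(location),
                 orientation = as.numeric(orientation),
                 components = components),
            class = "source_spec")
}

#' Define one signal component of a source
#'
#' Component kinds:
#' \describe{
#'   \item{evoked}{Phase-locked Gabor transient: identical waveform every
#'     epoch, envelope spanning `onset..offset`, carrier `freq` Hz.}
#'   \item{induced}{Non-phase-locked narrowband activity. The amplitude is
#'     `baseline_amplitude` outside `onset..offset` and
#'     `amplitude * gain` inside (gain is the per-subject multiplier), with
#'     raised-cosine ramps. `carrier = "noise"` draws fresh narrowband
#'     Gaussian noise per epoch (inherently non-phase-locked);
#'     `carrier = "sine"` uses a fixed-frequency sinusoid whose per-epoch
#'     phase is `phase0 + phase_jitter * U(-pi, pi)` — the dial used to probe
#'     the evoked/induced decomposition.}
#'   \item{background}{Per-epoch 1/f-shaped dipole noise, RMS `amplitude`.}
#'   \item{desync}{Ongoing narrowband activity whose amplitude is multiplied
#'     by `factor` (< 1 for a power decrease) over `onset..offset`.}
#' }
#'
#' @param kind One of "evoked", "induced", "background", "desync".
#' @param freq Center frequency, Hz.
#' @param bandwidth Bandwidth (Hz) of noise carriers.
#' @param onset,offset Envelope window, ms (onset < offset).
#' @param amplitude Dipole moment scale, nA·m.
#' @param baseline_amplitude Induced only: pre/post-window level, nA·m.
#' @param phase_jitter Induced "sine" carrier: 0 = phase-locked,
#'   1 = uniform random phase per epoch.
#' @param carrier "noise" or "sine" (induced/desync).
#' @param phase0 Carrier phase offset, radians.
#' @param factor Desync only: post-onset amplitude multiplier.
#' @return An object of class `source_component`.
#' @export
source_component <- function(kind = c("evoked", "induced", "background", "desync"),
                             freq = 60, bandwidth = 20, onset = 150, offset = 650,
                             amplitude = 20, baseline_amplitude = 0,
                             phase_jitter = 1, carrier = c("noise", "sine"),
                             phase0 = 0, factor = 0.5) {
  kind <- match.arg(kind)
  carrier <- match.arg(carrier)
  if (onset >= offset) stop("source_component: onset must precede offset")
  if (kind == "evoked" && phase_jitter != 0) phase_jitter <- 0  # evoked is phase-locked
  structure(list(kind = kind, freq = freq, bandwidth = bandwidth,
                 onset = onset, offset = offset, amplitude = amplitude,
                 baseline_amplitude = baseline_amplitude,
                 phase_jitter = phase_jitter, carrier = carrier,
                 phase0 = phase0, factor = factor),
            class = "source_component")
}

# raised-cosine step from 0 to 1 over [a, b] (ms) with ramp_ms ramps
.smooth_window <- function(time_ms, a, b, ramp_ms = 50) {
  w <- numeric(length(time_ms))
  w[time_ms >= a + ramp_ms & time_ms <= b - ramp_ms] <- 1
  up <- time_ms >= a & time_ms < a + ramp_ms
  w[up] <- 0.5 * (1 - cos(pi * (time_ms[up] - a) / ramp_ms))
  dn <- time_ms > b - ramp_ms & time_ms <= b
  w[dn] <- 0.5 * (1 - cos(pi * (b - time_ms[dn]) / ramp_ms))
  w
}

# T x E matrix of per-epoch narrowband unit-RMS Gaussian noise
.narrowband_noise <- function(n_t, n_ep, sfreq, band) {
  X <- matrix(stats::rnorm(n_t * n_ep), n_t, n_ep)
  Y <- .bandpass_matrix(X, sfreq, band)
  sweep(Y, 2, apply(Y, 2, stats::sd), "/")
}

# T x E matrix of per-epoch 1/f-shaped unit-RMS noise
.pink_noise <- function(n_t, n_ep, sfreq) {
  X <- matrix(stats::rnorm(n_t * n_ep), n_t, n_ep)
  f <- (seq_len(n_t) - 1) * sfreq / n_t
  f <- pmin(f, sfreq - f)
  g <- 1 / sqrt(pmax(f, 1))
  g[1] <- 0
  Y <- Re(stats::mvfft(stats::mvfft(X) * g, inverse = TRUE)) / n_t
  sweep(Y, 2, apply(Y, 2, stats::sd), "/")
}

# time course matrix (T x E) for one component
.component_signal <- function(comp, time_ms, sfreq, n_ep, gain) {
  n_t <- length(time_ms)
  t_s <- time_ms / 1000
  if (comp$freq >= sfreq / 2)
    stop("simulate_epoch_set: component frequency ", comp$freq,
         " Hz is at or above Nyquist (", sfreq / 2, " Hz)")
  switch(comp$kind,
    evoked = {
      t0 <- (comp$onset + comp$offset) / 2000
      sigma <- (comp$offset - comp$onset) / 6000
      s <- comp$amplitude * exp(-(t_s - t0)^2 / (2 * sigma^2)) *
        cos(2 * pi * comp$freq * (t_s - t0) + comp$phase0)
      matrix(s, n_t, n_ep)
    },
    induced = {
      env <- comp$baseline_amplitude +
        (comp$amplitude * gain - comp$baseline_amplitude) *
        .smooth_window(time_ms, comp$onset, comp$offset)
      if (comp$carrier == "sine") {
        ph <- comp$phase0 + comp$phase_jitter * stats::runif(n_ep, -pi, pi)
        carr <- cos(outer(2 * pi * comp$freq * t_s, rep(1, n_ep)) +
                      matrix(ph, n_t, n_ep, byrow = TRUE))
      } else {
        band <- comp$freq + c(-0.5, 0.5) * comp$bandwidth
        carr <- .narrowband_noise(n_t, n_ep, sfreq, band) * sqrt(2)
      }
      carr * env
    },
    background = {
      comp$amplitude * .pink_noise(n_t, n_ep, sfreq)
    },
    desync = {
      env <- comp$amplitude *
        (1 + (comp$factor - 1) * .smooth_window(time_ms, comp$onset, comp$offset))
      band <- comp$freq + c(-0.5, 0.5) * comp$bandwidth
      .narrowband_noise(n_t, n_ep, sfreq, band) * sqrt(2) * env
    })
}

#' Simulate a sensor-level epoch set
#'
#' Projects each source's component time courses through its analytic lead
#' field, adds 1/f dipole noise at random interior "distractor" locations
#' and white sensor noise, and returns stimulus-locked epochs. Evoked
#' components repeat identically every epoch; induced components are
#' non-phase-locked across epochs.
#'
#' @param sources List of [source_spec()]s (locations in the same space as
#'   `sensors`/`head`, i.e. subject space if an affine was applied).
#' @param sensors A `sensor_array`.
#' @param head A `head_model`.
#' @param n_epochs Number of epochs.
#' @param gain Subject-level induced-gain multiplier (applied to the active
#'   window of induced components).
#' @param sfreq Sampling rate, Hz (default 678.17).
#' @param window_ms Epoch window, ms (default -1000..1000: 1000 ms stimulus
#'   followed by 1000 ms fixation in the emulated protocol, with the epoch
#'   time-locked so that 0 is stimulus onset).
#' @param labels Optional condition labels (length `n_epochs`); default
#'   cycles through `n_conditions` emotion tags.
#' @param n_conditions Number of condition labels when `labels` is NULL.
#' @param sensor_noise_sd White sensor noise SD, tesla.
#' @param n_background Number of random background dipoles.
#' @param background_amplitude RMS dipole moment of background dipoles, nA·m.
#' @param seed Integer seed; same seed + arguments give bitwise-identical data.
#' @return An `epoch_set` (epochs x channels x samples).
#' @export
simulate_epoch_set <- function(sources, sensors, head = head_model(),
                               n_epochs = 60, gain = 1, sfreq = 678.17,
                               window_ms = c(-1000, 1000), labels = NULL,
                               n_conditions = 6, sensor_noise_sd = 3e-14,
                               n_background = 8, background_amplitude = 15,
                               seed = NULL) {
  n_t <- floor(diff(window_ms) / 1000 * sfreq)
  time_ms <- window_ms[1] + (seq_len(n_t) - 1) / sfreq * 1000
  n_ch <- nrow(sensors$positions)
  sim <- function() {
    dat <- matrix(0, n_ch, n_t * n_epochs)
    for (src in sources) {
      lf <- lead_field_point(src$location, sensors, head)
      l <- as.numeric(lf$L %*% c(cos(src$orientation), sin(src$orientation)))
      for (comp in src$components) {
        S <- .component_signal(comp, time_ms, sfreq, n_epochs, gain)
        dat <- dat + l %*% t(as.vector(S))
      }
    }
    if (n_background > 0) {
      for (b in seq_len(n_background)) {
        repeat {
          p <- head$center + stats::runif(3, -1, 1) * (head$radius - 15)
          d <- sqrt(sum((p - head$center)^2))
          if (d > 25 && d < head$radius - 15) break
        }
        lf <- lead_field_point(p, sensors, head)
        l <- as.numeric(lf$L %*% c(cos(stats::runif(1, 0, 2 * pi)),
                                   sin(stats::runif(1, 0, 2 * pi))))
        S <- background_amplitude * .pink_noise(n_t, n_epochs, sfreq)
        dat <- dat + l %*% t(as.vector(S))
      }
    }
    if (sensor_noise_sd > 0)
      dat <- dat + stats::rnorm(length(dat), sd = sensor_noise_sd)
    dat
  }
  dat <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())
  if (is.null(labels))
    labels <- rep(paste0("cond", seq_len(n_conditions)), length.out = n_epochs)
  arr <- aperm(array(dat, c(n_ch, n_t, n_epochs)), c(3, 1, 2))
  epoch_set(arr, sfreq, time_ms, labels)
}

#' Default planted sources for the two-cohort study
#'
#' The statistical structure the pipeline is designed to detect: an evoked
#' occipital transient near 100 ms (both groups), ongoing occipital and
#' fusiform induced gamma (60 +/- 10 Hz) whose active-window amplitude is
#' scaled by the subject's gamma gain over 150-650 ms, and a beta-band
#' (12-28 Hz) desynchronization at the occipital pole (both groups).
#'
#' @param gamma_amplitude Baseline induced-gamma dipole moment, nA·m.
#' @param evoked_amplitude Evoked transient dipole moment, nA·m.
#' @return List of `source_spec`s.
#' @export
default_sources <- function(gamma_amplitude = 20, evoked_amplitude = 30) {
  list(
    source_spec(c(36, -86, 2), orientation = 0.4, components = list(
      source_component("induced", freq = 60, bandwidth = 20, onset = 150,
                       offset = 650, amplitude = gamma_amplitude,
                       baseline_amplitude = gamma_amplitude),
      source_component("evoked", freq = 10, onset = 40, offset = 160,
                       amplitude = evoked_amplitude))),
    source_spec(c(32, -57, -3), orientation = 1.1, components = list(
      source_component("induced", freq = 60, bandwidth = 20, onset = 150,
                       offset = 650, amplitude = 0.6 * gamma_amplitude,
                       baseline_amplitude = 0.6 * gamma_amplitude))),
    source_spec(c(0, -96, -6), orientation = 2.0, components = list(
      source_component("desync", freq = 20, bandwidth = 16, onset = 150,
                       offset = 1000, amplitude = 25, factor = 0.5)))
  )
}

#' Specification of a two-cohort synthetic study
#'
#' Defaults reproduce the emulated study's conditions: 13 TD-like and 12
#' ASD-like subjects, 600 epochs over 6 emotion conditions, 248 sensors at
#' 678.17 Hz, AQ distributed 12.33 (6.47) in the TD-like and 38.62 (6.16)
#' in the ASD-like group, and AQ negatively correlated (r = -0.5) with the
#' subject's induced-gamma gain. Group gamma gains default to 2.0 (TD-like:
#' post-stimulus gamma increase) and 0.5 (ASD-like: decrease).
#'
#' @param n_td,n_asd Subjects per group.
#' @param gamma_gain Named multipliers, `c(td = ..., asd = ...)`.
#' @param gain_cv Coefficient of variation of the subject gain around its
#'   group value.
#' @param aq List: `td = c(mean, sd)`, `asd = c(mean, sd)`, `r` (correlation
#'   between AQ and gain, usually negative).
#' @param age List of group means/SDs, months.
#' @param fsiq List of group means/SDs.
#' @param n_epochs,n_conditions Epoch counts (`n_epochs` divisible by
#'   `n_conditions`).
#' @param sfreq Sampling rate, Hz; must exceed twice the highest simulated
#'   frequency.
#' @param window_ms Epoch window.
#' @param n_sensors,shell_radius_mm Sensor layout.
#' @param sensor_noise_sd White sensor-noise SD, tesla.
#' @param n_background,background_amplitude Background dipole noise.
#' @param sources Planted sources ([default_sources()]).
#' @param head Head model.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_td = 13, n_asd = 12,
                        gamma_gain = c(td = 2.0, asd = 0.5), gain_cv = 0.2,
                        aq = list(td = c(12.33, 6.47), asd = c(38.62, 6.16), r = -0.5),
                        age = list(td = c(185, 25), asd = c(185, 25)),
                        fsiq = list(td = c(104, 12), asd = c(104, 12)),
                        n_epochs = 600, n_conditions = 6, sfreq = 678.17,
                        window_ms = c(-1000, 1000), n_sensors = 248,
                        shell_radius_mm = 120, sensor_noise_sd = 3e-14,
                        n_background = 8, background_amplitude = 15,
                        sources = default_sources(), head = head_model()) {
  if (n_epochs %% n_conditions != 0)
    stop("cohort_spec: n_epochs must be divisible by n_conditions")
  fmax <- max(vapply(sources, function(s)
    max(vapply(s$components, function(cc) cc$freq + cc$bandwidth / 2, 0)), 0))
  if (sfreq <= 2 * fmax)
    stop("cohort_spec: sampling_rate must exceed twice the highest simulated frequency")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Scaled-down cohort preset for interactive runs
#'
#' 8 + 8 subjects, 60 epochs, 64 sensors; otherwise the default conditions.
#' @param ... Overrides passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
cohort_spec_demo <- function(...) {
  args <- list(n_td = 8, n_asd = 8, n_epochs = 60, n_sensors = 64)
  user <- list(...)
  args[names(user)] <- user
  do.call(cohort_spec, args)
}

# small random rigid transform (rotation about the head center + translation)
.random_rigid_affine <- function(head, rot_sd_deg = 2, trans_sd_mm = 3) {
  th <- stats::rnorm(3, sd = rot_sd_deg * pi / 180)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  t <- stats::rnorm(3, sd = trans_sd_mm) + head$center - R %*% head$center
  rbind(cbind(R, t), c(0, 0, 0, 1))
}

#' Simulate a two-cohort MEG study
#'
#' Generates per-subject epoch data (via [simulate_epoch_set()]), an
#' MNI-to-subject affine (identity plus a small random rigid perturbation),
#' covariates (AQ, age, FSIQ), and the simulation ground truth. The
#' subject's induced-gamma gain is drawn around the group gain, and AQ is
#' coupled to the gain through a Gaussian copula so that the within-group
#' correlation between AQ and gain equals `spec$aq$r` in expectation
#' (AQ truncated to 0..50).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (whole-cohort determinism).
#' @param signals If FALSE, skip signal generation (covariates, affines and
#'   ground truth only) — used for covariate-level studies at scale.
#' @return List of `subject_record`s, each with fields `subject_id`, `group`
#'   ("td" or "asd"), `epochs`, `affine` (MNI to subject), `covariates`
#'   (AQ, age_months, FSIQ) and `truth` (gamma_gain, source locations).
#' @export
simulate_cohort <- function(spec, seed = 1L, signals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_td + spec$n_asd
  if (spec$n_td < 2 || spec$n_asd < 2)
    stop("simulate_cohort: need at least 2 subjects per group")
  sensors <- build_sensor_array(spec$n_sensors, spec$shell_radius_mm, spec$head)
  groups <- rep(c("td", "asd"), c(spec$n_td, spec$n_asd))
  r <- spec$aq$r
  withr::with_seed(seed, {
    meta <- lapply(seq_len(n_total), function(i) {
      g <- groups[i]
      z_g <- stats::rnorm(1)
      gain <- max(spec$gamma_gain[[g]] * (1 + spec$gain_cv * z_g), 0.05)
      z_a <- r * z_g + sqrt(1 - r^2) * stats::rnorm(1)
      aq <- min(max(spec$aq[[g]][1] + spec$aq[[g]][2] * z_a, 0), 50)
      list(group = g, gain = gain,
           aq = aq,
           age = stats::rnorm(1, spec$age[[g]][1], spec$age[[g]][2]),
           fsiq = stats::rnorm(1, spec$fsiq[[g]][1], spec$fsiq[[g]][2]),
           affine = .random_rigid_affine(spec$head),
           epoch_seed = sample.int(.Machine$integer.max - 1L, 1))
    })
  })
  lapply(seq_len(n_total), function(i) {
    m <- meta[[i]]
    epochs <- NULL
    if (signals) {
      subj_sources <- lapply(spec$sources, function(s) {
        s$location <- warp_point(s$location, m$affine)
        s
      })
      epochs <- simulate_epoch_set(
        subj_sources, sensors, spec$head, n_epochs = spec$n_epochs,
        gain = m$gain, sfreq = spec$sfreq, window_ms = spec$window_ms,
        n_conditions = spec$n_conditions,
        sensor_noise_sd = spec$sensor_noise_sd,
        n_background = spec$n_background,
        background_amplitude = spec$background_amplitude,
        seed = m$epoch_seed)
    }
    structure(list(
      subject_id = sprintf("sub-%02d", i),
      group = m$group,
      epochs = epochs,
      affine = m$affine,
      covariates = list(AQ = m$aq, age_months = m$age, FSIQ = m$fsiq),
      truth = list(gamma_gain = m$gain,
                   source_locations = t(vapply(spec$sources, `[[`, numeric(3),
                                               "location")),
                   epoch_seed = m$epoch_seed)),
      class = "subject_record")
  })
}

#' Simulate a behavioral emotion-recognition table
#'
#' Per subject x condition response times (right-skewed lognormal, ms) and
#' accuracy proportions, with a configurable fraction of planted outliers
#' beyond 2 group SDs.
#'
#' @param cohort List of `subject_record`s.
#' @param rt_model List: per-group mean RT (ms), lognormal `sdlog`,
#'   per-condition additive offsets (ms), `outlier_rate`, per-group accuracy.
#' @param conditions Condition labels (default the six basic emotions).
#' @param seed Integer seed.
#' @return data.frame (subject, group, condition, rt_ms, accuracy).
#' @export
simulate_behavioral <- function(cohort,
                                rt_model = list(mean = c(td = 850, asd = 1050),
                                                sdlog = 0.15,
                                                condition_offset = c(0, -20, 10, 25, 40, -10),
                                                outlier_rate = 0.02,
                                                accuracy = c(td = 0.90, asd = 0.85)),
                                conditions = c("surprise", "happiness", "sadness",
                                               "fear", "anger", "disgust"),
                                seed = 1L) {
  if (length(conditions) != length(rt_model$condition_offset))
    stop("simulate_behavioral: one condition_offset per condition required")
  if (any(rt_model$mean <= 0) || rt_model$sdlog <= 0)
    stop("simulate_behavioral: RT parameters must be positive")
  withr::with_seed(seed, {
    rows <- lapply(cohort, function(s) {
      g <- s$group
      mu <- rt_model$mean[[g]] + rt_model$condition_offset
      rt <- stats::rlnorm(length(conditions),
                          meanlog = log(mu) - rt_model$sdlog^2 / 2,
                          sdlog = rt_model$sdlog)
      out <- stats::runif(length(conditions)) < rt_model$outlier_rate
      rt[out] <- rt[out] * stats::runif(sum(out), 2.2, 3.0)
      acc <- stats::rbinom(length(conditions), 20,
                           rt_model$accuracy[[g]]) / 20
      data.frame(subject = s$subject_id, group = g, condition = conditions,
                 rt_ms = rt, accuracy = acc)
    })
  })
  do.call(rbind, rows)
}
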