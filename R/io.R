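.EPOCH_FORMAT_VERSION <- "1.0"

#' Write / read a subject epoch container
#'
#' Versioned single-file container for one subject: epoch data, time axis,
#' labels, sensor geometry, head model, MNI-to-subject affine and
#' covariates. Serialized with R's native format; the logical schema
#' (field names, shapes, units) is validated on read, and files with an
#' unknown major version are rejected.
#'
#' @param record A `subject_record` (epochs must be present).
#' @param path Output file path.
#' @param sensors The `sensor_array` the data were simulated/recorded with.
#' @param head The `head_model`.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns
#'   the `subject_record` with `sensors`/`head` attached as attributes.
#' @export
write_epochs <- function(record, path, sensors = NULL, head = NULL) {
  stopifnot(inherits(record, "subject_record"))
  if (is.null(record$epochs)) stop("write_epochs: record carries no epochs")
  obj <- list(
    format = "megbeam-epochs", version = .EPOCH_FORMAT_VERSION,
    data = record$epochs$data, sfreq = record$epochs$sfreq,
    time_ms = record$epochs$time_ms, labels = record$epochs$labels,
    rejected = record$epochs$rejected,
    subject_id = record$subject_id, group = record$group,
    affine = record$affine, covariates = record$covariates,
    truth = record$truth,
    sensors = sensors, head = head)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("read_epochs: cannot read '", path, "': ", conditionMessage(e)))
  .validate_epoch_container(obj)
  rec <- structure(list(
    subject_id = obj$subject_id, group = obj$group,
    epochs = epoch_set(obj$data, obj$sfreq, obj$time_ms, obj$labels,
                       obj$rejected),
    affine = obj$affine, covariates = obj$covariates, truth = obj$truth),
    class = "subject_record")
  attr(rec, "sensors") <- obj$sensors
  attr(rec, "head") <- obj$head
  rec
}

.validate_epoch_container <- function(obj) {
  if (!is.list(obj) || !identical(obj$format, "megbeam-epochs"))
    stop("epoch container schema error: not a megbeam epoch container")
  major <- strsplit(as.character(obj$version %||% ""), ".", fixed = TRUE)[[1]][1]
  if (!identical(major, strsplit(.EPOCH_FORMAT_VERSION, ".", fixed = TRUE)[[1]][1]))
    stop("epoch container schema error: unknown format version '",
         obj$version, "'")
  req <- c("data", "sfreq", "time_ms", "labels", "affine", "covariates")
  miss <- setdiff(req, names(obj))
  if (length(miss))
    stop("epoch container schema error: missing dataset(s) ",
         paste(miss, collapse = ", "))
  if (!is.array(obj$data) || length(dim(obj$data)) != 3)
    stop("epoch container schema error: /data must be epochs x channels x samples")
  if (length(obj$time_ms) != dim(obj$data)[3])
    stop("epoch container schema error: /time_ms length mismatch")
  if (length(obj$labels) != dim(obj$data)[1])
    stop("epoch container schema error: /labels length mismatch")
  if (!all(dim(as.matrix(obj$affine)) == c(4, 4)))
    stop("epoch container schema error: /affine must be 4x4")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a 4x4 affine as plain text
#'
#' Four whitespace-delimited rows.
#' @param affine 4x4 matrix.
#' @param path File path.
#' @return The affine (read) or `path` invisibly (write).
#' @export
write_affine <- function(affine, path) {
  utils::write.table(.check_affine(affine), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  .check_affine(as.matrix(utils::read.table(path)))
}

#' Export a statistic map as a NIfTI volume
#'
#' Scatters the grid values into a volume over the grid's bounding box and
#' writes NIfTI with an affine that reproduces the MNI mm coordinate of
#' every grid point, plus a JSON sidecar (band, windows, df, threshold,
#' kind). Voxels off the grid are zero; a `_mask` companion volume encodes
#' significance.
#'
#' @param map A `stat_map`.
#' @param path Output path (".nii" / ".nii.gz").
#' @param write_mask Also write the significance mask volume.
#' @return Invisibly, the NIfTI affine used.
#' @export
write_statmap_nifti <- function(map, path, write_mask = TRUE) {
  stopifnot(inherits(map, "stat_map"))
  sp <- map$grid$spacing
  p <- map$grid$points
  org <- apply(p, 2, min)
  ijk <- round(sweep(p, 2, org) / sp) + 1
  dims <- apply(ijk, 2, max)
  vol <- array(0, dims)
  vol[ijk] <- ifelse(is.finite(map$values), map$values, 0)
  # NIfTI affines map 0-based voxel indices to world mm
  aff <- rbind(cbind(diag(sp, 3), org), c(0, 0, 0, 1))
  as_img <- function(v) {
    img <- RNifti::asNifti(v)
    RNifti::pixdim(img) <- rep(sp, 3)
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::sform(img) <- structure(aff, code = 2L)
    img
  }
  RNifti::writeNifti(as_img(vol), path)
  if (write_mask) {
    mvol <- array(0, dims)
    mvol[ijk] <- as.numeric(map$mask)
    RNifti::writeNifti(as_img(mvol),
                       sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path))
  }
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(kind = map$kind, band = map$band,
                            windows = map$windows, df = map$df,
                            threshold = map$threshold,
                            n_voxels = length(map$values),
                            spacing_mm = sp),
                       sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(aff)
}

#' Write a peak table as CSV
#'
#' Columns x, y, z, region (placeholder), value — the usual published
#' peak-table layout.
#' @param peaks data.frame from [find_peaks()].
#' @param path Output path.
#' @export
write_peak_csv <- function(peaks, path) {
  out <- data.frame(x = peaks$x, y = peaks$y, z = peaks$z,
                    region = rep("", nrow(peaks)), value = peaks$value,
                    sign = peaks$sign)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a time-frequency map (CSV matrix + JSON sidecar)
#'
#' @param map A `tf_map`.
#' @param path Output CSV path; the sidecar replaces the extension with
#'   ".json"; the mask (if any) goes to "_mask.csv".
#' @export
write_tfmap <- function(map, path) {
  stopifnot(inherits(map, "tf_map"))
  m <- map$values
  dimnames(m) <- list(sprintf("%.3f", map$freqs), sprintf("%.2f", map$time_ms))
  utils::write.csv(m, path)
  if (!is.null(map$mask)) {
    mm <- map$mask * 1
    dimnames(mm) <- dimnames(m)
    utils::write.csv(mm, sub("\\.csv$", "_mask.csv", path))
  }
  jsonlite::write_json(list(kind = map$kind, freqs_hz = map$freqs,
                            time_ms = map$time_ms),
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate an analysis configuration
#'
#' YAML (or list) configuration for [run_pipeline()]. Unknown keys are an
#' error; missing keys take defaults. The resolved configuration is written
#' next to the outputs of every run.
#'
#' @param x Path to a YAML file, or a named list of overrides.
#' @return A validated `analysis_config` list.
#' @export
read_analysis_config <- function(x = list()) {
  user <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    seed = 1L,
    n_td = 8L, n_asd = 8L, n_epochs = 60L, n_sensors = 64L,
    grid_spacing = 10, roi_lower = c(-45, -100, -25), roi_upper = c(45, -40, 35),
    regularization = 0.02,
    bands = list(lower = c(3, 30), gamma = c(30, 80)),
    passive = c(-300, -100),
    actives = list(c(50, 250), c(250, 450), c(450, 650)),
    n_permutations_group = 1000L, alpha_group = 0.05,
    n_permutations_between = 300L, alpha_between = 0.001,
    ve_theory_sites = list(c(32, -57, -3)),
    tf_fmin = 4, tf_fmax = 100, tf_fstep = 2, tf_decimate = 4,
    regression_window = c(250, 450), regression_band = c(30, 80),
    per_emotion = FALSE,
    out_dir = NULL)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("read_analysis_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  stopifnot(cfg$grid_spacing > 0, cfg$regularization >= 0,
            cfg$alpha_group > 0, cfg$alpha_group < 1,
            cfg$alpha_between > 0, cfg$alpha_between < 1,
            cfg$n_permutations_group >= 10, cfg$n_permutations_between >= 10)
  structure(cfg, class = "analysis_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end chain: simulate cohort -> DC removal + artifact rejection ->
#' volumetric beamforming (both bands x three active windows) -> per-subject
#' t-to-z -> within-group one-sample permutation maps -> between-groups
#' contrast of contrasts -> VE site selection -> Stockwell evoked/induced
#' decomposition and first-level TF t-maps -> group TF permutation ->
#' backward regression of the mean induced-gamma t on AQ, age and FSIQ.
#' Deterministic given `config$seed`. Artifacts (NIfTI maps, peak CSVs, TF
#' CSVs, JSON reports, resolved config) are written when `config$out_dir`
#' is set.
#'
#' @param config An `analysis_config` (see [read_analysis_config()]).
#' @return A list of results per stage (invisible file manifest attached
#'   when writing outputs).
#' @export
run_pipeline <- function(config = read_analysis_config()) {
  if (!inherits(config, "analysis_config")) config <- read_analysis_config(config)
  t0 <- Sys.time()
  log_stage <- function(name) message(sprintf("[megbeam %6.1fs] %s",
                                              as.numeric(Sys.time() - t0, units = "secs"), name))
  stage <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  head <- head_model()
  sensors <- build_sensor_array(config$n_sensors, head = head)
  spec <- cohort_spec_demo(n_td = config$n_td, n_asd = config$n_asd,
                           n_epochs = config$n_epochs,
                           n_sensors = config$n_sensors, head = head)
  cohort <- stage("simulate", simulate_cohort(spec, seed = config$seed))
  cohort <- stage("preprocess", lapply(cohort, function(s) {
    s$epochs <- reject_artifacts(remove_dc(s$epochs))
    s
  }))
  grid <- crop_grid(build_source_grid(config$grid_spacing, head),
                    config$roi_lower, config$roi_upper)
  wins <- analysis_windows(config$passive, config$actives, config$bands)

  scan_subject <- function(s, band, active, conditions = NULL) {
    ep <- s$epochs
    if (!is.null(conditions)) ep <- subset_conditions(ep, conditions)
    sg <- warp_grid(grid, s$affine)
    lf <- lead_field_matrix(sg, sensors, head)
    m <- scan_volume(ep, lf, band, active, config$passive,
                     regularization = config$regularization)
    m$grid <- grid   # group maps live on the common MNI grid
    m
  }

  results <- list(config = config)
  groups <- vapply(cohort, `[[`, "", "group")
  for (bname in names(config$bands)) {
    band <- config$bands[[bname]]
    for (wi in seq_along(config$actives)) {
      active <- config$actives[[wi]]
      key <- sprintf("%s_w%d", bname, wi)
      scans <- stage(paste("beamform", key),
                     lapply(cohort, scan_subject, band = band, active = active))
      zmaps <- lapply(scans, t_to_z)
      within <- list(
        td = group_onesample(zmaps[groups == "td"],
                             config$n_permutations_group, config$alpha_group,
                             seed = config$seed + 11L),
        asd = group_onesample(zmaps[groups == "asd"],
                              config$n_permutations_group, config$alpha_group,
                              seed = config$seed + 12L))
      between <- stage(paste("between-groups", key),
                       between_groups_contrast(scans[groups == "td"],
                                               scans[groups == "asd"],
                                               config$n_permutations_between,
                                               config$alpha_between,
                                               seed = config$seed + 13L))
      results$volumetric[[key]] <- list(band = band, active = active,
                                        scans = scans, within = within,
                                        between = between)
    }
  }

  # VE sites from the gamma-band 250-450 ms analysis (middle window)
  key_ve <- sprintf("gamma_w%d", min(2, length(config$actives)))
  vres <- results$volumetric[[key_ve]]
  sites <- stage("ve-selection", {
    data_driven <- select_ve_sites(between_map = vres$between)
    mean_peak <- tryCatch(
      select_ve_sites(within_maps = list(vres$within$td$map,
                                         vres$within$asd$map)),
      error = function(e) {
        message("ve-selection: ", conditionMessage(e),
                " (within-group mean-peak site skipped)")
        list()
      })
    c(data_driven, mean_peak,
      select_ve_sites(theory_sites = config$ve_theory_sites))
  })

  results$ve <- stage("ve-tf", lapply(sites, function(site) {
    per_subj <- lapply(cohort, function(s) {
      cov <- covariance(s$epochs, band = NULL,
                        windows = c(list(config$passive), config$actives),
                        regularization = config$regularization)
      w <- place_ve(site, s$affine, sensors, head, cov)
      ve <- reconstruct_trace(w, s$epochs)
      list(evoked = evoked_tf(ve, config$tf_fmin, config$tf_fmax,
                              config$tf_fstep, config$tf_decimate),
           induced = induced_tf(ve, config$tf_fmin, config$tf_fmax,
                                config$tf_fstep, config$tf_decimate),
           first_level = tf_first_level(ve, wins, config$tf_fmin,
                                        config$tf_fmax, config$tf_fstep,
                                        config$tf_decimate))
    })
    list(site = site, per_subject = per_subj,
         group = list(
           td = tf_group_permutation(lapply(per_subj[groups == "td"],
                                            `[[`, "first_level"),
                                     config$n_permutations_group,
                                     config$alpha_group,
                                     seed = config$seed + 21L),
           asd = tf_group_permutation(lapply(per_subj[groups == "asd"],
                                             `[[`, "first_level"),
                                      config$n_permutations_group,
                                      config$alpha_group,
                                      seed = config$seed + 22L)))
  }))

  # regression: mean induced-gamma first-level t in the regression window
  results$regression <- stage("regression", {
    fl <- results$ve[[1]]$per_subject
    y <- vapply(seq_along(cohort), function(i) {
      m <- fl[[i]]$first_level
      sel_f <- m$freqs >= config$regression_band[1] &
               m$freqs <= config$regression_band[2]
      sel_t <- m$time_ms >= config$regression_window[1] &
               m$time_ms <= config$regression_window[2]
      mean(m$values[sel_f, sel_t])
    }, numeric(1))
    X <- data.frame(
      AQ = vapply(cohort, function(s) s$covariates$AQ, 0),
      age = vapply(cohort, function(s) s$covariates$age_months, 0),
      FSIQ = vapply(cohort, function(s) s$covariates$FSIQ, 0))
    backward_regression(y, X)
  })

  if (isTRUE(config$per_emotion)) {
    emos <- sort(unique(cohort[[1]]$epochs$labels))
    results$per_emotion <- stage("per-emotion", lapply(stats::setNames(emos, emos),
      function(em) {
        scans <- lapply(cohort, scan_subject, band = config$bands$gamma,
                        active = config$actives[[min(2, length(config$actives))]],
                        conditions = em)
        between_groups_contrast(scans[groups == "td"], scans[groups == "asd"],
                                config$n_permutations_between,
                                config$alpha_between, seed = config$seed + 31L)
      }))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    yaml::write_yaml(unclass(config), file.path(od, "resolved_config.yaml"))
    for (key in names(results$volumetric)) {
      v <- results$volumetric[[key]]
      write_statmap_nifti(v$between, file.path(od, paste0("between_", key, ".nii")))
      write_peak_csv(find_peaks(v$between), file.path(od, paste0("between_", key, "_peaks.csv")))
      write_statmap_nifti(v$within$td$map, file.path(od, paste0("within_td_", key, ".nii")))
      write_statmap_nifti(v$within$asd$map, file.path(od, paste0("within_asd_", key, ".nii")))
    }
    for (i in seq_along(results$ve)) {
      write_tfmap(results$ve[[i]]$group$td,
                  file.path(od, sprintf("ve%d_group_td.csv", i)))
      write_tfmap(results$ve[[i]]$group$asd,
                  file.path(od, sprintf("ve%d_group_asd.csv", i)))
    }
    reg <- results$regression
    jsonlite::write_json(list(retained = reg$retained,
                              betas = as.list(reg$betas),
                              r_squared = reg$r_squared, f = reg$f,
                              df = reg$df),
                         file.path(od, "regression.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log_stage("done")
  results
}
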