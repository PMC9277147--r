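#' Dice similarity index of two binary masks
#'
#' `2 |A and B| / (|A| + |B|)`; two empty masks are defined as
#' identical (Dice 1), one empty mask against a nonempty one gives 0.
#'
#' @param a,b binary masks on the same grid (any shared dimension).
#' @return Dice value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop_invalid("masks must share the same grid")
  }
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Center-of-mass difference between two BEV projections
#'
#' Euclidean distance (mm) between the silhouette centers of mass of
#' two [bev_project()] results sharing a beam geometry.
#'
#' @param a,b `bev_projection` objects.
#' @return distance, mm.
#' @export
delta_com <- function(a, b) {
  if (!isTRUE(all.equal(a$beam$angle, b$beam$angle))) {
    stop_invalid("projections must share the beam geometry")
  }
  if (anyNA(a$com_silhouette) || anyNA(b$com_silhouette)) {
    stop("undefined-COM: empty silhouette", call. = FALSE)
  }
  sqrt(sum((a$com_silhouette - b$com_silhouette)^2))
}

#' Beam-angle schedule for IMRT or VMAT delivery
#'
#' IMRT uses the six fixed gantry angles 0-150 degrees at 30-degree
#' intervals. VMAT assumes a constant gantry rotation locked 1:1 to the
#' cine frames: 1.5 degrees per frame at 4 Hz (240 sections per full
#' rotation) and 0.75 degrees at 8 Hz (480 sections), i.e. 6 degrees/s;
#' other frame rates require an explicit `angular_interval`.
#'
#' @param mode `"IMRT"` or `"VMAT"`.
#' @param f cine frame rate, Hz (VMAT defaults exist for 4 and 8).
#' @param angular_interval VMAT degrees per frame (overrides the
#'   default).
#' @param start_angle VMAT starting angle, degrees.
#' @return object of class `beam_schedule`.
#' @export
make_schedule <- function(mode = c("IMRT", "VMAT"), f = 4,
                          angular_interval = NULL, start_angle = 0) {
  mode <- match.arg(mode)
  if (mode == "IMRT") {
    sched <- list(mode = mode, angles = seq(0, 150, by = 30), f = f)
  } else {
    if (is.null(angular_interval)) {
      if (!f %in% c(4, 8)) {
        stop_invalid("VMAT defaults exist for f = 4 or 8 Hz; give angular_interval")
      }
      angular_interval <- 6 / f  # constant 6 degrees per second
    }
    sched <- list(mode = mode, angular_interval = angular_interval,
                  start_angle = start_angle,
                  sections = as.integer(round(360 / angular_interval)),
                  f = f)
  }
  structure(sched, class = "beam_schedule")
}

#' Beam angles for a sequence of cine frames
#'
#' @param schedule a [make_schedule()] result.
#' @param frame_numbers 1-based global frame counters.
#' @return for IMRT, the fixed angle set (independent of frames); for
#'   VMAT, one angle per frame, wrapping at 360 degrees.
#' @export
schedule_angles <- function(schedule, frame_numbers) {
  if (schedule$mode == "IMRT") {
    schedule$angles
  } else {
    (schedule$start_angle +
       (frame_numbers - 1) * schedule$angular_interval) %% 360
  }
}

#' Two-tailed Welch t test between two error groups
#'
#' @param errors_a,errors_b numeric vectors (each n >= 2).
#' @return list with `statistic`, `df`, `p_value`. Two degenerate
#'   zero-variance groups with equal means give `p_value = 1`.
#' @export
compare_groups <- function(errors_a, errors_b) {
  if (length(errors_a) < 2 || length(errors_b) < 2) {
    stop_invalid("each group needs n >= 2")
  }
  if (sd(errors_a) == 0 && sd(errors_b) == 0) {
    if (mean(errors_a) == mean(errors_b)) {
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    }
    return(list(statistic = Inf, df = NA_real_, p_value = 0))
  }
  tt <- t.test(errors_a, errors_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

## Truth tumor mask at an arbitrary time of a synthetic waveform: the
## SI position interpolates the per-frame true positions (the actual
## mechanical trajectory including within-cycle irregularity), while
## the hysteresis phase comes from the generating cycle table.
truth_mask_at <- function(config, w2, pos_spline, t) {
  kern <- waveform_truth_at(w2, t)
  pos <- pos_spline(t)
  st <- tumor_state(config, displacement = pos - w2$baseline,
                    u = kern$u, direction = kern$direction)
  ellipsoid_mask(config, st$center, st$semi_axes)
}

#' Run the predict-match-project pipeline on one phantom
#'
#' End-to-end simulation of the predictive BEV cine strategy:
#'
#' 1. generate `n_series` 40-s volume series from the breathing model;
#' 2. extract diaphragm waveforms with the navigator-box method and
#'    build the inhalation/exhalation motion libraries (masks from
#'    automated threshold segmentation by default);
#' 3. b-spline interpolate the extracted waveforms to the cine rate and
#'    run the sliding-window forecaster;
#' 4. for every predicted frame, select the direction-resolved library
#'    entry nearest the predicted amplitude (optionally perturbed by an
#'    injected matching error) and project its tumor mask, and the
#'    ground-truth mask at the frame time, onto the BEV at the
#'    scheduled beam angle(s);
#' 5. score each pair with the silhouette center-of-mass difference and
#'    the 2D (in-plane) and 3D (projected-volume) Dice indices.
#'
#' In `oracle` mode the true (extracted) positions and library
#' direction labels are passed through at the native series rate with
#' truth masks taken from the library itself, so a correct pipeline
#' returns ΔCOM = 0 and Dice = 1 identically.
#'
#' @param model a [waveform_model()].
#' @param config a [phantom_config()].
#' @param rate cine frame rate, Hz (4 or 8; ignored in oracle mode,
#'   which runs at the series rate).
#' @param method forecaster, `"ar"` or `"lstm"`.
#' @param modes beam schedules to evaluate (`"IMRT"`, `"VMAT"` or
#'   both).
#' @param n_series number of 40-s series (default 3).
#' @param duration series length, s.
#' @param swc a [sliding_window_config()].
#' @param matching_error injected matching-error fraction (0 disables).
#' @param segment use threshold segmentation for library masks
#'   (default) or the ground-truth voxel masks.
#' @param grid a [bev_grid()] (default 120-mm extent, 2-mm pixels).
#' @param step_mm slice-stack cut interval, mm.
#' @param order AR order.
#' @param lstm an [lstm_config()].
#' @param oracle logical; run the end-to-end identity mode.
#' @param seed seed for the matching-error draws.
#' @param phantom_id label carried into the records.
#' @return object of class `pipeline_result`: `records` (one row per
#'   prediction frame x angle: `phantom`, `waveform`, `frame_index`,
#'   `time`, `mode`, `angle`, `delta_com`, `dice2d`, `dice3d`,
#'   `dD_prediction`, `dD_matching`, `dD_matched`, `inplane_empty`),
#'   `summary` (mean and SD per mode), `prediction_error` (mean
#'   first-step |error|, mm), `library_sizes`, `method`, `rate`.
#' @export
run_pipeline <- function(model, config, rate = 4, method = "ar",
                         modes = c("IMRT", "VMAT"), n_series = 3,
                         duration = 40,
                         swc = sliding_window_config(),
                         matching_error = 0, segment = TRUE,
                         grid = bev_grid(), step_mm = 2, order = 10,
                         lstm = lstm_config(), oracle = FALSE,
                         seed = 1L, phantom_id = "phantom1") {
  modes <- match.arg(modes, several.ok = TRUE)
  wfs <- lapply(seq_len(n_series) - 1L, function(s) {
    m <- model
    m$seed <- model$seed + 1013L * s
    generate_waveform(m, duration = duration, rate = 2)
  })
  series <- generate_series(config, wfs, n_series = n_series)
  box <- default_navigator_box(config, model)
  ext <- lapply(series, extract_waveform, box = box)
  masks <- if (segment) {
    thr <- mean(config$intensity[c("subdiaphragm", "tumor")])
    lapply(series, function(s) lapply(s$frames, segment_tumor, threshold = thr))
  } else {
    NULL
  }
  lib <- build_libraries(series, ext, masks = masks)
  iso <- colMeans(do.call(rbind, lapply(series, function(s) {
    do.call(rbind, lapply(s$frames, `[[`, "true_tumor_center"))
  })))
  true_pos <- lapply(series, function(s) {
    vapply(s$frames, `[[`, numeric(1), "true_diaphragm_position")
  })
  vs <- config$voxel_size
  rm(series, masks)
  gc(FALSE)

  schedules <- lapply(modes, make_schedule, f = if (oracle) 4 else rate)
  names(schedules) <- modes
  lib_dirs <- lib$entries  # per-(series, frame) direction labels
  recs <- list()
  seed_stream <- if (matching_error > 0) as.integer(seed) else NULL
  global_frame <- 0L
  for (i in seq_along(wfs)) {
    w2 <- ext[[i]]
    # generator truth rides on the synthetic waveform of this series
    w2$cycles <- wfs[[i]]$cycles
    w2$baseline <- wfs[[i]]$baseline
    w2$shape <- wfs[[i]]$shape
    w2$inhale_fraction <- wfs[[i]]$inhale_fraction
    pos_spline <- splinefun(wfs[[i]]$times, true_pos[[i]], method = "fmm")
    wf_rate <- if (oracle) w2$rate else rate
    wi <- if (oracle) w2 else interpolate_waveform(w2, rate)
    ps <- run_sliding_forecast(wi, method = if (oracle) "oracle" else method,
                               swc = swc, order = order, lstm = lstm)
    fs <- ps$first_step
    sid <- sprintf("series%02d", i)
    ser_dirs <- lib_dirs$direction[lib_dirs$series == sid][
      order(lib_dirs$frame_index[lib_dirs$series == sid])]
    for (j in seq_len(nrow(fs))) {
      global_frame <- global_frame + 1L
      tgt <- fs$frame_index[j]
      t_tgt <- wi$times[tgt]
      predicted <- fs$predicted[j]
      if (oracle) {
        pred_dir <- ser_dirs[tgt]
        truth_mask <- NULL  # taken from the matched entry below
      } else {
        prev <- wi$positions[tgt - 1]
        pred_dir <- if (predicted < prev) "inhale"
          else if (predicted > prev) "exhale"
          else waveform_truth_at(w2, t_tgt)$direction
        truth_mask <- truth_mask_at(config, w2, pos_spline, t_tgt)
      }
      m <- match_library(predicted, pred_dir, lib,
                         dD_prediction = fs$truth[j] - predicted)
      if (matching_error > 0) {
        m <- inject_matching_error(m, matching_error, lib,
                                   seed = seed_stream + global_frame)
      }
      matched_mask <- library_mask(lib, m$entry)
      if (oracle) truth_mask <- library_mask(lib, m$entry)
      for (mode in modes) {
        angs <- schedule_angles(schedules[[mode]], global_frame)
        for (ang in angs) {
          beam <- beam_geometry(ang, iso)
          pm <- bev_project(matched_mask, beam, grid, step = step_mm,
                            voxel_size = vs)
          pt <- bev_project(truth_mask, beam, grid, step = step_mm,
                            voxel_size = vs)
          both_empty <- !any(pm$inplane) && !any(pt$inplane)
          recs[[length(recs) + 1]] <- data.frame(
            phantom = phantom_id, waveform = i, frame_index = tgt,
            time = t_tgt, mode = mode, angle = ang,
            delta_com = delta_com(pm, pt),
            dice2d = dice(pm$inplane, pt$inplane),
            dice3d = dice(pm$silhouette, pt$silhouette),
            dD_prediction = m$dD_prediction,
            dD_matching = m$dD_matching,
            dD_matched = m$dD_matched,
            inplane_empty = both_empty,
            method = ps$method, rate = wi$rate,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- do.call(rbind, recs)
  structure(list(records = records,
                 summary = summarize_records(records),
                 prediction_error = mean(abs(records$dD_prediction)),
                 library_sizes = table(lib$entries$direction),
                 displacement_interval = lib$displacement_interval,
                 method = if (oracle) "oracle" else method,
                 rate = if (oracle) 2 else rate),
            class = "pipeline_result")
}

#' Summarize per-frame evaluation records
#'
#' Mean and SD of ΔCOM, 2D Dice and 3D Dice per beam schedule mode.
#'
#' @param records the `records` data frame of a [run_pipeline()] /
#'   [run_cohort()] result.
#' @return data frame with one row per mode.
#' @export
summarize_records <- function(records) {
  do.call(rbind, lapply(split(records, records$mode), function(d) {
    data.frame(mode = d$mode[1], n = nrow(d),
               delta_com_mean = mean(d$delta_com),
               delta_com_sd = sd(d$delta_com),
               dice2d_mean = mean(d$dice2d), dice2d_sd = sd(d$dice2d),
               dice3d_mean = mean(d$dice3d), dice3d_sd = sd(d$dice3d))
  }))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s @ %g Hz: %d records, mean |prediction error| = %.3f mm\n",
              x$method, x$rate, nrow(x$records), x$prediction_error))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the pipeline over a phantom cohort
#'
#' @param cohort a [cohort_config()] list.
#' @param ... passed to [run_pipeline()].
#' @param verbose print per-phantom progress.
#' @return object of class `cohort_result`: pooled `records`,
#'   per-phantom summaries, pooled `summary`, and the cohort mean
#'   first-step prediction error.
#' @export
run_cohort <- function(cohort, ..., verbose = FALSE) {
  results <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    results[[i]] <- run_pipeline(cohort[[i]]$model, cohort[[i]]$config,
                                 phantom_id = sprintf("phantom%d", i),
                                 ...)
    if (verbose) {
      message(sprintf("phantom %d/%d: mean 3D Dice %.3f", i,
                      length(cohort),
                      mean(results[[i]]$records$dice3d)))
    }
    gc(FALSE)
  }
  records <- do.call(rbind, lapply(results, `[[`, "records"))
  structure(list(records = records,
                 summary = summarize_records(records),
                 per_phantom = lapply(results, `[[`, "summary"),
                 prediction_error = mean(abs(records$dD_prediction[
                   !duplicated(paste(records$phantom, records$waveform,
                                     records$frame_index))]))),
            class = "cohort_result")
}
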