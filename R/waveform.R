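#' Navigator box
#'
#' Axis-aligned box (in mm) over the diaphragm dome used to derive the
#' 1D breathing signal from image volumes. The conventional extent is
#' 30 x 30 x 60 mm in LR x AP x SI, with the SI extent spanning the full
#' diaphragm motion range.
#'
#' @param corner_min,corner_max mm triples (LR, AP, SI).
#' @return object of class `navigator_box`.
#' @export
navigator_box <- function(corner_min, corner_max) {
  if (any(corner_max <= corner_min)) {
    stop_invalid("corner_max must exceed corner_min on every axis")
  }
  structure(list(corner_min = corner_min, corner_max = corner_max),
            class = "navigator_box")
}

#' Default navigator box for a phantom
#'
#' Centers a 30 x 30 mm (LR x AP) box on the diaphragm dome apex with an
#' SI extent of at least 60 mm covering the full modeled motion range.
#'
#' @param config a [phantom_config()].
#' @param model the [waveform_model()] whose amplitude sets the SI span.
#' @return a [navigator_box()].
#' @export
default_navigator_box <- function(config, model) {
  half <- c(15, 15)
  span <- max(60, model$amplitude + 20)
  zc <- model$baseline - model$amplitude / 2
  navigator_box(
    corner_min = c(config$dome_center - half, zc - span / 2),
    corner_max = c(config$dome_center + half, zc + span / 2))
}

## Voxel index range whose centers fall inside [lo, hi] mm.
box_index_range <- function(lo, hi, n, voxel_size) {
  i0 <- ceiling(lo / voxel_size) + 1
  i1 <- floor(hi / voxel_size) + 1
  c(max(1, i0), min(n, i1))
}

#' Extract the diaphragm position from one volume frame
#'
#' Averages voxel intensity over the LR x AP extent of the navigator box
#' at each SI level, takes centered differences of the resulting 1D
#' profile, and returns the SI location of the largest absolute
#' gradient. Sub-voxel refinement fits a parabola through the gradient
#' magnitude peak and its two neighbors (switchable off, e.g. to study
#' pure voxel quantization). Equal gradient maxima break toward the most
#' inferior location.
#'
#' @param frame a `volume_frame` (or any list with `intensity` and
#'   `voxel_size`).
#' @param box a [navigator_box()].
#' @param refine logical; parabolic sub-voxel refinement (default TRUE).
#' @return diaphragm SI position, mm.
#' @export
extract_diaphragm <- function(frame, box, refine = TRUE) {
  vs <- frame$voxel_size
  dm <- dim(frame$intensity)
  ir <- Map(function(lo, hi, n) box_index_range(lo, hi, n, vs),
            as.list(box$corner_min), as.list(box$corner_max),
            as.list(dm))
  if (any(vapply(ir, function(r) r[1] > r[2], logical(1)))) {
    stop_invalid("navigator box lies outside the volume grid")
  }
  iz <- ir[[3]][1]:ir[[3]][2]
  if (length(iz) < 3) stop_invalid("navigator box must span >= 3 SI samples")
  sub <- frame$intensity[ir[[1]][1]:ir[[1]][2],
                         ir[[2]][1]:ir[[2]][2], iz, drop = FALSE]
  profile <- apply(sub, 3, mean)
  m <- length(profile)
  grad <- (profile[3:m] - profile[1:(m - 2)]) / 2  # at profile index 2..m-1
  ag <- abs(grad)
  scale <- max(abs(profile))
  if (max(ag) <= 1e-12 * max(scale, 1)) {
    stop("no-edge-found: intensity profile has no gradient peak",
         call. = FALSE)
  }
  k <- which.max(ag)  # which.max returns the first (most inferior) max
  pos_idx <- iz[k + 1]  # global SI voxel index of the peak
  z <- (pos_idx - 1) * vs
  if (refine && k > 1 && k < length(ag)) {
    denom <- ag[k - 1] - 2 * ag[k] + ag[k + 1]
    if (denom < 0) {
      delta <- 0.5 * (ag[k - 1] - ag[k + 1]) / denom
      z <- z + max(-0.5, min(0.5, delta)) * vs
    }
  }
  z
}

#' Extract the breathing waveform from a volume series
#'
#' Applies [extract_diaphragm()] to every frame of a series.
#'
#' @param series a `tr_series`.
#' @param box a [navigator_box()].
#' @param refine passed to [extract_diaphragm()].
#' @return a [breathing_waveform()] with `provenance = "extracted"`.
#' @export
extract_waveform <- function(series, box, refine = TRUE) {
  pos <- vapply(seq_along(series$frames), function(i) {
    tryCatch(extract_diaphragm(series$frames[[i]], box, refine = refine),
             error = function(e) {
               stop(sprintf("frame %d: %s", i, conditionMessage(e)),
                    call. = FALSE)
             })
  }, numeric(1))
  times <- vapply(series$frames, `[[`, numeric(1), "timestamp")
  breathing_waveform(times = times, positions = pos,
                     rate = series$frame_rate, provenance = "extracted")
}

#' Resample a waveform to a higher cine frame rate
#'
#' Fits a cubic b-spline interpolant through the original samples and
#' resamples it uniformly at `target_rate`, producing
#' `duration * target_rate` points (the original samples are reproduced
#' exactly; the final partial frame period beyond the last original
#' sample is filled by the end cubic). The generator truth (cycle table)
#' of a synthetic source waveform is carried through so ground truth
#' remains queryable at the new times.
#'
#' @param w a [breathing_waveform()] with at least 4 points.
#' @param target_rate target rate, Hz; must be a positive integer
#'   multiple of `w$rate`.
#' @return a [breathing_waveform()] with `provenance = "interpolated"`
#'   (or `w` unchanged when `target_rate == w$rate`).
#' @export
interpolate_waveform <- function(w, target_rate) {
  if (target_rate <= 0) stop_invalid("target_rate must be > 0")
  m <- target_rate / w$rate
  if (abs(m - round(m)) > 1e-9) {
    stop_invalid("target_rate must be an integer multiple of the waveform rate")
  }
  m <- as.integer(round(m))
  if (m == 1L) return(w)
  if (length(w$positions) < 4) stop_invalid("waveform must have >= 4 points")
  sf <- splinefun(w$times, w$positions, method = "fmm")
  n_out <- length(w$positions) * m
  times <- w$times[1] + (seq_len(n_out) - 1) / target_rate
  breathing_waveform(times = times, positions = sf(times),
                     rate = target_rate, provenance = "interpolated",
                     cycles = w$cycles, baseline = w$baseline,
                     shape = w$shape,
                     inhale_fraction = w$inhale_fraction)
}

#' Add range-scaled uniform noise to a waveform
#'
#' Perturbs every sample with zero-mean uniform noise of half-width
#' `percent * (max - min)` of the waveform, the robustness model for
#' imperfect surrogate signals.
#'
#' @param w a [breathing_waveform()].
#' @param percent noise fraction (>= 0); e.g. 0.02 for the 2% check.
#' @param seed integer seed.
#' @return a [breathing_waveform()] with `provenance = "noisy"`.
#' @export
add_waveform_noise <- function(w, percent, seed = 1L) {
  if (percent < 0) stop_invalid("percent must be >= 0")
  if (percent == 0) return(w)
  hw <- percent * (max(w$positions) - min(w$positions))
  pos <- with_seed(seed,
                   w$positions + runif(length(w$positions), -hw, hw))
  breathing_waveform(times = w$times, positions = pos, rate = w$rate,
                     provenance = "noisy", cycles = w$cycles,
                     baseline = w$baseline, shape = w$shape,
                     inhale_fraction = w$inhale_fraction)
}

#' Read / write waveform files
#'
#' Waveforms are stored as 2-column delimited text with header
#' `time_s`, `position_mm`.
#'
#' @param w a [breathing_waveform()].
#' @param path file path.
#' @param rate frame rate of the stored waveform, Hz; inferred from the
#'   time column when `NULL`.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns a [breathing_waveform()].
#' @export
write_waveform <- function(w, path) {
  write.table(data.frame(time_s = w$times, position_mm = w$positions),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path, rate = NULL) {
  d <- read.table(path, header = TRUE, sep = "\t")
  if (is.null(rate)) {
    dt <- diff(d$time_s)
    rate <- 1 / stats::median(dt)
  }
  breathing_waveform(times = d$time_s, positions = d$position_mm,
                     rate = rate, provenance = "extracted")
}
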