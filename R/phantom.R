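#' Respiratory waveform model
#'
#' Parameterizes the breathing kernel used by the synthetic phantom:
#' `position(t) = baseline - A_k * cos^(2n)(pi * (t - t_k)/tau_k + pi/2)`
#' within breathing cycle k. The even cosine power concentrates time near
#' the baseline (end-exhale), reproducing the longer dwell in exhalation
#' seen in free-breathing subjects, while the trough at mid-cycle is full
#' inhale (diaphragm displaced inferior by the cycle amplitude). Cycle
#' amplitude and period are resampled per cycle (uniform jitter) to
#' emulate cycle-to-cycle breathing irregularity, and zero-mean Gaussian
#' noise models within-cycle irregularity of the diaphragm trajectory.
#'
#' @param baseline diaphragm SI rest (end-exhale) position, mm.
#' @param amplitude peak-to-trough motion range A, mm (>= 0; 0 gives a
#'   degenerate flat waveform).
#' @param period mean breathing period tau, s.
#' @param shape positive integer n of the `cos^(2n)` kernel; larger n
#'   lengthens the end-exhale dwell.
#' @param inhale_fraction fraction of each cycle spent inhaling
#'   (descending limb). The default 0.45 encodes the usual
#'   inspiration:expiration time asymmetry, so direction-classified
#'   frame libraries show the expected exhalation excess; 0.5 gives a
#'   time-symmetric cycle.
#' @param amplitude_jitter,period_jitter per-cycle uniform jitter
#'   fractions in `[0, 0.5]`.
#' @param noise_sd per-sample Gaussian noise, mm.
#' @param seed integer seed; identical seeds give identical waveforms.
#' @return an object of class `waveform_model`.
#' @export
waveform_model <- function(baseline = 140, amplitude = 16, period = 4,
                           shape = 2, inhale_fraction = 0.45,
                           amplitude_jitter = 0.05,
                           period_jitter = 0.05, noise_sd = 0.2,
                           seed = 1L) {
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  if (period <= 0) stop_invalid("period must be > 0")
  if (shape < 1 || shape != round(shape)) {
    stop_invalid("shape must be a positive integer")
  }
  for (j in c(amplitude_jitter, period_jitter)) {
    if (j < 0 || j > 0.5) stop_invalid("jitter fractions must lie in [0, 0.5]")
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (inhale_fraction <= 0 || inhale_fraction >= 1) {
    stop_invalid("inhale_fraction must lie in (0, 1)")
  }
  structure(
    list(baseline = baseline, amplitude = amplitude, period = period,
         shape = as.integer(shape), inhale_fraction = inhale_fraction,
         amplitude_jitter = amplitude_jitter,
         period_jitter = period_jitter, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "waveform_model")
}

#' Construct a breathing waveform object
#'
#' @param times sample times, s (uniformly spaced).
#' @param positions diaphragm SI positions, mm.
#' @param rate frame rate, Hz.
#' @param provenance one of `"synthetic"`, `"extracted"`,
#'   `"interpolated"`, `"noisy"`.
#' @param ... further fields carried along (generator truth, cycles).
#' @return an object of class `breathing_waveform` with fields `times`,
#'   `positions`, `rate`, `provenance`.
#' @export
breathing_waveform <- function(times, positions, rate, provenance,
                               ...) {
  if (length(times) != length(positions)) {
    stop_invalid("times and positions must have equal length")
  }
  if (any(!is.finite(positions))) stop_invalid("positions must be finite")
  structure(list(times = times, positions = positions, rate = rate,
                 provenance = provenance, ...),
            class = "breathing_waveform")
}

#' @export
print.breathing_waveform <- function(x, ...) {
  cat(sprintf("<breathing_waveform> %d points @ %g Hz (%s), range %.2f-%.2f mm\n",
              length(x$positions), x$rate, x$provenance,
              min(x$positions), max(x$positions)))
  invisible(x)
}

## Piecewise cycle table covering [0, duration]; one row per cycle.
wf_cycles <- function(model, duration) {
  starts <- taus <- amps <- numeric(0)
  t0 <- 0
  while (t0 <= duration) {
    tau <- model$period *
      (1 + runif(1, -model$period_jitter, model$period_jitter))
    amp <- model$amplitude *
      (1 + runif(1, -model$amplitude_jitter, model$amplitude_jitter))
    starts <- c(starts, t0)
    taus <- c(taus, tau)
    amps <- c(amps, amp)
    t0 <- t0 + tau
  }
  data.frame(start = starts, tau = taus, amplitude = amps)
}

## Evaluate the noiseless kernel (position, normalized displacement u,
## phase direction) at arbitrary times from a cycle table. The cycle
## phase is time-warped so a fraction rho of each cycle is spent on the
## descending (inhale) limb (trough at time fraction rho).
wf_kernel_at <- function(cycles, baseline, shape, t, rho = 0.45) {
  k <- findInterval(t, cycles$start)
  k[k < 1] <- 1L
  tf <- (t - cycles$start[k]) / cycles$tau[k]  # cycle time fraction
  s <- ifelse(tf < rho, tf / (2 * rho),
              0.5 + (tf - rho) / (2 * (1 - rho)))
  x <- pi * s + pi / 2
  u <- cos(x)^(2 * shape)
  list(position = baseline - cycles$amplitude[k] * u,
       u = u,
       direction = ifelse(s %% 1 < 0.5, "inhale", "exhale"))
}

#' Generate a synthetic diaphragm breathing waveform
#'
#' Samples the `cos^(2n)` breathing kernel of a [waveform_model()] at a
#' uniform frame rate. Inhalation moves the diaphragm inferior
#' (decreasing SI coordinate) from the baseline by up to the cycle
#' amplitude. The returned waveform carries the generating truth
#' (noiseless kernel position, normalized displacement, phase direction)
#' and the per-cycle table so downstream code can query ground truth at
#' arbitrary times via [waveform_truth_at()].
#'
#' @param model a [waveform_model()].
#' @param duration scan length, s.
#' @param rate frame rate, Hz.
#' @return a [breathing_waveform()] with `provenance = "synthetic"` and
#'   extra fields `truth` (data frame: position, u, direction),
#'   `cycles`, `baseline`, `shape`.
#' @export
generate_waveform <- function(model, duration = 40, rate = 2) {
  if (!inherits(model, "waveform_model")) stop_invalid("model must be a waveform_model")
  if (duration <= 0 || rate <= 0) stop_invalid("duration and rate must be > 0")
  n <- as.integer(round(duration * rate))
  if (n < 2) stop_invalid("duration * rate must be >= 2")
  times <- (seq_len(n) - 1) / rate
  with_seed(model$seed, {
    cycles <- wf_cycles(model, duration)
    kern <- wf_kernel_at(cycles, model$baseline, model$shape, times,
                         rho = model$inhale_fraction)
    noise <- if (model$noise_sd > 0) rnorm(n, 0, model$noise_sd) else numeric(n)
    breathing_waveform(
      times = times, positions = kern$position + noise, rate = rate,
      provenance = "synthetic",
      truth = data.frame(position = kern$position, u = kern$u,
                         direction = kern$direction,
                         stringsAsFactors = FALSE),
      cycles = cycles, baseline = model$baseline, shape = model$shape,
      inhale_fraction = model$inhale_fraction, model = model)
  })
}

#' Ground-truth breathing state at arbitrary times
#'
#' Evaluates the noiseless generating kernel of a synthetic waveform
#' (or one interpolated from it) at the requested times.
#'
#' @param w a synthetic [breathing_waveform()] carrying its cycle table.
#' @param t times, s.
#' @return list with `position` (mm), `u` (normalized displacement in
#'   `[0,1]`), `direction` (`"inhale"`/`"exhale"`).
#' @export
waveform_truth_at <- function(w, t) {
  if (is.null(w$cycles)) {
    stop_invalid("waveform carries no generator truth (not synthetic)")
  }
  wf_kernel_at(w$cycles, w$baseline, w$shape, t,
               rho = w$inhale_fraction %||% 0.45)
}

#' Phantom geometry and intensity configuration
#'
#' Describes the digital breathing thorax: a dark lung compartment above
#' a bright sub-diaphragmatic compartment separated by a (gently curved)
#' diaphragm dome whose apex follows the breathing waveform, plus an
#' ellipsoidal tumor whose SI position is coupled to the diaphragm and
#' whose AP position traces a direction-dependent (hysteretic) loop.
#'
#' The hysteresis loop: with normalized displacement `u` in `[0,1]`
#' (0 = end-exhale, 1 = full inhale) the tumor AP center is
#' `rest_AP + s * h * g(u)` where `g(u) = sqrt(u * (1 - u))` and
#' `s = +1` on the exhale branch, `-1` on inhale. The inhale/exhale AP
#' separation at equal SI displacement is thus `2 h g(u)`, peaking at
#' the configured `hysteresis_width` h at mid-displacement.
#'
#' @param grid_shape voxels per axis, (LR, AP, SI).
#' @param voxel_size isotropic voxel size, mm.
#' @param tumor_semi_axes ellipsoid semi-axes, mm (LR, AP, SI).
#' @param tumor_rest_center tumor center at end-exhale, mm (LR, AP, SI).
#' @param tumor_si_coupling fraction of diaphragm SI motion transferred
#'   to the tumor.
#' @param hysteresis_width maximal AP separation h between inhale and
#'   exhale paths at equal SI displacement, mm.
#' @param shape_modulation optional fraction for phase-dependent
#'   isotropic tumor scaling (0 disables).
#' @param dome_center (LR, AP) position of the diaphragm dome apex, mm.
#' @param dome_curvature quadratic dome droop, mm^-1 (0 gives a flat
#'   diaphragm).
#' @param intensity named vector of intensity levels for `lung`,
#'   `subdiaphragm` and `tumor` compartments.
#' @param image_noise_sd Gaussian image noise, intensity units.
#' @param seed integer seed for the image noise.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64), voxel_size = 5,
                           tumor_semi_axes = c(15, 12, 18),
                           tumor_rest_center = c(160, 200, 190),
                           tumor_si_coupling = 0.9,
                           hysteresis_width = 3,
                           shape_modulation = 0,
                           dome_center = c(160, 160),
                           dome_curvature = 0.001,
                           intensity = c(lung = 20, subdiaphragm = 100,
                                         tumor = 160),
                           image_noise_sd = 2, seed = 1L) {
  if (voxel_size <= 0) stop_invalid("voxel_size must be > 0")
  if (hysteresis_width < 0) stop_invalid("hysteresis_width must be >= 0")
  if (any(tumor_semi_axes <= 0)) stop_invalid("tumor_semi_axes must be > 0")
  if (length(grid_shape) != 3) stop_invalid("grid_shape must have 3 axes")
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         tumor_semi_axes = tumor_semi_axes,
         tumor_rest_center = tumor_rest_center,
         tumor_si_coupling = tumor_si_coupling,
         hysteresis_width = hysteresis_width,
         shape_modulation = shape_modulation,
         dome_center = dome_center, dome_curvature = dome_curvature,
         intensity = intensity, image_noise_sd = image_noise_sd,
         seed = as.integer(seed)),
    class = "phantom_config")
}

## mm coordinates of voxel centers along one axis (voxel i at (i-1)*vs).
grid_axis <- function(n, voxel_size) (seq_len(n) - 1) * voxel_size

## Tumor state (center mm, semi-axes mm) for a breathing state.
tumor_state <- function(config, displacement, u, direction) {
  s <- ifelse(direction == "exhale", 1, -1)
  g <- sqrt(pmax(u * (1 - u), 0))
  center <- config$tumor_rest_center +
    c(0, s * config$hysteresis_width * g,
      config$tumor_si_coupling * displacement)
  scale <- 1 + config$shape_modulation * s * 2 * g
  list(center = center, semi_axes = config$tumor_semi_axes * scale)
}

## Voxelize an ellipsoid by the inequality test at voxel centers.
ellipsoid_mask <- function(config, center, semi_axes) {
  gs <- config$grid_shape
  vs <- config$voxel_size
  lo <- center - semi_axes
  hi <- center + semi_axes
  if (any(lo < 0) || any(hi > (gs - 1) * vs)) {
    stop("invalid-configuration: tumor leaves the phantom grid",
         call. = FALSE)
  }
  qx <- ((grid_axis(gs[1], vs) - center[1]) / semi_axes[1])^2
  qy <- ((grid_axis(gs[2], vs) - center[2]) / semi_axes[2])^2
  qz <- ((grid_axis(gs[3], vs) - center[3]) / semi_axes[3])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= 1
}

## Intensity volume: lung everywhere, partial-volume bright compartment
## below the dome surface, tumor level inside the mask.
phantom_intensity <- function(config, dome_apex_z, tumor_mask) {
  gs <- config$grid_shape
  vs <- config$voxel_size
  lev <- config$intensity
  xs <- grid_axis(gs[1], vs)
  ys <- grid_axis(gs[2], vs)
  zs <- grid_axis(gs[3], vs)
  r2 <- outer((xs - config$dome_center[1])^2,
              (ys - config$dome_center[2])^2, `+`)
  zd <- dome_apex_z - config$dome_curvature * r2   # dome surface z(x, y)
  vol <- array(lev[["lung"]], dim = gs)
  for (k in seq_len(gs[3])) {
    frac <- pmin(pmax((zd - zs[k] + vs / 2) / vs, 0), 1)
    vol[, , k] <- lev[["lung"]] +
      (lev[["subdiaphragm"]] - lev[["lung"]]) * frac
  }
  vol[tumor_mask] <- lev[["tumor"]]
  vol
}

#' Generate one phantom volume frame
#'
#' @param config a [phantom_config()].
#' @param position diaphragm SI position (dome apex), mm.
#' @param displacement diaphragm displacement from baseline, mm
#'   (negative toward inhale).
#' @param u normalized displacement in `[0,1]`.
#' @param direction `"inhale"` or `"exhale"` (generating phase).
#' @param timestamp frame time, s.
#' @param noise logical; add image noise (drawn from the current RNG
#'   stream; [generate_series()] seeds it).
#' @return an object of class `volume_frame` with fields `intensity`,
#'   `tumor_mask`, `true_diaphragm_position`, `true_phase_direction`,
#'   `true_tumor_center`, `timestamp`, `voxel_size`, `grid_shape`.
#' @export
generate_frame <- function(config, position, displacement, u, direction,
                           timestamp = 0, noise = TRUE) {
  st <- tumor_state(config, displacement, u, direction)
  mask <- ellipsoid_mask(config, st$center, st$semi_axes)
  if (!any(mask)) stop("invalid-configuration: empty tumor mask", call. = FALSE)
  vol <- phantom_intensity(config, position, mask)
  if (noise && config$image_noise_sd > 0) {
    vol <- vol + array(rnorm(length(vol), 0, config$image_noise_sd),
                       dim = dim(vol))
  }
  structure(
    list(intensity = vol, tumor_mask = mask,
         true_diaphragm_position = position,
         true_phase_direction = direction,
         true_tumor_center = st$center,
         timestamp = timestamp,
         voxel_size = config$voxel_size,
         grid_shape = config$grid_shape),
    class = "volume_frame")
}

#' Generate time-resolved 4D phantom series
#'
#' Builds `n_series` ordered volume series (one [generate_frame()] per
#' waveform sample). The diaphragm dome apex follows the waveform
#' position; the tumor SI center is `rest + coupling * (position -
#' baseline)` and its AP center traces the hysteresis loop of the
#' generating phase (recorded, not inferred from finite differences).
#'
#' @param config a [phantom_config()].
#' @param waveform a synthetic [breathing_waveform()], or a list of
#'   `n_series` of them (one per series; a single waveform is reused).
#' @param n_series number of series.
#' @return list of `tr_series` objects (fields `frames`, `frame_rate`,
#'   `series_id`, `voxel_size`, `grid_shape`).
#' @export
generate_series <- function(config, waveform, n_series = 3) {
  wfs <- if (inherits(waveform, "breathing_waveform")) {
    rep(list(waveform), n_series)
  } else {
    if (length(waveform) != n_series) {
      stop_invalid("need one waveform (or one per series)")
    }
    waveform
  }
  lapply(seq_len(n_series), function(s) {
    w <- wfs[[s]]
    if (is.null(w$truth)) {
      stop_invalid("generate_series needs a synthetic waveform with truth")
    }
    frames <- with_seed(config$seed + 7919L * s, {
      lapply(seq_along(w$times), function(i) {
        generate_frame(
          config,
          position = w$positions[i],
          displacement = w$positions[i] - w$baseline,
          u = w$truth$u[i],
          direction = w$truth$direction[i],
          timestamp = w$times[i])
      })
    })
    structure(list(frames = frames, frame_rate = w$rate,
                   series_id = sprintf("series%02d", s),
                   voxel_size = config$voxel_size,
                   grid_shape = config$grid_shape),
              class = "tr_series")
  })
}

#' @export
print.tr_series <- function(x, ...) {
  cat(sprintf("<tr_series> %s: %d frames @ %g Hz, %s voxels @ %g mm\n",
              x$series_id, length(x$frames), x$frame_rate,
              paste(x$grid_shape, collapse = "x"), x$voxel_size))
  invisible(x)
}

#' Study-cohort phantom configurations
#'
#' Defines the eight-subject synthetic cohort used throughout the
#' package's evaluation runs: per-subject diaphragm motion amplitudes of
#' 15.8, 12.9, 20.7, 14.4, 9.6, 15.8, 11.6 and 29.1 mm (the observed
#' free-breathing diaphragm excursions the phantom emulates), breathing
#' periods between 2 and 4 s (subject 2 at 2.0 s and subject 7 at
#' 40/17 s, matching their observed 20 and 17 cycles per 40-s scan),
#' 5-10% per-cycle amplitude/period jitter, and hysteresis widths
#' spanning 2-4 mm.
#'
#' @param n number of phantoms (<= 8).
#' @param seed base seed; per-phantom seeds are derived from it.
#' @return list of length `n`; each element has `model`
#'   ([waveform_model()]) and `config` ([phantom_config()]).
#' @export
cohort_config <- function(n = 8, seed = 1L) {
  if (n < 1 || n > 8) stop_invalid("cohort defines up to 8 phantoms")
  amplitudes <- c(15.8, 12.9, 20.7, 14.4, 9.6, 15.8, 11.6, 29.1)
  periods <- c(3.2, 2.0, 4.0, 3.5, 2.8, 4.4, 40 / 17, 3.0)
  amp_jit <- seq(0.05, 0.10, length.out = 8)
  per_jit <- rev(seq(0.05, 0.10, length.out = 8))
  hyst <- seq(2, 4, length.out = 8)
  lapply(seq_len(n), function(i) {
    list(model = waveform_model(amplitude = amplitudes[i],
                                period = periods[i],
                                amplitude_jitter = amp_jit[i],
                                period_jitter = per_jit[i],
                                seed = as.integer(seed) * 101L + i),
         config = phantom_config(hysteresis_width = hyst[i],
                                 seed = as.integer(seed) * 211L + i))
  })
}
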