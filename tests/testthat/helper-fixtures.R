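# Shared fixtures: a small (32^3) phantom keeps per-test volume
# generation cheap while preserving all geometric relations of the
# default 64^3 phantom (dome below, tumor in lung, navigator box clear
# of the tumor in AP).

small_model <- function(...) {
  defaults <- list(baseline = 70, amplitude = 12, period = 4, seed = 11L)
  do.call(waveform_model, utils::modifyList(defaults, list(...)))
}

small_config <- function(...) {
  defaults <- list(grid_shape = c(32, 32, 32), voxel_size = 5,
                   tumor_semi_axes = c(12, 10, 14),
                   tumor_rest_center = c(80, 110, 100),
                   dome_center = c(80, 80), seed = 3L)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# One noise-free small series + extracted waveform, built once per
# test run and cached.
.fixture_env <- new.env(parent = emptyenv())

small_series_noisefree <- function() {
  if (is.null(.fixture_env$ser)) {
    m <- small_model(noise_sd = 0)
    w <- generate_waveform(m, duration = 20, rate = 2)
    .fixture_env$model <- m
    .fixture_env$wf <- w
    .fixture_env$ser <- generate_series(small_config(image_noise_sd = 0),
                                        w, n_series = 1)[[1]]
  }
  list(model = .fixture_env$model, wf = .fixture_env$wf,
       series = .fixture_env$ser, config = small_config(image_noise_sd = 0))
}

# Independent pure-R trilinear sampler + dense-ray max projection,
# used as the brute-force oracle for BEV silhouettes.
ref_trilinear <- function(vol, p) {
  d <- dim(vol)
  x0 <- floor(p[1]); y0 <- floor(p[2]); z0 <- floor(p[3])
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xx <- x0 + dx; yy <- y0 + dy; zz <- z0 + dz
    if (xx >= 0 && xx < d[1] && yy >= 0 && yy < d[2] &&
        zz >= 0 && zz < d[3]) {
      wgt <- (if (dx) p[1] - x0 else 1 - (p[1] - x0)) *
        (if (dy) p[2] - y0 else 1 - (p[2] - y0)) *
        (if (dz) p[3] - z0 else 1 - (p[3] - z0))
      acc <- acc + wgt * vol[xx + 1, yy + 1, zz + 1]
    }
  }
  acc
}

ref_max_projection <- function(mask, angle, iso, grid, voxel_size,
                               w_range, w_step = 0.5) {
  b <- bev_basis(angle)
  vol <- mask * 1
  out <- matrix(FALSE, length(grid$u), length(grid$v))
  ws <- seq(-w_range, w_range, by = w_step)
  for (i in seq_along(grid$u)) for (j in seq_along(grid$v)) {
    for (d in ws) {
      p <- (iso + grid$u[i] * b$u + grid$v[j] * b$v + d * b$w) / voxel_size
      if (ref_trilinear(vol, p) >= 0.5) {
        out[i, j] <- TRUE
        break
      }
    }
  }
  out
}

# Minimal fake series for library tests: frames carry only a tiny mask
# and a timestamp, which is all build_libraries touches.
fake_series <- function(positions, id = "series01", rate = 2) {
  frames <- lapply(seq_along(positions), function(i) {
    list(tumor_mask = array(i, dim = c(1, 1, 1)),
         timestamp = (i - 1) / rate)
  })
  structure(list(frames = frames, frame_rate = rate, series_id = id,
                 voxel_size = 5, grid_shape = c(1, 1, 1)),
            class = "tr_series")
}
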