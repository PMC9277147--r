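#' Write / read phantom volumes as NIfTI
#'
#' Volumes and masks are exchanged in NIfTI format with the voxel size
#' encoded in the affine (mm grid, axis order LR, AP, SI).
#'
#' @param frame a `volume_frame`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param what `"intensity"` or `"mask"`.
#' @return `write_frame_nifti` returns `path` invisibly;
#'   `read_frame_nifti` returns a list with `data` (3D array) and
#'   `voxel_size`.
#' @export
write_frame_nifti <- function(frame, path, what = c("intensity", "mask")) {
  what <- match.arg(what)
  arr <- if (what == "intensity") frame$intensity else frame$tumor_mask * 1
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- rep(frame$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_frame_nifti
#' @export
read_frame_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_size = RNifti::pixdim(img)[1])
}

#' Write a whole series as one NIfTI file per frame
#'
#' @param series a `tr_series`.
#' @param dir output directory (created if missing).
#' @param what `"intensity"` or `"mask"`.
#' @return character vector of file paths, invisibly.
#' @export
write_series_nifti <- function(series, dir, what = "intensity") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_along(series$frames), function(i) {
    p <- file.path(dir, sprintf("%s_frame%03d.nii.gz", series$series_id, i))
    write_frame_nifti(series$frames[[i]], p, what = what)
    p
  }, character(1))
  invisible(paths)
}

#' Read a run configuration file
#'
#' YAML configuration with optional top-level blocks `waveform`
#' (fields of [waveform_model()]), `phantom` ([phantom_config()]),
#' `navigator` (`corner_min`, `corner_max`), and `run` (fields of
#' [run_pipeline()]: `rate`, `method`, `modes`, `matching_error`, ...).
#'
#' @param path YAML file path.
#' @return list with `model`, `config`, `box` (or `NULL`), `run`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  model <- do.call(waveform_model, y$waveform %||% list())
  config <- do.call(phantom_config, y$phantom %||% list())
  box <- if (!is.null(y$navigator)) {
    navigator_box(unlist(y$navigator$corner_min),
                  unlist(y$navigator$corner_max))
  }
  list(model = model, config = config, box = box,
       run = y$run %||% list())
}
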