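#' Beam geometry
#'
#' The gantry rotates about the patient's long (SI) axis. At gantry
#' angle 0 the beam axis lies along AP and the BEV plane is coronal
#' (contains LR and SI); at 90 degrees it is sagittal.
#'
#' @param angle gantry angle theta in degrees (normalized to
#'   `[0, 360)`).
#' @param isocenter mm triple (LR, AP, SI).
#' @return object of class `beam_geometry`.
#' @export
beam_geometry <- function(angle, isocenter) {
  structure(list(angle = angle %% 360, isocenter = isocenter),
            class = "beam_geometry")
}

#' Orthonormal BEV basis for a gantry angle
#'
#' Returns the right-handed triple `(u, v, w)` in (LR, AP, SI)
#' components: beam axis `w = (sin theta, cos theta, 0)`, vertical BEV
#' axis `v` along SI, and lateral BEV axis `u = v x w =
#' (-cos theta, sin theta, 0)`. At theta = 0 the beam axis lies along
#' AP and `u` along the LR axis (pointing to -LR; the sign is a fixed
#' in-plane mirror applied consistently everywhere, so overlap and COM
#' metrics are unaffected).
#'
#' @param angle gantry angle, degrees.
#' @return list with unit vectors `u`, `v`, `w`.
#' @export
bev_basis <- function(angle) {
  th <- angle * pi / 180
  w <- c(sin(th), cos(th), 0)
  v <- c(0, 0, 1)
  u <- c(v[2] * w[3] - v[3] * w[2],
         v[3] * w[1] - v[1] * w[3],
         v[1] * w[2] - v[2] * w[1])
  list(u = u, v = v, w = w)
}

#' BEV sampling grid
#'
#' Square pixel grid in the BEV plane, centered on the beam isocenter.
#'
#' @param extent full width of the grid, mm.
#' @param pixel_size pixel size, mm (default 2, consistent with the
#'   2-mm cut interval of the slice stack).
#' @return object of class `bev_grid` with pixel-center coordinate
#'   vectors `u` and `v` (mm, relative to the isocenter).
#' @export
bev_grid <- function(extent = 120, pixel_size = 2) {
  if (pixel_size <= 0) stop_invalid("pixel_size must be > 0")
  half <- extent / 2
  cc <- seq(-half, half, by = pixel_size)
  structure(list(u = cc, v = cc, pixel_size = pixel_size),
            class = "bev_grid")
}

## Sample a 3D mask on BEV planes at the given offsets along w.
## Returns an (nu x nv x n_offsets) logical array.
bev_sample <- function(mask, beam, grid, offsets, voxel_size) {
  basis <- bev_basis(beam$angle)
  nu <- length(grid$u)
  nv <- length(grid$v)
  uu <- rep(grid$u, times = nv)
  vv <- rep(grid$v, each = nu)
  base <- cbind(uu, uu, uu) * rep(basis$u, each = nu * nv) +
    cbind(vv, vv, vv) * rep(basis$v, each = nu * nv)
  base <- sweep(base, 2, beam$isocenter, `+`)
  pts <- do.call(rbind, lapply(offsets, function(d) {
    base + rep(d * basis$w, each = nu * nv)
  }))
  vals <- sample_trilinear(as.numeric(mask), dim(mask),
                           pts / voxel_size)
  array(vals >= 0.5, dim = c(nu, nv, length(offsets)))
}

## Signed offsets along the beam axis of the occupied mask extent,
## anchored so that one plane passes through the isocenter.
slice_offsets <- function(mask, beam, step, voxel_size) {
  idx <- which(mask)
  if (length(idx) == 0) {
    stop("empty-input: mask has no foreground voxels", call. = FALSE)
  }
  w <- bev_basis(beam$angle)$w
  ai <- arrayInd(idx, dim(mask))
  dw <- (ai - 1) %*% (w * voxel_size) -
    sum(w * beam$isocenter)
  dmin <- min(dw) - voxel_size / 2
  dmax <- max(dw) + voxel_size / 2
  ks <- seq(ceiling(dmin / step), floor(dmax / step))
  if (length(ks) == 0) (dmin + dmax) / 2 else ks * step
}

#' Cut a 3D mask into a stack of BEV-parallel slices
#'
#' Resamples the mask onto planes orthogonal to the beam axis, spaced
#' `step` mm apart and spanning the mask's occupied extent along the
#' beam (one plane is anchored at the isocenter; if the extent is
#' smaller than `step`, a single slice through the occupied interval
#' midpoint is returned). Each plane is sampled on the BEV grid by
#' trilinear interpolation of the binary mask, thresholded at 0.5.
#'
#' @param mask 3D binary array.
#' @param beam a [beam_geometry()].
#' @param grid a [bev_grid()].
#' @param step slice spacing, mm (default 2).
#' @param voxel_size voxel size of `mask`, mm.
#' @return list of 2D logical matrices (one per slice).
#' @export
slice_stack <- function(mask, beam, grid = bev_grid(), step = 2,
                        voxel_size = 5) {
  if (step <= 0) stop_invalid("step must be > 0")
  offs <- slice_offsets(mask, beam, step, voxel_size)
  arr <- bev_sample(mask, beam, grid, offs, voxel_size)
  lapply(seq_along(offs), function(k) arr[, , k])
}

#' Union of projected slice contours
#'
#' Pixelwise OR over a slice stack: the projected tumor-volume
#' silhouette on the BEV.
#'
#' @param slices nonempty list of 2D masks on a shared BEV grid.
#' @return 2D logical matrix.
#' @export
project_union <- function(slices) {
  if (length(slices) == 0) {
    stop("empty-input: no slices to project", call. = FALSE)
  }
  dims <- vapply(slices, function(s) paste(dim(s), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1) stop_invalid("slices must share the BEV grid")
  Reduce(`|`, slices)
}

#' In-plane BEV slice through the isocenter
#'
#' The single BEV-plane sample at beam-axis offset 0, i.e. what a thin
#' 2D cine slice through the isocenter sees. An isocenter plane that
#' misses the mask returns an empty matrix (a through-plane miss, not
#' an error).
#'
#' @inheritParams slice_stack
#' @return 2D logical matrix.
#' @export
inplane_slice <- function(mask, beam, grid = bev_grid(),
                          voxel_size = 5) {
  if (!any(mask)) stop("empty-input: mask has no foreground voxels",
                       call. = FALSE)
  bev_sample(mask, beam, grid, 0, voxel_size)[, , 1]
}

## COM of a 2D mask in BEV mm (relative to the isocenter); NA if empty.
mask_com <- function(mask2d, grid) {
  idx <- which(mask2d, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_))
  c(mean(grid$u[idx[, 1]]), mean(grid$v[idx[, 2]]))
}

#' Project a tumor mask onto the beam's-eye-view
#'
#' Convenience wrapper producing the full BEV projection for one beam:
#' the slice-stack silhouette (union of all BEV-parallel cuts), the
#' in-plane isocenter slice, and their centers of mass.
#'
#' @inheritParams slice_stack
#' @return object of class `bev_projection`: `silhouette`, `inplane`
#'   (2D logical), `com_silhouette`, `com_inplane` (mm `(u, v)`
#'   relative to the isocenter), `beam`, `grid`.
#' @export
bev_project <- function(mask, beam, grid = bev_grid(), step = 2,
                        voxel_size = 5) {
  offs <- slice_offsets(mask, beam, step, voxel_size)
  if (!any(offs == 0)) offs <- c(offs, 0)  # ensure the in-plane sample
  arr <- bev_sample(mask, beam, grid, offs, voxel_size)
  sil <- matrix(FALSE, length(grid$u), length(grid$v))
  for (k in seq_along(offs)) sil <- sil | arr[, , k]
  inp <- arr[, , which(offs == 0)[1]]
  structure(list(silhouette = sil, inplane = inp,
                 com_silhouette = mask_com(sil, grid),
                 com_inplane = mask_com(inp, grid),
                 beam = beam, grid = grid),
            class = "bev_projection")
}

#' Threshold-based tumor segmentation
#'
#' Thresholds the intensity volume and keeps the largest 6-connected
#' component, the automated stand-in for tumor delineation on the
#' phantom (where the tumor is the brightest compartment).
#'
#' @param frame a `volume_frame`.
#' @param threshold intensity threshold separating tumor from
#'   background.
#' @return 3D logical mask.
#' @export
segment_tumor <- function(frame, threshold) {
  bw <- frame$intensity > threshold
  if (!any(bw)) {
    stop("segmentation-failure: no voxels above the threshold",
         call. = FALSE)
  }
  dm <- dim(bw)
  idx <- which(bw)
  lab <- array(0L, dim = dm)
  lab[idx] <- seq_along(idx)
  edges <- list()
  ai <- arrayInd(idx, dm)
  for (ax in 1:3) {
    ok <- ai[, ax] < dm[ax]
    nb <- idx[ok] + c(1L, dm[1], dm[1] * dm[2])[ax]
    sel <- lab[nb] > 0L
    if (any(sel)) {
      edges[[length(edges) + 1]] <- cbind(lab[idx[ok]][sel], lab[nb][sel])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  out <- array(FALSE, dim = dm)
  out[idx[keep]] <- TRUE
  out
}
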