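#' 3-D volume with a voxel-to-world affine
#'
#' A `volume_grid` couples a 3-D scalar array with a 4x4 affine mapping
#' 0-based voxel indices to world coordinates in millimetres. The voxel's
#' world position is the position of its *center*; all geometry in the
#' package is computed in world mm so anisotropic voxels (e.g. the
#' 0.43 x 0.43 x 0.75 mm grids typical of rotational angiography) are
#' handled uniformly.
#'
#' @param values 3-D numeric or logical array.
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices
#'   `(i, j, k, 1)` to world mm. Must be invertible.
#' @param modality free-text label (e.g. `"DSA"`, `"MRV"`, `"T1Gad"`).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, affine = diag(4), modality = "") {
  if (!(is.array(values) && length(dim(values)) == 3L)) {
    stop("`values` must be a 3-D array")
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
  det_a <- det(affine[1:3, 1:3, drop = FALSE])
  if (!is.finite(det_a) || abs(det_a) < 1e-12) {
    stop("`affine` is not invertible")
  }
  structure(
    list(values = values, affine = affine, modality = as.character(modality)),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  sp <- grid_spacing(x)
  cat(sprintf(
    "<volume_grid%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    if (nzchar(x$modality)) paste0(" ", x$modality) else "",
    d[1], d[2], d[3], sp[1], sp[2], sp[3]
  ))
  invisible(x)
}

#' Voxel spacing (mm) of a volume grid
#'
#' Column norms of the affine's rotation/scaling block.
#' @param vol a `volume_grid`.
#' @return numeric length-3 vector, mm per voxel along each array axis.
#' @export
grid_spacing <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3, drop = FALSE]^2))
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based (NIfTI convention); R array subscripts are
#' these indices plus one.
#'
#' @param vol a `volume_grid`.
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world mm positions.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind_matrix(ijk)
  h <- cbind(ijk, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

#' @param xyz n x 3 matrix of world mm positions.
#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind_matrix(xyz)
  h <- cbind(xyz, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE]
}

# coerce a length-3 vector or n x 3 matrix to matrix form
rbind_matrix <- function(x) {
  if (is.null(dim(x))) {
    matrix(x, ncol = 3L)
  } else {
    as.matrix(x)
  }
}

#' Sample a volume at arbitrary world positions
#'
#' Trilinear or nearest-neighbour interpolation; positions outside the
#' grid return `background` (default 0) rather than erroring, so
#' trajectory reviews near the volume edge degrade gracefully.
#'
#' @param vol a `volume_grid`.
#' @param points n x 3 matrix of world mm positions.
#' @param method `"linear"` or `"nearest"`.
#' @param background value for out-of-field samples.
#' @return numeric vector of n sampled values.
#' @export
sample_volume <- function(vol, points, method = c("linear", "nearest"),
                          background = 0) {
  method <- match.arg(method)
  vox <- world_to_voxel(vol, points)
  d <- dim(vol$values)
  vals <- as.double(vol$values)
  if (method == "nearest") {
    idx <- round(vox)
    inb <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
      idx[, 1] <= d[1] - 1 & idx[, 2] <= d[2] - 1 & idx[, 3] <= d[3] - 1
    out <- rep(background, nrow(vox))
    if (any(inb)) {
      lin <- idx[inb, 1] + d[1] * (idx[inb, 2] + d[2] * idx[inb, 3]) + 1
      out[inb] <- vals[lin]
    }
    out
  } else {
    .trilinear_cpp(vals, as.integer(d), vox, background)
  }
}

#' World coordinates of every voxel center
#'
#' @param vol a `volume_grid`.
#' @return an n-voxel x 3 matrix in array (column-major) order.
#' @export
grid_coordinates <- function(vol) {
  d <- dim(vol$values)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  voxel_to_world(vol, ijk)
}
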