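#' Read and write NIfTI-1 volumes
#'
#' Volumes are stored as NIfTI-1 with the voxel-to-world affine in the
#' sform (code 2). Reading recovers values exactly and the affine to the
#' precision of the on-disk float32 header fields.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop("failed to parse NIfTI file '", path, "': ", conditionMessage(e))
  })
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) {
    stop("expected a 3-D volume, got ", length(dim(vals)), " dimensions")
  }
  volume_grid(array(as.double(vals), dim(vals)), aff)
}

#' @param vol a [volume_grid()].
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- grid_spacing(vol)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Rigid world-to-world transform
#'
#' Validates and wraps a 4x4 homogeneous matrix whose rotation block is
#' orthonormal with determinant +1. Transforms map the *moving* volume's
#' world coordinates into the *reference* world frame; the registration
#' solver that produces them is outside the scope of this package.
#'
#' @param matrix 4x4 homogeneous rigid matrix.
#' @param tol orthonormality tolerance.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(matrix = diag(4), tol = 1e-6) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(4, 4))) stop("transform must be 4x4")
  r <- m[1:3, 1:3]
  if (max(abs(crossprod(r) - diag(3))) > tol) {
    stop("rotation block is not orthonormal")
  }
  if (abs(det(r) - 1) > tol) stop("rotation block must have determinant +1")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > tol) {
    stop("last row must be (0, 0, 0, 1)")
  }
  structure(list(matrix = m), class = "rigid_transform")
}

#' @param path file path for a plain-text 4x4 matrix (4 rows, row-major).
#' @rdname rigid_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  rigid_transform(m)
}

#' @param transform a `rigid_transform`.
#' @rdname rigid_transform
#' @export
write_transform <- function(transform, path) {
  utils::write.table(transform$matrix, path,
    row.names = FALSE,
    col.names = FALSE
  )
  invisible(path)
}

#' Resample a volume onto a reference grid
#'
#' Pulls the moving volume through a given rigid world-to-world transform
#' onto the reference grid, e.g. mapping a post-implantation CT into the
#' preoperative contrast reference frame. Masks should be resampled with
#' `"nearest"` so they stay binary.
#'
#' @param moving a [volume_grid()] to resample.
#' @param transform a [rigid_transform()] mapping moving-world to
#'   reference-world, or `NULL` for identity.
#' @param reference a [volume_grid()] defining the output grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param background fill value outside the moving field of view.
#' @return a [volume_grid()] on the reference grid.
#' @export
resample_to_reference <- function(moving, transform = NULL, reference,
                                  interpolation = c("linear", "nearest"),
                                  background = 0) {
  interpolation <- match.arg(interpolation)
  if (is.null(transform)) transform <- rigid_transform(diag(4))
  if (!inherits(transform, "rigid_transform")) {
    transform <- rigid_transform(transform)
  }
  ref_world <- grid_coordinates(reference)
  # moving-world position that lands on each reference voxel
  inv <- solve(transform$matrix)
  mov_world <- cbind(ref_world, 1) %*% t(inv)
  vals <- sample_volume(moving, mov_world[, 1:3, drop = FALSE],
    method = interpolation, background = background
  )
  volume_grid(
    array(vals, dim(reference$values)), reference$affine,
    modality = moving$modality
  )
}

#' Probe-eye view: slice stack orthogonal to a trajectory
#'
#' Reformats a volume into a stack of 2-D planes perpendicular to the
#' local trajectory direction, one plane per arc-length step, emulating
#' the scrolling review a surgeon performs along an implanted electrode.
#'
#' @param vol a [volume_grid()].
#' @param trajectory n x 3 matrix of world mm points (>= 2 rows), ordered
#'   entry to tip.
#' @param step arc-length spacing between planes, mm.
#' @param fov in-plane field of view (edge length), mm.
#' @param pixel_size in-plane pixel size, mm; defaults to the smallest
#'   voxel dimension.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return list with `frames` (npix x npix x nplanes array), `centers`,
#'   `tangents`, and `arc` (mm from the first trajectory point).
#' @export
probe_eye_slices <- function(vol, trajectory, step, fov,
                             pixel_size = NULL,
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  trajectory <- rbind_matrix(trajectory)
  if (nrow(trajectory) < 2) stop("trajectory needs at least 2 points")
  if (step <= 0) stop("`step` must be positive")
  if (is.null(pixel_size)) pixel_size <- min(grid_spacing(vol))
  if (fov < min(grid_spacing(vol))) {
    stop("`fov` must cover at least one voxel")
  }
  rs <- resample_polyline(trajectory, step)
  np <- nrow(rs$points)
  half <- fov / 2
  offs <- seq(-half, half, by = pixel_size)
  npx <- length(offs)
  frames <- array(NA_real_, c(npx, npx, np))
  for (p in seq_len(np)) {
    tv <- rs$tangents[p, ]
    b <- plane_basis(tv)
    gu <- rep(offs, npx)
    gv <- rep(offs, each = npx)
    pts <- cbind(
      rs$points[p, 1] + gu * b$u[1] + gv * b$v[1],
      rs$points[p, 2] + gu * b$u[2] + gv * b$v[2],
      rs$points[p, 3] + gu * b$u[3] + gv * b$v[3]
    )
    frames[, , p] <- matrix(
      sample_volume(vol, pts, method = interpolation),
      npx, npx
    )
  }
  list(
    frames = frames, centers = rs$points, tangents = rs$tangents,
    arc = rs$arc, pixel_size = pixel_size, offsets = offs
  )
}

# deterministic orthonormal in-plane basis for a plane normal to `t`
plane_basis <- function(t) {
  t <- unit(t)
  a <- c(1, 0, 0)
  if (abs(sum(a * t)) > 0.9) a <- c(0, 1, 0)
  u <- unit(cross3(t, a))
  v <- cross3(t, u)
  list(u = u, v = v)
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Resample a polyline at uniform arc-length steps from its first point.
# Returns points, arc lengths, and per-sample unit tangents.
resample_polyline <- function(points, step) {
  points <- rbind_matrix(points)
  seglen <- sqrt(rowSums((points[-1, , drop = FALSE] -
    points[-nrow(points), , drop = FALSE])^2))
  keep <- seglen > 0
  if (!any(keep)) stop("degenerate polyline: zero total length")
  # drop zero-length duplicate vertices
  if (!all(keep)) {
    points <- points[c(TRUE, keep), , drop = FALSE]
    seglen <- seglen[keep]
  }
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  arcs <- seq(0, total, by = step)
  seg_idx <- findInterval(arcs, cum, rightmost.closed = TRUE)
  seg_idx <- pmin(seg_idx, length(seglen))
  frac <- (arcs - cum[seg_idx]) / seglen[seg_idx]
  p0 <- points[seg_idx, , drop = FALSE]
  p1 <- points[seg_idx + 1, , drop = FALSE]
  pts <- p0 + (p1 - p0) * frac
  tans <- (p1 - p0) / seglen[seg_idx]
  list(points = pts, arc = arcs, tangents = tans, total_length = total)
}
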