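#' Estimate mean cortical-mantle thickness by ray casting
#'
#' Casts rays inward from points sampled uniformly on the brain-mask
#' surface, along inward surface normals estimated from the gradient of
#' the Gaussian-smoothed mask. Each ray's thickness is the chord length
#' through the gray-matter mask from its first entry to its first exit;
#' rays that never enter gray matter are excluded from the mean and
#' counted.
#'
#' @param gm_mask gray-matter mask [volume_grid()] (subset of
#'   `brain_mask`).
#' @param brain_mask brain mask [volume_grid()] on the same grid.
#' @param n_rays number of rays (default 400).
#' @param seed RNG seed for surface sampling (reproducible estimates).
#' @param step marching step, mm; defaults to a quarter of the smallest
#'   voxel dimension.
#' @param max_depth how far a ray marches, mm; defaults to half the
#'   largest grid extent.
#' @return object of class `cortical_thickness`: `mean_thickness`,
#'   `per_ray_thicknesses`, `n_valid_rays`, `n_rays`.
#' @export
estimate_thickness <- function(gm_mask, brain_mask, n_rays = 400,
                               seed = 1L, step = NULL, max_depth = NULL) {
  d <- dim(brain_mask$values)
  if (!all(dim(gm_mask$values) == d)) {
    stop("masks must share one grid")
  }
  if (!any(gm_mask$values > 0.5)) {
    stop("gray-matter mask is empty: cannot estimate thickness")
  }
  sp <- grid_spacing(brain_mask)
  if (is.null(step)) step <- min(sp) / 4
  if (is.null(max_depth)) max_depth <- max(d * sp) / 2

  bm <- brain_mask$values > 0.5
  surf <- surface_voxels(bm)
  if (nrow(surf) == 0) stop("brain mask has no surface")
  picks <- with_seed(seed, {
    surf[sample.int(nrow(surf), n_rays, replace = nrow(surf) < n_rays), ,
      drop = FALSE
    ]
  })
  # inward normals from the smoothed-mask gradient (sigma = 1 voxel);
  # the mask increases from outside (0) to inside (1)
  smv <- .gaussian_smooth_cpp(
    as.double(bm), as.integer(d), sp, min(sp)
  )
  smg <- volume_grid(array(smv, d), brain_mask$affine)
  p0 <- voxel_to_world(brain_mask, picks)
  normals <- mask_gradient(smg, p0)
  nn <- sqrt(rowSums(normals^2))
  keep <- nn > 1e-6
  p0 <- p0[keep, , drop = FALSE]
  normals <- normals[keep, , drop = FALSE] / nn[keep]
  # start half a voxel outside the surface voxel center so a cortex
  # that reaches the surface is entered, not started inside
  p0 <- p0 - 0.5 * min(sp) * normals

  ts <- seq(0, max_depth, by = step)
  nr <- nrow(p0)
  entry <- rep(NA_real_, nr)
  exit <- rep(NA_real_, nr)
  active <- rep(TRUE, nr)
  for (t in ts) {
    if (!any(active)) break
    pts <- p0[active, , drop = FALSE] + t * normals[active, , drop = FALSE]
    ing <- sample_volume(gm_mask, pts, "nearest") > 0.5
    ids <- which(active)
    newly_in <- ids[ing & is.na(entry[ids])]
    entry[newly_in] <- t
    leaving <- ids[!ing & !is.na(entry[ids]) & is.na(exit[ids])]
    exit[leaving] <- t
    active[leaving] <- FALSE
  }
  exit[!is.na(entry) & is.na(exit)] <- max_depth
  valid <- !is.na(entry)
  per_ray <- exit[valid] - entry[valid]
  if (length(per_ray) == 0) {
    stop("no ray entered the gray-matter mask")
  }
  structure(
    list(
      mean_thickness = mean(per_ray),
      per_ray_thicknesses = per_ray,
      n_valid_rays = length(per_ray),
      n_rays = n_rays
    ),
    class = "cortical_thickness"
  )
}

#' @export
print.cortical_thickness <- function(x, ...) {
  cat(sprintf(
    "<cortical_thickness> mean %.2f mm from %d/%d valid rays\n",
    x$mean_thickness, x$n_valid_rays, x$n_rays
  ))
  invisible(x)
}

# 0-based indices of mask voxels with at least one 6-neighbour outside
surface_voxels <- function(m) {
  d <- dim(m)
  inner <- m
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, dim(m))
    idx_src <- lapply(dim(m), seq_len)
    idx_dst <- idx_src
    n <- dim(m)[ax]
    if (by > 0) {
      idx_dst[[ax]] <- seq(1 + by, n)
      idx_src[[ax]] <- seq(1, n - by)
    } else {
      idx_dst[[ax]] <- seq(1, n + by)
      idx_src[[ax]] <- seq(1 - by, n)
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  all_in <- m
  for (ax in 1:3) {
    for (by in c(-1, 1)) {
      all_in <- all_in & shift_and(m, ax, by)
    }
  }
  surf <- m & !all_in
  which(surf, arr.ind = TRUE) - 1L
}

# central-difference gradient of a smooth scalar volume at world points
mask_gradient <- function(vol, points) {
  sp <- grid_spacing(vol)
  h <- min(sp)
  g <- matrix(0, nrow(points), 3)
  for (ax in 1:3) {
    e <- c(0, 0, 0)
    e[ax] <- h
    up <- sample_volume(vol, sweep(points, 2, e, "+"), "linear")
    dn <- sample_volume(vol, sweep(points, 2, e, "-"), "linear")
    g[, ax] <- (up - dn) / (2 * h)
  }
  g
}

#' Build the sulcal exclusion model
#'
#' Erodes the intracerebral mask by a world-metric ball whose radius is
#' `margin_factor` times the mean cortical thickness (so everything at
#' or above the level of the gyral crown is removed), then intersects
#' with the gray-matter mask: what remains is gray matter buried below
#' the crowns, i.e. sulcal cortex. Erosion is implemented by
#' thresholding the exact distance-to-surface field, which is correct
#' under anisotropic voxels where iterated structuring elements are
#' not.
#'
#' @param brain_mask,gm_mask masks on the reference grid.
#' @param thickness a [estimate_thickness()] result or a plain mm value.
#' @param margin_factor erosion depth as a multiple of the mean
#'   thickness (default 1).
#' @return object of class `sulcal_model`: `mask` ([volume_grid()]),
#'   `erosion_depth_used` (mm).
#' @export
build_sulcal_model <- function(brain_mask, gm_mask, thickness,
                               margin_factor = 1) {
  t_mm <- if (inherits(thickness, "cortical_thickness")) {
    thickness$mean_thickness
  } else {
    as.numeric(thickness)
  }
  r_e <- margin_factor * t_mm
  d <- as.integer(dim(brain_mask$values))
  sp <- grid_spacing(brain_mask)
  bm <- brain_mask$values > 0.5
  if (!any(!bm)) stop("brain mask fills the whole grid; no surface exists")
  # distance to the brain surface: voxel-center distances to the
  # complement overshoot the boundary by about half a voxel
  depth <- array(
    .edt_cpp(as.logical(!bm), d, sp) - mean(sp) / 2,
    dim(brain_mask$values)
  )
  eroded <- bm & depth > r_e
  model <- eroded & (gm_mask$values > 0.5)
  if (!any(model)) {
    warning(
      "sulcal model is empty (erosion depth ", round(r_e, 2),
      " mm leaves no gray matter)"
    )
  }
  structure(
    list(
      mask = volume_grid(
        array(as.double(model), dim(brain_mask$values)),
        brain_mask$affine, "sulcal_model"
      ),
      erosion_depth_used = r_e,
      depth_to_surface = volume_grid(
        depth, brain_mask$affine, "depth_to_surface"
      )
    ),
    class = "sulcal_model"
  )
}
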