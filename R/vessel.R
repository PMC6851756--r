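#' Multiscale Hessian vesselness filter
#'
#' Enhances bright tubular structures with the classic three-ratio
#' Hessian eigenvalue measure evaluated at several Gaussian scales and
#' combined by a voxelwise maximum. The response lies in [0, 1] by
#' construction and is invariant to adding a constant intensity offset.
#'
#' @param vol a [volume_grid()] with bright vessels on a darker
#'   background.
#' @param scales Gaussian scales (standard deviations) in mm. Scales
#'   smaller than half the smallest voxel dimension are dropped with a
#'   warning; if none survive, an error is raised.
#' @param alpha,beta plate/blob discrimination constants of the tube
#'   measure (defaults 0.5).
#' @param c structure-sensitivity constant; defaults to half the
#'   volume's intensity range.
#' @return a [volume_grid()] of vesselness values in [0, 1].
#' @export
vesselness_filter <- function(vol, scales = c(0.25, 0.5, 1, 1.5, 2),
                              alpha = 0.5, beta = 0.5, c = NULL) {
  sp <- grid_spacing(vol)
  if (length(scales) < 1 || any(scales <= 0)) {
    stop("need at least one positive scale")
  }
  ok <- scales >= min(sp) / 2
  if (!all(ok)) {
    warning(
      "dropping scales smaller than half a voxel: ",
      paste(scales[!ok], collapse = ", "), " mm"
    )
    scales <- scales[ok]
  }
  if (length(scales) == 0) stop("all scales were below half a voxel")
  rng <- range(vol$values)
  if (is.null(c)) c <- (rng[2] - rng[1]) / 2
  if (c <= 0) {
    # constant volume: no structure anywhere
    return(volume_grid(
      array(0, dim(vol$values)), vol$affine, vol$modality
    ))
  }
  d <- as.integer(dim(vol$values))
  vals <- as.double(vol$values)
  best <- numeric(length(vals))
  for (s in scales) {
    sm <- .gaussian_smooth_cpp(vals, d, sp, s)
    resp <- .tube_response_cpp(sm, d, sp, s, alpha, beta, c)
    best <- pmax(best, resp)
  }
  volume_grid(array(best, dim(vol$values)), vol$affine, vol$modality)
}

#' Per-scale vesselness responses
#'
#' Same measure as [vesselness_filter()] but keeping each scale's
#' response separate, for inspecting scale selection.
#'
#' @inheritParams vesselness_filter
#' @return named list of [volume_grid()]s, one per scale.
#' @export
vesselness_by_scale <- function(vol, scales, alpha = 0.5, beta = 0.5,
                                c = NULL) {
  sp <- grid_spacing(vol)
  rng <- range(vol$values)
  if (is.null(c)) c <- (rng[2] - rng[1]) / 2
  d <- as.integer(dim(vol$values))
  vals <- as.double(vol$values)
  out <- list()
  for (s in scales) {
    sm <- .gaussian_smooth_cpp(vals, d, sp, s)
    resp <- .tube_response_cpp(sm, d, sp, s, alpha, beta, c)
    out[[as.character(s)]] <- volume_grid(
      array(resp, dim(vol$values)), vol$affine, vol$modality
    )
  }
  out
}

#' Segment vessels from a vesselness map
#'
#' Thresholds the vesselness and removes connected components smaller
#' than `min_component_voxels`. An empty mask is legal (e.g. a modality
#' that resolves no vessels along a trajectory).
#'
#' @param vesselness a [volume_grid()] in [0, 1] (from
#'   [vesselness_filter()]).
#' @param threshold vesselness threshold in (0, 1].
#' @param min_component_voxels minimum component size (1 = plain
#'   thresholding).
#' @param connectivity 6 or 26 for component analysis.
#' @return object of class `vessel_segmentation`: list with `mask` and
#'   `vesselness` [volume_grid()]s and `source_modality`.
#' @export
segment_vessels <- function(vesselness, threshold = 0.05,
                            min_component_voxels = 10,
                            connectivity = 26) {
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]")
  mask <- vesselness$values >= threshold
  d <- as.integer(dim(vesselness$values))
  if (min_component_voxels > 1 && any(mask)) {
    lab <- .label_components_cpp(as.logical(mask), d, as.integer(connectivity))
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_component_voxels)
    if (length(small) > 0) mask[lab %in% small] <- FALSE
  }
  structure(
    list(
      mask = volume_grid(
        array(as.double(mask), dim(vesselness$values)),
        vesselness$affine, vesselness$modality
      ),
      vesselness = vesselness,
      source_modality = vesselness$modality,
      threshold = threshold
    ),
    class = "vessel_segmentation"
  )
}

#' Segmentation from a known binary mask
#'
#' Wraps an existing binary vessel mask as a `vessel_segmentation`
#' (used when ground-truth vasculature is available, e.g. phantom
#' reference sets).
#'
#' @param mask binary [volume_grid()].
#' @param modality label.
#' @return a `vessel_segmentation`.
#' @export
segmentation_from_mask <- function(mask, modality = mask$modality) {
  structure(
    list(
      mask = mask,
      vesselness = volume_grid(
        array(as.double(mask$values > 0.5), dim(mask$values)),
        mask$affine, modality
      ),
      source_modality = modality, threshold = 0.5
    ),
    class = "vessel_segmentation"
  )
}

#' Euclidean distance field to segmented vasculature
#'
#' Exact anisotropy-aware Euclidean distance transform in world mm:
#' zero exactly on the vessel mask, 1-Lipschitz in the world metric.
#' An empty mask yields an all-infinite field with `empty = TRUE`, which
#' downstream profile code propagates as "no vasculature".
#'
#' @param seg a `vessel_segmentation` (or a binary [volume_grid()]).
#' @param signed when `TRUE`, voxels inside the mask carry the
#'   *negative* distance to the mask boundary, so the field resolves
#'   how deeply a trajectory penetrates a vessel; the default keeps
#'   the plain non-negative field (zero on the mask).
#' @return object of class `distance_field`: list with `distances`
#'   ([volume_grid()], mm), `empty` and `signed` flags.
#' @export
distance_field <- function(seg, signed = FALSE) {
  mask_vol <- if (inherits(seg, "vessel_segmentation")) seg$mask else seg
  m <- mask_vol$values > 0.5
  d <- as.integer(dim(mask_vol$values))
  sp <- grid_spacing(mask_vol)
  if (!any(m)) {
    return(structure(
      list(
        distances = volume_grid(
          array(Inf, dim(mask_vol$values)),
          mask_vol$affine, mask_vol$modality
        ),
        empty = TRUE, signed = signed
      ),
      class = "distance_field"
    ))
  }
  dist <- .edt_cpp(as.logical(m), d, sp)
  if (signed && !all(m)) {
    inner <- .edt_cpp(as.logical(!m), d, sp)
    dist[m] <- -inner[m]
  }
  structure(
    list(
      distances = volume_grid(
        array(dist, dim(mask_vol$values)),
        mask_vol$affine, mask_vol$modality
      ),
      empty = FALSE, signed = signed
    ),
    class = "distance_field"
  )
}

# distance from inside the mask to the nearest background voxel; used
# for inscribed-sphere diameter estimates
internal_distance <- function(seg) {
  mask_vol <- if (inherits(seg, "vessel_segmentation")) seg$mask else seg
  m <- mask_vol$values > 0.5
  d <- as.integer(dim(mask_vol$values))
  sp <- grid_spacing(mask_vol)
  if (all(m) || !any(m)) {
    return(volume_grid(
      array(if (all(m)) Inf else 0, dim(mask_vol$values)),
      mask_vol$affine, mask_vol$modality
    ))
  }
  dist <- .edt_cpp(as.logical(!m), d, sp)
  dist[!m] <- 0
  volume_grid(array(dist, dim(mask_vol$values)), mask_vol$affine,
    modality = mask_vol$modality
  )
}

#' Local vessel diameter at a point
#'
#' Inscribed-sphere estimate: from the mask voxel nearest the query
#' point, climb the internal distance-to-boundary field over
#' 26-neighbours until a local maximum - a voxel of the local medial
#' axis - and report twice its distance to the boundary. The climb
#' keeps the estimate on the vessel actually crossed instead of
#' jumping to a thicker structure that merely passes nearby. Distances
#' run from voxel center to voxel center; the overshoot past the
#' boundary and the offset of the sampled center from the true medial
#' axis cancel on average, so no half-voxel correction is applied.
#' Voxel-resolution-limited by design.
#'
#' @param seg a `vessel_segmentation`.
#' @param point world mm position (the conflict site).
#' @param capture_radius how far (mm) to search for vessel voxels
#'   around the query point (default 2; grazing conflicts sit just off
#'   the mask).
#' @param internal optional precomputed [volume_grid()] of internal
#'   distances (from repeated calls on the same segmentation).
#' @return diameter in mm.
#' @export
local_diameter <- function(seg, point, capture_radius = 2,
                           internal = NULL) {
  mask_vol <- seg$mask
  if (is.null(internal)) internal <- internal_distance(seg)
  sp <- grid_spacing(mask_vol)
  d <- dim(mask_vol$values)
  vox <- as.vector(world_to_voxel(mask_vol, point))
  rad_vox <- ceiling(capture_radius / sp)
  i0 <- pmax(0, floor(vox - rad_vox))
  i1 <- pmin(d - 1, ceiling(vox + rad_vox))
  if (any(i1 < i0)) stop("no vessel within the capture radius of the point")
  ii <- seq(i0[1], i1[1])
  jj <- seq(i0[2], i1[2])
  kk <- seq(i0[3], i1[3])
  box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  wpts <- voxel_to_world(mask_vol, box)
  dist2 <- rowSums(sweep(wpts, 2, point)^2)
  lin <- box[, 1] + d[1] * (box[, 2] + d[2] * box[, 3]) + 1
  inmask <- mask_vol$values[lin] > 0.5 & dist2 <= capture_radius^2
  if (!any(inmask)) {
    stop("no vessel within the capture radius of the point")
  }
  # start at the mask voxel nearest the conflict site ...
  start <- box[inmask, , drop = FALSE][which.min(dist2[inmask]), ]
  # ... and hill-climb the internal distance field to the local
  # medial axis; the climb is capped at the capture radius so it
  # cannot wander onto a thicker structure that merely lies nearby
  cur <- start
  val <- internal$values[cur[1] + d[1] * (cur[2] + d[2] * cur[3]) + 1]
  repeat {
    nb <- as.matrix(expand.grid(
      i = cur[1] + (-1):1, j = cur[2] + (-1):1, k = cur[3] + (-1):1
    ))
    nb <- nb[
      nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
        nb[, 1] <= d[1] - 1 & nb[, 2] <= d[2] - 1 & nb[, 3] <= d[3] - 1, ,
      drop = FALSE
    ]
    travel2 <- colSums((t(sweep(nb, 2, start)) * sp)^2)
    nb <- nb[travel2 <= capture_radius^2, , drop = FALSE]
    if (nrow(nb) == 0) break
    nlin <- nb[, 1] + d[1] * (nb[, 2] + d[2] * nb[, 3]) + 1
    nv <- internal$values[nlin]
    bi <- which.max(nv)
    if (nv[bi] <= val) break
    val <- nv[bi]
    cur <- nb[bi, ]
  }
  max(2 * val, min(sp))
}
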