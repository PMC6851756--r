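# Shared fixture builders. Everything is generated in code; no files.

# axis-aligned grid centered on the world origin
centered_grid <- function(dim, spacing) {
  if (length(dim) == 1) dim <- rep(dim, 3)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4] <- -(dim - 1) / 2 * spacing
  volume_grid(array(0, dim), aff)
}

# rasterize capsules into a grid: segs is a matrix with rows
# (x0 y0 z0 x1 y1 z1 r); returns intensity `amp` inside, anti-aliased
capsule_volume <- function(grid, segs, amp = 100) {
  d <- dim(grid$values)
  sp <- grid_spacing(grid)
  origin <- grid$affine[1:3, 4]
  fld <- seegconflict:::.capsule_field_cpp(
    as.integer(d), origin, sp, rbind(segs)
  )
  occ <- pmin(1, pmax(0, fld / min(sp) + 0.5))
  volume_grid(array(amp * occ, d), grid$affine, grid$modality)
}

# a solid sphere mask of radius r (mm) about the world origin
sphere_mask <- function(grid, r, r_inner = -Inf) {
  co <- grid_coordinates(grid)
  rad <- sqrt(rowSums(co^2))
  volume_grid(
    array(as.double(rad <= r & rad >= r_inner), dim(grid$values)),
    grid$affine
  )
}

# straight-trajectory samples data.frame compatible with
# distance_profile()/risk_metrics(): from `start`, direction `dirv`,
# length L, sampled every `step`, arc 0 at start
straight_samples <- function(start, dirv, L, step = 0.5, radius = 0.4,
                             inside = TRUE) {
  dirv <- dirv / sqrt(sum(dirv^2))
  arcs <- seq(0, L, by = step)
  pts <- t(vapply(arcs, function(t) start + t * dirv, numeric(3)))
  out <- data.frame(
    x = pts[, 1], y = pts[, 2], z = pts[, 3], arc = arcs,
    tx = dirv[1], ty = dirv[2], tz = dirv[3],
    inside = rep(inside, length(arcs))
  )
  attr(out, "electrode") <- "T"
  attr(out, "radius") <- radius
  attr(out, "step") <- step
  class(out) <- c("trajectory_samples", "data.frame")
  out
}

# hand-built distance profile from (arc, distance) vectors
manual_profile <- function(arc, distance, positions = NULL,
                           safety_margin = 3) {
  out <- data.frame(arc = arc, distance = distance, signed = distance)
  if (is.null(positions)) {
    positions <- cbind(arc, 0, 0)
  }
  attr(out, "no_vasculature") <- FALSE
  attr(out, "safety_margin") <- safety_margin
  attr(out, "electrode_radius") <- 0
  attr(out, "electrode") <- "T"
  attr(out, "positions") <- positions
  attr(out, "tangents") <- cbind(1, 0, 0)[rep(1, length(arc)), ]
  class(out) <- c("distance_profile", "data.frame")
  out
}

# small, fast phantom spec for pipeline-level tests
tiny_spec <- function(seed = 1, ...) {
  args <- list(
    grid_shape = 64, voxel_size = 0.75, n_vessels = 20,
    n_electrodes = 4, contacts_per_electrode = 6, contact_spacing = 4,
    seed = seed
  )
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# brute-force nearest-seed distance (independent of the EDT path)
brute_force_edt <- function(mask, spacing) {
  d <- dim(mask)
  seeds <- which(mask, arr.ind = TRUE) - 1
  seeds <- sweep(seeds, 2, spacing, "*")
  co <- as.matrix(expand.grid(
    x = (seq_len(d[1]) - 1) * spacing[1],
    y = (seq_len(d[2]) - 1) * spacing[2],
    z = (seq_len(d[3]) - 1) * spacing[3]
  ))
  out <- vapply(seq_len(nrow(co)), function(i) {
    sqrt(min(colSums((t(seeds) - co[i, ])^2)))
  }, numeric(1))
  array(out, d)
}

# closed-form 2x2 chi-squared statistic N(ad-bc)^2 / (row/col products)
chisq_closed_form <- function(a, b, c, d) {
  a <- as.double(a)
  b <- as.double(b)
  c <- as.double(c)
  d <- as.double(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
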