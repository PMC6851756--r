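#' Specification for a synthetic multimodal SEEG phantom
#'
#' Defines the study conditions a generated phantom emulates: a spherical
#' brain with a sinusoidally folded cortical sheet (so gyral crowns and
#' sulcal depths are analytically known), a vessel tree whose segment
#' radii follow a lognormal law concentrated around 1-1.5 mm, three
#' vascular imaging modalities with diameter-dependent visibility
#' (the DSA-like modality resolves the smallest vessels), and depth
#' electrodes planted so that each passes through a chosen vessel at a
#' known depth from the cortical entry point.
#'
#' @param grid_shape voxels per axis (length 1 or 3, each >= 32).
#' @param voxel_size isotropic voxel size, mm.
#' @param n_vessels number of vessel tree roots.
#' @param radius_law lognormal law for root segment radii (mm), given as
#'   `list(median =, iqr = c(lo, hi))`. Defaults to median 1.3 mm with
#'   interquartile range 1.0-1.5 mm.
#' @param modality_visibility named vector: minimum vessel *diameter*
#'   (mm) visible per modality. The first (DSA-like) entry must be the
#'   smallest.
#' @param n_electrodes number of depth electrodes to plant.
#' @param contacts_per_electrode contacts per electrode (>= 2).
#' @param contact_spacing center-to-center contact spacing, mm.
#' @param fold_wavelength,fold_amplitude cortical folding wavelength and
#'   sulcal depth, mm.
#' @param fold_mode `"sin"` (default, periodic folding), `"single"`
#'   (one groove, used for closed-form sulcal-model checks) or `"none"`.
#' @param cortical_thickness gray-matter sheet thickness, mm.
#' @param depth_law lognormal law for planted conflict depths (mm from
#'   the cortical entry); defaults to median 31 mm, IQR 14.3-45 mm.
#' @param noise_sd additive Gaussian intensity noise (intensity units).
#' @param vessel_intensity,contact_intensity rendered intensities of
#'   vessels (vascular volumes) and contacts (CT-like volume).
#' @param electrode_radius physical electrode radius, mm.
#' @param branch_levels bifurcation generations beyond each root.
#' @param radius_decay child/parent radius ratio at a bifurcation
#'   (default 0.79, the cube-root flow-splitting value).
#' @param vessel_dilation extra rendered radius (mm) applied to the
#'   DSA-like volume, emulating an extraction filter that dilates the
#'   segmentation beyond the true lumen (a source of false positives).
#' @param seed integer seed; the whole phantom is a deterministic
#'   function of the spec including this seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 128),
                         voxel_size = 0.5,
                         n_vessels = 60,
                         radius_law = list(median = 1.3, iqr = c(1.0, 1.5)),
                         modality_visibility = c(
                           DSA = 0.5, MRV = 2.0, T1Gad = 2.5
                         ),
                         n_electrodes = 8,
                         contacts_per_electrode = 8,
                         contact_spacing = 5,
                         fold_wavelength = 30,
                         fold_amplitude = 8,
                         fold_mode = c("sin", "single", "none"),
                         cortical_thickness = 3,
                         depth_law = list(median = 31, iqr = c(14.3, 45)),
                         noise_sd = 1,
                         vessel_intensity = 100,
                         contact_intensity = 1000,
                         electrode_radius = 0.4,
                         branch_levels = 1,
                         radius_decay = 0.79,
                         vessel_dilation = 0,
                         seed = 1L) {
  fold_mode <- match.arg(fold_mode)
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  if (any(grid_shape < 32)) stop("`grid_shape` must be at least 32 per axis")
  if (voxel_size <= 0) stop("`voxel_size` must be positive")
  if (contact_spacing <= 0) stop("`contact_spacing` must be positive")
  if (contacts_per_electrode < 2) stop("electrodes need >= 2 contacts")
  if (any(modality_visibility <= 0)) {
    stop("visibility thresholds must be positive")
  }
  if (modality_visibility[1] != min(modality_visibility)) {
    stop(
      "the first (DSA-like) modality must have the smallest ",
      "visibility threshold"
    )
  }
  extent <- grid_shape * voxel_size
  r0 <- 0.45 * min(extent)
  if (2 * r0 < 2 * contact_spacing) {
    stop(
      "grid too small to contain the requested electrodes: brain ",
      "diameter ", round(2 * r0, 1), " mm cannot hold contacts spaced ",
      contact_spacing, " mm apart"
    )
  }
  structure(
    list(
      grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
      n_vessels = n_vessels, radius_law = radius_law,
      modality_visibility = modality_visibility,
      n_electrodes = n_electrodes,
      contacts_per_electrode = as.integer(contacts_per_electrode),
      contact_spacing = contact_spacing,
      fold_wavelength = fold_wavelength, fold_amplitude = fold_amplitude,
      fold_mode = fold_mode, cortical_thickness = cortical_thickness,
      depth_law = depth_law, noise_sd = noise_sd,
      vessel_intensity = vessel_intensity,
      contact_intensity = contact_intensity,
      electrode_radius = electrode_radius,
      branch_levels = branch_levels, radius_decay = radius_decay,
      vessel_dilation = vessel_dilation,
      brain_radius = r0, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Draw from a lognormal law parameterized by median and IQR
#'
#' `sdlog` is fitted from the quartile ratio: for a lognormal the
#' quartiles sit at `meanlog +/- qnorm(0.75) * sdlog`.
#'
#' @param law `list(median =, iqr = c(lo, hi))`.
#' @param n number of draws.
#' @return numeric vector of n draws (uses the current RNG stream).
#' @export
draw_lognormal_law <- function(law, n) {
  sdlog <- log(law$iqr[2] / law$iqr[1]) / (2 * qnorm(0.75))
  rlnorm(n, meanlog = log(law$median), sdlog = sdlog)
}

# Fold depth (mm) as a function of direction on the unit sphere.
# 0 at gyral crowns, up to fold_amplitude at sulcal fundi.
fold_depth <- function(spec, w) {
  w <- rbind_matrix(w)
  r0 <- spec$brain_radius
  a <- spec$fold_amplitude
  switch(spec$fold_mode,
    none = rep(0, nrow(w)),
    single = {
      # one groove around the great circle x = 0
      sw <- spec$fold_wavelength / 6
      a * exp(-(r0 * w[, 1])^2 / (2 * sw^2))
    },
    sin = {
      k <- 2 * pi * r0 / spec$fold_wavelength
      a * pmax(0, sin(k * w[, 1]) * sin(k * w[, 2]))
    }
  )
}

# Reference grid: axis-aligned, isotropic, world origin at the volume center.
phantom_grid <- function(spec) {
  d <- spec$grid_shape
  sp <- rep(spec$voxel_size, 3)
  origin <- -(d - 1) / 2 * sp
  aff <- diag(4)
  diag(aff)[1:3] <- sp
  aff[1:3, 4] <- origin
  list(dim = d, spacing = sp, origin = origin, affine = aff)
}

make_grid_volume <- function(g, values, modality = "") {
  volume_grid(array(values, g$dim), g$affine, modality = modality)
}

#' Generate a synthetic multimodal SEEG phantom
#'
#' Builds tissue masks (brain, gray matter, white matter, skull), one
#' vascular volume per modality in which a vessel segment is rendered iff
#' its diameter reaches that modality's visibility threshold, a CT-like
#' volume with bright Gaussian blobs at the electrode contacts, and a
#' ground-truth manifest of vessel segments and planted electrode-vessel
#' conflicts. The output is a deterministic function of the spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `masks` (brain/gm/wm/skull [volume_grid()]s),
#'   `modalities` (named list of vascular volumes), `ct`, `truth`
#'   (segments, planted conflicts, electrode geometry), and `reference`
#'   (the reference grid as an empty volume).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- phantom_grid(spec)
  r0 <- spec$brain_radius
  tc <- spec$cortical_thickness

  xyz <- make_grid_volume(g, 0)
  coords <- grid_coordinates(xyz)
  r <- sqrt(rowSums(coords^2))
  w <- coords / pmax(r, 1e-9)
  f <- fold_depth(spec, w)

  brain <- r <= r0
  skull <- r >= r0 + 1 & r <= r0 + 3
  gm <- brain & (r >= r0 - f - tc) & (r <= r0 - f)
  wm <- brain & (r < r0 - f - tc)

  masks <- list(
    brain = make_grid_volume(g, as.double(brain), "brain_mask"),
    gm = make_grid_volume(g, as.double(gm), "gm_mask"),
    wm = make_grid_volume(g, as.double(wm), "wm_mask"),
    skull = make_grid_volume(g, as.double(skull), "skull_mask")
  )

  segments <- generate_vessel_tree(spec)
  modnames <- names(spec$modality_visibility)
  if (nrow(segments) > 0) {
    for (m in modnames) {
      segments[[paste0("visible_", m)]] <-
        segments$diameter >= spec$modality_visibility[[m]]
    }
  } else {
    for (m in modnames) {
      segments[[paste0("visible_", m)]] <- logical(0)
    }
  }

  modalities <- list()
  nvox <- prod(g$dim)
  for (m in modnames) {
    vals <- rnorm(nvox, 0, spec$noise_sd)
    vis <- segments[segments[[paste0("visible_", m)]], , drop = FALSE]
    if (nrow(vis) > 0) {
      rad <- vis$radius + if (m == modnames[1]) spec$vessel_dilation else 0
      segmat <- cbind(
        vis$x0, vis$y0, vis$z0, vis$x1, vis$y1, vis$z1, rad
      )
      fld <- .capsule_field_cpp(g$dim, g$origin, g$spacing, segmat)
      # anti-aliased edge: full intensity one voxel inside the surface
      occ <- pmin(1, pmax(0, fld / spec$voxel_size + 0.5))
      vals <- vals + spec$vessel_intensity * occ
    }
    modalities[[m]] <- make_grid_volume(g, vals, m)
  }

  truth <- list(
    vessel_segments = segments,
    planted_conflicts = empty_conflicts(modnames),
    electrodes = list(),
    geometry = list(
      center = c(0, 0, 0), brain_radius = r0,
      cortical_thickness = tc, fold_mode = spec$fold_mode,
      fold_amplitude = spec$fold_amplitude,
      fold_wavelength = spec$fold_wavelength
    )
  )

  # plant electrodes, one targeted conflict each where vessels exist
  if (spec$n_electrodes > 0) {
    targets <- integer(0)
    if (nrow(segments) > 0) {
      mid <- cbind(
        (segments$x0 + segments$x1) / 2,
        (segments$y0 + segments$y1) / 2,
        (segments$z0 + segments$z1) / 2
      )
      rho <- sqrt(rowSums(mid^2))
      ok <- which(rho < 0.88 * r0 & rho > 0.15 * r0)
      if (length(ok) > 0) {
        targets <- sample(ok, spec$n_electrodes, replace = length(ok) <
          spec$n_electrodes)
      }
    }
    for (e in seq_len(spec$n_electrodes)) {
      if (length(targets) >= e) {
        truth <- plant_conflicting_electrode(
          truth, masks, targets[e], spec,
          label = sprintf("E%02d", e)
        )
      } else {
        truth <- plant_free_electrode(truth, spec,
          label = sprintf("E%02d", e)
        )
      }
    }
  }

  # complete the manifest with incidental transverse crossings: every
  # electrode-vessel touch is a true conflict whether targeted or not
  inc <- enumerate_incidental_conflicts(truth, spec)
  if (!is.null(inc)) {
    truth$planted_conflicts <- rbind(truth$planted_conflicts, inc)
    rownames(truth$planted_conflicts) <- NULL
  }

  # render CT-like volume with contact blobs
  ct_vals <- rnorm(nvox, 0, spec$noise_sd)
  sigma <- spec$voxel_size / 2
  for (el in truth$electrodes) {
    for (ci in seq_len(nrow(el$contacts))) {
      ct_vals <- add_blob(
        ct_vals, g, el$contacts[ci, ], spec$contact_intensity, sigma
      )
    }
  }
  ct <- make_grid_volume(g, ct_vals, "CT")

  list(
    masks = masks, modalities = modalities, ct = ct, truth = truth,
    reference = xyz, spec = spec
  )
}

empty_conflicts <- function(modnames) {
  df <- data.frame(
    electrode = character(0), x = numeric(0), y = numeric(0),
    z = numeric(0), vessel_id = integer(0), radius = numeric(0),
    diameter = numeric(0), depth = numeric(0), in_sulcus = logical(0),
    planted = logical(0),
    stringsAsFactors = FALSE
  )
  for (m in modnames) df[[paste0("visible_", m)]] <- logical(0)
  df
}

# All true electrode-vessel conflicts of the implanted geometry:
# closest approach between the electrode axis (entry to tip) and each
# vessel segment axis at or below the touching distance. Planted
# target crossings are recognized and skipped (the manifest already
# carries them at the vessel-axis point).
enumerate_incidental_conflicts <- function(truth, spec) {
  segs <- truth$vessel_segments
  planted <- truth$planted_conflicts
  rows <- list()
  modnames <- names(spec$modality_visibility)
  for (label in names(truth$electrodes)) {
    el <- truth$electrodes[[label]]
    entry <- el$entry
    tip <- el$contacts[1, ]
    for (i in seq_len(nrow(segs))) {
      b0 <- c(segs$x0[i], segs$y0[i], segs$z0[i])
      b1 <- c(segs$x1[i], segs$y1[i], segs$z1[i])
      cc <- seg_seg_closest(entry, tip, b0, b1)
      touch <- spec$electrode_radius + segs$radius[i]
      if (sqrt(cc$d2) > touch) next
      depth <- cc$s * vnorm(tip - entry)
      dup <- planted$electrode == label &
        planted$vessel_id == segs$id[i] &
        abs(planted$depth - depth) < 3
      if (any(dup)) next
      p <- cc$pa
      fdep <- fold_depth_point(spec, truth$geometry, p)
      rho <- vnorm(p)
      r0 <- truth$geometry$brain_radius
      tc <- truth$geometry$cortical_thickness
      in_gm <- (rho <= r0 - fdep) && (rho >= r0 - fdep - tc)
      row <- data.frame(
        electrode = label, x = p[1], y = p[2], z = p[3],
        vessel_id = segs$id[i], radius = segs$radius[i],
        diameter = segs$diameter[i], depth = depth,
        in_sulcus = in_gm && (r0 - rho > tc), planted = FALSE,
        stringsAsFactors = FALSE
      )
      for (m in modnames) {
        row[[paste0("visible_", m)]] <- segs[[paste0("visible_", m)]][i]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) {
    return(NULL)
  }
  do.call(rbind, rows)
}

# Recursive bifurcating tree of capsule segments. Root radii follow the
# spec's lognormal law; children shrink by `radius_decay` per generation.
# Sub-1.3 mm-diameter roots are biased toward the folded cortical band
# (sulcal vessels run small; superficial cortical vessels run larger).
generate_vessel_tree <- function(spec) {
  cols <- c(
    "id", "x0", "y0", "z0", "x1", "y1", "z1", "radius", "diameter",
    "level", "root"
  )
  if (spec$n_vessels == 0) {
    df <- as.data.frame(matrix(numeric(0), ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  r0 <- spec$brain_radius
  radii <- draw_lognormal_law(spec$radius_law, spec$n_vessels)
  rows <- list()
  idc <- 0
  clip_inside <- function(p0, p1) {
    # shrink segment end toward start until inside radius r0 - 1
    lim <- r0 - 1
    if (vnorm(p1) > lim) {
      a <- p1 - p0
      lo <- 0
      hi <- 1
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        if (vnorm(p0 + mid * a) > lim) hi <- mid else lo <- mid
      }
      p1 <- p0 + lo * a
    }
    p1
  }
  for (v in seq_len(spec$n_vessels)) {
    rv <- radii[v]
    small <- 2 * rv < 1.3
    band_lo <- if (small) {
      max(0.3, (r0 - spec$fold_amplitude - spec$cortical_thickness) / r0)
    } else {
      0.5
    }
    band_hi <- if (small) 0.95 else 0.85
    u <- runif(1, band_lo, band_hi)
    dir0 <- unit(rnorm(3))
    p0 <- u * r0 * dir0
    len <- runif(1, 8, 18)
    d <- unit(rnorm(3))
    p1 <- clip_inside(p0, p0 + len * d)
    stack <- list(list(p0 = p0, p1 = p1, r = rv, level = 0L))
    while (length(stack) > 0) {
      s <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      idc <- idc + 1
      rows[[idc]] <- c(
        idc, s$p0, s$p1, s$r, 2 * s$r, s$level, v
      )
      if (s$level < spec$branch_levels) {
        axis <- s$p1 - s$p0
        if (vnorm(axis) > 1e-6) {
          axis <- unit(axis)
          for (ch in 1:2) {
            jit <- unit(axis + 0.7 * rnorm(3))
            clen <- 0.7 * vnorm(s$p1 - s$p0)
            cp1 <- clip_inside(s$p1, s$p1 + clen * jit)
            stack[[length(stack) + 1]] <- list(
              p0 = s$p1, p1 = cp1, r = s$r * spec$radius_decay,
              level = s$level + 1L
            )
          }
        }
      }
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- cols
  # clipping against the brain boundary can collapse a child segment
  seglen <- sqrt((df$x1 - df$x0)^2 + (df$y1 - df$y0)^2 +
    (df$z1 - df$z0)^2)
  df <- df[seglen >= 1, , drop = FALSE]
  df$id <- seq_len(nrow(df))
  df$level <- as.integer(df$level)
  df$root <- as.integer(df$root)
  rownames(df) <- NULL
  attr(df, "root_radii") <- radii
  df
}

add_blob <- function(vals, g, center, amplitude, sigma) {
  pad <- 4 * sigma
  i0 <- pmax(0, floor((center - pad - g$origin) / g$spacing))
  i1 <- pmin(g$dim - 1, ceiling((center + pad - g$origin) / g$spacing))
  if (any(i1 < i0)) {
    return(vals)
  }
  ii <- seq(i0[1], i1[1])
  jj <- seq(i0[2], i1[2])
  kk <- seq(i0[3], i1[3])
  gx <- g$origin[1] + ii * g$spacing[1] - center[1]
  gy <- g$origin[2] + jj * g$spacing[2] - center[2]
  gz <- g$origin[3] + kk * g$spacing[3] - center[3]
  bx <- exp(-gx^2 / (2 * sigma^2))
  by <- exp(-gy^2 / (2 * sigma^2))
  bz <- exp(-gz^2 / (2 * sigma^2))
  blob <- amplitude * outer(outer(bx, by), bz)
  lin <- outer(
    outer(ii + 1, g$dim[1] * jj, "+"),
    g$dim[1] * g$dim[2] * kk, "+"
  )
  vals[lin] <- vals[lin] + as.vector(blob)
  vals
}

#' Plant an electrode that conflicts with a chosen vessel
#'
#' Chooses a point P on the target vessel's axis, draws a conflict depth
#' D from the spec's depth law (clamped to the geometrically feasible
#' interval), solves for a cortical entry point E on the smooth brain
#' surface with `|E - P| = D`, and lays a straight electrode from E
#' through P. The planted conflict's recorded depth is the arc length
#' from the brain-surface entry to the closest approach, which for a
#' straight trajectory through P is exactly D.
#'
#' @param truth ground-truth manifest (from [generate_phantom()] or
#'   being built up).
#' @param masks named list with at least the `brain` mask volume.
#' @param target_vessel row index into `truth$vessel_segments`.
#' @param spec the [phantom_spec()].
#' @param label electrode label.
#' @param depth optional conflict depth (mm); drawn from the depth law
#'   when `NULL`.
#' @param axis_frac position of P along the vessel axis in (0, 1).
#' @return the updated truth manifest (electrode appended to
#'   `truth$electrodes`, conflict appended to `truth$planted_conflicts`).
#' @export
plant_conflicting_electrode <- function(truth, masks, target_vessel, spec,
                                        label = "E01", depth = NULL,
                                        axis_frac = NULL) {
  segs <- truth$vessel_segments
  if (target_vessel < 1 || target_vessel > nrow(segs)) {
    stop("target vessel index out of range")
  }
  s <- segs[target_vessel, ]
  point_at <- function(frac) {
    c(
      s$x0 + frac * (s$x1 - s$x0),
      s$y0 + frac * (s$y1 - s$y0),
      s$z0 + frac * (s$z1 - s$z0)
    )
  }
  # plant where the target vessel is locally isolated: a conflict
  # point buried inside an overlapping larger vessel has no
  # well-defined diameter, so the ground truth would be ambiguous
  isolation <- function(pt) {
    gap <- Inf
    for (i in seq_len(nrow(segs))) {
      if (segs$id[i] == s$id) next
      b0 <- c(segs$x0[i], segs$y0[i], segs$z0[i])
      b1 <- c(segs$x1[i], segs$y1[i], segs$z1[i])
      cc <- seg_seg_closest(pt, pt, b0, b1)
      gap <- min(gap, sqrt(cc$d2) - segs$radius[i] - s$radius)
    }
    gap
  }
  if (is.null(axis_frac)) {
    fr0 <- runif(1, 0.3, 0.7)
    cand <- c(fr0, seq(0.2, 0.8, by = 0.1))
    gaps <- vapply(cand, function(f) isolation(point_at(f)), numeric(1))
    axis_frac <- if (any(gaps > 0.5)) {
      cand[which(gaps > 0.5)[1]]
    } else {
      cand[which.max(gaps)]
    }
  }
  p <- point_at(axis_frac)
  r0 <- truth$geometry$brain_radius
  rho <- vnorm(p)
  if (rho >= r0 || sample_volume(masks$brain, p, "nearest") < 0.5) {
    stop(
      "infeasible electrode: target vessel point lies outside the ",
      "brain mask"
    )
  }
  if (is.null(depth)) depth <- draw_lognormal_law(spec$depth_law, 1)
  n <- spec$contacts_per_electrode
  span <- (n - 1) * spec$contact_spacing
  # a planted conflict is a point event, which presupposes a
  # transverse crossing: sweep the entry circle until the trajectory
  # meets the vessel axis at >= 25 degrees (a grazing, near-parallel
  # pass has no well-defined conflict point or depth)
  vaxis <- unit(c(s$x1 - s$x0, s$y1 - s$y0, s$z1 - s$z0))
  phi0 <- runif(1, 0, 2 * pi)
  geom <- NULL
  best <- NULL
  best_score <- -Inf
  for (k in 0:15) {
    g <- solve_entry(p, rho, r0, depth, span, phi0 + k * pi / 8)
    if (is.null(g)) next
    ang <- acos(min(1, abs(sum(g$dir * vaxis)))) * 180 / pi
    # the whole path must not run lengthwise inside any vessel:
    # a grazing pass has no localizable conflict point
    grazes <- path_grazes_vessel(
      g$entry, g$dir, g$t_exit, segs, spec$electrode_radius,
      exclude = s$id
    )
    score <- ang - if (grazes) 1000 else 0
    if (score > best_score) {
      best_score <- score
      best <- g
    }
    if (ang >= 25 && !grazes) {
      geom <- g
      break
    }
  }
  if (is.null(geom)) geom <- best
  if (is.null(geom)) {
    stop(
      "infeasible electrode: no straight path through the target ",
      "fits ", n, " contacts spaced ", spec$contact_spacing, " mm"
    )
  }
  entry <- geom$entry
  dirv <- geom$dir
  d_use <- geom$depth
  # tip a few mm past the conflict, the whole contact span intracerebral
  tip_t <- min(max(d_use + 3, span + 0.5), geom$t_exit - 0.5)
  tip <- entry + tip_t * dirv
  contacts <- t(vapply(
    seq_len(n) - 1,
    function(j) tip - j * spec$contact_spacing * dirv,
    numeric(3)
  ))
  el <- electrode(contacts,
    label = label,
    radius = spec$electrode_radius
  )
  el$entry <- entry
  el$direction <- dirv
  truth$electrodes[[label]] <- el

  tc <- truth$geometry$cortical_thickness
  fdep <- fold_depth_point(spec, truth$geometry, p)
  in_gm <- (rho <= r0 - fdep) && (rho >= r0 - fdep - tc)
  in_sulcus <- in_gm && (r0 - rho > tc)
  row <- data.frame(
    electrode = label, x = p[1], y = p[2], z = p[3],
    vessel_id = s$id, radius = s$radius, diameter = s$diameter,
    depth = d_use, in_sulcus = in_sulcus, planted = TRUE,
    stringsAsFactors = FALSE
  )
  for (m in names(spec$modality_visibility)) {
    row[[paste0("visible_", m)]] <- s[[paste0("visible_", m)]]
  }
  truth$planted_conflicts <- rbind(truth$planted_conflicts, row)
  truth
}

# Closest points between two segments a0-a1 and b0-b1 (standard
# clamped quadratic). Returns squared distance and the parameters.
seg_seg_closest <- function(a0, a1, b0, b1) {
  u <- a1 - a0
  v <- b1 - b0
  w <- a0 - b0
  a <- sum(u * u)
  b <- sum(u * v)
  c <- sum(v * v)
  d <- sum(u * w)
  e <- sum(v * w)
  den <- a * c - b * b
  s <- if (den > 1e-12) (b * e - c * d) / den else 0
  s <- min(max(s, 0), 1)
  t <- if (c > 1e-12) (b * s + e) / c else 0
  t <- min(max(t, 0), 1)
  # re-clamp s for the clamped t
  s <- if (a > 1e-12) (b * t - d) / a else 0
  s <- min(max(s, 0), 1)
  pa <- a0 + s * u
  pb <- b0 + t * v
  list(d2 = sum((pa - pb)^2), s = s, t = t, pa = pa, pb = pb)
}

# TRUE if the straight path entry -> entry + t_exit*dir passes within
# (electrode radius + vessel radius + 0.3 mm) of a vessel axis at an
# incidence angle below 20 degrees (a lengthwise graze).
path_grazes_vessel <- function(entry, dirv, t_exit, segs, e_radius,
                               exclude = -1L) {
  if (nrow(segs) == 0) {
    return(FALSE)
  }
  a1 <- entry + t_exit * dirv
  for (i in seq_len(nrow(segs))) {
    if (segs$id[i] == exclude) next
    b0 <- c(segs$x0[i], segs$y0[i], segs$z0[i])
    b1 <- c(segs$x1[i], segs$y1[i], segs$z1[i])
    axis <- b1 - b0
    alen <- vnorm(axis)
    if (alen < 1e-6) next
    cc <- seg_seg_closest(entry, a1, b0, b1)
    if (sqrt(cc$d2) > e_radius + segs$radius[i] + 0.3) next
    ang <- acos(min(1, abs(sum(dirv * axis / alen)))) * 180 / pi
    if (ang < 20) {
      return(TRUE)
    }
  }
  FALSE
}

# Entry-point geometry for a straight electrode through P at depth
# `depth` from the spherical brain surface of radius r0. Entry points
# with |E| = r0 and |E - P| = d form a circle; the chord length through
# the brain grows monotonically with d, so if the drawn depth leaves no
# room for the contact span the depth is deepened to the smallest
# feasible value. Returns NULL when even the diametral path is too
# short.
solve_entry <- function(p, rho, r0, depth, span, phi) {
  dmin <- r0 - rho + 0.5
  dmax <- r0 + rho - 0.5
  if (dmin > dmax || span + 1 > 2 * r0) {
    return(NULL)
  }
  wv <- p / rho
  b <- plane_basis(wv)
  make <- function(d) {
    h <- (r0^2 + rho^2 - d^2) / (2 * rho)
    rad_c <- sqrt(max(0, r0^2 - h^2))
    entry <- h * wv + rad_c * (cos(phi) * b$u + sin(phi) * b$v)
    dirv <- unit(p - entry)
    tmid <- -sum(entry * dirv)
    t_exit <- tmid + sqrt(max(0, tmid^2 + r0^2 - sum(entry^2)))
    list(entry = entry, dir = dirv, depth = d, t_exit = t_exit)
  }
  d_use <- min(max(depth, dmin), dmax)
  g <- make(d_use)
  if (g$t_exit >= span + 1) {
    return(g)
  }
  # deepen until the chord fits the contact span
  for (d in seq(d_use, dmax, by = 0.5)) {
    g <- make(d)
    if (g$t_exit >= span + 1) {
      return(g)
    }
  }
  g <- make(dmax)
  if (g$t_exit >= span + 1) g else NULL
}

fold_depth_point <- function(spec, geometry, p) {
  rho <- vnorm(p)
  if (rho < 1e-9) {
    return(0)
  }
  fold_depth(spec, matrix(p / rho, ncol = 3))
}

# electrode along a random chord with no vessel target (used when the
# phantom has no vessels); records no conflict
plant_free_electrode <- function(truth, spec, label = "E01") {
  r0 <- truth$geometry$brain_radius
  p <- runif(1, 0.3, 0.6) * r0 * unit(rnorm(3))
  depth <- draw_lognormal_law(spec$depth_law, 1)
  rho <- vnorm(p)
  n <- spec$contacts_per_electrode
  span <- (n - 1) * spec$contact_spacing
  geom <- solve_entry(p, rho, r0, depth, span, runif(1, 0, 2 * pi))
  if (is.null(geom)) {
    stop(
      "grid too small to contain the requested electrodes: the brain ",
      "chord cannot fit ", n, " contacts spaced ",
      spec$contact_spacing, " mm"
    )
  }
  entry <- geom$entry
  dirv <- geom$dir
  tip_t <- min(max(geom$depth, span + 0.5), geom$t_exit - 0.5)
  tip <- entry + tip_t * dirv
  contacts <- t(vapply(
    seq_len(n) - 1,
    function(j) tip - j * spec$contact_spacing * dirv,
    numeric(3)
  ))
  el <- electrode(contacts, label = label, radius = spec$electrode_radius)
  el$entry <- entry
  el$direction <- dirv
  truth$electrodes[[label]] <- el
  truth
}

#' Write a phantom to disk
#'
#' Volumes go out as NIfTI-1 (RAS+ affines); the ground-truth manifest as
#' JSON.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(phantom$masks)) {
    write_volume(phantom$masks[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  }
  for (nm in names(phantom$modalities)) {
    write_volume(
      phantom$modalities[[nm]],
      file.path(dir, paste0(nm, ".nii.gz"))
    )
  }
  write_volume(phantom$ct, file.path(dir, "ct.nii.gz"))
  manifest <- list(
    vessel_segments = phantom$truth$vessel_segments,
    planted_conflicts = phantom$truth$planted_conflicts,
    geometry = phantom$truth$geometry,
    electrodes = lapply(phantom$truth$electrodes, function(e) {
      list(
        label = e$label, radius = e$radius,
        contacts = unname(as.matrix(e$contacts))
      )
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
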