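#' Depth electrode with ordered contacts
#'
#' Contacts are world-mm centroids ordered tip first. The implemented
#' trajectory is the piecewise-linear chain through the contacts: SEEG
#' electrodes bend only slightly, so linear interpolation between
#' contacts recovers the radiotransparent lead between them.
#'
#' @param contacts n x 3 matrix of contact centroids (mm), tip first.
#' @param label electrode label.
#' @param radius physical electrode radius, mm (default 0.4; set 0 to
#'   measure distances from the electrode axis instead of its surface).
#' @return object of class `electrode`.
#' @export
electrode <- function(contacts, label = "E", radius = 0.4) {
  contacts <- rbind_matrix(contacts)
  if (nrow(contacts) < 2) stop("an electrode needs at least 2 contacts")
  gaps <- sqrt(rowSums((contacts[-1, , drop = FALSE] -
    contacts[-nrow(contacts), , drop = FALSE])^2))
  if (any(gaps <= 0)) stop("consecutive contacts must be distinct")
  structure(
    list(
      label = label, contacts = contacts, radius = radius,
      spacing = gaps
    ),
    class = "electrode"
  )
}

#' @export
print.electrode <- function(x, ...) {
  cat(sprintf(
    "<electrode %s> %d contacts, mean spacing %.2f mm, radius %.2f mm\n",
    x$label, nrow(x$contacts), mean(x$spacing), x$radius
  ))
  invisible(x)
}

#' Segment electrode contacts from a CT-like volume
#'
#' Thresholds the volume and returns one intensity-weighted centroid per
#' connected supra-threshold component, in world mm. The CT should
#' already be resampled into the reference space.
#'
#' @param ct a [volume_grid()].
#' @param intensity_threshold voxels above this value are contact
#'   candidates.
#' @param connectivity 6 or 26 (default 26).
#' @param min_voxels drop components smaller than this (noise guard).
#' @return list with `centroids` (n x 3 matrix, world mm) and `sizes`
#'   (component voxel counts). Zero components give a 0-row matrix.
#' @export
segment_contacts <- function(ct, intensity_threshold, connectivity = 26,
                             min_voxels = 1) {
  mask <- ct$values > intensity_threshold
  d <- dim(ct$values)
  lab <- .label_components_cpp(as.logical(mask), as.integer(d),
    connectivity = as.integer(connectivity)
  )
  nlab <- max(lab)
  if (nlab == 0) {
    return(list(centroids = matrix(numeric(0), 0, 3), sizes = integer(0)))
  }
  sel <- which(lab > 0)
  labs <- lab[sel]
  wts <- as.double(ct$values)[sel]
  ijk <- arrayInd(sel, d) - 1L
  totw <- tapply(wts, labs, sum)
  cx <- tapply(wts * ijk[, 1], labs, sum) / totw
  cy <- tapply(wts * ijk[, 2], labs, sum) / totw
  cz <- tapply(wts * ijk[, 3], labs, sum) / totw
  sizes <- as.integer(table(labs))
  keep <- sizes >= min_voxels
  cen_vox <- cbind(cx, cy, cz)[keep, , drop = FALSE]
  list(
    centroids = voxel_to_world(ct, cen_vox),
    sizes = sizes[keep]
  )
}

#' Group contact centroids into electrodes
#'
#' Greedy collinear grouping: repeatedly finds the line (seeded by a
#' centroid pair) that collects the most centroids within
#' `collinearity_tol` of it with plausible along-axis spacing, refines
#' the line by principal axis, and assigns the collected centroids to
#' one electrode. Each centroid is assigned at most once; leftovers are
#' reported, not silently dropped.
#'
#' @param centroids n x 3 matrix (world mm).
#' @param expected_spacing nominal contact spacing, mm.
#' @param collinearity_tol maximum perpendicular distance from the fitted
#'   axis, mm.
#' @param min_contacts minimum contacts per electrode (default 3).
#' @param max_contacts known contacts per electrode, if any: longer
#'   chains (a crossing electrode donating collinear-looking contacts)
#'   are trimmed from the ends, largest perpendicular residual first,
#'   and the trimmed contacts return to the pool.
#' @param radius electrode radius passed through to [electrode()].
#' @return list with `electrodes` (list of [electrode()]) and
#'   `unassigned` (row indices of unassigned centroids).
#' @export
group_into_electrodes <- function(centroids, expected_spacing,
                                  collinearity_tol = 1,
                                  min_contacts = 3,
                                  max_contacts = NULL,
                                  radius = 0.4) {
  centroids <- rbind_matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) {
    return(list(electrodes = list(), unassigned = seq_len(n)))
  }
  avail <- rep(TRUE, n)
  electrodes <- list()
  repeat {
    idx <- which(avail)
    if (length(idx) < min_contacts) break
    best <- NULL
    best_n <- 0
    best_rms <- Inf
    pts <- centroids[idx, , drop = FALSE]
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        p0 <- pts[a, ]
        dv <- pts[b, ] - p0
        L <- vnorm(dv)
        if (L < 0.25 * expected_spacing) next
        dv <- dv / L
        rel <- sweep(pts, 2, p0)
        tproj <- rel %*% dv
        perp2 <- rowSums(rel^2) - tproj^2
        hit <- perp2 <= collinearity_tol^2
        # require a contiguous chain: sort projections, break at big gaps,
        # keep the run containing the seed pair
        cand <- which(hit)
        if (length(cand) < 2) next
        runs <- chain_runs(cand, tproj, perp2, expected_spacing)
        run <- NULL
        for (rn in runs) if (a %in% rn && b %in% rn) run <- rn
        if (is.null(run)) next
        rms <- sqrt(mean(pmax(perp2[run], 0)))
        if (length(run) > best_n ||
          (length(run) == best_n && rms < best_rms)) {
          best_n <- length(run)
          best_rms <- rms
          best <- run
        }
      }
    }
    if (is.null(best) || best_n < min_contacts) break
    sel <- idx[best]
    # refine axis by principal component and order along it
    p <- centroids[sel, , drop = FALSE]
    ctr <- colMeans(p)
    ax <- svd(sweep(p, 2, ctr))$v[, 1]
    tproj <- as.vector(sweep(p, 2, ctr) %*% ax)
    perp2 <- rowSums(sweep(p, 2, ctr)^2) - tproj^2
    runs <- chain_runs(seq_len(nrow(p)), tproj, perp2, expected_spacing)
    keep <- runs[[which.max(lengths(runs))]]
    if (!is.null(max_contacts)) {
      while (length(keep) > max_contacts) {
        ends <- c(keep[1], keep[length(keep)])
        drop_first <- perp2[ends[1]] >= perp2[ends[2]]
        keep <- if (drop_first) keep[-1] else keep[-length(keep)]
      }
    }
    sel <- sel[keep]
    p <- p[keep, , drop = FALSE]
    ord <- order(tproj[keep])
    lab <- sprintf("G%02d", length(electrodes) + 1)
    electrodes[[lab]] <- electrode(p[ord, , drop = FALSE],
      label = lab,
      radius = radius
    )
    avail[sel] <- FALSE
  }
  list(electrodes = electrodes, unassigned = which(avail))
}

#' Sample a trajectory at uniform arc-length steps
#'
#' Densifies the piecewise-linear contact chain and extends it
#' proximally to the brain-mask entry point, so that
#' `arc_length_from_entry` is 0 where the trajectory first enters the
#' brain: depths of conflicts are measured from the cortical surface,
#' operationalized here as the brain-mask boundary. The contact order is
#' oriented automatically (the tip is the end lying deeper in the brain
#' mask).
#'
#' @param e an [electrode()].
#' @param step sampling step, mm (default 0.5).
#' @param brain_mask brain mask [volume_grid()]; required to locate the
#'   entry point.
#' @param entry_hint optional world-mm position of the planned entry
#'   point for this electrode (from the implantation plan). When a
#'   contact chain spans almost the whole brain, the deep and proximal
#'   ends cannot be told apart from geometry alone; the hint resolves
#'   the ambiguity the way the planning record does clinically.
#' @return data.frame of class `trajectory_samples` with columns
#'   `x, y, z` (mm), `arc` (mm from entry, negative = extracerebral) and
#'   unit tangents `tx, ty, tz`.
#' @export
interpolate_trajectory <- function(e, step = 0.5, brain_mask,
                                   entry_hint = NULL) {
  stopifnot(inherits(e, "electrode"))
  if (step <= 0) stop("`step` must be positive")
  contacts <- e$contacts
  inside <- sample_volume(brain_mask, contacts, "nearest") > 0.5
  if (!any(inside)) {
    stop("electrode ", e$label, " lies entirely outside the brain mask")
  }
  nlast <- nrow(contacts)
  if (!is.null(entry_hint)) {
    # tip = the end farther from the planned entry
    d1 <- vnorm(contacts[1, ] - entry_hint)
    dn <- vnorm(contacts[nlast, ] - entry_hint)
    if (dn > d1) contacts <- contacts[nlast:1, , drop = FALSE]
  } else {
    # orient tip-first: the tip is the deep end, i.e. the end with the
    # most brain ahead of it when extending outward beyond the
    # electrode; the proximal end exits through the surface quickly
    depth_a <- exit_distance(
      contacts[1, ],
      unit(contacts[1, ] - contacts[2, ]), brain_mask, step
    )
    depth_b <- exit_distance(
      contacts[nlast, ],
      unit(contacts[nlast, ] - contacts[nlast - 1, ]), brain_mask, step
    )
    score_a <- if (inside[1]) depth_a else -1
    score_b <- if (inside[nlast]) depth_b else -1
    if (score_b > score_a) contacts <- contacts[nlast:1, , drop = FALSE]
  }
  # walk from the last row (proximal) toward the first (tip)
  chain <- contacts[nrow(contacts):1, , drop = FALSE]
  back_dir <- unit(chain[1, ] - chain[2, ])
  # extend proximally until outside the brain mask; the march runs at
  # a fixed sub-voxel resolution so the polyline start (and with it
  # every sample position) is independent of the sampling step
  fine <- min(grid_spacing(brain_mask)) / 4
  ext <- 0
  pmax_ext <- 2 * max(dim(brain_mask$values) * grid_spacing(brain_mask))
  while (ext < pmax_ext &&
    sample_volume(brain_mask, chain[1, ] + ext * back_dir,
      "nearest") > 0.5) {
    ext <- ext + fine
  }
  start <- chain[1, ] + ext * back_dir
  poly <- rbind(start, chain)
  rs <- resample_polyline(poly, step)
  inside_s <- sample_volume(brain_mask, rs$points, "nearest") > 0.5
  if (!any(inside_s)) {
    stop("electrode ", e$label, " lies entirely outside the brain mask")
  }
  entry_arc <- rs$arc[which(inside_s)[1]]
  out <- data.frame(
    x = rs$points[, 1], y = rs$points[, 2], z = rs$points[, 3],
    arc = rs$arc - entry_arc,
    tx = rs$tangents[, 1], ty = rs$tangents[, 2], tz = rs$tangents[, 3],
    inside = inside_s
  )
  attr(out, "electrode") <- e$label
  attr(out, "radius") <- e$radius
  attr(out, "step") <- step
  class(out) <- c("trajectory_samples", "data.frame")
  out
}

# Split chain candidates into runs with electrode-like spacing:
# de-duplicate near-coincident axial positions, then break wherever
# the gap is not close to one contact spacing (or two, tolerating a
# single lost contact). Contacts stolen from a crossing electrode
# rarely land on the spacing grid, so they fall off here and stay in
# the pool for their own electrode.
chain_runs <- function(cand, tproj, perp2, spacing) {
  ord <- cand[order(tproj[cand])]
  ord <- dedupe_chain(ord, tproj, perp2, 0.5 * spacing)
  if (length(ord) < 2) {
    return(list(ord))
  }
  gaps <- diff(tproj[ord])
  # a gap must sit on the contact-spacing grid; up to two consecutive
  # contacts may be missing (lost to blobs merged where electrodes
  # cross)
  k <- round(gaps / spacing)
  bad <- k < 1 | k > 3 | abs(gaps - k * spacing) > 0.35 * spacing
  brk <- c(0, which(bad), length(ord))
  mapply(function(s, e) ord[(s + 1):e], head(brk, -1), tail(brk, -1),
    SIMPLIFY = FALSE
  )
}

# Resolve axial-position collisions in a sorted chain: when two points
# project within `min_sep` of each other along the axis, keep the one
# with the smaller perpendicular residual. `ord` is index order by
# projection; returns the surviving subset in projection order.
dedupe_chain <- function(ord, tproj, perp2, min_sep) {
  if (length(ord) < 2) {
    return(ord)
  }
  keep <- rep(TRUE, length(ord))
  i <- 1
  while (i < length(ord)) {
    ni <- i + 1
    while (ni <= length(ord) && !keep[ni]) ni <- ni + 1
    if (ni > length(ord)) break
    if (tproj[ord[ni]] - tproj[ord[i]] < min_sep) {
      if (perp2[ord[ni]] < perp2[ord[i]]) {
        keep[i] <- FALSE
        i <- ni
      } else {
        keep[ni] <- FALSE
      }
    } else {
      i <- ni
    }
  }
  ord[keep]
}

# distance travelled from p along direction d before leaving the mask
exit_distance <- function(p, d, mask, step) {
  t <- 0
  lim <- 2 * max(dim(mask$values) * grid_spacing(mask))
  while (t < lim) {
    if (sample_volume(mask, p + t * d, "nearest") < 0.5) {
      return(t)
    }
    t <- t + step
  }
  lim
}

#' Serialize electrodes to JSON
#'
#' @param electrodes list of [electrode()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_electrodes <- function(electrodes, path) {
  jsonlite::write_json(
    lapply(electrodes, function(e) {
      list(
        label = e$label, radius = e$radius,
        contacts = unname(as.matrix(e$contacts))
      )
    }),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
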