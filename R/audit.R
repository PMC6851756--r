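#' Distance profile of an electrode against a vascular distance field
#'
#' Samples the distance field along the trajectory (linear
#' interpolation for sub-voxel smoothness) and subtracts the electrode
#' radius, clamped at zero: the profile is the surface-to-vessel
#' distance at each arc-length position. Only intracerebral samples
#' (arc >= 0) enter the profile. Two distinct thresholds matter
#' downstream: the *conflict* threshold (0 mm = overlap, the definition
#' of an electrode-vessel conflict) and the *safety margin* SM (3 mm,
#' the planning margin used in risk scoring and review displays).
#'
#' @param samples a `trajectory_samples` data.frame from
#'   [interpolate_trajectory()].
#' @param field a [distance_field()].
#' @param electrode_radius mm; defaults to the radius recorded on the
#'   samples.
#' @param safety_margin SM in mm (default 3).
#' @return data.frame of class `distance_profile` with columns `arc`
#'   and `distance` (mm); attribute `no_vasculature` is `TRUE` when the
#'   field was empty.
#' @export
distance_profile <- function(samples, field, electrode_radius = NULL,
                             safety_margin = 3) {
  if (is.null(electrode_radius)) {
    electrode_radius <- attr(samples, "radius")
    if (is.null(electrode_radius)) electrode_radius <- 0
  }
  keep <- samples$arc >= 0
  pts <- as.matrix(samples[keep, c("x", "y", "z")])
  arc <- samples$arc[keep]
  if (field$empty) {
    out <- data.frame(arc = arc, distance = rep(Inf, length(arc)))
  } else {
    # background = max finite distance so edge samples never fake a hit
    bg <- max(field$distances$values[is.finite(field$distances$values)])
    dv <- sample_volume(field$distances, pts, "linear", background = bg)
    # `distance` is clamped at 0 (surface-to-structure separation);
    # `signed` keeps the raw field minus radius so the deepest
    # penetration of a crossed vessel stays localizable
    out <- data.frame(
      arc = arc, distance = pmax(0, dv - electrode_radius),
      signed = dv - electrode_radius
    )
  }
  attr(out, "no_vasculature") <- field$empty
  attr(out, "safety_margin") <- safety_margin
  attr(out, "electrode_radius") <- electrode_radius
  attr(out, "electrode") <- attr(samples, "electrode")
  attr(out, "positions") <- pts
  attr(out, "tangents") <- as.matrix(samples[keep, c("tx", "ty", "tz")])
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Detect electrode-vessel conflicts along a profile
#'
#' A conflict is a maximal run of profile samples whose distance is at
#' or below `conflict_threshold` (default 0 mm: overlap between the
#' electrode and the vascular segmentation). Runs separated by less
#' than `merge_gap` of arc length are merged so one vessel crossed
#' obliquely is not double-counted. Each event is located at its run's
#' minimum-distance sample.
#'
#' @param profile a [distance_profile()].
#' @param conflict_threshold mm (default 0 = overlap).
#' @param merge_gap mm (default 2).
#' @param split_prominence mm (default 0.5): within one below-threshold
#'   run, distinct penetration minima separated by a rise of at least
#'   this much are reported as separate events - two vessels crossed
#'   back to back are two conflicts even when the clamped profile
#'   never surfaces between them. Requires a signed profile; with only
#'   clamped distances a run stays one event.
#' @return data.frame of conflict events: `electrode`, `x, y, z`,
#'   `arc` (= depth from cortical entry, mm), `min_distance`,
#'   `arc_start`, `arc_end`. Empty when nothing dips below threshold.
#' @export
detect_conflicts <- function(profile, conflict_threshold = 0,
                             merge_gap = 2, split_prominence = 0.5) {
  lab <- attr(profile, "electrode")
  if (is.null(lab)) lab <- ""
  empty <- data.frame(
    electrode = character(0), x = numeric(0), y = numeric(0),
    z = numeric(0), arc = numeric(0), min_distance = numeric(0),
    arc_start = numeric(0), arc_end = numeric(0),
    stringsAsFactors = FALSE
  )
  if (isTRUE(attr(profile, "no_vasculature")) || nrow(profile) == 0) {
    return(empty)
  }
  loc <- if (!is.null(profile$signed)) profile$signed else profile$distance
  hit <- profile$distance <= conflict_threshold
  if (!any(hit)) {
    return(empty)
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(
    start = starts[r$values], end = ends[r$values]
  )
  # merge runs separated by less than merge_gap of arc
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- profile$arc[runs$start[i]] -
        profile$arc[merged$end[nrow(merged)]]
      if (gap < merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  pos <- attr(profile, "positions")
  out <- lapply(seq_len(nrow(merged)), function(i) {
    sel <- merged$start[i]:merged$end[i]
    # events sit where the electrode penetrates deepest: the signed
    # distance keeps those points resolvable inside the vasculature,
    # where the clamped distance is a flat run of zeros; prominent
    # separate dips are separate vessels
    pieces <- split_run_minima(loc[sel], split_prominence)
    rows <- lapply(pieces, function(pc) {
      j <- sel[pc$minimum]
      data.frame(
        electrode = lab, x = pos[j, 1], y = pos[j, 2], z = pos[j, 3],
        arc = profile$arc[j], min_distance = profile$distance[j],
        arc_start = profile$arc[sel[pc$from]],
        arc_end = profile$arc[sel[pc$to]],
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

# Partition one below-threshold run into sub-events at its prominent
# local minima. Adjacent minima are merged while the col between them
# rises less than `prominence` above the shallower one; plateaus
# resolve to their middle sample. Returns a list of pieces
# (from, to, minimum), indices relative to the run.
split_run_minima <- function(v, prominence) {
  n <- length(v)
  plateau_mid <- function(from, to) from + (to - from) %/% 2
  # local minima with plateau handling
  mins <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    left_ok <- i == 1 || v[i - 1] > v[i]
    right_ok <- j == n || v[j + 1] > v[i]
    if (left_ok && right_ok) mins <- c(mins, plateau_mid(i, j))
    i <- j + 1
  }
  if (length(mins) == 0) mins <- which.min(v)
  # merge adjacent minima with insufficient separating col
  while (length(mins) > 1) {
    cols <- vapply(seq_len(length(mins) - 1), function(k) {
      max(v[mins[k]:mins[k + 1]])
    }, numeric(1))
    gain <- cols - pmax(v[mins[-length(mins)]], v[mins[-1]])
    k <- which.min(gain)
    if (gain[k] >= prominence) break
    drop <- if (v[mins[k]] > v[mins[k + 1]]) k else k + 1
    mins <- mins[-drop]
  }
  # piece boundaries at the cols between surviving minima
  bounds <- c(1)
  if (length(mins) > 1) {
    for (k in seq_len(length(mins) - 1)) {
      seg <- mins[k]:mins[k + 1]
      bounds <- c(bounds, seg[which.max(v[seg])])
    }
  }
  bounds <- c(bounds, n)
  lapply(seq_along(mins), function(k) {
    list(from = bounds[k], to = bounds[k + 1], minimum = mins[k])
  })
}

#' Characterize conflict events
#'
#' Completes detected events with the vessel diameter at the conflict
#' site (inscribed-sphere estimate on the segmentation), the depth from
#' the cortical entry (the event's arc length), and sulcal membership
#' (event position inside the sulcal exclusion model). Events whose
#' site has no vessel within the capture radius keep `diameter = NA`
#' (unresolved) but are retained.
#'
#' @param events data.frame from [detect_conflicts()].
#' @param seg the `vessel_segmentation` the conflicts were detected
#'   against.
#' @param sulcal optional [build_sulcal_model()] result.
#' @param capture_radius passed to [local_diameter()].
#' @return the events data.frame with `depth`, `diameter`, `in_sulcus`
#'   columns added.
#' @export
characterize_conflicts <- function(events, seg, sulcal = NULL,
                                   capture_radius = 2) {
  if (nrow(events) == 0) {
    events$depth <- numeric(0)
    events$diameter <- numeric(0)
    events$in_sulcus <- logical(0)
    return(events)
  }
  internal <- internal_distance(seg)
  events$depth <- events$arc
  events$diameter <- vapply(seq_len(nrow(events)), function(i) {
    tryCatch(
      local_diameter(seg, c(events$x[i], events$y[i], events$z[i]),
        capture_radius = capture_radius, internal = internal
      ),
      error = function(e) NA_real_
    )
  }, numeric(1))
  events$in_sulcus <- if (is.null(sulcal)) {
    rep(NA, nrow(events))
  } else {
    sample_volume(
      sulcal$mask, as.matrix(events[, c("x", "y", "z")]), "nearest"
    ) > 0.5
  }
  events
}

#' Per-electrode risk metrics
#'
#' Summaries displayed alongside each implanted trajectory:
#' intracerebral length, the drilling angle to the skull surface at the
#' entry point (90 degrees = orthogonal, the planning ideal), a
#' cumulative margin-violation risk score, the gray/white sampling
#' ratio, and the minimum distance from vasculature. The risk score is
#' the mean over intracerebral samples of `max(0, (SM - d) / SM)`: 0
#' iff the whole profile respects the safety margin, 1 iff the
#' electrode tracks the vasculature the whole way.
#'
#' @param samples a `trajectory_samples` data.frame.
#' @param profile the matching [distance_profile()].
#' @param brain_mask,gm_mask,wm_mask tissue masks on the reference
#'   grid.
#' @param safety_margin SM in mm (default 3).
#' @return list of class `risk_metrics`.
#' @export
risk_metrics <- function(samples, profile, brain_mask, gm_mask = NULL,
                         wm_mask = NULL, safety_margin = 3) {
  inb <- samples$arc >= 0 & samples$inside
  if (!any(inb)) stop("degenerate trajectory: no intracerebral samples")
  step <- attr(samples, "step")
  intra_len <- sum(inb) * step
  # angle to the skull plane at entry: 90 deg when the trajectory is
  # parallel to the inward surface normal (orthogonal drilling)
  entry_i <- which(samples$arc >= 0)[1]
  p_entry <- as.numeric(samples[entry_i, c("x", "y", "z")])
  tangent <- as.numeric(samples[entry_i, c("tx", "ty", "tz")])
  sp <- grid_spacing(brain_mask)
  smv <- .gaussian_smooth_cpp(
    as.double(brain_mask$values > 0.5),
    as.integer(dim(brain_mask$values)), sp, min(sp)
  )
  smg <- volume_grid(array(smv, dim(brain_mask$values)), brain_mask$affine)
  nrm <- as.numeric(mask_gradient(smg, matrix(p_entry, ncol = 3)))
  angle <- if (vnorm(nrm) < 1e-9) {
    NA_real_
  } else {
    ca <- abs(sum(unit(nrm) * unit(tangent)))
    90 - acos(min(1, ca)) * 180 / pi
  }
  dists <- profile$distance[is.finite(profile$distance)]
  risk <- if (length(dists) == 0) {
    0
  } else {
    mean(pmax(0, (safety_margin - dists) / safety_margin))
  }
  gw <- NA_real_
  if (!is.null(gm_mask) && !is.null(wm_mask)) {
    pts <- as.matrix(samples[inb, c("x", "y", "z")])
    ng <- sum(sample_volume(gm_mask, pts, "nearest") > 0.5)
    nw <- sum(sample_volume(wm_mask, pts, "nearest") > 0.5)
    gw <- if (nw == 0) Inf else ng / nw
  }
  structure(
    list(
      intracerebral_length = intra_len,
      angle_to_skull = angle,
      risk_score = risk,
      gw_ratio = gw,
      min_distance = if (nrow(profile) > 0) min(profile$distance) else Inf
    ),
    class = "risk_metrics"
  )
}

#' @export
print.risk_metrics <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<risk_metrics> length %.1f mm | angle %.0f deg | risk %.3f | ",
      "G/W %.2f | min dist %.2f mm\n"
    ),
    x$intracerebral_length, x$angle_to_skull, x$risk_score, x$gw_ratio,
    x$min_distance
  ))
  invisible(x)
}

#' Summarize an audit into a report
#'
#' @param events conflict events across all electrodes (characterized).
#' @param n_electrodes number of electrodes audited.
#' @param n_patients number of patients (default 1).
#' @return list of class `audit_report` with per-electrode counts,
#'   conflict medians/IQRs, and the sulcal fraction.
#' @export
audit_report <- function(events, n_electrodes, n_patients = 1) {
  qs <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) {
      return(c(median = NA, q1 = NA, q3 = NA))
    }
    c(
      median = median(x), q1 = unname(quantile(x, 0.25)),
      q3 = unname(quantile(x, 0.75))
    )
  }
  per_el <- if (nrow(events) > 0) table(events$electrode) else table(character(0))
  structure(
    list(
      n_conflicts = nrow(events),
      n_electrodes = n_electrodes,
      n_patients = n_patients,
      conflicts_per_electrode = as.integer(per_el),
      diameter = qs(events$diameter),
      depth = qs(events$depth),
      sulcal_fraction = if (nrow(events) == 0 ||
        all(is.na(events$in_sulcus))) {
        NA_real_
      } else {
        mean(events$in_sulcus, na.rm = TRUE)
      }
    ),
    class = "audit_report"
  )
}

#' Write conflict events as CSV
#'
#' One row per conflict (electrode, position, depth, diameter, sulcal
#' flag, any per-modality detection flags). Formatting is fixed so
#' identical audits produce byte-identical files.
#'
#' @param events conflict events data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_audit_csv <- function(events, path) {
  num <- vapply(events, is.numeric, logical(1))
  out <- events
  out[num] <- lapply(events[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.6f", x))
  })
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
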