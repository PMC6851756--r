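#' Detection table for one modality variant
#'
#' Counts of how an automated collision detector working from one
#' modality's vascular segmentation performed against the reference
#' conflict set (the manually verified raw-DSA conflicts in the
#' clinical setting; the planted manifest on phantoms).
#'
#' @param modality modality label.
#' @param variant `"raw"`, `"segmentation"` or `"+sulcal"`.
#' @param n_reference total reference conflicts.
#' @param n_detected reference conflicts the detector found.
#' @param n_flagged all conflicts the detector reported
#'   (default `n_detected + n_spurious`).
#' @param n_spurious flagged conflicts absent from the reference set.
#' @param detected optional logical vector (length `n_reference`),
#'   per-reference-event detection flags; enables [sulcal_union()].
#' @param n_raw_visible reference conflicts visible on this modality's
#'   raw image (NA when unknown).
#' @param n_raw_missed_by_seg raw-visible conflicts the segmentation
#'   missed.
#' @return object of class `detection_table`.
#' @export
detection_table <- function(modality, variant = "segmentation",
                            n_reference, n_detected,
                            n_spurious = 0,
                            n_flagged = n_detected + n_spurious,
                            detected = NULL,
                            n_raw_visible = NA_integer_,
                            n_raw_missed_by_seg = NA_integer_) {
  if (n_detected > n_reference) {
    stop("n_detected cannot exceed n_reference")
  }
  if (n_flagged != n_detected + n_spurious) {
    stop("n_flagged must equal n_detected + n_spurious")
  }
  if (!is.na(n_raw_visible) && !is.na(n_raw_missed_by_seg) &&
    n_raw_missed_by_seg > n_raw_visible) {
    stop("n_raw_missed_by_seg cannot exceed n_raw_visible")
  }
  if (!is.null(detected)) {
    if (length(detected) != n_reference) {
      stop("`detected` must have one flag per reference conflict")
    }
    if (sum(detected) != n_detected) {
      stop("`detected` flags disagree with n_detected")
    }
  }
  structure(
    list(
      modality = modality, variant = variant,
      n_reference = n_reference, n_detected = n_detected,
      n_flagged = n_flagged, n_spurious = n_spurious,
      detected = detected,
      n_raw_visible = n_raw_visible,
      n_raw_missed_by_seg = n_raw_missed_by_seg
    ),
    class = "detection_table"
  )
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf(
    "<detection_table %s %s> detected %d/%d, flagged %d (%d spurious)\n",
    x$modality, x$variant, x$n_detected, x$n_reference, x$n_flagged,
    x$n_spurious
  ))
  invisible(x)
}

#' Match candidate conflicts against the reference set
#'
#' Greedy nearest-pair matching within a world-distance tolerance: the
#' closest reference-candidate pair is matched first, each event at
#' most once. Matched candidates are detections; unmatched reference
#' events are misses; unmatched candidates are spurious.
#'
#' @param reference n x 3 matrix of reference conflict positions (mm).
#' @param candidates m x 3 matrix of detector-reported positions (mm).
#' @param tolerance matching radius, mm (default 3, one safety margin).
#' @param modality,variant labels for the resulting table.
#' @return a [detection_table()] carrying per-reference `detected`
#'   flags and a `matched_candidate` attribute (candidate row per
#'   reference event, NA when missed).
#' @export
match_conflicts <- function(reference, candidates, tolerance = 3,
                            modality = "", variant = "segmentation") {
  reference <- rbind_matrix(reference)
  candidates <- rbind_matrix(candidates)
  nr <- nrow(reference)
  nc <- nrow(candidates)
  matched <- rep(NA_integer_, nr)
  if (nr > 0 && nc > 0) {
    dd <- outer(seq_len(nr), seq_len(nc), function(i, j) {
      sqrt(rowSums((reference[i, , drop = FALSE] -
        candidates[j, , drop = FALSE])^2))
    })
    dd[dd > tolerance] <- Inf
    while (any(is.finite(dd))) {
      k <- arrayInd(which.min(dd), dim(dd))
      matched[k[1]] <- k[2]
      dd[k[1], ] <- Inf
      dd[, k[2]] <- Inf
    }
  }
  detected <- !is.na(matched)
  tab <- detection_table(
    modality = modality, variant = variant,
    n_reference = nr, n_detected = sum(detected),
    n_spurious = nc - sum(detected),
    detected = detected
  )
  attr(tab, "matched_candidate") <- matched
  tab
}

#' Record raw-image visibility on a detection table
#'
#' @param tab a [detection_table()] with per-event `detected` flags.
#' @param raw_visible logical vector: reference conflicts visible on
#'   this modality's raw image.
#' @return the table with `n_raw_visible` / `n_raw_missed_by_seg` set.
#' @export
set_raw_visibility <- function(tab, raw_visible) {
  if (length(raw_visible) != tab$n_reference) {
    stop("`raw_visible` must have one flag per reference conflict")
  }
  tab$n_raw_visible <- sum(raw_visible)
  tab$n_raw_missed_by_seg <- if (is.null(tab$detected)) {
    NA_integer_
  } else {
    sum(raw_visible & !tab$detected)
  }
  tab
}

#' Sensitivity and error rates of a detection table
#'
#' The rates use the mixed denominators of the clinical accounting:
#' sensitivity and the false-negative rate are fractions of the
#' *reference* conflicts; the false-positive rate is a fraction of the
#' conflicts the detector *flagged*; the raw-vs-segmentation
#' false-negative rate is a fraction of the conflicts *visible on the
#' raw image* of that modality. Percentages are rounded to the nearest
#' integer, except that one decimal is kept when the value sits close
#' enough to halfway that integer rounding would misstate it (e.g.
#' 44/166 prints as 26.5).
#'
#' @param tab a [detection_table()].
#' @return list with `sensitivity`, `fn_rate`, `fp_rate`,
#'   `raw_seg_fn_rate` (percent, paper-style rounding), their `_exact`
#'   unrounded counterparts, and the fractions as strings. Undefined
#'   rates (zero denominator) are `NA`, never 0.
#' @export
detection_metrics <- function(tab) {
  pct <- function(num, den) {
    if (is.na(den) || den == 0) {
      return(list(p = NA_real_, e = NA_real_, f = NA_character_))
    }
    e <- 100 * num / den
    list(p = round_rate(e), e = e, f = sprintf("%d/%d", num, den))
  }
  sens <- pct(tab$n_detected, tab$n_reference)
  fn <- pct(tab$n_reference - tab$n_detected, tab$n_reference)
  fp <- pct(tab$n_spurious, tab$n_flagged)
  rs <- pct(tab$n_raw_missed_by_seg, tab$n_raw_visible)
  list(
    sensitivity = sens$p, fn_rate = fn$p, fp_rate = fp$p,
    raw_seg_fn_rate = rs$p,
    sensitivity_exact = sens$e, fn_rate_exact = fn$e,
    fp_rate_exact = fp$e, raw_seg_fn_rate_exact = rs$e,
    fractions = c(
      sensitivity = sens$f, fn_rate = fn$f, fp_rate = fp$f,
      raw_seg_fn_rate = rs$f
    )
  )
}

# integer percent, except one decimal when the value is near halfway
# (within 0.05 of *.5) so integer rounding would misstate it
round_rate <- function(x) {
  if (abs(x - round(x)) >= 0.45) round(x, 1) else round(x)
}

#' Chi-squared comparison of two detection tables
#'
#' 2x2 test on detected/missed counts (no continuity correction by
#' default, matching the closed-form `N(ad-bc)^2 / row-column
#' products` statistic). A warning is attached when any expected cell
#' falls below 1.
#'
#' @param a,b [detection_table()]s sharing reference semantics.
#' @param correct apply the Yates continuity correction.
#' @return list of class `comparison_result`: `chi_square`, `p_value`,
#'   `df`, `table`, `expected_warning`.
#' @export
chi_square_compare <- function(a, b, correct = FALSE) {
  m <- rbind(
    c(a$n_detected, a$n_reference - a$n_detected),
    c(b$n_detected, b$n_reference - b$n_detected)
  )
  if (all(m[1, ] == m[2, ])) {
    # identical tables: statistic is exactly 0 (chisq.test NaNs when a
    # margin is empty)
    res <- list(statistic = 0, p.value = 1)
  } else {
    res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  }
  expect <- outer(rowSums(m), colSums(m)) / sum(m)
  structure(
    list(
      pair = c(
        paste(a$modality, a$variant),
        paste(b$modality, b$variant)
      ),
      chi_square = unname(res$statistic),
      p_value = unname(res$p.value),
      df = 1L,
      table = m,
      expected_warning = any(expect < 1)
    ),
    class = "comparison_result"
  )
}

#' All pairwise modality comparisons with Bonferroni correction
#'
#' @param tables list of [detection_table()]s.
#' @param alpha family-wise significance level (default 0.05).
#' @param correct Yates correction flag passed through.
#' @return data.frame: one row per pair with `chi_square`, `p_value`,
#'   `bonferroni_m` (the number of comparisons actually run),
#'   `p_adjusted` (= min(1, m * p)), `adjusted_alpha` and
#'   `significant`.
#' @export
compare_modalities <- function(tables, alpha = 0.05, correct = FALSE) {
  n <- length(tables)
  if (n < 2) stop("need at least two tables to compare")
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    a <- tables[[pairs[1, k]]]
    b <- tables[[pairs[2, k]]]
    cmp <- chi_square_compare(a, b, correct = correct)
    data.frame(
      a = paste(a$modality, a$variant), b = paste(b$modality, b$variant),
      chi_square = cmp$chi_square, p_value = cmp$p_value,
      bonferroni_m = m, p_adjusted = min(1, m * cmp$p_value),
      adjusted_alpha = alpha / m,
      significant = cmp$p_value < alpha / m,
      expected_warning = cmp$expected_warning,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Add the sulcal exclusion zone to a detection table
#'
#' A conflict is prevented (counted as covered) if the segmentation
#' detected it *or* it lies inside the sulcal exclusion model:
#' `n_detected` becomes the size of the union. Coverage never
#' decreases.
#'
#' @param tab a [detection_table()] with per-event `detected` flags.
#' @param sulcal_flags logical vector (length `n_reference`): reference
#'   conflicts inside the sulcal model.
#' @return a new [detection_table()] with variant `"+sulcal"`.
#' @export
sulcal_union <- function(tab, sulcal_flags) {
  if (is.null(tab$detected)) {
    stop("table lacks per-event detection flags")
  }
  if (length(sulcal_flags) != tab$n_reference) {
    stop("`sulcal_flags` must have one flag per reference conflict")
  }
  covered <- tab$detected | sulcal_flags
  out <- detection_table(
    modality = tab$modality, variant = paste0(tab$variant, "+sulcal"),
    n_reference = tab$n_reference, n_detected = sum(covered),
    n_spurious = tab$n_spurious, detected = covered,
    n_raw_visible = tab$n_raw_visible,
    n_raw_missed_by_seg = tab$n_raw_missed_by_seg
  )
  out
}
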