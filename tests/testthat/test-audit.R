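test_that("an empty vascular field propagates as a no-vasculature profile", {
  g <- centered_grid(32, 1)
  field <- distance_field(g) # empty mask
  s <- straight_samples(c(-10, 0, 0), c(1, 0, 0), 20)
  prof <- distance_profile(s, field)
  expect_true(attr(prof, "no_vasculature"))
  expect_equal(nrow(detect_conflicts(prof)), 0)
})

test_that("a parallel electrode and vessel plateau at offset minus both radii", {
  g <- centered_grid(c(70, 50, 70), 0.2) # 14 x 10 x 14 mm fine grid
  # vessel of radius 0.6 along z through (0, 0); electrode parallel at
  # (4, 0) with radius 0.4: plateau = 4 - 0.6 - 0.4 = 3.0 mm
  ves <- capsule_volume(g, c(0, 0, -6, 0, 0, 6, 0.6), amp = 1)
  mask <- volume_grid(
    array(as.double(ves$values >= 0.5), dim(g$values)), g$affine
  )
  field <- distance_field(mask)
  s <- straight_samples(c(4, 0, -4), c(0, 0, 1), 8,
    step = 0.5,
    radius = 0.4
  )
  prof <- distance_profile(s, field, electrode_radius = 0.4)
  mid <- prof$arc > 1 & prof$arc < 7
  expect_lte(max(abs(prof$distance[mid] - 3.0)), 0.1 + 1e-9)
})

test_that("an electrode through a vessel reaches distance zero with one conflict", {
  g <- centered_grid(c(60, 60, 60), 0.4)
  ves <- capsule_volume(g, c(0, -8, 0, 0, 8, 0, 1.2), amp = 1)
  mask <- volume_grid(
    array(as.double(ves$values >= 0.5), dim(g$values)), g$affine
  )
  field <- distance_field(mask, signed = TRUE)
  s <- straight_samples(c(-9, 0, 0), c(1, 0, 0), 18,
    step = 0.5,
    radius = 0.4
  )
  prof <- distance_profile(s, field, electrode_radius = 0.4)
  expect_equal(min(prof$distance), 0)
  ev <- detect_conflicts(prof)
  expect_equal(nrow(ev), 1)
  # the event sits at the crossing point (x = 0 on this path)
  expect_lt(abs(ev$x), 0.6)
  expect_equal(ev$arc, 9, tolerance = 0.8)
})

test_that("conflict runs merge under merge_gap and split beyond it", {
  arc <- seq(0, 30, by = 0.5)
  d <- rep(5, length(arc))
  d[arc >= 8 & arc <= 9] <- 0
  d[arc >= 18.5 & arc <= 19.5] <- 0 # 9.5 mm apart
  prof <- manual_profile(arc, d)
  ev <- detect_conflicts(prof, conflict_threshold = 0, merge_gap = 2)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$arc, c(8.5, 19), tolerance = 0.01)
  # with splitting disabled, a 15 mm merge gap fuses the two runs ...
  ev1 <- detect_conflicts(prof,
    conflict_threshold = 0, merge_gap = 15,
    split_prominence = Inf
  )
  expect_equal(nrow(ev1), 1)
  # ... but at the default prominence two distinct dips stay distinct
  ev2 <- detect_conflicts(prof, conflict_threshold = 0, merge_gap = 15)
  expect_equal(nrow(ev2), 2)
  # nothing below threshold, nothing reported
  expect_equal(nrow(detect_conflicts(manual_profile(arc, rep(4, length(arc))))), 0)
})

test_that("a safety-margin threshold flags where the profile dips below it", {
  arc <- seq(0, 40, by = 0.5)
  d <- 6 - 5 * exp(-((arc - 21)^2) / 8) # dips to ~1 mm at arc 21
  prof <- manual_profile(arc, d)
  ev <- detect_conflicts(prof, conflict_threshold = 3, merge_gap = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$arc, 21, tolerance = 0.5)
  expect_true(all(d[abs(arc - ev$arc) < 1] < 3))
})

test_that("characterization adds depth, diameter, and sulcal membership", {
  g <- centered_grid(c(60, 60, 60), 0.4)
  ves <- capsule_volume(g, c(0, -8, 0, 0, 8, 0, 1.2), amp = 1)
  seg <- segmentation_from_mask(volume_grid(
    array(as.double(ves$values >= 0.5), dim(g$values)), g$affine
  ))
  field <- distance_field(seg, signed = TRUE)
  s <- straight_samples(c(-9, 0, 0), c(1, 0, 0), 18, radius = 0.4)
  prof <- distance_profile(s, field, electrode_radius = 0.4)
  ev <- detect_conflicts(prof)
  # a sulcal "model" covering x > -2 for the membership lookup
  co <- grid_coordinates(g)
  sulcal <- list(mask = volume_grid(
    array(as.double(co[, 1] > -2), dim(g$values)), g$affine
  ))
  out <- characterize_conflicts(ev, seg, sulcal = sulcal)
  expect_equal(out$depth, out$arc)
  expect_equal(out$diameter, 2.4, tolerance = 0.8)
  expect_true(out$in_sulcus)
  # conflict at the entry point has depth zero
  arc <- seq(0, 10, 0.5)
  d <- c(0, rep(4, length(arc) - 1))
  pr0 <- manual_profile(arc, d)
  ev0 <- detect_conflicts(pr0)
  expect_equal(ev0$arc, 0)
  # event with no vessel nearby keeps an unresolved diameter
  evfar <- ev
  evfar$x <- 20
  evfar$y <- 20
  evfar$z <- 20
  outfar <- characterize_conflicts(evfar, seg, sulcal = NULL)
  expect_true(is.na(outfar$diameter))
})

test_that("risk scores hit their endpoints and shrink as distances grow", {
  g <- centered_grid(48, 1)
  brain <- sphere_mask(g, 20)
  s <- straight_samples(c(-20, 0, 0), c(1, 0, 0), 40, radius = 0)
  far <- manual_profile(s$arc, rep(10, nrow(s)))
  rm_far <- risk_metrics(s, far, brain)
  expect_equal(rm_far$risk_score, 0)
  zero <- manual_profile(s$arc, rep(0, nrow(s)))
  rm_zero <- risk_metrics(s, zero, brain)
  expect_equal(rm_zero$risk_score, 1)
  # monotone: raising every distance cannot raise the risk
  d0 <- pmax(0, 4 - 0.2 * s$arc)
  r1 <- risk_metrics(s, manual_profile(s$arc, d0), brain)$risk_score
  r2 <- risk_metrics(s, manual_profile(s$arc, d0 + 1), brain)$risk_score
  expect_lte(r2, r1)
  # intracerebral length spans the 40 mm diameter chord
  expect_equal(rm_far$intracerebral_length, 40, tolerance = 1.5)
})

test_that("an orthogonal entry reads as a 90-degree drilling angle", {
  g <- centered_grid(48, 1)
  brain <- sphere_mask(g, 18)
  gm <- sphere_mask(g, 18, r_inner = 15)
  wm <- sphere_mask(g, 15)
  s <- straight_samples(c(-18, 0, 0), c(1, 0, 0), 30, radius = 0)
  prof <- manual_profile(s$arc, rep(10, nrow(s)))
  rm <- risk_metrics(s, prof, brain, gm, wm)
  expect_equal(rm$angle_to_skull, 90, tolerance = 3)
  expect_true(rm$gw_ratio > 0)
  # a degenerate all-outside trajectory errors
  sout <- straight_samples(c(30, 30, 30), c(1, 0, 0), 5, inside = FALSE)
  expect_error(risk_metrics(sout, manual_profile(sout$arc, rep(1, nrow(sout))), brain), "degenerate")
})

test_that("conflicts are stable under sampling-step halving", {
  g <- centered_grid(c(60, 60, 60), 0.4)
  ves <- capsule_volume(g, c(0, -8, 0, 0, 8, 0, 1.2), amp = 1)
  mask <- volume_grid(
    array(as.double(ves$values >= 0.5), dim(g$values)), g$affine
  )
  field <- distance_field(mask, signed = TRUE)
  for (st in c(0.5, 0.25)) {
    s <- straight_samples(c(-9, 0.4, 0), c(1, 0, 0), 18,
      step = st,
      radius = 0.4
    )
    ev <- detect_conflicts(distance_profile(s, field,
      electrode_radius = 0.4
    ))
    if (st == 0.5) {
      n0 <- nrow(ev)
      x0 <- ev$x
    } else {
      expect_equal(nrow(ev), n0)
      expect_lt(max(abs(ev$x - x0)), 0.5 + 1e-9)
    }
  }
})

test_that("audit frames summarize counts and write byte-stable CSVs", {
  ev <- data.frame(
    electrode = c("E1", "E1", "E2"), x = c(1, 2, 3), y = 0, z = 0,
    arc = c(5, 20, 11), min_distance = 0, arc_start = 0, arc_end = 1,
    depth = c(5, 20, 11), diameter = c(1.2, 2.5, 1.4),
    in_sulcus = c(TRUE, FALSE, FALSE)
  )
  rep <- audit_report(ev, n_electrodes = 4)
  expect_equal(rep$n_conflicts, 3)
  expect_equal(sum(rep$conflicts_per_electrode), 3)
  expect_equal(unname(rep$diameter["median"]), 1.4)
  expect_equal(rep$sulcal_fraction, 1 / 3)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_audit_csv(ev, f1)
  write_audit_csv(ev, f2)
  expect_identical(readBin(f1, "raw", 1e5), readBin(f2, "raw", 1e5))
  unlink(c(f1, f2))
})
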