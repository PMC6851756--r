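test_that("vesselness is zero on structureless volumes and bounded in [0,1]", {
  g <- centered_grid(24, 0.5)
  g$values <- array(5, dim(g$values))
  v <- vesselness_filter(g, scales = c(0.5, 1))
  expect_true(all(v$values == 0))
  set.seed(1)
  g$values <- array(rnorm(24^3), dim(g$values))
  v <- vesselness_filter(g, scales = c(0.5, 1))
  expect_true(all(v$values >= 0 & v$values <= 1))
})

test_that("a bright tube outranks a bright plate of equal contrast", {
  g <- centered_grid(49, 0.25)
  co <- grid_coordinates(g)
  rad2 <- co[, 1]^2 + co[, 2]^2
  cyl <- g
  cyl$values <- array(100 * (rad2 <= 1), dim(g$values))
  plate <- g
  plate$values <- array(100 * (abs(co[, 1]) <= 1), dim(g$values))
  vs_c <- vesselness_filter(cyl, scales = c(0.5, 1, 2))
  vs_p <- vesselness_filter(plate, scales = c(0.5, 1, 2))
  band <- abs(co[, 3]) < 3
  on_axis <- rad2 < 0.05 & band
  in_plate <- abs(co[, 1]) < 0.05 & abs(co[, 2]) < 3 & band
  expect_gt(mean(vs_c$values[on_axis]), 0.15)
  expect_gt(
    mean(vs_c$values[on_axis]),
    5 * mean(vs_p$values[in_plate]) + 0.1
  )
})

test_that("the response of a 1 mm-radius tube peaks at the 1 mm scale", {
  g <- centered_grid(49, 0.25)
  co <- grid_coordinates(g)
  rad2 <- co[, 1]^2 + co[, 2]^2
  cyl <- g
  cyl$values <- array(100 * (rad2 <= 1), dim(g$values))
  on_axis <- rad2 < 0.05 & abs(co[, 3]) < 3
  by_scale <- vesselness_by_scale(cyl, scales = c(0.5, 1, 2))
  means <- vapply(by_scale, function(v) mean(v$values[on_axis]), numeric(1))
  expect_equal(names(which.max(means)), "1")
})

test_that("vesselness is invariant to a constant intensity offset", {
  g <- centered_grid(32, 0.5)
  co <- grid_coordinates(g)
  g$values <- array(100 * (co[, 1]^2 + co[, 2]^2 <= 1), dim(g$values))
  v1 <- vesselness_filter(g, scales = c(0.5, 1))
  g2 <- g
  g2$values <- g$values + 37
  v2 <- vesselness_filter(g2, scales = c(0.5, 1))
  expect_equal(v1$values, v2$values, tolerance = 1e-10)
})

test_that("sub-half-voxel scales are dropped with a warning; none left errors", {
  g <- centered_grid(16, 1)
  g$values <- array(rnorm(16^3), dim(g$values))
  expect_warning(vesselness_filter(g, scales = c(0.1, 1)), "dropping")
  expect_error(
    suppressWarnings(vesselness_filter(g, scales = 0.1)),
    "below half a voxel"
  )
  expect_error(vesselness_filter(g, scales = numeric(0)), "positive scale")
})

test_that("segmentation thresholds, size filtering, and contrast visibility behave", {
  g <- centered_grid(c(64, 48, 48), 0.5)
  # two parallel tubes, radius 1, one bright and one faint
  bright <- capsule_volume(g, c(-8, -10, 0, -8, 10, 0, 1), amp = 100)
  faint <- capsule_volume(g, c(8, -10, 0, 8, 10, 0, 1), amp = 8)
  vol <- g
  vol$values <- bright$values + faint$values
  v <- vesselness_filter(vol, scales = c(0.5, 1, 1.5))
  seg <- segment_vessels(v, threshold = 0.1, min_component_voxels = 10)
  lab <- seegconflict:::.label_components_cpp(
    as.logical(seg$mask$values > 0.5),
    as.integer(dim(seg$mask$values)), 26L
  )
  expect_equal(max(lab), 1) # only the bright tube survives
  # the surviving component sits on the bright tube
  co <- grid_coordinates(g)
  expect_true(mean(co[lab == 1, 1]) < 0)

  # threshold 1.0 on strictly sub-1 vesselness gives an empty mask
  expect_lt(max(v$values), 1)
  seg_empty <- segment_vessels(v, threshold = 1.0)
  expect_equal(sum(seg_empty$mask$values), 0)

  # min_component_voxels = 1 equals plain thresholding
  seg1 <- segment_vessels(v, threshold = 0.1, min_component_voxels = 1)
  expect_equal(
    seg1$mask$values,
    array(as.double(v$values >= 0.1), dim(v$values))
  )
  expect_error(segment_vessels(v, threshold = 0), "threshold")
})

test_that("distance fields are exact on axis cases and against brute force", {
  # single marked voxel, 0.5 mm spacing, 3 indices away -> 1.5 mm
  m <- array(FALSE, c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  vg <- volume_grid(array(as.double(m), dim(m)), diag(c(0.5, 0.5, 0.5, 1)))
  df <- distance_field(vg)
  expect_equal(df$distances$values[8, 5, 5], 1.5, tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:5) {
    sp <- runif(3, 0.4, 1.2)
    m <- array(runif(16^3) < 0.02, c(16, 16, 16))
    if (!any(m)) m[8, 8, 8] <- TRUE
    vg <- volume_grid(array(as.double(m), dim(m)), diag(c(sp, 1)))
    df <- distance_field(vg)
    expect_lt(
      max(abs(df$distances$values - brute_force_edt(m, sp))), 1e-9
    )
  }
})

test_that("all-ones masks give a zero field; empty masks flag the sentinel", {
  g <- centered_grid(8, 1)
  full <- g
  full$values <- array(1, dim(g$values))
  expect_true(all(distance_field(full)$distances$values == 0))
  empty <- g
  df <- distance_field(empty)
  expect_true(df$empty)
  expect_true(all(is.infinite(df$distances$values)))
})

test_that("distance fields are 1-Lipschitz in the world metric", {
  set.seed(8)
  sp <- c(0.5, 0.8, 1.1)
  m <- array(runif(14^3) < 0.03, c(14, 14, 14))
  m[7, 7, 7] <- TRUE
  vg <- volume_grid(array(as.double(m), dim(m)), diag(c(sp, 1)))
  d <- distance_field(vg)$distances$values
  expect_true(all(abs(d[-1, , ] - d[-14, , ]) <= sp[1] + 1e-9))
  expect_true(all(abs(d[, -1, ] - d[, -14, ]) <= sp[2] + 1e-9))
  expect_true(all(abs(d[, , -1] - d[, , -14]) <= sp[3] + 1e-9))
})

test_that("signed fields negate interior distances and agree outside", {
  g <- centered_grid(32, 0.5)
  ves <- capsule_volume(g, c(0, -6, 0, 0, 6, 0, 1.5), amp = 1)
  mask <- volume_grid(
    array(as.double(ves$values >= 0.5), dim(g$values)), g$affine
  )
  plain <- distance_field(mask)
  signed <- distance_field(mask, signed = TRUE)
  inside <- mask$values > 0.5
  expect_true(all(signed$distances$values[inside] <= 0))
  expect_equal(
    signed$distances$values[!inside],
    plain$distances$values[!inside]
  )
})

test_that("local diameters recover analytic cylinders and spheres", {
  g <- centered_grid(c(64, 64, 64), 0.25)
  cyl <- capsule_volume(g, c(0, -7, 0, 0, 7, 0, 1.0), amp = 1)
  seg <- segmentation_from_mask(
    volume_grid(array(as.double(cyl$values >= 0.5), dim(g$values)), g$affine)
  )
  expect_equal(local_diameter(seg, c(0, 0, 0)), 2.0, tolerance = 0.5)
  # rasterized sphere: a zero-length capsule
  sph <- capsule_volume(g, c(0, 0, 0, 0, 0, 0, 2.0), amp = 1)
  seg2 <- segmentation_from_mask(
    volume_grid(array(as.double(sph$values >= 0.5), dim(g$values)), g$affine)
  )
  expect_equal(local_diameter(seg2, c(0, 0, 0)), 4.0, tolerance = 0.5)
  # far from any vessel -> error
  expect_error(
    local_diameter(seg, c(0, 0, 7.9), capture_radius = 1), "capture radius"
  )
})

test_that("the diameter estimate is monotone in the planted radius", {
  g <- centered_grid(c(72, 48, 48), 0.5)
  est <- vapply(c(0.6, 0.9, 1.2, 1.6), function(r) {
    cyl <- capsule_volume(g, c(0, -8, 0, 0, 8, 0, r), amp = 1)
    seg <- segmentation_from_mask(volume_grid(
      array(as.double(cyl$values >= 0.5), dim(g$values)), g$affine
    ))
    local_diameter(seg, c(0, 0, 0))
  }, numeric(1))
  expect_true(all(diff(est) >= 0))
})
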