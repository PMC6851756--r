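test_that("phantom specs enforce their invariants", {
  expect_error(phantom_spec(grid_shape = 16), "at least 32")
  expect_error(phantom_spec(voxel_size = 0), "positive")
  expect_error(phantom_spec(contact_spacing = -1), "positive")
  expect_error(phantom_spec(contacts_per_electrode = 1), ">= 2")
  expect_error(
    phantom_spec(modality_visibility = c(DSA = 3, MRV = 2, T1Gad = 2.5)),
    "smallest"
  )
  expect_error(
    phantom_spec(
      grid_shape = 32, voxel_size = 0.5,
      contact_spacing = 30
    ),
    "grid too small"
  )
})

test_that("the same spec and seed reproduce the phantom bit for bit", {
  spec <- tiny_spec(seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$modalities$DSA$values, b$modalities$DSA$values)
  expect_identical(a$modalities$MRV$values, b$modalities$MRV$values)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$masks$brain$values, b$masks$brain$values)
  expect_identical(a$truth$planted_conflicts, b$truth$planted_conflicts)
  expect_identical(a$truth$vessel_segments, b$truth$vessel_segments)
})

test_that("a vessel-free phantom renders background only, with no conflicts", {
  spec <- tiny_spec(seed = 3, n_vessels = 0, noise_sd = 1)
  ph <- generate_phantom(spec)
  expect_equal(nrow(ph$truth$vessel_segments), 0)
  expect_equal(nrow(ph$truth$planted_conflicts), 0)
  for (m in names(ph$modalities)) {
    expect_lt(max(abs(ph$modalities[[m]]$values)), 8) # pure noise
  }
  # electrodes still render in the CT
  expect_gt(max(ph$ct$values), spec$contact_intensity * 0.15)
})

test_that("lognormal radius draws hit the stated median (n = 200)", {
  law <- list(median = 1.3, iqr = c(1.0, 1.5))
  set.seed(11)
  r <- draw_lognormal_law(law, 200)
  # binomial order-statistic bounds around the median of the stated law
  expect_gt(median(r), 1.15)
  expect_lt(median(r), 1.45)
})

test_that("modality visibility is monotone in the threshold", {
  spec <- tiny_spec(seed = 9)
  ph <- generate_phantom(spec)
  segs <- ph$truth$vessel_segments
  # thresholds DSA < MRV < T1Gad: visible sets must be nested
  expect_true(all(segs$visible_MRV <= segs$visible_DSA))
  expect_true(all(segs$visible_T1Gad <= segs$visible_MRV))
  # rendered intensity appears iff the segment diameter clears the bar
  expect_equal(
    segs$visible_MRV,
    segs$diameter >= spec$modality_visibility[["MRV"]]
  )
})

test_that("planted conflicts verify by analytic geometry", {
  spec <- tiny_spec(seed = 13)
  ph <- generate_phantom(spec)
  ref <- ph$truth$planted_conflicts
  segs <- ph$truth$vessel_segments
  expect_gt(sum(ref$planted), 0)
  p2seg <- function(pt, a, b) {
    ab <- b - a
    t <- sum((pt - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((a + t * ab - pt)^2))
  }
  for (i in which(ref$planted)) {
    s <- segs[segs$id == ref$vessel_id[i], ]
    pt <- c(ref$x[i], ref$y[i], ref$z[i])
    # on the vessel axis ...
    expect_lt(
      p2seg(pt, c(s$x0, s$y0, s$z0), c(s$x1, s$y1, s$z1)), 1e-6
    )
    # ... and on the electrode trajectory at the recorded depth
    el <- ph$truth$electrodes[[ref$electrode[i]]]
    expect_lt(
      p2seg(pt, el$entry, el$contacts[1, ]),
      spec$electrode_radius + s$radius
    )
    expect_equal(
      sqrt(sum((pt - el$entry)^2)), ref$depth[i],
      tolerance = 1e-6
    )
  }
  # incidental rows satisfy the touch condition too
  for (i in which(!ref$planted)) {
    s <- segs[segs$id == ref$vessel_id[i], ]
    el <- ph$truth$electrodes[[ref$electrode[i]]]
    pt <- c(ref$x[i], ref$y[i], ref$z[i])
    expect_lte(
      p2seg(pt, c(s$x0, s$y0, s$z0), c(s$x1, s$y1, s$z1)),
      spec$electrode_radius + s$radius + 1e-6
    )
  }
})

test_that("planting honours a requested depth and rejects infeasible targets", {
  spec <- tiny_spec(seed = 21)
  ph <- generate_phantom(spec)
  segs <- ph$truth$vessel_segments
  mid <- cbind(
    (segs$x0 + segs$x1) / 2, (segs$y0 + segs$y1) / 2,
    (segs$z0 + segs$z1) / 2
  )
  rho <- sqrt(rowSums(mid^2))
  r0 <- ph$truth$geometry$brain_radius
  tgt <- which(rho < 0.6 * r0)[1]
  # depth D feasible for this target: entry on the surface, closest
  # approach at depth D (analytic line geometry oracle)
  d_req <- r0 - rho[tgt] + 5
  set.seed(1)
  tr2 <- plant_conflicting_electrode(
    ph$truth, ph$masks, tgt, spec,
    label = "EX", depth = d_req, axis_frac = 0.5
  )
  row <- tail(tr2$planted_conflicts[tr2$planted_conflicts$planted, ], 1)
  expect_equal(row$depth, d_req, tolerance = 1e-6)
  el <- tr2$electrodes[["EX"]]
  expect_equal(sqrt(sum(el$entry^2)), r0, tolerance = 1e-6)

  # a target outside the brain is infeasible
  fake <- ph$truth
  fake$vessel_segments <- rbind(
    segs,
    data.frame(
      id = max(segs$id) + 1, x0 = r0 + 5, y0 = 0, z0 = 0,
      x1 = r0 + 10, y1 = 0, z1 = 0, radius = 1, diameter = 2,
      level = 0L, root = 99L, visible_DSA = TRUE, visible_MRV = TRUE,
      visible_T1Gad = FALSE
    )
  )
  expect_error(
    plant_conflicting_electrode(
      fake, ph$masks, nrow(fake$vessel_segments), spec
    ),
    "outside the brain"
  )
})

test_that("written phantoms land on disk as NIfTI plus a JSON manifest", {
  spec <- phantom_spec(
    grid_shape = 32, voxel_size = 1, n_vessels = 5,
    n_electrodes = 1, contacts_per_electrode = 4, contact_spacing = 3,
    seed = 2
  )
  ph <- generate_phantom(spec)
  dir <- file.path(tempdir(), "phantom-out")
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "DSA.nii.gz")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_volume(file.path(dir, "DSA.nii.gz"))
  expect_equal(back$values, ph$modalities$DSA$values, tolerance = 1e-12)
  man <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(
    length(man$vessel_segments),
    nrow(ph$truth$vessel_segments)
  )
  unlink(dir, recursive = TRUE)
})
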