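test_that("matching handles identical, displaced, and partial candidate sets", {
  ref <- cbind(seq(0, 40, by = 10), 0, 0)
  t_id <- match_conflicts(ref, ref, tolerance = 3)
  expect_equal(t_id$n_detected, 5)
  expect_equal(t_id$n_spurious, 0)
  far <- sweep(ref, 2, c(10, 10, 10), "+")
  t_far <- match_conflicts(ref, far, tolerance = 3)
  expect_equal(t_far$n_detected, 0)
  expect_equal(t_far$n_spurious, 5)
  # 5 reference, 4 candidates of which 3 within tolerance: the greedy
  # result equals the brute-force optimal assignment here
  cand <- rbind(
    ref[1, ] + c(1, 0, 0), ref[2, ] + c(0, 2, 0),
    ref[4, ] + c(0, 0, 2.5), c(100, 100, 100)
  )
  t3 <- match_conflicts(ref, cand, tolerance = 3)
  expect_equal(t3$n_detected, 3)
  expect_equal(t3$n_spurious, 1)
  expect_equal(which(t3$detected), c(1L, 2L, 4L))
})

test_that("detection metrics reproduce the worked clinical ratios", {
  dsa <- detection_table("DSA", "segmentation",
    n_reference = 166,
    n_detected = 120, n_spurious = 21
  )
  m <- detection_metrics(dsa)
  expect_equal(m$sensitivity, 72)
  expect_equal(m$fn_rate, 28)
  expect_equal(m$fp_rate, 15)
  expect_equal(m$sensitivity + m$fn_rate, 100)

  mrv <- detection_table("MRV", "raw",
    n_reference = 166, n_detected = 20,
    detected = c(rep(TRUE, 20), rep(FALSE, 146)),
    n_raw_visible = 20, n_raw_missed_by_seg = 6
  )
  expect_equal(detection_metrics(mrv)$raw_seg_fn_rate, 30)
  t1 <- detection_table("T1Gad", "raw",
    n_reference = 166, n_detected = 14,
    n_raw_visible = 14, n_raw_missed_by_seg = 7
  )
  expect_equal(detection_metrics(t1)$raw_seg_fn_rate, 50)

  perfect <- detection_table("X", n_reference = 10, n_detected = 10)
  mp <- detection_metrics(perfect)
  expect_equal(mp$sensitivity, 100)
  expect_equal(mp$fn_rate, 0)
  expect_equal(mp$fp_rate, 0)

  nothing <- detection_table("Y", n_reference = 5, n_detected = 0)
  expect_true(is.na(detection_metrics(nothing)$fp_rate)) # 0/0 undefined
  expect_true(is.na(detection_metrics(nothing)$raw_seg_fn_rate))
})

test_that("table invariants are enforced at construction", {
  expect_error(
    detection_table("A", n_reference = 5, n_detected = 6),
    "exceed"
  )
  expect_error(
    detection_table("A",
      n_reference = 5, n_detected = 3, n_spurious = 1,
      n_flagged = 9
    ),
    "n_flagged"
  )
  expect_error(
    detection_table("A",
      n_reference = 3, n_detected = 2,
      detected = c(TRUE, TRUE, TRUE)
    ),
    "disagree"
  )
  expect_error(
    detection_table("A",
      n_reference = 3, n_detected = 2,
      n_raw_visible = 2, n_raw_missed_by_seg = 3
    ),
    "exceed"
  )
})

test_that("chi-squared comparisons match the closed 2x2 form", {
  a <- detection_table("MRV", n_reference = 166, n_detected = 14)
  b <- detection_table("T1Gad", n_reference = 166, n_detected = 7)
  cmp <- chi_square_compare(a, b)
  expect_equal(cmp$chi_square, 2.4909, tolerance = 1e-3)
  expect_equal(cmp$chi_square, chisq_closed_form(14, 152, 7, 159),
    tolerance = 1e-10
  )
  # symmetry
  expect_equal(chi_square_compare(b, a)$chi_square, cmp$chi_square)
  # identical tables give exactly zero and p = 1
  same <- chi_square_compare(a, a)
  expect_equal(same$chi_square, 0)
  expect_equal(same$p_value, 1)
  # random tables agree with the closed form to 1e-6
  set.seed(10)
  for (i in 1:20) {
    n1 <- sample(20:200, 1)
    n2 <- sample(20:200, 1)
    k1 <- sample.int(n1, 1)
    k2 <- sample.int(n2, 1)
    if ((k1 == n1 && k2 == n2) || (k1 == 0 && k2 == 0)) next
    ta <- detection_table("A", n_reference = n1, n_detected = k1)
    tb <- detection_table("B", n_reference = n2, n_detected = k2)
    got <- chi_square_compare(ta, tb)$chi_square
    want <- chisq_closed_form(k1, n1 - k1, k2, n2 - k2)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # small expected counts attach a warning flag
  small <- chi_square_compare(
    detection_table("A", n_reference = 3, n_detected = 0),
    detection_table("B", n_reference = 3, n_detected = 1)
  )
  expect_true(small$expected_warning)
})

test_that("pairwise comparisons report the Bonferroni family size", {
  tabs <- list(
    detection_table("DSA", n_reference = 166, n_detected = 120),
    detection_table("MRV", n_reference = 166, n_detected = 14),
    detection_table("T1Gad", n_reference = 166, n_detected = 7)
  )
  cmp <- compare_modalities(tabs, alpha = 0.05)
  expect_equal(nrow(cmp), 3)
  expect_true(all(cmp$bonferroni_m == 3))
  expect_equal(cmp$adjusted_alpha, rep(0.05 / 3, 3))
  expect_equal(cmp$p_adjusted, pmin(1, 3 * cmp$p_value))
  # DSA vs either MR modality is significant after correction
  expect_true(all(cmp$significant[startsWith(cmp$a, "DSA")]))
  expect_error(compare_modalities(tabs[1]), "at least two")
})

test_that("the sulcal union grows coverage by exactly the set union", {
  det <- c(rep(TRUE, 10), rep(FALSE, 10))
  tab <- detection_table("MRV",
    n_reference = 20, n_detected = 10,
    detected = det
  )
  # all flagged events outside the model: unchanged
  same <- sulcal_union(tab, rep(FALSE, 20))
  expect_equal(same$n_detected, 10)
  # disjoint sets of 10 and 5 out of 20 -> 15
  sul <- c(rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 5))
  up <- sulcal_union(tab, sul)
  expect_equal(up$n_detected, 15)
  expect_equal(up$variant, "segmentation+sulcal")
  # never decreases, matches brute-force union on random flags
  set.seed(3)
  for (i in 1:10) {
    fl <- runif(20) < 0.4
    u <- sulcal_union(tab, fl)
    expect_gte(u$n_detected, tab$n_detected)
    expect_equal(u$n_detected, sum(det | fl))
  }
  expect_error(sulcal_union(tab, TRUE), "one flag per")
})

test_that("sensitivity plus false-negative rate is always 100 percent", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(10:300, 1)
    k <- sample.int(n, 1)
    m <- detection_metrics(detection_table("Z", n_reference = n, n_detected = k))
    expect_equal(m$sensitivity_exact + m$fn_rate_exact, 100,
      tolerance = 1e-9
    )
  }
})
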