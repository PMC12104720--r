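test_that("territory volume is voxel count times voxel volume", {
  sp <- c(0.5, 0.5, 0.625)
  m <- array(FALSE, c(20, 20, 5))
  m[1:10, 1:20, 1:5] <- TRUE  # exactly 1000 voxels
  m <- vessel_mask(m, sp)
  everything <- array(TRUE, dim(m))
  expect_equal(territory_volume(m, everything), 1000 * prod(sp))
  expect_equal(territory_volume(m, everything), 156.25)
  expect_equal(territory_volume(m, array(FALSE, dim(m))), 0)
  # restriction never exceeds the total
  half <- array(FALSE, dim(m)); half[1:10, , ] <- TRUE
  expect_lte(territory_volume(m, half), territory_volume(m, everything))
  expect_error(territory_volume(m, array(TRUE, c(2, 2, 2))), "shapes differ")
})

test_that("qCS is the stated volume percentage with the degenerate guard", {
  expect_equal(compute_qcs(63.8, 100)$qcs_percent, 63.8)
  expect_equal(compute_qcs(100, 100)$qcs_percent, 100)
  expect_equal(compute_qcs(120, 100)$qcs_percent, 120)  # may exceed 100
  err <- tryCatch(compute_qcs(50, 0), error = identity)
  expect_s3_class(err, "collateralq_degenerate")
  expect_match(conditionMessage(err),
               "healthy-hemisphere vessel volume is zero")
  err2 <- tryCatch(compute_qcs(50, 0, case_id = "case_007"),
                   error = identity)
  expect_match(conditionMessage(err2), "case_007")
})

test_that("grading boundaries follow the printed interval definitions", {
  g <- classify_qcs(c(49, 49.01, 5, 5.01, 95, 95.5, 75, 75.1, 0, 25, 25.1,
                      100, 120))
  expect_equal(g$binary,
               c("poor", "good", "poor", "poor", "good", "good", "good",
                 "good", "poor", "poor", "poor", "good", "good"))
  expect_equal(g$quaternary, c(1, 2, 0, 1, 2, 3, 2, 2, 0, 1, 1, 3, 3))
  expect_equal(g$six_class, c(2, 3, 0, 1, 4, 5, 3, 4, 0, 1, 2, 5, 5))
})

test_that("the three grading schemes are consistent and monotone", {
  set.seed(31)
  qcs <- c(runif(2e4, 0, 130), c(5, 25, 49, 75, 95, 0, 100))
  g <- classify_qcs(qcs)
  expect_identical(g$binary == "good", g$quaternary >= 2)
  expect_identical(g$binary == "good", g$six_class >= 3)
  ord <- order(qcs)
  expect_true(all(diff(g$quaternary[ord]) >= 0))
  expect_true(all(diff(g$six_class[ord]) >= 0))
  expect_true(all(diff(as.integer(g$binary[ord] == "good")) >= 0))
})

test_that("quantifying ground-truth phantoms recovers the realized ratio", {
  ph <- default_phantom(true_ratio = 0.5, seed = 7)
  q <- quantify_case(ph$gt_vessels, ph$affected_side,
                     list(left = ph$territory_left,
                          right = ph$territory_right))
  expect_equal(q$qcs_percent, 100 * ph$realized_ratio, tolerance = 1e-12)
  expect_identical(q$territory_source, "explicit_territories")
  # symmetric phantom: exactly 100, whichever side is declared affected
  ps <- tiny_phantom(true_ratio = 1, seed = 1)
  terr <- list(left = ps$territory_left, right = ps$territory_right)
  expect_identical(quantify_case(ps$gt_vessels, "left", terr)$qcs_percent,
                   100)
  expect_identical(quantify_case(ps$gt_vessels, "right", terr)$qcs_percent,
                   100)
  # hemisphere-partition fallback is recorded and agrees on phantoms whose
  # territories are hemisphere-separated
  qf <- quantify_case(ps$gt_vessels, "left")
  expect_identical(qf$territory_source, "hemisphere_partition")
  expect_identical(qf$qcs_percent, 100)
})

test_that("threshold sweep matches exhaustive enumeration on known sets", {
  # 10 poor cases at 40..44, 10 good at 55..59: candidates 45..54 are
  # perfect and the tie-break lands on the nominal 50
  qcs <- c(rep(40:44, 2), rep(55:59, 2))
  lab <- rep(c(0, 1), each = 10)
  sw <- sweep_thresholds(qcs, lab, nominal = 50)
  tab <- sw$tables[["50"]]
  perfect <- tab$candidate[tab$accuracy == 1]
  expect_setequal(perfect, 45:54)
  expect_equal(unname(sw$chosen[["50"]]), 50)
  expect_equal(unname(sw$chosen[["50"]]), sweep_oracle(qcs, lab, 50)$chosen)

  # labels cut exactly at 49 with nominal 50: the sweep refines 50 -> 49
  set.seed(8)
  q2 <- c(runif(30, 30, 70), 48.5, 49, 49.5)
  l2 <- as.integer(q2 > 49)
  sw2 <- sweep_thresholds(q2, l2, nominal = 50)
  expect_equal(unname(sw2$chosen[["50"]]), 49)
  expect_equal(unname(sw2$chosen[["50"]]), sweep_oracle(q2, l2, 50)$chosen)
})

test_that("threshold sweep equals the oracle on random instances", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    q <- round(runif(n, 0, 130), 1)
    lab <- as.integer(runif(n) > 0.5)
    if (length(unique(lab)) < 2) lab[1] <- 1L - lab[1]
    t_nom <- sample(c(0, 50, 100), 1)
    sw <- sweep_thresholds(q, lab, nominal = t_nom)
    orc <- sweep_oracle(q, lab, t_nom)
    expect_equal(unname(sw$chosen[[as.character(t_nom)]]), orc$chosen)
    expect_equal(unname(as.matrix(sw$tables[[as.character(t_nom)]])),
                 unname(orc$table))
  }
})

test_that("sweep handles ordinal grades and skips one-class boundaries", {
  # quaternary grades: boundary i dichotomizes at label >= i
  q <- c(2, 4, 30, 40, 60, 70, 97, 99)
  grades <- c(0, 0, 1, 1, 2, 2, 3, 3)
  sw <- sweep_thresholds(q, grades)
  expect_named(sw$chosen, c("0", "50", "100"))
  expect_true(all(abs(sw$chosen - sw$nominal) <= 5))
  # all scores above the floor with one-class labels: boundary skipped
  expect_warning(
    sw2 <- sweep_thresholds(c(10, 20, 30, 40), c(1, 1, 1, 1), nominal = 0),
    "single-class")
  expect_equal(sw2$skipped, 0)
  expect_length(sw2$chosen, 0)
})
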