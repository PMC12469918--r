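test_that("dose arithmetic follows the |1 - P/P0| convention", {
  expect_equal(apply_dose(mouse, intervention("V1", 1))$V1, 0)
  expect_equal(apply_dose(mouse, intervention("k2", 1))$k2, 900)
  expect_equal(apply_dose(mouse, intervention("k2p", 2))$k2p,
               3 * mouse$k2p)
  for (nm in c("V1", "V1p", "k2", "k2p")) {
    expect_equal(unclass(apply_dose(mouse, intervention(nm, 0))),
                 unclass(mouse))
  }
  expect_equal(apply_dose(mouse, intervention("V1p", 0.25))$V1p,
               0.75 * mouse$V1p)
})

test_that("intervention specs are validated", {
  expect_error(intervention("V1", 1.2), "cannot exceed 1")
  expect_error(intervention("V1p", 1.01), "cannot exceed 1")
  expect_error(intervention("K1", 0.5), "must be one of")
  expect_error(intervention("k2", -0.1), "non-negative")
  expect_error(intervention("k2", 0.5, t_start = 0.5), "1, 27")
  # removal doses above 1 are legitimate
  expect_s3_class(intervention("k2", 1.5), "intervention")
})

test_that("treated trajectories behave as the dose dictates", {
  untreated <- run_intervention(mouse, list())
  expect_equal(untreated$A, simulate_trajectory(mouse)$A)
  # halving V1 from month 1 is a successful intervention
  half_v1 <- run_intervention(mouse, intervention("V1", 0.5))
  expect_lte(half_v1$A[27], 100)
  # a comparable k2p dose leaves the buildup essentially untouched
  k2p_tr <- run_intervention(mouse, intervention("k2p", 0.63))
  expect_gt(k2p_tr$A[27], 2000)
  expect_error(run_intervention(mouse, list(intervention("V1", 0.2),
                                            intervention("V1", 0.3))),
               "conflicting")
})

test_that("interventions with distinct start ages stack piecewise", {
  tr <- run_intervention(mouse, list(intervention("V1", 0.3, t_start = 5),
                                     intervention("k2", 0.5, t_start = 10)))
  solo <- run_intervention(mouse, intervention("V1", 0.3, t_start = 5))
  # before month 10 the second intervention is inactive
  expect_equal(tr$A[tr$time_months <= 10],
               solo$A[solo$time_months <= 10], tolerance = 1e-6)
  expect_lt(tr$A[27], solo$A[27])
})

test_that("final Abeta level is monotone non-increasing in dose", {
  for (pm in c("V1", "V1p", "k2", "k2p")) {
    dmax <- if (pm %in% c("V1", "V1p")) 1 else 2
    for (ts in c(1, 10)) {
      a <- vapply(seq(0, dmax, length.out = 20), function(d)
        a27_at(pm, d, t_start = ts), numeric(1))
      expect_true(all(diff(a) <= a[-20] * 1e-6 + 1e-6),
                  label = paste("monotone dose response:", pm, "t0 =", ts))
    }
  }
})

test_that("minimum effective doses are bracketed and verified", {
  md <- min_effective_dose(mouse, "V1")
  expect_true(md$feasible)
  expect_lte(md$achieved_A27, 100)
  expect_lte(diff(md$bracket), 1e-3)
  # just below the minimum dose the intervention fails
  expect_gt(a27_at("V1", md$min_dose - 2e-3), 100)
  # a threshold above the untreated endpoint needs no dose at all
  free_ride <- min_effective_dose(mouse, "V1", threshold = 5000)
  expect_identical(free_ride$min_dose, 0)
  # k2p cannot reach the threshold even at dose 1
  fut <- min_effective_dose(mouse, "k2p", d_max = 1)
  expect_false(fut$feasible)
  expect_gt(fut$achieved_A27, 100)
})

test_that("later starts require larger minimum V1 doses", {
  doses <- vapply(c(1, 5, 10, 15), function(ts)
    min_effective_dose(mouse, "V1", t_start = ts)$min_dose, numeric(1))
  expect_true(all(diff(doses) >= 0))
  expect_gt(doses[4], doses[1])
})

test_that("equal-dose combinations bisect correctly", {
  expect_error(equal_dose_combination(mouse, "V1", "V1"), "differ")
  cmb <- equal_dose_combination(mouse, "k2", "V1")
  expect_true(cmb$feasible)
  expect_lte(cmb$achieved_A27, 100)
  # the combination needs less than either monotherapy
  expect_lt(cmb$min_dose, min_effective_dose(mouse, "V1")$min_dose)
  # bisection consistency: at the reported dose the criterion holds,
  # just below it fails
  expect_gt(a27_at(c("k2", "V1"), rep(cmb$min_dose - 2e-3, 2)), 100)
})

test_that("dose surfaces agree with monotherapy along their edges", {
  g1 <- seq(0, 1, length.out = 7)
  g2 <- seq(0, 1, length.out = 7)
  surf <- dose_surface(mouse, "V1", "V1p", grid_a = g1, grid_b = g2)
  expect_equal(surf$A27[1, 1], a27_at("V1", 0), tolerance = 1e-8)
  mono1 <- vapply(g1, function(d) a27_at("V1", d), numeric(1))
  mono2 <- vapply(g2, function(d) a27_at("V1p", d), numeric(1))
  expect_equal(surf$A27[, 1], mono1, tolerance = 1e-8)
  expect_equal(surf$A27[1, ], mono2, tolerance = 1e-8)
  expect_true(surf$monotone)
})

test_that("threshold contour points re-simulate to the iso-effect level", {
  g <- seq(0, 1, length.out = 9)
  surf <- dose_surface(mouse, "V1", "V1p", grid_a = g, grid_b = g)
  ctr <- threshold_contour(surf, threshold = 100, a_tol = 0.5)
  expect_true(ctr$feasible)
  expect_gt(nrow(ctr$points), 3)
  for (k in seq_len(nrow(ctr$points))) {
    a <- a27_at(c("V1", "V1p"),
                c(ctr$points$dose_1[k], ctr$points$dose_2[k]))
    expect_lt(abs(a - 100), 1)
  }
  # optimal point: strictly inside and no farther than the diagonal
  eq <- equal_dose_combination(mouse, "V1", "V1p")
  expect_lte(ctr$R, eq$min_dose * sqrt(2) + 1e-3)
  expect_true(all(ctr$optimal_point > 0))
  expect_lt(ctr$R, min_effective_dose(mouse, "V1")$min_dose)
})

test_that("an unreachable threshold yields an infeasible contour", {
  g <- seq(0, 0.05, length.out = 4)
  surf <- dose_surface(mouse, "V1", "V1p", grid_a = g, grid_b = g)
  ctr <- threshold_contour(surf, threshold = 100)
  expect_false(ctr$feasible)
  expect_identical(nrow(ctr$points), 0L)
})

test_that("synergy report distinguishes the qualitative categories", {
  mono_a <- structure(list(min_dose = 0.4, achieved_A27 = 99,
                           bracket = c(0.399, 0.4), feasible = TRUE),
                      class = "dose_search")
  mono_b <- structure(list(min_dose = 0.6, achieved_A27 = 99,
                           bracket = c(0.599, 0.6), feasible = TRUE),
                      class = "dose_search")
  ctr <- function(opt) structure(
    list(points = data.frame(dose_1 = opt[1], dose_2 = opt[2], A27 = 100),
         optimal_point = opt, R = sqrt(sum(opt^2)), feasible = TRUE,
         threshold = 100), class = "threshold_contour")
  expect_identical(synergy_report(ctr(c(0.15, 0.2)), mono_a, mono_b)$category,
                   "synergistic")
  expect_identical(synergy_report(ctr(c(0.39, 0.005)), mono_a,
                                  mono_b)$category,
                   "second intervention hardly useful")
  expect_identical(synergy_report(ctr(c(0.3, 0.35)), mono_a, mono_b)$category,
                   "favorable")
  inf <- structure(list(points = data.frame(), optimal_point = c(NA, NA),
                        R = NA_real_, feasible = FALSE, threshold = 100),
                   class = "threshold_contour")
  expect_identical(synergy_report(inf, mono_a, mono_b)$category,
                   "infeasible")
})
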