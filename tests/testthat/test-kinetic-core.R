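test_that("feedback right-hand side matches hand evaluations", {
  p <- mouse
  # the origin is a fixed point: both Hill terms vanish
  z <- feedback_rhs(0, 0, p)
  expect_identical(z$dA, 0)
  expect_identical(z$dX, 0)
  # at half-saturation each Hill term equals half its ceiling
  hs <- feedback_rhs(A = p$K1p, X = p$K1, p)
  expect_equal(hs$dA, p$V1 / 2 - p$k2 * p$K1p)
  expect_equal(hs$dX, p$V1p / 2 - p$k2p * p$K1)
  # hand evaluation at the initial state (34, 1)
  init <- feedback_rhs(34, 1, p)
  expect_equal(init$dX, 0.998 * 34^2 / (134.2^2 + 34^2) - 0.00168 * 1,
               tolerance = 1e-12)
  expect_equal(init$dX, 0.0585, tolerance = 2e-3)
  expect_error(feedback_rhs(-1, 0, p), "non-negative")
})

test_that("default simulation tracks the logistic target to ~5% at t=27", {
  traj <- simulate_trajectory(mouse)
  expect_equal(traj$time_months, as.numeric(1:27))
  a27 <- traj$A[27]
  target27 <- abeta_logistic(27)
  expect_lt(abs(log(a27 / target27)), log(1.06))
  # regression anchor for the untreated endpoint
  expect_equal(a27, 2189.96, tolerance = 1e-3)
  expect_true(is_sigmoidal(traj)$sigmoidal)
})

test_that("degenerate parameter limits behave as the equations dictate", {
  # no Abeta production: A decays monotonically toward 0
  noprod <- update_params(mouse, V1 = 0)
  traj <- simulate_trajectory(noprod, eval_times = seq(1, 27, by = 0.5))
  expect_true(all(diff(traj$A) <= 0))
  expect_lt(traj$A[nrow(traj)], 1e-6)
  # no X removal: X strictly increasing
  expect_error(update_params(mouse, k2p = 0), "positive")
  traj2 <- simulate_trajectory(update_params(mouse, k2p = 1e-12))
  expect_true(all(diff(traj2$X) > 0))
})

test_that("state stays non-negative and below the production ceilings", {
  set.seed(21)
  for (i in 1:8) {
    p <- kinetic_params(V1 = 10^runif(1, 3, 7), K1 = 10^runif(1, -1, 2),
                        k2 = 10^runif(1, 1, 3), V1p = 10^runif(1, -1, 1),
                        K1p = 10^runif(1, 1, 3), k2p = 10^runif(1, -4, -1),
                        A_init = runif(1, 0, 100), X_init = runif(1, 0, 10))
    traj <- simulate_trajectory(p, eval_times = seq(1, 27, length.out = 53))
    expect_true(all(traj$A >= 0))
    expect_true(all(traj$X >= 0))
    expect_true(all(traj$A <= max(p$A_init, p$V1 / p$k2) * (1 + 1e-6)))
    expect_true(all(traj$X <= max(p$X_init, p$V1p / p$k2p) * (1 + 1e-6)))
  }
})

test_that("halving the solver tolerance moves A(27) by under 0.1%", {
  a_ref <- simulate_trajectory(mouse, rtol = 1e-8)$A[27]
  a_tight <- simulate_trajectory(mouse, rtol = 5e-9)$A[27]
  expect_lt(abs(a_tight - a_ref) / a_ref, 1e-3)
})

test_that("Abeta sits in quasi-steady state along the fitted trajectory", {
  # A relaxes ~1e5 times faster than X, so A should track
  # (V1/k2) X^2/(K1^2+X^2) closely from the second month on
  traj <- simulate_trajectory(mouse)
  qss <- (mouse$V1 / mouse$k2) * traj$X^2 / (mouse$K1^2 + traj$X^2)
  gap <- abs(traj$A - qss) / traj$A
  expect_lt(max(gap[traj$time_months >= 2]), 0.02)
})

test_that("piecewise integration reduces to plain simulation", {
  plain <- simulate_trajectory(mouse)
  expect_equal(simulate_piecewise(mouse, list()), plain)
  noop <- simulate_piecewise(mouse,
                             list(list(at = 10, params = mouse)))
  expect_equal(noop$A, plain$A, tolerance = 1e-6)
  expect_equal(noop$X, plain$X, tolerance = 1e-6)
})

test_that("an earlier parameter switch suppresses the endpoint more", {
  halved <- update_params(mouse, V1 = mouse$V1 / 2)
  early <- simulate_piecewise(mouse, list(list(at = 1.0001, params = halved)))
  late <- simulate_piecewise(mouse, list(list(at = 15, params = halved)))
  expect_lt(early$A[27], late$A[27])
})

test_that("piecewise schedules validate their change times", {
  halved <- update_params(mouse, V1 = mouse$V1 / 2)
  expect_error(simulate_piecewise(mouse,
    list(list(at = 15, params = halved), list(at = 10, params = halved))),
    "increasing")
  expect_error(simulate_piecewise(mouse,
    list(list(at = 30, params = halved))), "inside")
})

test_that("linear model solution is exact and never sigmoidal", {
  expect_equal(linear_solution(100, 2, t = 1, A_init = 34), 34)
  expect_equal(linear_solution(100, 2, t = 1e4, A_init = 34), 50)
  # growing solutions decelerate from the very first interval
  set.seed(22)
  for (i in 1:25) {
    k2 <- 10^runif(1, -2, 2)
    k1 <- k2 * runif(1, 35, 5000)   # k1/k2 > A_init: growth case
    a <- linear_solution(k1, k2, t = 1:27, A_init = 34)
    d <- diff(a)
    # growth is fastest over the first interval and decays (to
    # floating-point zero once e^(-k2 t) underflows)
    expect_identical(which.max(d), 1L)
    expect_true(all(diff(d) <= 1e-9 * d[1]))
    sig <- is_sigmoidal(a)
    expect_false(sig$sigmoidal)
    expect_identical(sig$which_max, 1L)
  }
  expect_error(is_sigmoidal(c(1, 2)), "3 points")
})

test_that("kinetic parameters round-trip through YAML and JSON", {
  p <- update_params(mouse, V1 = 123456.7, k2p = 0.00201)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_kinetic_params(p, path)
    back <- read_kinetic_params(path)
    expect_s3_class(back, "kinetic_params")
    expect_equal(unclass(back), unclass(p), tolerance = 1e-9)
  }
})

test_that("the packaged parameter file equals the in-code defaults", {
  path <- system.file("extdata", "mouse_params.yaml",
                      package = "amyloidcycle")
  expect_true(nzchar(path))
  expect_equal(unclass(read_kinetic_params(path)), unclass(mouse))
})

test_that("trajectory CSV export has the documented columns", {
  traj <- simulate_trajectory(mouse, eval_times = c(1, 14, 27))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  df <- read.csv(path)
  expect_named(df, c("time_months", "A_pg_per_mg", "X_dimensionless"))
  expect_equal(df$A_pg_per_mg, traj$A, tolerance = 1e-10)
})
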