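#' Right-hand side of the coupled feedback equations
#'
#' Rates of change of the Abeta concentration `A` and the disease factor
#' `X` under mutual Hill-type positive feedback with first-order removal.
#'
#' @param A Abeta concentration (pg/mg), >= 0 (vectorised).
#' @param X Disease-factor level (dimensionless), >= 0 (same length).
#' @param params A [kinetic_params()] object.
#' @return A list with components `dA` (pg mg^-1 mo^-1) and `dX` (mo^-1).
#' @export
#' @examples
#' feedback_rhs(0, 0, kinetic_params())   # the origin is a fixed point
feedback_rhs <- function(A, X, params = kinetic_params()) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(A < 0) || any(X < 0))
    stop("state must be non-negative", call. = FALSE)
  n <- params$hill_n
  dA <- params$V1 * X^n / (params$K1^n + X^n) - params$k2 * A + params$basal
  dX <- params$V1p * A^n / (params$K1p^n + A^n) - params$k2p * X
  list(dA = dA, dX = dX)
}

# deSolve-facing RHS; p is the plain list form of kinetic_params
.rhs_desolve <- function(t, y, p) {
  A <- max(y[1L], 0)
  X <- max(y[2L], 0)
  n <- p$hill_n
  list(c(p$V1 * X^n / (p$K1^n + X^n) - p$k2 * A + p$basal,
         p$V1p * A^n / (p$K1p^n + A^n) - p$k2p * X))
}

# one integration segment; y0 = c(A, X); returns matrix with columns
# time, A, X evaluated at `times` (which must include the segment ends)
.integrate_segment <- function(p, y0, times, rtol, atol) {
  out <- try(suppressWarnings(
    deSolve::ode(y = c(A = unname(y0[1L]), X = unname(y0[2L])),
                 times = times, func = .rhs_desolve, parms = unclass(p),
                 method = "lsoda", rtol = rtol,
                 atol = atol, maxsteps = 50000)), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("ODE solver failed: ", attr(out, "condition")$message,
         call. = FALSE)
  if (nrow(out) < length(times) || any(!is.finite(out[, "A"])))
    stop("ODE solver failed or state blew up; last good time = ",
         signif(out[max(which(is.finite(out[, "A"]))), 1L], 6),
         " months", call. = FALSE)
  out
}

#' Simulate the vicious-cycle model
#'
#' Integrates the coupled feedback equations from the initial state
#' `(A_init, X_init)` at `t_start` (months).  The system is stiff:
#' Abeta relaxes on a timescale of `1/k2` (about 0.002 months) while
#' `X` evolves over months, so the solver is run with tight tolerances
#' and automatic stiff/non-stiff switching (LSODA).
#'
#' @param params A [kinetic_params()] object.
#' @param t_start,t_end Integration window in months (default 1 to 27,
#'   the adult lifespan of the mouse).
#' @param eval_times Output grid within `[t_start, t_end]`; defaults to
#'   the integer months.
#' @param rtol Relative solver tolerance.
#' @param atol Absolute tolerances for `(A, X)` in their own units.
#' @return An `abeta_trajectory`: a data frame with columns
#'   `time_months`, `A` (pg/mg) and `X` (dimensionless).
#' @export
#' @examples
#' traj <- simulate_trajectory(kinetic_params())
#' tail(traj, 3)          # A(27) approaches the untreated plateau
simulate_trajectory <- function(params = kinetic_params(),
                                t_start = 1, t_end = 27,
                                eval_times = NULL,
                                rtol = 1e-8, atol = c(1e-10, 1e-12)) {
  stopifnot(inherits(params, "kinetic_params"))
  if (t_start >= t_end) stop("'t_start' must be < 't_end'", call. = FALSE)
  if (is.null(eval_times))
    eval_times <- seq(ceiling(t_start), floor(t_end))
  if (any(eval_times < t_start) || any(eval_times > t_end))
    stop("'eval_times' must lie within [t_start, t_end]", call. = FALSE)
  times <- sort(unique(c(t_start, eval_times, t_end)))
  out <- .integrate_segment(params, c(params$A_init, params$X_init),
                            times, rtol, atol)
  keep <- match_times(out[, 1L], eval_times)
  traj <- data.frame(time_months = eval_times,
                     A = pmax(out[keep, "A"], 0),
                     X = pmax(out[keep, "X"], 0))
  class(traj) <- c("abeta_trajectory", "data.frame")
  traj
}

match_times <- function(have, want) {
  idx <- vapply(want, function(t) which.min(abs(have - t)), integer(1L))
  if (any(abs(have[idx] - want) > 1e-9))
    stop("internal error: evaluation times not on solver grid",
         call. = FALSE)
  idx
}

#' Simulate with a piecewise-constant parameter schedule
#'
#' Integrates segment by segment, switching the kinetic parameters
#' instantaneously at the given months while carrying the state
#' `(A, X)` continuously across each switch.  This is how permanent
#' interventions starting mid-life are simulated: a parameter change at
#' month `N` stays in force until the next change (or the end).
#'
#' @inheritParams simulate_trajectory
#' @param changes A list of `list(at = <month>, params = <kinetic_params>)`
#'   entries with strictly increasing `at` inside `(t_start, t_end)`.
#'   Empty list reproduces [simulate_trajectory()].
#' @return An `abeta_trajectory`.
#' @export
simulate_piecewise <- function(params = kinetic_params(), changes = list(),
                               t_start = 1, t_end = 27, eval_times = NULL,
                               rtol = 1e-8, atol = c(1e-10, 1e-12)) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(eval_times))
    eval_times <- seq(ceiling(t_start), floor(t_end))
  if (length(changes) == 0L)
    return(simulate_trajectory(params, t_start, t_end, eval_times,
                               rtol, atol))
  ats <- vapply(changes, function(ch) ch$at, numeric(1L))
  if (any(diff(ats) <= 0) || any(ats <= t_start) || any(ats >= t_end))
    stop("'changes' must have strictly increasing times inside ",
         "(t_start, t_end)", call. = FALSE)
  for (ch in changes) stopifnot(inherits(ch$params, "kinetic_params"))

  bounds <- c(t_start, ats, t_end)
  psets <- c(list(params), lapply(changes, `[[`, "params"))
  y <- c(params$A_init, params$X_init)
  rows <- vector("list", length(psets))
  for (i in seq_along(psets)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    seg_eval <- eval_times[eval_times >= lo & eval_times <= hi]
    times <- sort(unique(c(lo, seg_eval, hi)))
    out <- .integrate_segment(psets[[i]], y, times, rtol, atol)
    y <- out[nrow(out), c("A", "X")]
    if (length(seg_eval)) {
      keep <- match_times(out[, 1L], seg_eval)
      rows[[i]] <- data.frame(time_months = seg_eval,
                              A = pmax(out[keep, "A"], 0),
                              X = pmax(out[keep, "X"], 0))
    }
  }
  traj <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  traj <- traj[!duplicated(traj$time_months), , drop = FALSE]
  rownames(traj) <- NULL
  class(traj) <- c("abeta_trajectory", "data.frame")
  traj
}

#' Closed-form solution of the linear production/removal model
#'
#' The null model `dA/dt = k1 - k2 A` with `A(1) = A_init` has the
#' solution `A(t) = k1/k2 + (A_init - k1/k2) exp(-k2 (t - 1))`.  Its
#' growth rate is maximal at `t = 1` and decays monotonically, so a
#' purely linear scheme can never produce the sigmoidal
#' (slow-fast-slow) time course seen in the mouse data — the argument
#' for a nonlinear feedback model.
#'
#' @param k1 Zeroth-order production (pg mg^-1 mo^-1), >= 0.
#' @param k2 First-order removal (mo^-1), > 0.
#' @param t Ages in months, >= 1 (vectorised).
#' @param A_init Concentration at `t = 1` (pg/mg).
#' @return Concentration(s) in pg/mg.
#' @export
linear_solution <- function(k1, k2, t, A_init = 34) {
  if (k1 < 0 || k2 <= 0) stop("require k1 >= 0 and k2 > 0", call. = FALSE)
  if (any(t < 1)) stop("'t' must be >= 1", call. = FALSE)
  k1 / k2 + (A_init - k1 / k2) * exp(-k2 * (t - 1))
}

#' Test a series for sigmoidal (slow-fast-slow) growth
#'
#' A series is sigmoidal in this operational sense when its largest
#' successive increase occurs strictly in the interior of the grid,
#' i.e. growth first accelerates and later decelerates.
#'
#' @param values Numeric series on an (implicitly uniform) time grid, or
#'   an `abeta_trajectory` (its `A` column is used).
#' @return A list with `sigmoidal` (logical) and `which_max` (index of
#'   the steepest interval, 1 = first interval).
#' @export
is_sigmoidal <- function(values) {
  if (inherits(values, "abeta_trajectory")) values <- values$A
  if (inherits(values, "target_series")) values <- values$abeta_pg_per_mg
  if (length(values) < 3L)
    stop("need at least 3 points to assess sigmoidality", call. = FALSE)
  d <- diff(values)
  i <- which.max(d)
  list(sigmoidal = (i > 1L && i < length(d)), which_max = i)
}

#' @export
print.abeta_trajectory <- function(x, ...) {
  cat("Abeta trajectory over", nrow(x), "time points,",
      "t in [", min(x$time_months), ",", max(x$time_months), "] months\n")
  cat("final state: A =", signif(x$A[nrow(x)], 5), "pg/mg, X =",
      signif(x$X[nrow(x)], 5), "\n")
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Columns `time_months`, `A_pg_per_mg`, `X_dimensionless`.
#'
#' @param traj An `abeta_trajectory`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "abeta_trajectory"))
  df <- data.frame(time_months = traj$time_months,
                   A_pg_per_mg = traj$A,
                   X_dimensionless = traj$X)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
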