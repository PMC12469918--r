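#' Specify a permanent kinetic intervention
#'
#' An intervention changes one kinetic parameter permanently from a
#' start age onward.  The dose is the fractional parameter change
#' `D = |1 - P/P0|`: production ceilings (`V1`, `V1p`) are scaled by
#' `1 - D` (so `D = 1` switches the feedback off and `D` is capped at
#' 1), removal rates (`k2`, `k2p`) are scaled by `1 + D` (so `D = 1`
#' doubles the rate and `D > 1` is allowed).  The half-saturation
#' constants `K1`/`K1p` are not intervention targets.
#'
#' @param param One of `"V1"`, `"V1p"`, `"k2"`, `"k2p"`.
#' @param dose Dimensionless dose, >= 0 (and <= 1 for `V1`/`V1p`).
#' @param t_start Age in months at which the intervention begins,
#'   within `[1, 27)`.
#' @return An object of class `intervention`.
#' @export
#' @examples
#' intervention("V1", 0.5)               # halve the Abeta feedback ceiling
#' intervention("k2", 0.63, t_start = 5) # +63% Abeta clearance from 5 mo
intervention <- function(param, dose, t_start = 1) {
  .PRODUCTION <- c("V1", "V1p")
  .REMOVAL <- c("k2", "k2p")
  if (!param %in% c(.PRODUCTION, .REMOVAL))
    stop("'param' must be one of V1, V1p, k2, k2p", call. = FALSE)
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) ||
      dose < 0)
    stop("'dose' must be a single non-negative number", call. = FALSE)
  if (param %in% .PRODUCTION && dose > 1)
    stop("dose on a production parameter (", param,
         ") cannot exceed 1", call. = FALSE)
  if (t_start < 1 || t_start >= 27)
    stop("'t_start' must lie in [1, 27)", call. = FALSE)
  structure(list(param = param, dose = dose, t_start = t_start,
                 kind = if (param %in% .PRODUCTION) "production"
                        else "removal"),
            class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  eff <- if (x$kind == "production") sprintf("x %.3g", 1 - x$dose)
         else sprintf("x %.3g", 1 + x$dose)
  cat("Intervention: ", x$param, " ", eff, " from t = ", x$t_start,
      " mo (dose ", signif(x$dose, 3), ")\n", sep = "")
  invisible(x)
}

#' Apply an intervention dose to a parameter set
#'
#' @param base A [kinetic_params()] object.
#' @param iv An [intervention()].
#' @return A `kinetic_params` with the dosed parameter changed.
#' @export
#' @examples
#' apply_dose(kinetic_params(), intervention("k2", 1))$k2   # 900
apply_dose <- function(base, iv) {
  stopifnot(inherits(base, "kinetic_params"), inherits(iv, "intervention"))
  fac <- if (iv$kind == "production") 1 - iv$dose else 1 + iv$dose
  newval <- base[[iv$param]] * fac
  do.call(update_params, c(list(base), stats::setNames(list(newval),
                                                       iv$param)))
}

#' Simulate a treated trajectory
#'
#' Runs the model with one or more permanent interventions.
#' Interventions sharing a start time are applied simultaneously;
#' distinct start times produce a piecewise schedule in which each
#' intervention stays in force once begun.  The state `(A, X)` is
#' carried continuously across every switch.
#'
#' @param base A [kinetic_params()] object (untreated parameterisation).
#' @param ivs A single [intervention()] or a list of them; an empty
#'   list gives the untreated trajectory.  Dosing the same parameter
#'   twice is an error.
#' @param eval_times Output grid in months (default integer months
#'   1 to 27).
#' @inheritParams simulate_trajectory
#' @return An `abeta_trajectory`.
#' @export
#' @examples
#' \donttest{
#' tr <- run_intervention(kinetic_params(),
#'                        intervention("V1", 0.5, t_start = 1))
#' tail(tr, 1)   # A(27) well below the 100 pg/mg success threshold
#' }
run_intervention <- function(base, ivs = list(), eval_times = 1:27,
                             t_end = max(eval_times),
                             rtol = 1e-8, atol = c(1e-10, 1e-12)) {
  stopifnot(inherits(base, "kinetic_params"))
  if (inherits(ivs, "intervention")) ivs <- list(ivs)
  if (!all(vapply(ivs, inherits, logical(1L), "intervention")))
    stop("'ivs' must be intervention objects", call. = FALSE)
  pars <- vapply(ivs, `[[`, character(1L), "param")
  if (anyDuplicated(pars))
    stop("conflicting doses on the same parameter: ",
         paste(pars[duplicated(pars)], collapse = ", "), call. = FALSE)
  if (length(ivs) == 0L)
    return(simulate_trajectory(base, t_start = 1, t_end = t_end,
                               eval_times = eval_times, rtol = rtol,
                               atol = atol))
  starts <- vapply(ivs, `[[`, numeric(1L), "t_start")
  ord <- order(starts)
  ivs <- ivs[ord]; starts <- starts[ord]
  current <- base
  changes <- list()
  for (s in unique(starts)) {
    for (iv in ivs[starts == s]) current <- apply_dose(current, iv)
    if (s <= 1) next                 # active from the very beginning
    changes[[length(changes) + 1L]] <- list(at = s, params = current)
  }
  init <- if (min(starts) <= 1) {
    # all interventions starting at t = 1 are in the initial parameter set
    first_active <- base
    for (iv in ivs[starts <= 1]) first_active <- apply_dose(first_active, iv)
    first_active
  } else base
  simulate_piecewise(init, changes, t_start = 1, t_end = t_end,
                     eval_times = eval_times, rtol = rtol, atol = atol)
}

# final Abeta level under simultaneous doses on one or two parameters
.a_final <- function(base, params, doses, t_start, t_end = 27,
                     rtol = 1e-8) {
  ivs <- Map(function(p, d) intervention(p, d, t_start), params, doses)
  traj <- run_intervention(base, ivs, eval_times = t_end, t_end = t_end,
                           rtol = rtol)
  traj$A[nrow(traj)]
}

#' Minimum effective dose of a single intervention
#'
#' Bisects the dose of one parameter for the smallest permanent dose
#' whose treated trajectory satisfies `A(27) <= threshold` (default
#' 100 pg/mg, the "successful intervention" criterion — under 1/20 of
#' the untreated final level).  The search relies on the numerically
#' verified monotone dose response.
#'
#' @param base A [kinetic_params()] object.
#' @param param One of `"V1"`, `"V1p"`, `"k2"`, `"k2p"`.
#' @param t_start Intervention start age (months).
#' @param threshold Success criterion on the final concentration
#'   (pg/mg).
#' @param d_max Largest dose searched; defaults to 1 for production
#'   parameters, 2 for `k2` and 10 for `k2p`.
#' @param tol Dose tolerance of the bisection.
#' @param t_end Final age at which the criterion is evaluated (months).
#' @return A `dose_search` object: `min_dose`, `achieved_A27`,
#'   `bracket` and `feasible`.  Infeasibility (even `d_max` fails) is a
#'   result, not an error.
#' @export
#' @examples
#' \donttest{
#' min_effective_dose(kinetic_params(), "V1")$min_dose   # about 0.39
#' }
min_effective_dose <- function(base, param, t_start = 1, threshold = 100,
                               d_max = NULL, tol = 1e-3, t_end = 27) {
  if (is.null(d_max))
    d_max <- switch(param, V1 = 1, V1p = 1, k2 = 2, k2p = 10,
                    stop("'param' must be one of V1, V1p, k2, k2p",
                         call. = FALSE))
  f <- function(d) .a_final(base, param, d, t_start, t_end)
  .bisect_dose(f, d_max, threshold, tol)
}

#' Minimum equal dose of a two-parameter combination
#'
#' Bisects a single scalar dose applied simultaneously to two distinct
#' parameters from the same start age.
#'
#' @inheritParams min_effective_dose
#' @param param_a,param_b Distinct parameter names.
#' @return A `dose_search` object.
#' @export
equal_dose_combination <- function(base, param_a, param_b, t_start = 1,
                                   threshold = 100, d_max = NULL,
                                   tol = 1e-3, t_end = 27) {
  if (identical(param_a, param_b))
    stop("the two parameters must differ", call. = FALSE)
  if (is.null(d_max)) {
    caps <- vapply(c(param_a, param_b), function(p)
      switch(p, V1 = 1, V1p = 1, k2 = 2, k2p = 10,
             stop("invalid parameter '", p, "'", call. = FALSE)),
      numeric(1L))
    d_max <- min(caps)
  }
  f <- function(d) .a_final(base, c(param_a, param_b), c(d, d), t_start,
                            t_end)
  .bisect_dose(f, d_max, threshold, tol)
}

.bisect_dose <- function(f, d_max, threshold, tol) {
  a0 <- f(0)
  if (a0 <= threshold)
    return(structure(list(min_dose = 0, achieved_A27 = a0,
                          bracket = c(0, 0), feasible = TRUE),
                     class = "dose_search"))
  amax <- f(d_max)
  if (amax > threshold)
    return(structure(list(min_dose = NA_real_, achieved_A27 = amax,
                          bracket = c(d_max, d_max), feasible = FALSE),
                     class = "dose_search"))
  lo <- 0; hi <- d_max; a_hi <- amax
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    a <- f(mid)
    if (a <= threshold) { hi <- mid; a_hi <- a } else lo <- mid
  }
  structure(list(min_dose = hi, achieved_A27 = a_hi,
                 bracket = c(lo, hi), feasible = TRUE),
            class = "dose_search")
}

#' @export
print.dose_search <- function(x, ...) {
  if (x$feasible) {
    cat("Minimum effective dose:", signif(x$min_dose, 4),
        " (A at end =", signif(x$achieved_A27, 4), "pg/mg)\n")
  } else {
    cat("Infeasible within the search cap; best A at end =",
        signif(x$achieved_A27, 5), "pg/mg\n")
  }
  invisible(x)
}

#' Two-parameter dose-response surface of the final Abeta level
#'
#' Evaluates `A(27)` on a grid of simultaneous doses of two parameters,
#' both starting at `t_start`.  Monotone non-increase along each axis
#' is checked and any violation beyond solver noise is flagged in the
#' `monotone` attribute.
#'
#' @inheritParams min_effective_dose
#' @param param_a,param_b Distinct parameter names (axis 1 and 2).
#' @param grid_a,grid_b Ascending dose grids; default 41 points over
#'   `[0, 1]` for production parameters and `[0, 1.5]` for `k2`
#'   (`[0, 10]` for `k2p`).
#' @param rtol Solver relative tolerance for the grid sweep.
#' @return A `dose_surface` object with the dose grids and the matrix
#'   `A27[i, j]` for `grid_a[i]`, `grid_b[j]` (`NA` where the solver
#'   failed).
#' @export
dose_surface <- function(base, param_a, param_b, t_start = 1,
                         grid_a = NULL, grid_b = NULL, t_end = 27,
                         rtol = 1e-8) {
  if (identical(param_a, param_b))
    stop("the two parameters must differ", call. = FALSE)
  dgrid <- function(p) switch(p,
    V1 = , V1p = seq(0, 1, length.out = 41L),
    k2 = seq(0, 1.5, length.out = 41L),
    k2p = seq(0, 10, length.out = 41L),
    stop("invalid parameter '", p, "'", call. = FALSE))
  if (is.null(grid_a)) grid_a <- dgrid(param_a)
  if (is.null(grid_b)) grid_b <- dgrid(param_b)
  if (any(diff(grid_a) <= 0) || any(diff(grid_b) <= 0))
    stop("dose grids must be strictly ascending", call. = FALSE)
  A27 <- matrix(NA_real_, length(grid_a), length(grid_b))
  for (i in seq_along(grid_a)) for (j in seq_along(grid_b)) {
    v <- try(.a_final(base, c(param_a, param_b),
                      c(grid_a[i], grid_b[j]), t_start, t_end,
                      rtol = rtol), silent = TRUE)
    if (!inherits(v, "try-error")) A27[i, j] <- v
  }
  mono <- all(apply(A27, 2, function(col) all(diff(col) <= 1e-6 * col[-1] +
                                                1e-6, na.rm = TRUE))) &&
          all(apply(A27, 1, function(row) all(diff(row) <= 1e-6 * row[-1] +
                                                1e-6, na.rm = TRUE)))
  structure(list(param_pair = c(param_a, param_b), dose_grid_1 = grid_a,
                 dose_grid_2 = grid_b, A27 = A27, t_start = t_start,
                 t_end = t_end, base = base, monotone = mono),
            class = "dose_surface")
}

#' @export
print.dose_surface <- function(x, ...) {
  cat("Dose-response surface:", x$param_pair[1], "x", x$param_pair[2],
      "starting at t =", x$t_start, "mo\n")
  cat("  grid:", length(x$dose_grid_1), "x", length(x$dose_grid_2),
      "; A(t_end) range",
      paste(signif(range(x$A27, na.rm = TRUE), 4), collapse = " - "),
      "pg/mg\n")
  if (!x$monotone)
    cat("  warning: monotone dose response violated beyond tolerance\n")
  invisible(x)
}

#' Iso-effect contour and optimal dose combination
#'
#' Extracts the locus of dose pairs with final Abeta equal to the
#' success threshold from a [dose_surface()], by per-ray bisection:
#' for each grid value of the first dose the second dose is bisected
#' (and vice versa), each contour point refined until the re-simulated
#' `A(27)` is within `a_tol` of the threshold.  The optimal combination
#' is the contour point with the shortest Cartesian (Euclidean)
#' distance `R` from the zero-dose origin, with unscaled axes.
#'
#' @param surface A `dose_surface`.
#' @param threshold Final-concentration criterion (pg/mg).
#' @param a_tol Refinement tolerance on `A(27)` (pg/mg).
#' @return A `threshold_contour` object: data frame `points`
#'   (`dose_1`, `dose_2`, `A27`), `optimal_point`, `R` and `feasible`.
#'   If the threshold is never attained on the surface, an infeasible
#'   contour (empty `points`) is returned.
#' @export
threshold_contour <- function(surface, threshold = 100, a_tol = 0.5) {
  stopifnot(inherits(surface, "dose_surface"))
  pa <- surface$param_pair[1]; pb <- surface$param_pair[2]
  g1 <- surface$dose_grid_1; g2 <- surface$dose_grid_2
  base <- surface$base; ts <- surface$t_start; te <- surface$t_end
  f <- function(d1, d2) .a_final(base, c(pa, pb), c(d1, d2), ts, te)

  if (all(surface$A27 > threshold, na.rm = TRUE))
    return(structure(list(points = data.frame(dose_1 = numeric(0),
                                              dose_2 = numeric(0),
                                              A27 = numeric(0)),
                          optimal_point = c(NA_real_, NA_real_),
                          R = NA_real_, feasible = FALSE,
                          threshold = threshold),
                     class = "threshold_contour"))

  bis <- function(fun, lo, hi, alo) {
    # fun decreasing; fun(lo) > threshold >= fun(hi)
    ahi <- fun(hi)
    while (TRUE) {
      mid <- (lo + hi) / 2
      a <- fun(mid)
      if (a <= threshold) { hi <- mid; ahi <- a } else { lo <- mid; alo <- a }
      if (abs(ahi - threshold) <= a_tol || hi - lo < 1e-7) break
    }
    c(hi, ahi)
  }

  pts <- list()
  # rays along axis 2 (fixed dose_1)
  for (i in seq_along(g1)) {
    col <- surface$A27[i, ]
    if (all(is.na(col))) next
    if (col[1L] <= threshold) {
      if (i > 1L && !is.na(surface$A27[i - 1L, 1L]) &&
          surface$A27[i - 1L, 1L] > threshold) {
        # crossing lies on the dose_2 = 0 edge between g1[i-1] and g1[i]
        r <- bis(function(d) f(d, g2[1L]), g1[i - 1L], g1[i],
                 surface$A27[i - 1L, 1L])
        pts[[length(pts) + 1L]] <- c(r[1L], g2[1L], r[2L])
      }
      next
    }
    j <- which(col <= threshold)[1L]
    if (is.na(j)) next
    r <- bis(function(d) f(g1[i], d), g2[j - 1L], g2[j], col[j - 1L])
    pts[[length(pts) + 1L]] <- c(g1[i], r[1L], r[2L])
  }
  # rays along axis 1 (fixed dose_2), adds resolution near the axis
  for (j in seq_along(g2)) {
    row <- surface$A27[, j]
    if (all(is.na(row)) || row[1L] <= threshold) next
    i <- which(row <= threshold)[1L]
    if (is.na(i)) next
    r <- bis(function(d) f(d, g2[j]), g1[i - 1L], g1[i], row[i - 1L])
    pts[[length(pts) + 1L]] <- c(r[1L], g2[j], r[2L])
  }
  m <- do.call(rbind, pts)
  pts_df <- data.frame(dose_1 = m[, 1L], dose_2 = m[, 2L], A27 = m[, 3L])
  pts_df <- pts_df[!duplicated(round(pts_df[, 1:2], 6)), , drop = FALSE]
  d <- sqrt(pts_df$dose_1^2 + pts_df$dose_2^2)
  k <- which.min(d)
  structure(list(points = pts_df,
                 optimal_point = c(dose_1 = pts_df$dose_1[k],
                                   dose_2 = pts_df$dose_2[k]),
                 R = d[k], feasible = TRUE, threshold = threshold),
            class = "threshold_contour")
}

#' @export
print.threshold_contour <- function(x, ...) {
  if (!x$feasible) {
    cat("Threshold", x$threshold, "pg/mg not attainable on this surface\n")
    return(invisible(x))
  }
  cat("Iso-effect contour at A =", x$threshold, "pg/mg:",
      nrow(x$points), "points\n")
  cat("  optimal combination: (",
      paste(signif(x$optimal_point, 3), collapse = ", "),
      "), distance R =", signif(x$R, 4), "\n")
  invisible(x)
}

#' Synergy assessment of a dose combination
#'
#' Compares the optimal combined doses against the two monotherapy
#' minimum doses.  The combination is flagged `"synergistic"` when both
#' combined doses fall below `synergy_frac` of the corresponding
#' monotherapy dose; `"second intervention hardly useful"` when the
#' optimal point sits essentially on one axis (the other component is
#' below `axis_tol`); `"favorable"` otherwise.
#'
#' @param contour A [threshold_contour()] result.
#' @param mono_a,mono_b `dose_search` results for the two monotherapies
#'   (axis 1 and axis 2 of the surface).
#' @param synergy_frac Fraction of the monotherapy dose below which a
#'   component counts as substantially smaller (default 0.5).
#' @param axis_tol Dose below which a component counts as "on the axis".
#' @return A `synergy_report` list with the category, the optimal
#'   combined doses and the monotherapy doses.
#' @export
synergy_report <- function(contour, mono_a, mono_b, synergy_frac = 0.5,
                           axis_tol = 0.02) {
  stopifnot(inherits(contour, "threshold_contour"),
            inherits(mono_a, "dose_search"),
            inherits(mono_b, "dose_search"))
  if (!contour$feasible)
    return(structure(list(category = "infeasible",
                          optimal = c(NA_real_, NA_real_),
                          mono = c(mono_a$min_dose, mono_b$min_dose)),
                     class = "synergy_report"))
  opt <- contour$optimal_point
  mono <- c(mono_a$min_dose, mono_b$min_dose)
  category <- if (any(opt <= axis_tol)) {
    "second intervention hardly useful"
  } else if (all(is.finite(mono)) && all(opt < synergy_frac * mono)) {
    "synergistic"
  } else "favorable"
  structure(list(category = category, optimal = opt, mono = mono,
                 R = contour$R), class = "synergy_report")
}

#' @export
print.synergy_report <- function(x, ...) {
  cat("Combination assessment:", x$category, "\n")
  cat("  optimal combined doses:",
      paste(signif(x$optimal, 3), collapse = ", "), "\n")
  cat("  monotherapy minimum doses:",
      paste(signif(x$mono, 3), collapse = ", "), "\n")
  invisible(x)
}
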