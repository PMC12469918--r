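#' Fixed points and stability of the feedback system
#'
#' Steady states of the coupled equations are found by substituting
#' the A-nullcline `A = (V1 X^n / (K1^n + X^n) + basal) / k2` into the
#' X-nullcline, reducing the problem to one dimension in `X`.  Roots
#' are located by a sign-change scan on a log-spaced grid (2000 points
#' over `[1e-6, 10 V1p/k2p]`, wide enough to capture tight root pairs
#' near saddle-node events) followed by bisection, and each is
#' classified from the eigenvalues of the analytic Jacobian.  With
#' `basal = 0` the origin is always a fixed point and, for Hill
#' coefficient >= 2, always locally stable (eigenvalues `-k2`,
#' `-k2p`): both Hill terms have zero value and zero slope there.
#'
#' For the default mouse parameterisation the system has three fixed
#' points — a stable origin, an interior saddle at an Abeta level far
#' below the 34 pg/mg starting concentration, and a high stable state
#' — so the observed life trajectory never crosses a basin boundary:
#' disease progression is a drift within the high-state basin, not a
#' bistable jump.
#'
#' @param params A [kinetic_params()] object.
#' @param n_grid Number of scan points.
#' @param x_max Upper end of the `X` scan range; defaults to
#'   `10 * V1p / k2p`.
#' @return A data frame of class `fixed_points` with columns `A_star`,
#'   `X_star`, `eig1`, `eig2` (complex), `classification` and
#'   `residual` (largest scaled right-hand-side component).
#' @export
#' @examples
#' fps <- find_fixed_points(kinetic_params())
#' fps[, c("A_star", "X_star", "classification")]
find_fixed_points <- function(params = kinetic_params(), n_grid = 2000L,
                              x_max = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  p <- unclass(params)
  n <- p$hill_n
  if (is.null(x_max)) x_max <- 10 * p$V1p / p$k2p
  a_of_x <- function(X) (p$V1 * X^n / (p$K1^n + X^n) + p$basal) / p$k2
  g <- function(X) {
    A <- a_of_x(X)
    p$V1p * A^n / (p$K1p^n + A^n) - p$k2p * X
  }

  roots <- numeric(0)
  if (p$basal == 0) roots <- 0          # exact fixed point at the origin
  xg <- 10^seq(log10(1e-6), log10(x_max), length.out = n_grid)
  gv <- g(xg)
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    r <- try(stats::uniroot(g, c(xg[i], xg[i + 1L]),
                            tol = 1e-13 * max(1, xg[i]))$root,
             silent = TRUE)
    if (!inherits(r, "try-error")) roots <- c(roots, r)
  }
  exact <- which(gv == 0)
  roots <- sort(unique(c(roots, xg[exact])))

  rows <- lapply(roots, function(X) {
    A <- a_of_x(X)
    J <- .jacobian(A, X, p)
    ev <- eigen(J, only.values = TRUE)$values
    rhs <- feedback_rhs(A, X, params)
    resid <- max(abs(rhs$dA) / (p$k2 * max(A, 1)),
                 abs(rhs$dX) / (p$k2p * max(X, 1)))
    data.frame(A_star = A, X_star = X,
               eig1 = as.complex(ev[1L]), eig2 = as.complex(ev[2L]),
               classification = .classify_eigs(ev),
               residual = resid)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fixed_points", "data.frame")
  out
}

.jacobian <- function(A, X, p) {
  n <- p$hill_n
  dAdX <- if (X == 0 && n > 1) 0 else
    p$V1 * n * X^(n - 1) * p$K1^n / (p$K1^n + X^n)^2
  dXdA <- if (A == 0 && n > 1) 0 else
    p$V1p * n * A^(n - 1) * p$K1p^n / (p$K1p^n + A^n)^2
  matrix(c(-p$k2, dXdA, dAdX, -p$k2p), 2L, 2L)
}

.classify_eigs <- function(ev, rel_tol = 1e-9) {
  re <- Re(ev); im <- Im(ev)
  scale <- max(abs(ev), 1e-300)
  if (any(abs(re) < rel_tol * scale)) return("non-hyperbolic (flagged)")
  complex_pair <- any(abs(im) > rel_tol * scale)
  if (all(re < 0)) return(if (complex_pair) "stable focus" else
                            "stable node")
  if (all(re > 0)) return(if (complex_pair) "unstable focus" else
                            "unstable node")
  "saddle"
}

#' @export
print.fixed_points <- function(x, ...) {
  cat("Fixed points of the vicious-cycle system:\n")
  df <- data.frame(A_star = signif(x$A_star, 5),
                   X_star = signif(x$X_star, 5),
                   classification = x$classification)
  print(df)
  invisible(x)
}

#' Long-horizon basin membership of an initial state
#'
#' Integrates from the given state until the trajectory settles onto
#' one of the system's fixed points (the integration window is doubled
#' until convergence or `max_time`).  The slow variable relaxes on the
#' `1/k2p` timescale — roughly 600 months for the mouse
#' parameterisation, far beyond the lifespan — so deciding the
#' destination requires integrating well past 27 months.
#'
#' @param params A [kinetic_params()] object.
#' @param initial Numeric `c(A, X)` initial state, non-negative;
#'   defaults to the parameterisation's `(A_init, X_init)`.
#' @param horizon First integration window (months); default 270,
#'   ten lifespans.
#' @param max_time Give up (report `"undecided"`) beyond this time.
#' @param rel_tol Relative closeness to a fixed point that counts as
#'   arrival.
#' @return A list with `destination` (row index into the fixed-point
#'   table, or `NA`), `fixed_points`, `final_state` and `decided`.
#' @export
#' @examples
#' \donttest{
#' basin_check(kinetic_params(), c(34, 1))$destination   # the high state
#' }
basin_check <- function(params = kinetic_params(), initial = NULL,
                        horizon = 270, max_time = 2e4, rel_tol = 1e-3) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(initial)) initial <- c(params$A_init, params$X_init)
  if (any(initial < 0)) stop("initial state must be non-negative",
                             call. = FALSE)
  fps <- find_fixed_points(params)
  near <- function(y) {
    d <- abs(y[1L] - fps$A_star) / (1 + fps$A_star) +
         abs(y[2L] - fps$X_star) / (1 + fps$X_star)
    i <- which.min(d)
    if (d[i] < rel_tol) i else NA_integer_
  }
  y <- initial; t0 <- 1; span <- horizon
  dest <- near(y)
  while (is.na(dest) && t0 < max_time) {
    t1 <- min(t0 + span, max_time)
    out <- .integrate_segment(params, y, c(t0, t1), rtol = 1e-8,
                              atol = c(1e-10, 1e-12))
    y <- pmax(out[nrow(out), c("A", "X")], 0)
    t0 <- t1; span <- span * 2
    dest <- near(y)
  }
  list(destination = dest, fixed_points = fps,
       final_state = c(A = unname(y[1L]), X = unname(y[2L])),
       decided = !is.na(dest))
}

#' One-parameter bifurcation scan
#'
#' Re-runs the fixed-point solver along a grid of one kinetic
#' parameter, recording the fixed-point count and the Abeta level of
#' the saddle (if present).  Count changes between adjacent grid
#' values locate saddle-node events.
#'
#' @param params A [kinetic_params()] baseline.
#' @param param_name Name of the scanned parameter.
#' @param grid Positive parameter values.
#' @return A data frame with columns `value`, `n_fixed_points` and
#'   `saddle_A` (`NA` when no saddle exists or the solve failed).
#' @export
bifurcation_scan <- function(params = kinetic_params(), param_name,
                             grid) {
  stopifnot(inherits(params, "kinetic_params"),
            param_name %in% names(params))
  if (any(grid <= 0)) stop("'grid' must be positive", call. = FALSE)
  rows <- lapply(grid, function(v) {
    p <- do.call(update_params,
                 c(list(params), stats::setNames(list(v), param_name)))
    fps <- try(find_fixed_points(p), silent = TRUE)
    if (inherits(fps, "try-error"))
      return(data.frame(value = v, n_fixed_points = NA_integer_,
                        saddle_A = NA_real_))
    sad <- fps$A_star[fps$classification == "saddle"]
    data.frame(value = v, n_fixed_points = nrow(fps),
               saddle_A = if (length(sad)) sad[1L] else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
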