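#' Summed absolute log-ratio error
#'
#' The fitting objective: `sum_i |log10(pred_i / target_i)|` over a
#' common time grid.  The base-10 convention is fixed; it is the one
#' under which refitting the default mouse target reproduces the
#' published objective value (the natural-log value is larger by a
#' factor of ln 10).  The statistic is a pseudometric on positive
#' series: symmetric, zero iff equal, and satisfying the triangle
#' inequality.
#'
#' @param pred,target Positive numeric vectors of equal length, or
#'   `target_series`/`abeta_trajectory` objects on identical grids.
#' @return The non-negative summed absolute log10 ratio.
#' @export
#' @examples
#' log_error(c(10, 100), c(10, 100))       # 0
#' log_error(2 * c(10, 100), c(10, 100))   # 2 * log10(2)
log_error <- function(pred, target) {
  pt <- .series_values(pred)
  tt <- .series_values(target)
  if (!is.null(pt$times) && !is.null(tt$times) &&
      (length(pt$times) != length(tt$times) ||
       any(abs(pt$times - tt$times) > 1e-9)))
    stop("'pred' and 'target' are on different time grids", call. = FALSE)
  p <- pt$values; t <- tt$values
  if (length(p) != length(t))
    stop("'pred' and 'target' must have equal length", call. = FALSE)
  if (any(!is.finite(p)) || any(!is.finite(t)) || any(p <= 0) ||
      any(t <= 0))
    stop("all values must be finite and positive", call. = FALSE)
  sum(abs(log10(p / t)))
}

.series_values <- function(x) {
  if (inherits(x, "abeta_trajectory"))
    return(list(times = x$time_months, values = x$A))
  if (is.data.frame(x) &&
      all(c("time_months", "abeta_pg_per_mg") %in% names(x)))
    return(list(times = x$time_months, values = x$abeta_pg_per_mg))
  list(times = NULL, values = as.numeric(x))
}

#' Default fitting bounds
#'
#' Each free parameter is bounded within `10^-3` to `10^3` times its
#' reference value — wide enough to bracket the published optimum
#' generously.
#'
#' @param base A [kinetic_params()] reference parameterisation.
#' @param free Character vector of free parameter names.
#' @return A named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function(base = kinetic_params(),
                           free = c("V1", "K1", "V1p", "K1p", "k2p")) {
  stats::setNames(lapply(free, function(nm)
    c(base[[nm]] * 1e-3, base[[nm]] * 1e3)), free)
}

.FIXED_ALWAYS <- c("k2", "A_init", "X_init")

#' Fit the vicious-cycle model to a target series
#'
#' Minimises the summed absolute log10-ratio between the integrated
#' model and the target concentrations over the target's time grid.
#' Following the mouse study design, `k2` (the fast Abeta turnover,
#' known independently), `A_init` and `X_init` are always held fixed;
#' by default the five remaining rate/saturation parameters
#' (`V1, K1, V1p, K1p, k2p`) are free.  Optimisation is multi-start
#' Nelder-Mead in log-parameter space (the free parameters span many
#' orders of magnitude), with the reference parameterisation as the
#' first start and further starts drawn log-uniformly around it; the
#' best start is polished by restarting the simplex until it
#' stagnates.  Results are deterministic for a fixed `seed`.
#'
#' @param target A `target_series` (see [make_target_series()]), with
#'   strictly positive values.
#' @param free Names of the free parameters; any subset of
#'   `c("V1", "K1", "V1p", "K1p", "k2p")`.
#' @param base A [kinetic_params()] giving fixed values and the centre
#'   of the start distribution.
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   defaults to [default_bounds()].
#' @param n_starts Number of optimisation starts (>= 1).
#' @param seed Integer seed controlling the random starts.
#' @param start_spread Random starts are drawn log-uniformly within
#'   `base * [1/start_spread, start_spread]` (clipped to the bounds).
#' @param maxit Simplex iteration cap per start.
#' @param fit_rtol Solver relative tolerance used inside the objective
#'   (looser than the reporting tolerance, for speed); the returned
#'   `log_err` is re-evaluated at full tolerance.
#' @return An object of class `vicious_fit` with components `params`
#'   (the fitted [kinetic_params()]), `log_err`, `converged`,
#'   `n_evals`, `per_start_errors`, `free`, `bounds`, `seed`, and the
#'   `target` it was fitted to.  Supports `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate` and `plot`.
#' @export
#' @examples
#' \donttest{
#' tgt <- make_target_series()
#' fit <- fit_vicious_cycle(tgt, n_starts = 2, seed = 1)
#' fit$log_err
#' }
fit_vicious_cycle <- function(target,
                              free = c("V1", "K1", "V1p", "K1p", "k2p"),
                              base = kinetic_params(),
                              bounds = default_bounds(base, free),
                              n_starts = 20L, seed = 1L,
                              start_spread = 10, maxit = 1000L,
                              fit_rtol = 1e-6) {
  target <- as_target_series(target)
  if (any(target$abeta_pg_per_mg <= 0))
    stop("target values must be strictly positive", call. = FALSE)
  if (length(free) == 0L) stop("'free' must be non-empty", call. = FALSE)
  bad <- intersect(free, .FIXED_ALWAYS)
  if (length(bad))
    stop(paste(bad, collapse = ", "), " must stay fixed in the fit",
         call. = FALSE)
  bad <- setdiff(free, c("V1", "K1", "V1p", "K1p", "k2p"))
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(free %in% names(bounds)))
    stop("'bounds' must cover every free parameter", call. = FALSE)
  for (nm in free)
    if (any(bounds[[nm]] <= 0) || diff(bounds[[nm]]) <= 0)
      stop("bounds for '", nm, "' must be positive and increasing",
           call. = FALSE)

  times <- target$time_months
  tvals <- target$abeta_pg_per_mg
  lo <- log(vapply(bounds[free], `[[`, numeric(1L), 1L))
  hi <- log(vapply(bounds[free], `[[`, numeric(1L), 2L))
  n_evals <- 0L

  objective <- function(lp, rtol) {
    n_evals <<- n_evals + 1L
    if (any(lp < lo) || any(lp > hi)) return(1e3 + sum(pmax(lo - lp, 0) +
                                                       pmax(lp - hi, 0)))
    p <- base
    p[free] <- as.list(exp(lp))
    traj <- try(simulate_trajectory(p, t_start = min(times, 1),
                                    t_end = max(times),
                                    eval_times = times, rtol = rtol,
                                    atol = c(1e-8, 1e-10)),
                silent = TRUE)
    if (inherits(traj, "try-error")) return(1e3)
    A <- traj$A
    if (any(!is.finite(A)) || any(A <= 0)) return(1e3)
    sum(abs(log10(A / tvals)))
  }

  center <- log(unlist(base[free]))
  starts <- list(pmin(pmax(center, lo), hi))
  if (n_starts > 1L) {
    u <- local_runif((n_starts - 1L) * length(free), seed = seed)
    u <- matrix(u, ncol = length(free))
    spread <- log(start_spread)
    for (i in seq_len(n_starts - 1L)) {
      s <- center + (2 * u[i, ] - 1) * spread
      starts[[i + 1L]] <- pmin(pmax(s, lo), hi)
    }
  }

  one_free <- length(free) == 1L
  run_optim <- function(par, maxiter, reltol) {
    if (one_free) {
      # the simplex is unreliable in 1-D; use Brent's method instead
      stats::optim(par, objective, rtol = fit_rtol, method = "Brent",
                   lower = lo, upper = hi)
    } else {
      stats::optim(par, objective, rtol = fit_rtol,
                   method = "Nelder-Mead",
                   control = list(maxit = maxiter, reltol = reltol))
    }
  }
  per_start <- numeric(length(starts))
  best <- NULL
  for (i in seq_along(starts)) {
    f <- run_optim(starts[[i]], maxit, 1e-9)
    per_start[i] <- f$value
    if (is.null(best) || f$value < best$value) best <- f
  }
  converged <- FALSE
  for (k in 1:3) {           # polish: restart the simplex until stagnant
    f <- run_optim(best$par, 2L * maxit, 1e-12)
    if (f$value < best$value - 1e-10) best <- f
    else { converged <- f$convergence == 0L; best <- f; break }
  }
  if (best$value >= 1e3)
    stop("all optimisation starts failed; per-start objectives: ",
         paste(signif(per_start, 4), collapse = ", "), call. = FALSE)

  params <- base
  params[free] <- as.list(exp(best$par))
  params <- do.call(kinetic_params, unclass(params))
  final_traj <- simulate_trajectory(params, t_start = min(times, 1),
                                    t_end = max(times),
                                    eval_times = times)
  final_err <- sum(abs(log10(final_traj$A / tvals)))

  structure(list(params = params, log_err = final_err,
                 converged = converged, n_evals = n_evals,
                 per_start_errors = per_start, free = free,
                 bounds = bounds, seed = as.integer(seed),
                 base = base, target = target),
            class = "vicious_fit")
}

local_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}

#' @export
print.vicious_fit <- function(x, ...) {
  cat("Vicious-cycle model fit\n")
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  cat("  summed |log10 ratio| =", signif(x$log_err, 4), "over",
      nrow(x$target), "time points\n")
  cat("  converged:", x$converged, " (", x$n_evals,
      "objective evaluations )\n")
  invisible(x)
}

#' @export
summary.vicious_fit <- function(object, ...) {
  p <- object$params
  nm <- c("V1", "K1", "k2", "V1p", "K1p", "k2p")
  tab <- data.frame(value = unlist(p[nm]),
                    role = ifelse(nm %in% object$free, "free", "fixed"),
                    row.names = nm)
  res <- structure(list(coefficients = tab, log_err = object$log_err,
                        hill_n = p$hill_n, converged = object$converged,
                        per_start_errors = object$per_start_errors),
                   class = "summary.vicious_fit")
  res
}

#' @export
print.summary.vicious_fit <- function(x, ...) {
  cat("Vicious-cycle model fit (Hill n =", x$hill_n, ")\n\n")
  print(format(x$coefficients, digits = 5))
  cat("\nsummed |log10 ratio|:", signif(x$log_err, 4), "\n")
  cat("per-start objectives:",
      paste(signif(sort(x$per_start_errors), 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.vicious_fit <- function(object, ...) {
  p <- object$params
  out <- unlist(p[c("V1", "K1", "k2", "V1p", "K1p", "k2p")])
  attr(out, "free") <- object$free
  out
}

#' Predicted Abeta concentrations from a fitted model
#'
#' @param object A `vicious_fit`.
#' @param times Months at which to predict; defaults to the target grid.
#' @param ... Unused.
#' @return Numeric vector of concentrations (pg/mg).
#' @export
predict.vicious_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$target$time_months
  traj <- simulate_trajectory(object$params, t_start = min(times, 1),
                              t_end = max(times), eval_times = times)
  stats::setNames(traj$A, times)
}

#' @export
fitted.vicious_fit <- function(object, ...) predict(object)

#' Log10-ratio residuals of a fitted model
#'
#' @param object A `vicious_fit`.
#' @param ... Unused.
#' @return `log10(predicted / target)` at each target time; their
#'   absolute sum is the fit objective.
#' @export
residuals.vicious_fit <- function(object, ...) {
  log10(predict(object) / object$target$abeta_pg_per_mg)
}

#' Simulate a trajectory from a fitted model
#'
#' @param object A `vicious_fit`.
#' @param nsim Number of trajectories (the model is deterministic, so
#'   replicates are identical; kept for generic compatibility).
#' @param seed Unused (deterministic model); accepted for the generic.
#' @param times Evaluation grid in months.
#' @param ... Unused.
#' @return An `abeta_trajectory` (or a list of them if `nsim > 1`).
#' @export
simulate.vicious_fit <- function(object, nsim = 1, seed = NULL,
                                 times = NULL, ...) {
  if (is.null(times)) times <- object$target$time_months
  one <- simulate_trajectory(object$params, t_start = min(times, 1),
                             t_end = max(times), eval_times = times)
  if (nsim == 1) one else replicate(nsim, one, simplify = FALSE)
}

#' Plot a fitted vicious-cycle model against its target
#'
#' Target points and the fitted curve on a log10 concentration axis.
#'
#' @param x A `vicious_fit`.
#' @param log Axis spec passed to [graphics::plot()] (`"y"` by default:
#'   the mouse data span two orders of magnitude).
#' @param ... Further graphical parameters.
#' @export
plot.vicious_fit <- function(x, log = "y", ...) {
  tgt <- x$target
  dense <- seq(min(tgt$time_months), max(tgt$time_months), length.out = 200)
  traj <- simulate_trajectory(x$params, t_start = min(dense, 1),
                              t_end = max(dense), eval_times = dense)
  graphics::plot(tgt$time_months, tgt$abeta_pg_per_mg, log = log,
                 xlab = "age (months)",
                 ylab = expression(paste("soluble A", beta[42],
                                         " (pg/mg)")), ...)
  graphics::lines(traj$time_months, traj$A, col = "red3", lwd = 2)
  graphics::legend("bottomright", c("target", "fitted model"),
                   pch = c(1, NA), lty = c(NA, 1),
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' One-dimensional slice of the fitting objective
#'
#' Evaluates the summed |log10 ratio| along a grid of one parameter,
#' holding the others at `base` — an identifiability diagnostic for the
#' published parameterisation.
#'
#' @param target A `target_series`.
#' @param base A [kinetic_params()].
#' @param param_name One of `"V1", "K1", "V1p", "K1p", "k2p"`.
#' @param grid Positive parameter values to profile over.
#' @return A data frame with columns `value` and `log_err` (`NA` where
#'   the solver failed).
#' @export
profile_objective <- function(target, base = kinetic_params(),
                              param_name, grid) {
  target <- as_target_series(target)
  stopifnot(param_name %in% c("V1", "K1", "V1p", "K1p", "k2p"))
  if (length(grid) == 0L)
    return(data.frame(value = numeric(0), log_err = numeric(0)))
  errs <- vapply(grid, function(v) {
    p <- do.call(update_params,
                 c(list(base), stats::setNames(list(v), param_name)))
    traj <- try(simulate_trajectory(p, t_start = 1,
                                    t_end = max(target$time_months),
                                    eval_times = target$time_months),
                silent = TRUE)
    if (inherits(traj, "try-error")) return(NA_real_)
    log_error(traj$A, target$abeta_pg_per_mg)
  }, numeric(1L))
  data.frame(value = grid, log_err = errs)
}
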