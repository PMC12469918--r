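#' Parameters of the logistic reference curve
#'
#' Constructs the four-constant parameterisation of the logistic curve
#' describing soluble Abeta42 accumulation (pg per mg wet brain tissue)
#' over the lifetime of the Tg2576 mouse.  The defaults are the published
#' constants of the mouse time course: baseline 34 pg/mg, amplitude
#' 2240 pg/mg, steepness 5.9 and midpoint 18 months.
#'
#' @param baseline Concentration floor at young age (pg/mg), > 0.
#' @param amplitude Rise from baseline to the old-age plateau (pg/mg), > 0.
#' @param steepness Dimensionless steepness of the rise, > 0.
#' @param midpoint Age at half-maximal rise (months), > 0.
#'
#' @return An object of class `logistic_params` (a named list).
#' @seealso [abeta_logistic()], [make_target_series()]
#' @export
#' @examples
#' p <- logistic_params()
#' abeta_logistic(18, p)  # baseline + amplitude/2 = 1154
logistic_params <- function(baseline = 34, amplitude = 2240,
                            steepness = 5.9, midpoint = 18) {
  p <- list(baseline = baseline, amplitude = amplitude,
            steepness = steepness, midpoint = midpoint)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  structure(p, class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat("Logistic Abeta42 curve: ", x$baseline, " + ", x$amplitude,
      " / (1 + (t/", x$midpoint, ")^-", x$steepness, ")\n", sep = "")
  invisible(x)
}

#' Evaluate the logistic reference curve
#'
#' The curve is `baseline + amplitude / (1 + (t/midpoint)^(-steepness))`.
#' The power-law form is algebraically identical to the exponential form
#' `exp(-steepness * ln(10) * log10(t/midpoint))` in the denominator: the
#' steepness multiplies a base-10 logarithm of scaled age.
#'
#' @param t Age in months; strictly positive (vectorised).
#' @param params A [logistic_params()] object.
#' @return Concentration(s) in pg/mg.
#' @export
abeta_logistic <- function(t, params = logistic_params()) {
  stopifnot(inherits(params, "logistic_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be positive and finite (months)", call. = FALSE)
  params$baseline +
    params$amplitude / (1 + (t / params$midpoint)^(-params$steepness))
}

#' Build a target concentration series
#'
#' Samples the logistic curve on a time grid, by default the integer
#' months 1 to 27 used as the fitting target for the mouse data.
#'
#' @param params A [logistic_params()] object.
#' @param times Strictly increasing ages in months, all > 0.
#' @return A `target_series`: a data frame with columns `time_months`
#'   and `abeta_pg_per_mg`.
#' @export
#' @examples
#' tgt <- make_target_series()
#' head(tgt)
make_target_series <- function(params = logistic_params(), times = 1:27) {
  if (length(times) == 0L) stop("'times' must be non-empty", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  out <- data.frame(time_months = as.numeric(times),
                    abeta_pg_per_mg = abeta_logistic(times, params))
  class(out) <- c("target_series", "data.frame")
  attr(out, "logistic_params") <- params
  out
}

#' Add multiplicative log-normal noise to a target series
#'
#' Each concentration is multiplied by `exp(eps)` with
#' `eps ~ Normal(0, sigma^2)`.  Multiplicative noise keeps all values
#' positive and matches the log-ratio scale of the fitting objective.
#' The global RNG state is left untouched.
#'
#' @param series A `target_series` (or data frame with the same columns).
#' @param sigma Standard deviation of the log-noise, >= 0.  `sigma = 0`
#'   returns the input unchanged.
#' @param seed Integer seed; the perturbation is reproducible.
#' @return A `target_series` with perturbed values.
#' @export
add_multiplicative_noise <- function(series, sigma, seed = 1L) {
  series <- as_target_series(series)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  if (sigma == 0) return(series)
  eps <- local_rnorm(nrow(series), sd = sigma, seed = seed)
  series$abeta_pg_per_mg <- series$abeta_pg_per_mg * exp(eps)
  attr(series, "noise_sigma") <- sigma
  attr(series, "noise_seed") <- as.integer(seed)
  series
}

# draw normals under a private RNG stream, restoring the global state
local_rnorm <- function(n, sd, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n, mean = 0, sd = sd)
}

as_target_series <- function(x) {
  if (inherits(x, "target_series")) return(x)
  if (is.data.frame(x) &&
      all(c("time_months", "abeta_pg_per_mg") %in% names(x))) {
    class(x) <- c("target_series", class(x)[class(x) != "target_series"])
    return(x)
  }
  stop("expected a target_series or a data frame with columns ",
       "'time_months' and 'abeta_pg_per_mg'", call. = FALSE)
}

#' Read or write a target series as CSV
#'
#' Two-column CSV with header `time_months,abeta_pg_per_mg`.
#'
#' @param series A `target_series`.
#' @param path File path.
#' @return `read_target_csv` returns a `target_series`;
#'   `write_target_csv` returns `path` invisibly.
#' @export
write_target_csv <- function(series, path) {
  series <- as_target_series(series)
  utils::write.csv(series[c("time_months", "abeta_pg_per_mg")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_target_csv
#' @export
read_target_csv <- function(path) {
  df <- utils::read.csv(path)
  as_target_series(df)
}
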