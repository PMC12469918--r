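#' Kinetic parameters of the vicious-cycle model
#'
#' The two-variable model couples the soluble Abeta42 concentration
#' `A(t)` (pg/mg) to an abstract disease factor `X(t)` (dimensionless;
#' tauopathy, oxidative stress, inflammation, ...) through mutual
#' Hill-type positive feedback:
#'
#' \deqn{dA/dt = V1 \, X^n / (K1^n + X^n) - k2 \, A + b}
#' \deqn{dX/dt = V1' \, A^n / (K1'^n + A^n) - k2' \, X}
#'
#' The defaults are the fitted mouse parameterisation: `V1 = 1.36e6`
#' pg mg^-1 mo^-1, `K1 = 10.7`, `k2 = 450` mo^-1 (from the ~1.1 h
#' turnover of soluble amyloid in mice), `V1p = 0.998` mo^-1,
#' `K1p = 134.2` pg/mg, `k2p = 0.00168` mo^-1, Hill coefficient `n = 2`
#' (the smallest integer giving a sigmoidal time course), and initial
#' state `A(1) = 34` pg/mg, `X(1) = 1` at the age of adulthood,
#' 1 month.  `basal` is an optional zeroth-order Abeta production term
#' `b` (pg mg^-1 mo^-1), zero by default, supporting model variants
#' with a linear source in addition to the feedback.
#'
#' @param V1 Feedback ceiling of Abeta production (pg mg^-1 mo^-1).
#' @param K1 Half-saturation of the Abeta production term in `X`
#'   (dimensionless).
#' @param k2 First-order Abeta removal rate (mo^-1).
#' @param V1p Feedback ceiling of `X` production (mo^-1).
#' @param K1p Half-saturation of the `X` production term in `A` (pg/mg).
#' @param k2p First-order `X` removal rate (mo^-1).
#' @param hill_n Hill coefficient, integer >= 1.
#' @param A_init Abeta concentration at the start of integration (pg/mg).
#' @param X_init `X` level at the start of integration (dimensionless).
#' @param basal Zeroth-order Abeta production (pg mg^-1 mo^-1), >= 0.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @seealso [simulate_trajectory()], [feedback_rhs()]
#' @export
#' @examples
#' p <- kinetic_params()
#' p
#' half_sat <- kinetic_params(K1 = 5)   # more sensitive feedback onto A
kinetic_params <- function(V1 = 1.36e6, K1 = 10.7, k2 = 450,
                           V1p = 0.998, K1p = 134.2, k2p = 0.00168,
                           hill_n = 2L, A_init = 34, X_init = 1,
                           basal = 0) {
  p <- list(V1 = V1, K1 = K1, k2 = k2, V1p = V1p, K1p = K1p, k2p = k2p,
            hill_n = as.integer(hill_n), A_init = A_init, X_init = X_init,
            basal = basal)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  # strictly positive: saturation constants and removal rates
  for (nm in c("K1", "k2", "K1p", "k2p")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("kinetic parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  # production ceilings may be dosed all the way to zero
  for (nm in c("V1", "V1p")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("kinetic parameter '", nm,
           "' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(p$hill_n) || length(p$hill_n) != 1L || p$hill_n < 1 ||
      p$hill_n != round(p$hill_n))
    stop("'hill_n' must be an integer >= 1", call. = FALSE)
  for (nm in c("A_init", "X_init", "basal")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
  }
  invisible(p)
}

#' Replace fields of a kinetic parameter set
#'
#' @param params A [kinetic_params()] object.
#' @param ... Named fields to replace (e.g. `V1 = 7e5`).
#' @return A validated `kinetic_params`.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "kinetic_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad))
    stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params[names(repl)] <- repl
  params$hill_n <- as.integer(params$hill_n)
  validate_kinetic_params(params)
  structure(params, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Vicious-cycle kinetic parameters (Hill n =", x$hill_n, ")\n")
  tab <- data.frame(
    value = unlist(x[c("V1", "K1", "k2", "V1p", "K1p", "k2p", "basal")]),
    unit = c("pg mg^-1 mo^-1", "-", "mo^-1", "mo^-1", "pg mg^-1", "mo^-1",
             "pg mg^-1 mo^-1"))
  print(format(tab, digits = 4))
  cat("initial state at t = 1 mo: A =", x$A_init, "pg/mg, X =",
      x$X_init, "\n")
  invisible(x)
}

#' Read or write kinetic parameters as YAML or JSON
#'
#' A flat mapping of the ten `kinetic_params` field names; the format is
#' chosen from the file extension (`.yaml`/`.yml` or `.json`).  A YAML
#' file with the default mouse parameterisation ships with the package:
#' `system.file("extdata", "mouse_params.yaml", package = "amyloidcycle")`.
#'
#' @param params A [kinetic_params()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_kinetic_params` returns a `kinetic_params`;
#'   `write_kinetic_params` returns `path` invisibly.
#' @export
write_kinetic_params <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  vals <- lapply(unclass(params), function(v) unname(v))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported extension in '", path, "'", call. = FALSE)
  invisible(path)
}

#' @rdname write_kinetic_params
#' @export
read_kinetic_params <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported extension in '", path, "'", call. = FALSE)
  do.call(kinetic_params, vals[names(vals) %in% names(formals(kinetic_params))])
}
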