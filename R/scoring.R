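#' Construct a SEAL model specification
#'
#' A linear workload model: an intercept plus named coefficients over a
#' subset of the 14 candidate variables, with score bounds. The score is the
#' affine form, clipped to `[lower, upper]` when `clip` is on.
#'
#' @param intercept numeric intercept, in score units.
#' @param coefficients named numeric vector; names must be among
#'   [seal_variable_names()].
#' @param lower,upper score bounds (default 1 and 6).
#' @param clip clip the affine form to the bounds (default `TRUE`).
#' @return an object of class `seal_model`.
#' @seealso [seal_2013()] for the published model.
#' @export
seal_model <- function(intercept, coefficients, lower = 1, upper = 6,
                       clip = TRUE) {
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    abort("coefficients must be a fully named numeric vector")
  }
  unknown <- setdiff(names(coefficients), seal_variable_names())
  if (length(unknown)) {
    abort(sprintf("unknown variable name(s) in coefficients: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!is.na(lower) && !is.na(upper) && lower > upper) {
    abort("lower bound exceeds upper bound")
  }
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 lower = lower, upper = upper, clip = isTRUE(clip)),
            class = "seal_model")
}

#' The published SEAL model ("SEAL-2013")
#'
#' The four-variable reduced model: score = 1.589 + 14.73 patient_hours +
#' 1.80 high_priority + 1.39 awaiting_md - 1.10 occupancy, clipped to
#' the 1-6 workload scale.
#'
#' @param clip clip to `[1, 6]` (default `TRUE`); with `clip = FALSE` the
#'   raw affine value is returned by [seal_score()], which is what the
#'   simulator uses as noise-free ground truth.
#' @return a `seal_model`.
#' @export
seal_2013 <- function(clip = TRUE) {
  seal_model(1.589,
             c(patient_hours = 14.73, high_priority = 1.80,
               awaiting_md = 1.39, occupancy = -1.10),
             clip = clip)
}

#' @export
print.seal_model <- function(x, ...) {
  cat("<seal_model>\n")
  cat(sprintf("  intercept: %g\n", x$intercept))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %-15s %+g\n", nm, x$coefficients[[nm]]))
  }
  cat(sprintf("  bounds: [%g, %g]%s\n", x$lower, x$upper,
              if (x$clip) " (clipped)" else " (not clipped)"))
  invisible(x)
}

#' Evaluate the SEAL score on variable vectors
#'
#' Computes `intercept + sum(coef * value)` per row, clipped to the model
#' bounds when clipping is on. A score of 6 represents the highest workload.
#'
#' @param v a named numeric vector, or a data frame / tibble of variable
#'   columns (one score per row). Every coefficient name in the model must
#'   be present.
#' @param model a [seal_model()]; defaults to the published [seal_2013()].
#' @return numeric vector of scores.
#' @examples
#' seal_score(c(patient_hours = 0.15, high_priority = 0.2,
#'              awaiting_md = 0.5, occupancy = 0.8))
#' @export
seal_score <- function(v, model = seal_2013()) {
  stopifnot(inherits(model, "seal_model"))
  vars <- names(model$coefficients)
  if (is.numeric(v) && !is.null(names(v))) {
    v <- as_tibble(as.list(v))
  }
  missing_vars <- setdiff(vars, names(v))
  if (length(missing_vars)) {
    abort(sprintf("variable(s) required by the model but absent: %s",
                  paste(missing_vars, collapse = ", ")))
  }
  x <- as.matrix(as.data.frame(v)[vars])
  raw <- drop(x %*% model$coefficients) + model$intercept
  if (model$clip) pmin(pmax(raw, model$lower), model$upper) else raw
}

#' Score time series from an event log
#'
#' Computes the 14 variables at each time point and evaluates the model,
#' the retrospective calculation used to monitor workload over a period
#' (e.g. an hourly grid).
#'
#' @inheritParams compute_variables
#' @param times sorted `POSIXct` vector.
#' @param model a [seal_model()].
#' @return a tibble with columns `time` and `score`.
#' @export
score_series <- function(visits, staff, cfg, times, model = seal_2013()) {
  vars <- variable_series(visits, staff, cfg, times)
  tibble(time = vars$time, score = seal_score(vars, model))
}

#' An hourly grid of time points
#'
#' @param start first time point (`POSIXct`).
#' @param hours number of hourly points.
#' @return `POSIXct` vector `start, start + 1h, ...` of length `hours`.
#' @export
hourly_grid <- function(start, hours) {
  stopifnot(inherits(start, "POSIXct"), hours >= 1)
  start + .HOUR * (seq_len(hours) - 1L)
}

#' Save and load model specifications
#'
#' Structured key-value text (YAML subset): `intercept`, `coefficients`
#' (map), `lower`, `upper`, `clip`. Numbers are written with 17 significant
#' digits so a read-back model is bit-identical.
#'
#' @param model a `seal_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "seal_model"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    sprintf("intercept: %s", num(model$intercept)),
    "coefficients:",
    sprintf("  %s: %s", names(model$coefficients),
            vapply(model$coefficients, num, "")),
    sprintf("lower: %s", num(model$lower)),
    sprintf("upper: %s", num(model$upper)),
    sprintf("clip: %s", if (model$clip) "true" else "false")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  kv <- yaml::read_yaml(path)
  seal_model(intercept = as.numeric(kv$intercept),
             coefficients = unlist(kv$coefficients),
             lower = as.numeric(kv$lower), upper = as.numeric(kv$upper),
             clip = isTRUE(kv$clip))
}
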