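#' Fit the multiple linear regression of workload on candidate variables
#'
#' Ordinary least squares with intercept of the mean workload assessment on
#' the variable columns, with the standard two-sided t-based p-values and
#' 95% confidence intervals. The design must be full rank: exactly collinear
#' columns are reported by name rather than silently dropped.
#'
#' @param X numeric matrix or data frame of variable values (one row per
#'   time point).
#' @param y numeric vector of mean workload scores, same length as
#'   `nrow(X)`.
#' @param names optional variable names (default `colnames(X)`).
#' @return an object of class `seal_fit`: a list with `intercept`, `table`
#'   (tibble: variable, coefficient, p_value, ci_low, ci_high),
#'   `r_squared`, `n`, and the fitting data (used by [select_reduced()]).
#' @export
fit_linear_model <- function(X, y, names = colnames(X)) {
  X <- as.matrix(X)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- names
  stopifnot(nrow(X) == length(y))
  if (nrow(X) <= ncol(X) + 1L) {
    abort("need more observations than variables + 1")
  }
  const <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    abort(sprintf("constant column(s): %s",
                  paste(names[const], collapse = ", ")))
  }
  design <- cbind(`(Intercept)` = 1, X)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    abort(sprintf("rank-deficient design; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  coefs <- stats::coef(fit)
  tab <- tibble(
    variable = names,
    coefficient = unname(coefs[names]),
    p_value = unname(sm$coefficients[names, "Pr(>|t|)"]),
    ci_low = unname(ci[names, 1]),
    ci_high = unname(ci[names, 2])
  )
  structure(list(intercept = unname(coefs["(Intercept)"]),
                 table = tab, r_squared = sm$r.squared,
                 n = length(y), data = list(X = X, y = y)),
            class = "seal_fit")
}

#' @export
print.seal_fit <- function(x, ...) {
  cat(sprintf("<seal_fit> n = %d, r-squared = %.3f\n", x$n, x$r_squared))
  cat(sprintf("  intercept: %s\n",
              if (is.na(x$intercept)) "(not available)" else
                sprintf("%.3f", x$intercept)))
  cat(sprintf("  %-16s %8s %10s %18s\n",
              "variable", "p-value", "coef", "95% CI"))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    lab <- if ("p_label" %in% names(x$table)) x$table$p_label[i] else
      formatC(r$p_value, digits = 2, format = "g")
    cat(sprintf("  %-16s %8s %10.2f %8.2f - %6.2f\n",
                r$variable, lab, r$coefficient, r$ci_low, r$ci_high))
  }
  invisible(x)
}

#' Univariate screening of candidate variables
#'
#' Pearson correlation of each variable with the workload assessment,
#' reported as r-squared with its two-sided p-value, evaluated before the
#' multiple regression. Zero-variance variables are flagged (r-squared
#' `NA`), not fatal.
#'
#' @inheritParams fit_linear_model
#' @return a tibble: variable, r_squared, p_value, zero_variance.
#' @export
univariate_screen <- function(X, y, names = colnames(X)) {
  X <- as.matrix(X)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  purrr::map(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (diff(range(x)) == 0 || diff(range(y)) == 0) {
      return(tibble(variable = names[j], r_squared = NA_real_,
                    p_value = NA_real_, zero_variance = TRUE))
    }
    ct <- stats::cor.test(x, y)
    tibble(variable = names[j], r_squared = unname(ct$estimate)^2,
           p_value = ct$p.value, zero_variance = FALSE)
  }) |> dplyr::bind_rows()
}

#' Pairwise collinearity report
#'
#' Flags variable pairs whose absolute pairwise Pearson correlation reaches
#' the threshold. Advisory only: nothing is dropped automatically.
#'
#' @param X numeric matrix or data frame.
#' @param names optional variable names.
#' @param threshold absolute correlation at or above which a pair is
#'   flagged (default 0.8).
#' @return a tibble: var1, var2, r (one row per flagged pair).
#' @export
collinearity_check <- function(X, names = colnames(X), threshold = 0.8) {
  X <- as.matrix(X)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2, function(col) diff(range(col)) > 0)
  cm <- matrix(NA_real_, ncol(X), ncol(X))
  if (sum(keep) >= 2) cm[keep, keep] <- stats::cor(X[, keep, drop = FALSE])
  out <- tibble(var1 = character(), var2 = character(), r = numeric())
  for (i in seq_len(ncol(X) - 1L)) {
    for (j in seq(i + 1L, ncol(X))) {
      if (!is.na(cm[i, j]) && abs(cm[i, j]) >= threshold) {
        out <- dplyr::bind_rows(out, tibble(var1 = names[i],
                                            var2 = names[j], r = cm[i, j]))
      }
    }
  }
  out
}

#' Reduce a full fit to the significant variables and refit
#'
#' Retains the variables with p-value strictly below `alpha` (default 0.05),
#' refits ordinary least squares on the retained set, and returns the refit
#' as a [seal_model()]. Reduction is single-pass: fit once, filter once,
#' refit once. A fit that carries no raw data (such as the published
#' coefficient table, [published_full_fit()]) cannot be refit; the retained
#' variables then keep their full-model coefficients and the intercept is
#' `NA` — such a model records the selection but cannot be scored.
#'
#' @param full a `seal_fit`.
#' @param alpha significance level; variables with `p < alpha` (strict) are
#'   retained.
#' @return a `seal_model` (clipped to 1-6).
#' @export
select_reduced <- function(full, alpha = 0.05) {
  stopifnot(inherits(full, "seal_fit"))
  retained <- full$table$variable[full$table$p_value < alpha]
  if (length(retained) == 0L) {
    abort(sprintf("no variable has p < %g; reduced model would be empty",
                  alpha))
  }
  if (is.null(full$data)) {
    coefs <- setNames(full$table$coefficient[match(retained,
                                                   full$table$variable)],
                      retained)
    return(seal_model(NA_real_, coefs))
  }
  refit <- fit_linear_model(full$data$X[, retained, drop = FALSE],
                            full$data$y, names = retained)
  seal_model(refit$intercept,
             setNames(refit$table$coefficient, refit$table$variable))
}

#' Ratio of variance explained by the reduced vs the full model
#'
#' @param reduced_r2,full_r2 r-squared values of the reduced and full fits.
#' @return `reduced_r2 / full_r2`.
#' @export
variance_explained_ratio <- function(reduced_r2, full_r2) {
  if (is.na(full_r2) || full_r2 <= 0 || full_r2 > 1) {
    abort("full-model r-squared must be in (0, 1]")
  }
  reduced_r2 / full_r2
}

#' The published full-model coefficient table
#'
#' The 14-variable regression summary as published: per-variable p-value,
#' coefficient and 95% CI. P-values printed as "<0.01" are stored as the
#' numeric placeholder 0.005 with the printed form kept in `p_label`; only
#' the strict `p < 0.05` comparison ever consumes the numeric value. No raw
#' data or intercept for the full model is available.
#'
#' @return `published_table()`: a tibble; `published_full_fit()`: a
#'   data-free `seal_fit` wrapping it (usable with [select_reduced()]).
#' @export
published_table <- function() {
  tibble(
    variable = seal_variable_names(),
    p_label = c("0.23", "0.48", "0.01", "<0.01", "0.13", "0.79", "<0.01",
                "<0.01", "0.72", "0.79", "0.95", "0.81", "0.43", "0.38"),
    p_value = c(0.23, 0.48, 0.01, 0.005, 0.13, 0.79, 0.005,
                0.005, 0.72, 0.79, 0.95, 0.81, 0.43, 0.38),
    coefficient = c(-0.64, -0.40, 1.80, 1.39, 0.07, 0.02, 14.73,
                    -1.10, 0.03, -0.12, 0.00, -0.03, -0.04, -0.05),
    ci_low = c(-0.79, -0.58, 0.39, 0.58, -0.02, -0.03, 11.12,
               -1.79, -1.01, -12.4, -26.3, -1.50, -1.92, -1.84),
    ci_high = c(0.19, 0.27, 3.21, 2.21, 0.14, 0.04, 18.34,
                -0.41, 1.58, 9.48, 28.2, -1.72, 0.83, 0.70)
  )
}

#' @rdname published_table
#' @export
published_full_fit <- function() {
  structure(list(intercept = NA_real_, table = published_table(),
                 r_squared = NA_real_, n = 233L, data = NULL),
            class = "seal_fit")
}
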