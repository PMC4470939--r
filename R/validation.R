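#' Combine rater assessments at each time point
#'
#' `mode = "head"`: the mean of the head nurse and head physician scores;
#' when only one answered, the available value is used; a time point with
#' neither is excluded. `mode = "all"`: the mean over every rater present
#' at the time point.
#'
#' @param assessments a tibble `time, ed_id, role, is_head, score` (see
#'   [read_assessments()]); `NA` scores mean the rater did not answer.
#' @param mode `"head"` or `"all"`.
#' @return a tibble `time, ed_id, combined`, one row per retained time
#'   point, sorted by time.
#' @export
combine_assessments <- function(assessments, mode = c("head", "all")) {
  mode <- match.arg(mode)
  a <- assessments
  if (mode == "head") a <- a[a$is_head, , drop = FALSE]
  a <- a[!is.na(a$score), , drop = FALSE]
  out <- a |>
    group_by(.data$time, .data$ed_id) |>
    summarise(combined = mean(.data$score), .groups = "drop") |>
    arrange(.data$time)
  out
}

#' Squared Pearson correlation with its p-value
#'
#' @param x,y numeric series of equal length (n >= 3), neither constant.
#' @return a list with `r_squared` and `p_value` (two-sided).
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a constant series")
  }
  ct <- stats::cor.test(x, y)
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value)
}

#' Agreement between head staff and the rest of the staff
#'
#' From an all-staff assessment table, computes (a) the squared Pearson
#' correlation between the head-staff combined score and the combined score
#' of the remaining raters at common time points, and (b) the nurse and
#' physician mean scores with a paired two-sided t-test on time points where
#' both roles answered. When the paired differences are all zero the t
#' statistic is undefined and the p-value is reported as `NA`.
#'
#' @param assessments a tibble `time, ed_id, role, is_head, score`.
#' @return a list of class `seal_agreement`: `head_vs_rest`
#'   (r_squared, p_value, n), `nurse_mean`, `md_mean`, `t_p_value`,
#'   `n_pairs`.
#' @export
staff_agreement <- function(assessments) {
  a <- assessments[!is.na(assessments$score), , drop = FALSE]
  head_s <- combine_assessments(a[a$is_head, , drop = FALSE], "all")
  rest_s <- combine_assessments(a[!a$is_head, , drop = FALSE], "all")
  common <- intersect(as.numeric(head_s$time), as.numeric(rest_s$time))
  if (length(common) < 3) abort("fewer than 3 paired head/rest time points")
  h <- head_s$combined[match(common, as.numeric(head_s$time))]
  r <- rest_s$combined[match(common, as.numeric(rest_s$time))]
  hv <- pearson_r2(h, r)
  hv$n <- length(common)

  by_role <- function(role) {
    s <- a[a$role == role, , drop = FALSE] |>
      group_by(.data$time) |>
      summarise(m = mean(.data$score), .groups = "drop")
    s
  }
  nr <- by_role("nurse")
  md <- by_role("md")
  both <- intersect(as.numeric(nr$time), as.numeric(md$time))
  if (length(both) < 3) abort("fewer than 3 paired nurse/physician time points")
  nv <- nr$m[match(both, as.numeric(nr$time))]
  mv <- md$m[match(both, as.numeric(md$time))]
  t_p <- if (stats::sd(nv - mv) == 0) NA_real_ else
    stats::t.test(nv, mv, paired = TRUE)$p.value
  structure(list(head_vs_rest = hv,
                 nurse_mean = mean(nv), md_mean = mean(mv),
                 t_p_value = t_p, n_pairs = length(both)),
            class = "seal_agreement")
}

#' @export
print.seal_agreement <- function(x, ...) {
  cat("<seal_agreement>\n")
  cat(sprintf("  head vs rest: r-squared = %.3f, p = %.3g (n = %d)\n",
              x$head_vs_rest$r_squared, x$head_vs_rest$p_value,
              x$head_vs_rest$n))
  cat(sprintf("  nurse mean %.2f vs physician mean %.2f, paired t p = %s (n = %d)\n",
              x$nurse_mean, x$md_mean,
              if (is.na(x$t_p_value)) "NA" else sprintf("%.3g", x$t_p_value),
              x$n_pairs))
  invisible(x)
}

#' Mean model score over a period
#'
#' @param scores a numeric vector of scores, or a tibble with a `score`
#'   column as returned by [score_series()].
#' @return the arithmetic mean.
#' @export
mean_period_score <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) == 0) abort("empty score series")
  mean(scores)
}

#' Read and write assessment records
#'
#' Comma-delimited text with columns `time,ed_id,role,is_head,score`;
#' `role` is `nurse` or `md`, `is_head` is `true`/`false`, and an empty
#' score marks an unanswered questionnaire.
#'
#' @param path file path.
#' @return `read_assessments()`: a tibble.
#' @export
read_assessments <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    time = "c", ed_id = "c", role = "c", is_head = "l", score = "d"),
    progress = FALSE)
  need <- c("time", "ed_id", "role", "is_head", "score")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- !raw$role %in% c("nurse", "md")
  if (any(bad)) {
    abort(sprintf("%s: invalid role at line(s) %s", path,
                  paste(utils::head(which(bad) + 1L, 5L), collapse = ", ")))
  }
  out_of_scale <- !is.na(raw$score) & (raw$score < 1 | raw$score > 6)
  if (any(out_of_scale)) {
    abort(sprintf("%s: score outside 1-6 at line(s) %s", path,
                  paste(utils::head(which(out_of_scale) + 1L, 5L),
                        collapse = ", ")))
  }
  mutate(raw[need], time = parse_ts(.data$time))
}

#' @rdname read_assessments
#' @param assessments an assessments tibble.
#' @export
write_assessments <- function(assessments, path) {
  out <- mutate(assessments, time = format_ts(.data$time),
                is_head = ifelse(.data$is_head, "true", "false"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}
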