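#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate group_by summarise arrange bind_rows n_distinct
#' @importFrom stats rnorm runif setNames
NULL

# seconds per hour; all interval arithmetic is done in numeric seconds (UTC)
.HOUR <- 3600

#' Parse and format minute-resolution timestamps
#'
#' Timestamps throughout the package are naive local times at minute
#' resolution, represented as `POSIXct` in the `UTC` zone (no daylight-saving
#' handling). The on-disk form is ISO-8601 `YYYY-MM-DDTHH:MM`; an empty field
#' means missing (for `first_md_contact`, `admit_decision`) or open (for
#' `departure`, `assign_end` of a patient/assignment still active).
#'
#' @param x character vector of `YYYY-MM-DDTHH:MM` strings; `""` and `NA`
#'   parse to `NA`.
#' @return `parse_ts()`: a `POSIXct` vector; `format_ts()`: a character
#'   vector with `""` for `NA`.
#' @examples
#' parse_ts("2013-03-11T12:00")
#' format_ts(parse_ts(c("2013-03-11T12:00", "")))
#' @export
parse_ts <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(sprintf("malformed timestamp(s): %s",
                  paste(utils::head(x[bad], 3L), collapse = ", ")))
  }
  out
}

#' @rdname parse_ts
#' @param t a `POSIXct` vector.
#' @export
format_ts <- function(t) {
  out <- format(t, "%Y-%m-%dT%H:%M", tz = "UTC")
  out[is.na(t)] <- ""
  out
}

#' Trailing one-hour assessment window
#'
#' All SEAL variables are measured over the hour preceding an assessment time
#' point. `window_of(t)` returns the half-open interval `[t - 1h, t)`: a visit
#' touching the window only at a boundary instant contributes nothing, so
#' adjacent windows partition time.
#'
#' @param t assessment time, `POSIXct` (length 1).
#' @return an object of class `seal_window` with elements `start` and `end`.
#' @examples
#' window_of(parse_ts("2013-03-11T12:00"))
#' @export
window_of <- function(t) {
  stopifnot(inherits(t, "POSIXct"), length(t) == 1L, !is.na(t))
  structure(list(start = t - .HOUR, end = t), class = "seal_window")
}

#' @export
print.seal_window <- function(x, ...) {
  cat(sprintf("<seal_window> [%s, %s)\n", format_ts(x$start), format_ts(x$end)))
  invisible(x)
}

#' Overlap of intervals with a window, in hours
#'
#' Computes, per element, the duration of `[start, end) intersect
#' [window$start, window$end)` in hours. An `NA` end is an open interval
#' (still active) and is truncated at the window end; an `NA` start yields
#' `NA`.
#'
#' @param start,end `POSIXct` vectors (recycled to common length).
#' @param window a `seal_window`.
#' @return numeric vector of overlap durations in hours (>= 0).
#' @export
interval_overlap_hours <- function(start, end, window) {
  stopifnot(inherits(window, "seal_window"))
  s <- pmax(as.numeric(start), as.numeric(window$start))
  e <- as.numeric(end)
  e[is.na(e)] <- Inf
  e <- pmin(e, as.numeric(window$end))
  pmax(e - s, 0) / .HOUR
}

#' Visits present in a window
#'
#' A patient counts as "in the ED" during the window if the presence interval
#' `[arrival, departure)` (open departure = still present) overlaps the window
#' with strictly positive duration. Departing exactly at the window start, or
#' arriving exactly at the window end, does not count (half-open convention).
#'
#' @param visits a validated visits tibble (see [read_visits()]).
#' @param window a `seal_window`.
#' @return the subset of `visits` present during the window.
#' @export
patients_in_window <- function(visits, window) {
  ov <- interval_overlap_hours(visits$arrival, visits$departure, window)
  visits[ov > 0, , drop = FALSE]
}

.VISIT_COLS <- c("visit_id", "arrival", "departure", "registration",
                 "triage_priority", "current_priority",
                 "first_md_contact", "admit_decision")
.STAFF_COLS <- c("visit_id", "staff_id", "role", "assign_start", "assign_end")

#' Validate a visits table
#'
#' Checks the `PatientVisit` invariants row by row: priorities in 1..5,
#' `arrival <= departure`, `arrival <= first_md_contact <= departure`,
#' `arrival <= admit_decision <= departure`, `registration <= arrival`
#' rejected. Missing `registration` / `current_priority` default to `arrival`
#' / `triage_priority`.
#'
#' @param visits a data frame with the visit columns.
#' @param rows optional original row labels used in error messages (defaults
#'   to `1:nrow`).
#' @return the validated tibble (with defaults filled in), invisibly usable.
#' @export
validate_visits <- function(visits, rows = NULL) {
  visits <- as_tibble(visits)
  missing_cols <- setdiff(.VISIT_COLS, names(visits))
  if (length(missing_cols)) {
    abort(sprintf("visits table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  rows <- rows %||% seq_len(nrow(visits))
  visits$registration[is.na(visits$registration)] <-
    visits$arrival[is.na(visits$registration)]
  visits$current_priority[is.na(visits$current_priority)] <-
    visits$triage_priority[is.na(visits$current_priority)]

  problem <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      abort(sprintf("invalid visit row(s) %s: %s",
                    paste(utils::head(rows[which(bad)], 5L), collapse = ", "),
                    what))
    }
  }
  problem(is.na(visits$arrival), "missing arrival")
  problem(!visits$triage_priority %in% 1:5, "triage_priority outside 1-5")
  problem(!visits$current_priority %in% 1:5, "current_priority outside 1-5")
  problem(!is.na(visits$departure) & visits$departure < visits$arrival,
          "departure before arrival")
  problem(visits$registration < visits$arrival, "registration before arrival")
  with_dep <- function(x) !is.na(x) & !is.na(visits$departure)
  problem(!is.na(visits$first_md_contact) &
            visits$first_md_contact < visits$arrival,
          "first_md_contact before arrival")
  problem(with_dep(visits$first_md_contact) &
            visits$first_md_contact > visits$departure,
          "first_md_contact after departure")
  problem(!is.na(visits$admit_decision) &
            visits$admit_decision < visits$arrival,
          "admit_decision before arrival")
  problem(with_dep(visits$admit_decision) &
            visits$admit_decision > visits$departure,
          "admit_decision after departure")
  visits
}

#' Read and write ED visit logs
#'
#' Visits files are comma-delimited text with a header row and columns
#' `visit_id,arrival,departure,registration,triage_priority,current_priority,
#' first_md_contact,admit_decision`. Timestamps are ISO-8601
#' `YYYY-MM-DDTHH:MM`; an empty field is missing/open. Rows violating the
#' visit invariants are rejected with their line numbers. Reading a written
#' file reproduces the original records.
#'
#' @param path file path.
#' @param extra_cols how to treat unknown columns: `"ignore"` (default,
#'   dropped) or `"keep"`.
#' @return `read_visits()`: a validated visits tibble.
#' @export
read_visits <- function(path, extra_cols = c("ignore", "keep")) {
  extra_cols <- match.arg(extra_cols)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(.VISIT_COLS, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (extra_cols == "ignore") raw <- raw[.VISIT_COLS]
  if (nrow(raw) == 0L) {
    return(empty_visits())
  }
  parse_col <- function(col) {
    tryCatch(parse_ts(raw[[col]]), error = function(e) {
      abort(sprintf("%s: column %s: %s", path, col, conditionMessage(e)))
    })
  }
  visits <- mutate(raw,
    arrival = parse_col("arrival"),
    departure = parse_col("departure"),
    registration = parse_col("registration"),
    first_md_contact = parse_col("first_md_contact"),
    admit_decision = parse_col("admit_decision"),
    triage_priority = as.integer(.data$triage_priority),
    current_priority = as.integer(.data$current_priority)
  )
  # header is line 1, first data row is line 2
  validate_visits(visits, rows = seq_len(nrow(visits)) + 1L)
}

#' @rdname read_visits
#' @param visits a visits tibble.
#' @export
write_visits <- function(visits, path) {
  visits <- validate_visits(visits)
  out <- mutate(visits,
    arrival = format_ts(.data$arrival),
    departure = format_ts(.data$departure),
    registration = format_ts(.data$registration),
    first_md_contact = format_ts(.data$first_md_contact),
    admit_decision = format_ts(.data$admit_decision)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' An empty, correctly typed visits table
#' @return a zero-row visits tibble.
#' @export
empty_visits <- function() {
  ts0 <- parse_ts(character())
  tibble(visit_id = character(), arrival = ts0, departure = ts0,
         registration = ts0, triage_priority = integer(),
         current_priority = integer(), first_md_contact = ts0,
         admit_decision = ts0)
}

#' An empty, correctly typed staff-assignment table
#' @return a zero-row staff tibble.
#' @export
empty_staff <- function() {
  ts0 <- parse_ts(character())
  tibble(visit_id = character(), staff_id = character(), role = character(),
         assign_start = ts0, assign_end = ts0)
}

#' Read and write staff assignment records
#'
#' Staff files are comma-delimited with columns
#' `visit_id,staff_id,role,assign_start,assign_end`; `role` is `md` or
#' `nurse`, and an empty `assign_end` means the assignment is still open.
#' A physician or nurse counts as active staff for a window if any of their
#' assignment intervals overlaps it.
#'
#' @param path file path.
#' @return `read_staff()`: a validated staff tibble.
#' @export
read_staff <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(.STAFF_COLS, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0L) return(empty_staff())
  staff <- mutate(raw[.STAFF_COLS],
    assign_start = parse_ts(.data$assign_start),
    assign_end = parse_ts(.data$assign_end)
  )
  validate_staff(staff, rows = seq_len(nrow(staff)) + 1L)
}

#' @rdname read_staff
#' @param staff a staff tibble.
#' @export
write_staff <- function(staff, path) {
  staff <- validate_staff(staff)
  out <- mutate(staff,
    assign_start = format_ts(.data$assign_start),
    assign_end = format_ts(.data$assign_end)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname validate_visits
#' @param staff a staff-assignment data frame.
#' @export
validate_staff <- function(staff, rows = NULL) {
  staff <- as_tibble(staff)
  missing_cols <- setdiff(.STAFF_COLS, names(staff))
  if (length(missing_cols)) {
    abort(sprintf("staff table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  rows <- rows %||% seq_len(nrow(staff))
  bad_role <- !staff$role %in% c("md", "nurse")
  if (any(bad_role)) {
    abort(sprintf("invalid staff row(s) %s: role must be 'md' or 'nurse'",
                  paste(utils::head(rows[which(bad_role)], 5L),
                        collapse = ", ")))
  }
  bad_iv <- is.na(staff$assign_start) |
    (!is.na(staff$assign_end) & staff$assign_end < staff$assign_start)
  if (any(bad_iv)) {
    abort(sprintf("invalid staff row(s) %s: bad assignment interval",
                  paste(utils::head(rows[which(bad_iv)], 5L),
                        collapse = ", ")))
  }
  staff
}

#' ED configuration (denominators of the SEAL ratio variables)
#'
#' Holds the per-ED normalizers that make the workload variables independent
#' of ED size: treatment beds, hospital beds and the average daily visit
#' volume. Either `avg_daily_visits` or `annual_visits` (divided by 365) must
#' be given.
#'
#' @param ed_id label for the ED.
#' @param ed_beds number of ED treatment beds (> 0).
#' @param hospital_beds number of beds in the parent hospital (> 0).
#' @param avg_daily_visits average visits per day (> 0).
#' @param annual_visits alternative to `avg_daily_visits`.
#' @return an object of class `ed_config`.
#' @examples
#' ed_config("A", ed_beds = 35, hospital_beds = 710, annual_visits = 65000)
#' @export
ed_config <- function(ed_id, ed_beds, hospital_beds,
                      avg_daily_visits = NULL, annual_visits = NULL) {
  if (is.null(avg_daily_visits)) {
    if (is.null(annual_visits)) {
      abort("one of avg_daily_visits or annual_visits is required")
    }
    avg_daily_visits <- annual_visits / 365
  }
  ed_beds <- as.numeric(ed_beds)
  hospital_beds <- as.numeric(hospital_beds)
  avg_daily_visits <- as.numeric(avg_daily_visits)
  if (!all(c(ed_beds, hospital_beds, avg_daily_visits) > 0)) {
    abort("ed_beds, hospital_beds and avg_daily_visits must be positive")
  }
  structure(list(ed_id = as.character(ed_id), ed_beds = ed_beds,
                 hospital_beds = hospital_beds,
                 avg_daily_visits = avg_daily_visits),
            class = "ed_config")
}

#' @export
print.ed_config <- function(x, ...) {
  cat(sprintf("<ed_config> %s: %g ED beds, %g hospital beds, %.1f visits/day\n",
              x$ed_id, x$ed_beds, x$hospital_beds, x$avg_daily_visits))
  invisible(x)
}

#' Read and write ED configuration files
#'
#' Key-value text (YAML subset) with keys `ed_id`, `ed_beds`,
#' `hospital_beds` and `avg_daily_visits` or `annual_visits`.
#'
#' @param path file path.
#' @return `read_ed_config()`: an [ed_config()] object.
#' @export
read_ed_config <- function(path) {
  kv <- yaml::read_yaml(path)
  ed_config(ed_id = kv$ed_id, ed_beds = kv$ed_beds,
            hospital_beds = kv$hospital_beds,
            avg_daily_visits = kv$avg_daily_visits,
            annual_visits = kv$annual_visits)
}

#' @rdname read_ed_config
#' @param cfg an `ed_config`.
#' @export
write_ed_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ed_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' The five study EDs
#'
#' Configurations of the five emergency departments the model was derived
#' on: the university hospitals in Lund (A) and Malmo (B) and the general
#' hospitals in Helsingborg (C), Ystad (D) and Kristianstad (E). Average
#' daily visits are annual visits / 365.
#'
#' @param ed one of `"A"`..`"E"`, or `NULL` for a list of all five.
#' @return an [ed_config()] or a named list of them.
#' @export
study_ed_configs <- function(ed = NULL) {
  cfgs <- list(
    A = ed_config("A", ed_beds = 35, hospital_beds = 710, annual_visits = 65000),
    B = ed_config("B", ed_beds = 72, hospital_beds = 660, annual_visits = 85000),
    C = ed_config("C", ed_beds = 38, hospital_beds = 380, annual_visits = 65000),
    D = ed_config("D", ed_beds = 16, hospital_beds = 160, annual_visits = 30000),
    E = ed_config("E", ed_beds = 24, hospital_beds = 280, annual_visits = 50000)
  )
  if (is.null(ed)) cfgs else cfgs[[match.arg(ed, names(cfgs))]]
}
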