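#' Names of the fourteen candidate workload variables
#'
#' The full SEAL candidate set, in the canonical column order used by
#' [compute_variables()] and the variable time-series writer.
#'
#' @return character vector of length 14.
#' @export
seal_variable_names <- function() {
  c("priority", "triage_priority", "high_priority", "awaiting_md",
    "average_time", "longest_stay", "patient_hours", "occupancy",
    "occupancy_rate", "average_volume", "admit_index", "unseen",
    "mds", "nurses")
}

#' Compute the fourteen SEAL workload variables at a time point
#'
#' Evaluates every candidate variable over the trailing one-hour window
#' `[t - 1h, t)`. "Patients in the ED" means the distinct patients whose
#' presence interval overlaps the window with positive duration; all
#' numerators are measured inside the window only. Per-patient ratios are
#' defined as 0 when the window is empty (minimal-workload convention).
#'
#' The variables, with their denominators:
#' \describe{
#'   \item{priority, triage_priority}{mean current / initial RETTS priority
#'     (1 = most acute) over patients in the window.}
#'   \item{high_priority}{fraction of patients with current priority 1 or 2.}
#'   \item{awaiting_md}{summed physician-waiting time accrued inside the
#'     window (arrival until first physician contact; never-seen patients
#'     accrue until the window end), hours, per patient in the window.}
#'   \item{average_time}{mean total length of stay, hours, of patients whose
#'     departure falls inside the window; 0 if none departed.}
#'   \item{longest_stay}{longest elapsed stay at the window end among
#'     patients in the window, hours.}
#'   \item{patient_hours}{total patient presence time inside the window
#'     (at most 1 h per patient), hours, divided by average daily visits.}
#'   \item{occupancy}{patients in the window per ED bed.}
#'   \item{occupancy_rate}{patients whose registration interval overlaps the
#'     window, per ED bed (equals occupancy when registration = arrival).}
#'   \item{average_volume}{patients in the window divided by average daily
#'     visits.}
#'   \item{admit_index}{patients boarding during the window (admission
#'     decision made, not yet departed) per hospital bed.}
#'   \item{unseen}{patients in the window with no physician contact before
#'     the window end, per ED bed.}
#'   \item{mds, nurses}{distinct physicians / nurses responsible for at
#'     least one patient during the window, per patient in the window.}
#' }
#'
#' @param visits validated visits tibble.
#' @param staff validated staff-assignment tibble.
#' @param cfg an [ed_config()].
#' @param t assessment time (`POSIXct`, length 1).
#' @return a one-row tibble with column `time` and the 14 variables.
#' @examples
#' v <- empty_visits()
#' compute_variables(v, empty_staff(), study_ed_configs("A"),
#'                   parse_ts("2013-03-11T12:00"))
#' @export
compute_variables <- function(visits, staff, cfg, t) {
  stopifnot(inherits(cfg, "ed_config"))
  w <- window_of(t)
  inw <- patients_in_window(visits, w)
  n <- nrow(inw)
  per_patient <- function(x) if (n == 0L) 0 else x / n

  presence <- interval_overlap_hours(inw$arrival, inw$departure, w)

  # waiting for a doctor: [arrival, first_md_contact or open) within window
  waiting <- interval_overlap_hours(inw$arrival, inw$first_md_contact, w)

  # elapsed stay at window end, truncated for patients still present
  dep <- as.numeric(inw$departure)
  dep[is.na(dep)] <- Inf
  elapsed <- (pmin(dep, as.numeric(w$end)) - as.numeric(inw$arrival)) / .HOUR

  departed <- !is.na(visits$departure) &
    visits$departure >= w$start & visits$departure < w$end
  los_departed <- as.numeric(visits$departure[departed] -
                               visits$arrival[departed], units = "hours")

  reg_n <- sum(interval_overlap_hours(visits$registration, visits$departure,
                                      w) > 0)
  boarding_n <- sum(interval_overlap_hours(visits$admit_decision,
                                           visits$departure, w) > 0,
                    na.rm = TRUE)
  unseen_n <- sum(is.na(inw$first_md_contact) | inw$first_md_contact >= w$end)

  active_staff <- function(role) {
    rows <- staff$role == role &
      interval_overlap_hours(staff$assign_start, staff$assign_end, w) > 0
    dplyr::n_distinct(staff$staff_id[rows])
  }

  tibble(
    time = t,
    priority = if (n == 0L) 0 else mean(inw$current_priority),
    triage_priority = if (n == 0L) 0 else mean(inw$triage_priority),
    high_priority = per_patient(sum(inw$current_priority <= 2L)),
    awaiting_md = per_patient(sum(waiting)),
    average_time = if (length(los_departed)) mean(los_departed) else 0,
    longest_stay = if (n == 0L) 0 else max(elapsed),
    patient_hours = sum(presence) / cfg$avg_daily_visits,
    occupancy = n / cfg$ed_beds,
    occupancy_rate = reg_n / cfg$ed_beds,
    average_volume = n / cfg$avg_daily_visits,
    admit_index = boarding_n / cfg$hospital_beds,
    unseen = unseen_n / cfg$ed_beds,
    mds = per_patient(active_staff("md")),
    nurses = per_patient(active_staff("nurse"))
  )
}

#' Variable time series over many time points
#'
#' @inheritParams compute_variables
#' @param times sorted `POSIXct` vector of assessment times.
#' @return a tibble with one row per time point (`time` + 14 variables).
#' @export
variable_series <- function(visits, staff, cfg, times) {
  stopifnot(inherits(times, "POSIXct"))
  purrr::map(seq_along(times),
             function(i) compute_variables(visits, staff, cfg, times[i])) |>
    dplyr::bind_rows()
}

#' Write or read a variable time series
#'
#' Comma-delimited text: column `t` (ISO-8601 minutes) followed by the 14
#' variable columns in canonical order.
#'
#' @param vars a tibble from [variable_series()].
#' @param path file path.
#' @export
write_variables <- function(vars, path) {
  out <- vars[c("time", seal_variable_names())]
  names(out)[1] <- "t"
  out$t <- format_ts(out$t)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_variables
#' @export
read_variables <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    t = "c", .default = "d"), progress = FALSE)
  out <- mutate(raw, t = parse_ts(.data$t))
  names(out)[1] <- "time"
  out
}
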