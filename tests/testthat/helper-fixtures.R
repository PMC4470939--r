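# shared fixtures: hand-built visits and a brute-force minute-grid oracle

ts <- function(hm, day = "2013-03-11") parse_ts(paste0(day, "T", hm))

# one-row visits tibble with sensible defaults
make_visit <- function(visit_id = "v1", arrival, departure = NA,
                       registration = NULL, triage_priority = 3L,
                       current_priority = NULL, first_md_contact = NA,
                       admit_decision = NA) {
  as_ts <- function(x) {
    if (length(x) == 1 && is.na(x)) parse_ts(NA_character_) else x
  }
  tibble::tibble(
    visit_id = visit_id, arrival = arrival,
    departure = as_ts(departure),
    registration = if (is.null(registration)) arrival else registration,
    triage_priority = as.integer(triage_priority),
    current_priority = as.integer(
      if (is.null(current_priority)) triage_priority else current_priority),
    first_md_contact = as_ts(first_md_contact),
    admit_decision = as_ts(admit_decision)
  )
}

bind_visits <- function(...) dplyr::bind_rows(...)

test_cfg <- function(ed_beds = 20, hospital_beds = 400,
                     avg_daily_visits = 10) {
  ed_config("T", ed_beds = ed_beds, hospital_beds = hospital_beds,
            avg_daily_visits = avg_daily_visits)
}

# random minute-resolution log spanning roughly one day around the window
random_visits <- function(n, seed) {
  withr::with_seed(seed, {
    base <- as.numeric(ts("00:00"))
    arr <- base + 60 * sample.int(24 * 60, n, replace = TRUE)
    stay <- 60 * sample.int(10 * 60, n, replace = TRUE)
    dep <- arr + stay
    dep[runif(n) < 0.1] <- NA  # still present
    wait <- 60 * sample.int(3 * 60, n, replace = TRUE)
    md <- arr + wait
    seen <- !is.na(dep) & md > dep
    md[seen] <- NA
    md[runif(n) < 0.15] <- NA
    adm <- rep(NA_real_, n)
    pick <- which(runif(n) < 0.3 & !is.na(dep))
    adm[pick] <- arr[pick] + round(runif(length(pick)) * (dep[pick] - arr[pick]) / 60) * 60
    tibble::tibble(
      visit_id = sprintf("r%04d", seq_len(n)),
      arrival = .POSIXct(arr, tz = "UTC"),
      departure = .POSIXct(dep, tz = "UTC"),
      registration = .POSIXct(arr, tz = "UTC"),
      triage_priority = sample.int(5L, n, replace = TRUE),
      current_priority = sample.int(5L, n, replace = TRUE),
      first_md_contact = .POSIXct(md, tz = "UTC"),
      admit_decision = .POSIXct(adm, tz = "UTC")
    )
  })
}

# brute-force minute-by-minute occupancy grid over a window: per-visit
# presence and physician-waiting hours, counting whole minutes
minute_oracle <- function(visits, w) {
  mins <- seq(as.numeric(w$start), as.numeric(w$end) - 60, by = 60)
  n <- nrow(visits)
  presence <- waiting <- numeric(n)
  for (i in seq_len(n)) {
    arr <- as.numeric(visits$arrival[i])
    dep <- as.numeric(visits$departure[i])
    if (is.na(dep)) dep <- Inf
    md <- as.numeric(visits$first_md_contact[i])
    if (is.na(md)) md <- Inf
    presence[i] <- sum(mins >= arr & mins < dep) / 60
    waiting[i] <- sum(mins >= arr & mins < md) / 60
  }
  list(presence = presence, waiting = waiting)
}

# independent evaluation of the affine model form (explicit loop, no
# matrix product) used as the scoring oracle
affine_oracle <- function(v, model) {
  out <- rep(model$intercept, nrow(v))
  for (nm in names(model$coefficients)) {
    out <- out + model$coefficients[[nm]] * v[[nm]]
  }
  out
}
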