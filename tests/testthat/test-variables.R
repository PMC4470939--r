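t0 <- function() ts("12:00")

test_that("patient hours normalizes window-truncated presence by daily volume", {
  cfg <- test_cfg(avg_daily_visits = 10)
  whole <- make_visit("a", arrival = ts("10:00"), departure = ts("13:00"))
  v <- compute_variables(whole, empty_staff(), cfg, t0())
  expect_equal(v$patient_hours, 1 / 10)

  empty <- compute_variables(empty_visits(), empty_staff(), cfg, t0())
  expect_equal(empty$patient_hours, 0)

  cfg4 <- test_cfg(avg_daily_visits = 4)
  halves <- bind_visits(
    make_visit("a", arrival = ts("10:00"), departure = ts("11:30")),
    make_visit("b", arrival = ts("11:30"), departure = ts("14:00"))
  )
  v2 <- compute_variables(halves, empty_staff(), cfg4, t0())
  expect_equal(v2$patient_hours, (0.5 + 0.5) / 4)
})

test_that("occupancy is patients in the window per ED bed", {
  cfg <- test_cfg(ed_beds = 20)
  ten <- bind_visits(lapply(1:10, function(i) {
    make_visit(paste0("p", i), arrival = ts("11:15"), departure = ts("11:45"))
  }))
  expect_equal(compute_variables(ten, empty_staff(), cfg, t0())$occupancy, 0.5)
  expect_equal(compute_variables(empty_visits(), empty_staff(), cfg,
                                 t0())$occupancy, 0)
  cfg10 <- test_cfg(ed_beds = 10)
  expect_equal(compute_variables(ten, empty_staff(), cfg10, t0())$occupancy, 1)
})

test_that("physician waiting accrues inside the window per patient present", {
  cfg <- test_cfg()
  seen_half <- make_visit("a", arrival = ts("11:00"), departure = ts("13:00"),
                          first_md_contact = ts("11:30"))
  expect_equal(compute_variables(seen_half, empty_staff(), cfg,
                                 t0())$awaiting_md, 0.5)

  seen_before <- make_visit("b", arrival = ts("09:00"),
                            departure = ts("13:00"),
                            first_md_contact = ts("10:00"))
  expect_equal(compute_variables(seen_before, empty_staff(), cfg,
                                 t0())$awaiting_md, 0)

  # one never-seen patient present the whole window + one already seen
  mix <- bind_visits(
    make_visit("c", arrival = ts("10:00"), departure = ts("14:00")),
    make_visit("d", arrival = ts("10:00"), departure = ts("14:00"),
               first_md_contact = ts("10:30"))
  )
  expect_equal(compute_variables(mix, empty_staff(), cfg, t0())$awaiting_md,
               1.0 / 2)
})

test_that("high priority is the fraction with current priority 1 or 2", {
  cfg <- test_cfg()
  eight <- bind_visits(lapply(1:8, function(i) {
    make_visit(paste0("p", i), arrival = ts("11:10"), departure = ts("11:50"),
               triage_priority = if (i <= 2) 2L else 4L)
  }))
  v <- compute_variables(eight, empty_staff(), cfg, t0())
  expect_equal(v$high_priority, 0.25)

  low <- bind_visits(lapply(1:3, function(i) {
    make_visit(paste0("p", i), arrival = ts("11:10"), triage_priority = 5L)
  }))
  expect_equal(compute_variables(low, empty_staff(), cfg, t0())$high_priority, 0)

  crit <- make_visit("p", arrival = ts("11:10"), triage_priority = 1L)
  expect_equal(compute_variables(crit, empty_staff(), cfg, t0())$high_priority, 1)
})

test_that("staff ratios count distinct responsible staff in the window", {
  cfg <- test_cfg()
  six <- bind_visits(lapply(1:6, function(i) {
    make_visit(paste0("p", i), arrival = ts("11:00"), departure = ts("12:30"))
  }))
  # 3 physicians, each responsible for two of the six patients
  staff <- tibble::tibble(
    visit_id = paste0("p", 1:6),
    staff_id = paste0("md", rep(1:3, each = 2)),
    role = "md",
    assign_start = rep(ts("11:00"), 6), assign_end = rep(ts("12:30"), 6)
  )
  v <- compute_variables(six, staff, cfg, t0())
  expect_equal(v$mds, 3 / 6)
  expect_equal(v$nurses, 0)

  # an assignment that ended before the window does not count
  old <- staff
  old$assign_start <- rep(ts("08:00"), 6)
  old$assign_end <- rep(ts("09:00"), 6)
  expect_equal(compute_variables(six, old, cfg, t0())$mds, 0)
})

test_that("priority means separate current from triage priority", {
  cfg <- test_cfg()
  raised <- make_visit("p", arrival = ts("10:00"), departure = ts("13:00"),
                       triage_priority = 3L, current_priority = 2L)
  v <- compute_variables(raised, empty_staff(), cfg, t0())
  expect_equal(v$priority, 2)
  expect_equal(v$triage_priority, 3)
  expect_equal(v$high_priority, 1)
})

test_that("stay, boarding and unseen variables follow their definitions", {
  cfg <- test_cfg(ed_beds = 10, hospital_beds = 100)
  visits <- bind_visits(
    # departs inside the window after a 3 h stay
    make_visit("a", arrival = ts("08:30"), departure = ts("11:30"),
               first_md_contact = ts("09:00")),
    # boarding: admission decision before the window, still present
    make_visit("b", arrival = ts("07:00"), departure = ts("13:00"),
               first_md_contact = ts("07:30"), admit_decision = ts("10:00")),
    # never seen, still present
    make_visit("c", arrival = ts("11:20"))
  )
  v <- compute_variables(visits, empty_staff(), cfg, t0())
  expect_equal(v$average_time, 3)
  expect_equal(v$admit_index, 1 / 100)
  expect_equal(v$unseen, 1 / 10)
  # longest elapsed stay at the window end: patient b, 07:00 -> 12:00
  expect_equal(v$longest_stay, 5)
  expect_equal(v$average_volume, 3 / cfg$avg_daily_visits)
  expect_equal(v$occupancy_rate, v$occupancy)

  none_departing <- make_visit("d", arrival = ts("11:00"))
  expect_equal(compute_variables(none_departing, empty_staff(), cfg,
                                 t0())$average_time, 0)
})

test_that("an empty window yields the zero variable vector", {
  v <- compute_variables(empty_visits(), empty_staff(), test_cfg(), t0())
  expect_true(all(as.matrix(v[seal_variable_names()]) == 0))
})

test_that("all variables are invariant to k-fold replication with scaled denominators", {
  visits <- random_visits(50, seed = 3)
  staff <- tibble::tibble(
    visit_id = visits$visit_id,
    staff_id = paste0("s", rep(1:5, 10)),
    role = rep(c("md", "nurse"), 25),
    assign_start = visits$arrival, assign_end = visits$departure
  )
  cfg <- test_cfg(ed_beds = 20, hospital_beds = 400, avg_daily_visits = 50)
  base <- compute_variables(visits, staff, cfg, ts("13:00"))
  for (k in c(2L, 3L, 5L)) {
    reps <- lapply(seq_len(k), function(r) {
      v <- visits
      v$visit_id <- paste0(v$visit_id, "_", r)
      s <- staff
      s$visit_id <- paste0(s$visit_id, "_", r)
      s$staff_id <- paste0(s$staff_id, "_", r)
      list(v = v, s = s)
    })
    big_visits <- dplyr::bind_rows(lapply(reps, `[[`, "v"))
    big_staff <- dplyr::bind_rows(lapply(reps, `[[`, "s"))
    big_cfg <- test_cfg(ed_beds = 20 * k, hospital_beds = 400 * k,
                        avg_daily_visits = 50 * k)
    big <- compute_variables(big_visits, big_staff, big_cfg, ts("13:00"))
    expect_equal(big, base, tolerance = 1e-12)
  }
})

test_that("variables satisfy their range invariants on random logs", {
  cfg <- test_cfg(ed_beds = 8, avg_daily_visits = 30)
  for (seed in 1:5) {
    visits <- random_visits(40, seed = seed)
    v <- compute_variables(visits, empty_staff(), cfg, ts("15:00"))
    vals <- as.numeric(as.matrix(v[seal_variable_names()]))
    expect_true(all(vals >= 0))
    expect_lte(v$high_priority, 1)
    expect_lte(v$unseen, v$occupancy)
    # presence overlap is capped at the window length per patient
    expect_lte(v$patient_hours, v$occupancy * cfg$ed_beds / cfg$avg_daily_visits)
  }
})

test_that("interval arithmetic agrees with the minute-grid oracle", {
  cfg <- test_cfg(avg_daily_visits = 25)
  for (seed in 1:8) {
    visits <- random_visits(30, seed = seed + 100)
    t <- ts("14:00")
    w <- window_of(t)
    inw <- patients_in_window(visits, w)
    oracle <- minute_oracle(inw, w)
    v <- compute_variables(visits, empty_staff(), cfg, t)
    expect_equal(v$patient_hours, sum(oracle$presence) / 25,
                 tolerance = nrow(inw) / 60 + 1e-9)
    expected_wait <- if (nrow(inw)) sum(oracle$waiting) / nrow(inw) else 0
    expect_equal(v$awaiting_md, expected_wait, tolerance = 1 / 60)
  }
})

test_that("variable series round-trips through the delimited writer", {
  cfg <- test_cfg()
  visits <- random_visits(30, seed = 77)
  times <- ts(c("10:00", "12:00", "14:00"))
  vars <- variable_series(visits, empty_staff(), cfg, times)
  path <- withr::local_tempfile(fileext = ".csv")
  write_variables(vars, path)
  back <- read_variables(path)
  expect_equal(back, vars, tolerance = 1e-12)
})
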