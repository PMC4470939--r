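#' Parameters of the synthetic ED simulator
#'
#' Controls the discrete-event generator of ED visit streams. Defaults
#' emulate a mid-size Swedish ED: a diurnal arrival curve (night trough,
#' late-morning-to-afternoon plateau), a RETTS acuity mix centred on
#' priority 3, log-normal door-to-physician and length-of-stay times that
#' lengthen with acuity, and a boarding interval for admitted patients.
#'
#' @param arrival_rate mean arrivals per hour, or `NULL` to derive it from
#'   the ED configuration (`avg_daily_visits / 24`).
#' @param diurnal 24 non-negative multipliers of the hourly arrival rate
#'   (hour 0 to 23); internally normalized to mean 1 so `arrival_rate`
#'   stays the daily mean.
#' @param priority_probs probabilities of RETTS priorities 1-5 (sum 1).
#' @param md_wait_meanlog,md_wait_sdlog log-normal door-to-physician time,
#'   hours.
#' @param los_meanlog,los_sdlog log-normal pre-decision length of stay,
#'   hours; `los_meanlog` has one value per priority (most acute stay
#'   longest).
#' @param admit_prob probability a visit ends in an admission decision.
#' @param boarding_meanlog,boarding_sdlog log-normal boarding time (from
#'   admission decision to departure), hours.
#' @param n_mds,n_nurses physician and nurse pool sizes; each visit is
#'   assigned one of each, round-robin, for its whole stay.
#' @param noise_sd rater noise standard deviation in score units (used by
#'   [simulate_assessments()]).
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(arrival_rate = NULL,
                       diurnal = c(0.5, 0.4, 0.35, 0.3, 0.3, 0.35,
                                   0.5, 0.8, 1.2, 1.5, 1.6, 1.6,
                                   1.5, 1.5, 1.4, 1.4, 1.3, 1.3,
                                   1.2, 1.1, 1.0, 0.9, 0.8, 0.7),
                       priority_probs = c(0.05, 0.20, 0.35, 0.25, 0.15),
                       md_wait_meanlog = log(0.6), md_wait_sdlog = 0.6,
                       los_meanlog = log(c(4.0, 3.4, 2.5, 1.8, 1.2)),
                       los_sdlog = 0.5,
                       admit_prob = 0.30,
                       boarding_meanlog = log(1.5), boarding_sdlog = 0.6,
                       n_mds = 8, n_nurses = 12,
                       noise_sd = 0.5) {
  stopifnot(length(diurnal) == 24, all(diurnal >= 0), any(diurnal > 0),
            length(priority_probs) == 5, all(priority_probs >= 0),
            abs(sum(priority_probs) - 1) < 1e-8,
            length(los_meanlog) == 5,
            md_wait_sdlog > 0, los_sdlog > 0, boarding_sdlog > 0,
            admit_prob >= 0, admit_prob <= 1,
            n_mds >= 1, n_nurses >= 1, noise_sd >= 0)
  if (!is.null(arrival_rate)) stopifnot(arrival_rate > 0)
  structure(list(arrival_rate = arrival_rate,
                 diurnal = diurnal / mean(diurnal),
                 priority_probs = priority_probs,
                 md_wait_meanlog = md_wait_meanlog,
                 md_wait_sdlog = md_wait_sdlog,
                 los_meanlog = los_meanlog, los_sdlog = los_sdlog,
                 admit_prob = admit_prob,
                 boarding_meanlog = boarding_meanlog,
                 boarding_sdlog = boarding_sdlog,
                 n_mds = n_mds, n_nurses = n_nurses,
                 noise_sd = noise_sd),
            class = "sim_params")
}

#' Simulate an ED event log with staff assignments
#'
#' Generates a nonhomogeneous Poisson visit stream by thinning against the
#' diurnal profile, then draws per visit: RETTS priority, door-to-physician
#' delay (a delay longer than the stay leaves the patient never seen),
#' priority-dependent length of stay, and for admitted visits an admission
#' decision followed by a boarding interval before departure. One physician
#' and one nurse from fixed pools are assigned round-robin for the whole
#' stay. All timestamps are at minute resolution; the same seed reproduces
#' the log exactly.
#'
#' @param cfg an [ed_config()].
#' @param params a [sim_params()].
#' @param hours simulated duration in hours.
#' @param seed integer seed (reproducibility); `NULL` uses the current RNG
#'   state.
#' @param start `POSIXct` start of the simulation (default
#'   2013-03-11 00:00).
#' @return a list with validated tibbles `visits` and `staff`.
#' @examples
#' sim <- simulate_ed_log(study_ed_configs("D"), sim_params(), 24, seed = 1)
#' nrow(sim$visits)
#' @export
simulate_ed_log <- function(cfg, params = sim_params(), hours,
                            seed = NULL,
                            start = parse_ts("2013-03-11T00:00")) {
  stopifnot(inherits(cfg, "ed_config"), inherits(params, "sim_params"),
            hours > 0)
  run <- function() .simulate_ed_log(cfg, params, hours, start)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.simulate_ed_log <- function(cfg, params, hours, start) {
  rate <- params$arrival_rate %||% (cfg$avg_daily_visits / 24)
  rate_max <- rate * max(params$diurnal)
  n_cand <- stats::rpois(1, rate_max * hours)
  cand <- sort(runif(n_cand) * hours)
  keep_p <- params$diurnal[(floor(cand) %% 24) + 1L] / max(params$diurnal)
  arr_h <- cand[runif(n_cand) < keep_p]
  n <- length(arr_h)
  if (n == 0L) return(list(visits = empty_visits(), staff = empty_staff()))

  priority <- sample.int(5L, n, replace = TRUE, prob = params$priority_probs)
  wait_h <- stats::rlnorm(n, params$md_wait_meanlog, params$md_wait_sdlog)
  los_h <- stats::rlnorm(n, params$los_meanlog[priority], params$los_sdlog)
  admitted <- runif(n) < params$admit_prob
  boarding_h <- ifelse(admitted,
                       stats::rlnorm(n, params$boarding_meanlog,
                                     params$boarding_sdlog), 0)

  arr_min <- round(arr_h * 60)
  total_min <- pmax(1, round((los_h + boarding_h) * 60))
  admit_min <- pmin(round(los_h * 60), total_min)
  contact_min <- round(wait_h * 60)

  arrival <- start + 60 * arr_min
  departure <- arrival + 60 * total_min
  first_md <- arrival + 60 * contact_min
  first_md[contact_min > total_min] <- NA       # never seen before leaving
  admit_decision <- arrival + 60 * admit_min
  admit_decision[!admitted] <- NA

  visits <- tibble(
    visit_id = sprintf("%s-%05d", cfg$ed_id, seq_len(n)),
    arrival = arrival, departure = departure, registration = arrival,
    triage_priority = priority, current_priority = priority,
    first_md_contact = first_md, admit_decision = admit_decision
  )
  staff <- dplyr::bind_rows(
    tibble(visit_id = visits$visit_id,
           staff_id = sprintf("%s-md%02d", cfg$ed_id,
                              (seq_len(n) - 1L) %% params$n_mds + 1L),
           role = "md", assign_start = arrival, assign_end = departure),
    tibble(visit_id = visits$visit_id,
           staff_id = sprintf("%s-rn%02d", cfg$ed_id,
                              (seq_len(n) - 1L) %% params$n_nurses + 1L),
           role = "nurse", assign_start = arrival, assign_end = departure)
  )
  list(visits = validate_visits(visits), staff = validate_staff(staff))
}

#' Simulate noisy workload assessments with known ground truth
#'
#' For each time point the clip-free value of `truth_model` on the computed
#' variables is the ground truth; each rater reports truth plus Gaussian
#' noise, optionally rounded to the nearest integer and clamped to the 1-6
#' scale (as on the paper questionnaire). `mode = "head"` produces one head
#' nurse and one head physician per time point (the derivation design);
#' `mode = "all"` produces `n_nurses` + `n_mds` raters with the first of
#' each role flagged as head staff (the validation design).
#'
#' @inheritParams compute_variables
#' @param times `POSIXct` assessment times.
#' @param truth_model the generating [seal_model()] (default the published
#'   model); its clip flag is ignored — truth is always the raw affine
#'   value.
#' @param noise_sd rater noise SD in score units; 0 gives truth exactly.
#' @param mode `"head"` or `"all"`.
#' @param n_nurses,n_mds raters per role in `"all"` mode.
#' @param rounding round and clamp rater scores to integers 1-6.
#' @param seed integer seed.
#' @return a tibble `time, ed_id, role, is_head, score`, with the
#'   ground-truth series attached as `attr(, "truth")`
#'   (tibble `time, truth`).
#' @export
simulate_assessments <- function(visits, staff, cfg, times,
                                 truth_model = seal_2013(),
                                 noise_sd = 0.5,
                                 mode = c("head", "all"),
                                 n_nurses = 6, n_mds = 5,
                                 rounding = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  raw_model <- truth_model
  raw_model$clip <- FALSE
  truth <- seal_score(variable_series(visits, staff, cfg, times), raw_model)

  raters <- if (mode == "head") {
    tibble(role = c("nurse", "md"), is_head = c(TRUE, TRUE))
  } else {
    tibble(role = c(rep("nurse", n_nurses), rep("md", n_mds)),
           is_head = c(TRUE, rep(FALSE, n_nurses - 1L),
                       TRUE, rep(FALSE, n_mds - 1L)))
  }
  k <- nrow(raters)
  draw <- function() rnorm(length(times) * k, sd = noise_sd)
  eps <- if (noise_sd == 0) {
    rep(0, length(times) * k)
  } else if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  out <- tibble(
    time = rep(times, each = k),
    ed_id = cfg$ed_id,
    role = rep(raters$role, length(times)),
    is_head = rep(raters$is_head, length(times)),
    score = rep(truth, each = k) + eps
  )
  if (rounding) out$score <- pmin(pmax(round(out$score), 1), 6)
  attr(out, "truth") <- tibble(time = times, truth = truth)
  out
}

#' Sample independent variable vectors over plausible ranges
#'
#' Draws uniform, independent values of the four model variables (and
#' optionally all fourteen), bypassing the event simulator so the design
#' matrix is well conditioned — the sampler used for coefficient-recovery
#' experiments.
#'
#' @param n number of vectors.
#' @param ranges named list of `c(min, max)` ranges; defaults cover the
#'   plausible operating ranges of the four model variables
#'   (patient_hours 0-0.3, high_priority 0-0.5, awaiting_md 0-1,
#'   occupancy 0-1.5).
#' @param seed integer seed.
#' @return a tibble with one column per range, `n` rows.
#' @export
sample_variable_vectors <- function(n,
                                    ranges = list(
                                      patient_hours = c(0, 0.3),
                                      high_priority = c(0, 0.5),
                                      awaiting_md = c(0, 1),
                                      occupancy = c(0, 1.5)),
                                    seed = NULL) {
  unknown <- setdiff(names(ranges), seal_variable_names())
  if (length(unknown)) {
    abort(sprintf("unknown variable name(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  draw <- function() {
    as_tibble(lapply(ranges, function(r) runif(n, r[1], r[2])))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
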