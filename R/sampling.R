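#' Generate the randomized assessment schedule
#'
#' Samples `n` distinct (day, slot) pairs without replacement from the
#' collection period. In derivation mode the daily slots are 04:00, 08:00,
#' 12:00, 16:00, 20:00 and 24:00 (materialized as 00:00 of the following
#' day), with the two night slots (04:00 and 24:00) at half the sampling
#' weight of the others, since workload is generally lower at night and
#' night assessments are harder to collect. Validation mode drops 04:00 and
#' replaces 24:00 with 23:00.
#'
#' With the default weighted mode the half frequency holds in expectation
#' (normalized slot probabilities 0.1, 0.2, 0.2, 0.2, 0.2, 0.1 in
#' derivation mode); `quota = TRUE` instead fixes the per-slot counts at
#' the rounded expectations and randomizes only the days.
#'
#' @param period_start,period_end first and last day of the collection
#'   period (`Date` or `YYYY-MM-DD` strings); the period must span at least
#'   one day.
#' @param n number of assessment time points to draw (default 50 per ED).
#' @param mode `"derivation"` (six slots, weighted nights) or
#'   `"validation"` (five slots, equal weights).
#' @param night_weight relative weight of the 04:00 and 24:00 slots
#'   (derivation mode; default 0.5).
#' @param quota use fixed per-slot counts instead of weighted sampling.
#' @param seed integer seed; the same seed yields the same schedule.
#' @return a tibble with columns `time` (`POSIXct`, sorted) and `slot`
#'   (the slot label, `"04:00"` ... `"24:00"`).
#' @examples
#' generate_schedule("2013-03-11", "2013-03-31", n = 50, seed = 1)
#' @export
generate_schedule <- function(period_start, period_end, n = 50,
                              mode = c("derivation", "validation"),
                              night_weight = 0.5, quota = FALSE,
                              seed = NULL) {
  mode <- match.arg(mode)
  start <- as.Date(period_start)
  end <- as.Date(period_end)
  if (is.na(start) || is.na(end) || end < start) {
    abort("collection period must span at least one day")
  }
  slots <- schedule_slots(mode, night_weight)
  days <- seq(start, end, by = "day")
  supply <- tidyr_expand(days, slots)
  if (n > nrow(supply)) {
    abort(sprintf("n = %d exceeds the %d available (day, slot) pairs",
                  n, nrow(supply)))
  }
  pick <- function() {
    if (quota) {
      idx <- integer(0)
      counts <- quota_counts(n, setNames(slots$weight, slots$slot))
      for (s in names(counts)) {
        rows <- which(supply$slot == s)
        if (counts[[s]] > length(rows)) {
          abort(sprintf("quota for slot %s exceeds its day supply", s))
        }
        idx <- c(idx, sample(rows, counts[[s]]))
      }
      idx
    } else {
      sample.int(nrow(supply), n, prob = supply$weight)
    }
  }
  idx <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  out <- supply[sort(idx), c("time", "slot")]
  arrange(out, .data$time)
}

# slot table for a mode: label, hour offset from the day's 00:00, weight
schedule_slots <- function(mode, night_weight) {
  if (mode == "derivation") {
    tibble(slot = c("04:00", "08:00", "12:00", "16:00", "20:00", "24:00"),
           hour = c(4, 8, 12, 16, 20, 24),
           weight = c(night_weight, 1, 1, 1, 1, night_weight))
  } else {
    tibble(slot = c("08:00", "12:00", "16:00", "20:00", "23:00"),
           hour = c(8, 12, 16, 20, 23),
           weight = rep(1, 5))
  }
}

# all (day, slot) pairs with materialized timestamps
tidyr_expand <- function(days, slots) {
  grid <- expand.grid(day = days, i = seq_len(nrow(slots)))
  tibble(
    day = grid$day,
    slot = slots$slot[grid$i],
    weight = slots$weight[grid$i],
    time = as.POSIXct(as.character(grid$day), tz = "UTC") +
      .HOUR * slots$hour[grid$i]
  )
}

# largest-remainder apportionment of n over the normalized slot weights
quota_counts <- function(n, weights) {
  p <- weights / sum(weights)
  raw <- n * p
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Normalized slot sampling probabilities
#'
#' @inheritParams generate_schedule
#' @return named numeric vector summing to 1 (derivation default:
#'   0.1, 0.2, 0.2, 0.2, 0.2, 0.1).
#' @export
slot_probabilities <- function(mode = c("derivation", "validation"),
                               night_weight = 0.5) {
  mode <- match.arg(mode)
  slots <- schedule_slots(mode, night_weight)
  setNames(slots$weight / sum(slots$weight), slots$slot)
}
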