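# Minute-epoch sleep/wake scoring.
#
# Each minute receives a linear score over a seven-minute activity window
# (four minutes back, the current minute, two minutes forward):
#   S = 0.0033 * (1.06 an4 + 0.54 an3 + 0.58 an2 + 0.76 an1 +
#                 2.30 a0  + 0.74 a1  + 0.67 a2)
# and is labeled sleep when S < 1. Webster-style rescoring then removes
# spurious sleep calls adjacent to long wake bouts.

score_weights <- c(1.06, 0.54, 0.58, 0.76, 2.30, 0.74, 0.67)
score_scale <- 0.0033

#' Score one minute from its seven-minute activity window
#'
#' @param window7 seven non-negative activity counts ordered t-4 .. t+2.
#' @return list with `s_value` and `label` ("sleep" iff s_value < 1).
#' @export
score_minute <- function(window7) {
  if (length(window7) != 7) stop("window must contain exactly 7 counts")
  if (any(is.na(window7)) || any(window7 < 0)) {
    stop("activity counts must be non-negative")
  }
  s <- score_scale * sum(score_weights * window7)
  list(s_value = s, label = if (s < 1) "sleep" else "wake")
}

#' Score a minute-epoch series
#'
#' Applies the seven-minute score over a sliding window. The first four and
#' last two minutes lack a full window and are labeled "undefined", as are
#' off-wrist minutes.
#'
#' @param series data.frame with `activity_zcm` and `offwrist` columns (as
#'   written by [generate_night()] / read by [read_epochs()]), or a bare
#'   numeric activity vector.
#' @return character vector of labels ("sleep"/"wake"/"undefined") with the
#'   per-minute score in attribute `s_value`.
#' @export
score_series <- function(series) {
  if (is.data.frame(series)) {
    x <- series$activity_zcm
    offwrist <- series$offwrist
  } else {
    x <- series
    offwrist <- rep(FALSE, length(x))
  }
  n <- length(x)
  if (n < 7) stop("series must contain at least 7 minutes")
  if (any(is.na(x)) || any(x < 0)) stop("activity counts must be non-negative")
  s <- rep(NA_real_, n)
  idx <- 5:(n - 2)
  s[idx] <- score_scale *
    (score_weights[1] * x[idx - 4] + score_weights[2] * x[idx - 3] +
     score_weights[3] * x[idx - 2] + score_weights[4] * x[idx - 1] +
     score_weights[5] * x[idx] + score_weights[6] * x[idx + 1] +
     score_weights[7] * x[idx + 2])
  labels <- ifelse(is.na(s), "undefined", ifelse(s < 1, "sleep", "wake"))
  labels[as.logical(offwrist)] <- "undefined"
  structure(labels, s_value = s)
}

#' Webster-style rescoring rule set
#'
#' After-wake rules rescore the first sleep minutes following a long wake
#' run; bout rules rescore short sleep bouts flanked by long wake runs on
#' both sides.
#'
#' @return list with `after_wake` (data.frame: min_wake_run, rescore_next)
#'   and `bouts` (data.frame: max_bout, min_flank).
#' @export
webster_rules <- function() {
  list(
    after_wake = data.frame(min_wake_run = c(4, 10, 15),
                            rescore_next = c(1, 3, 4)),
    bouts = data.frame(max_bout = c(6, 10), min_flank = c(10, 20))
  )
}

#' Rescore sleep minutes adjacent to long wake bouts
#'
#' Single-pass transformation defined on raw scorer output: all rules are
#' evaluated against the input labels and applied simultaneously. The result
#' carries attribute `rescored = TRUE`, and re-applying the function to an
#' already-rescored vector is a no-op (rescoring is defined relative to raw
#' scores, so a second application has nothing to act on).
#'
#' @param labels labels from [score_series()].
#' @param rules rule set, see [webster_rules()].
#' @param enabled set FALSE to pass labels through unchanged.
#' @return relabeled character vector with attribute `rescored`.
#' @export
rescore_labels <- function(labels, rules = webster_rules(), enabled = TRUE) {
  if (!enabled) return(labels)
  if (isTRUE(attr(labels, "rescored"))) return(labels)
  n <- length(labels)
  r <- rle(as.vector(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mark <- logical(n)
  nr <- length(r$values)
  aw <- rules$after_wake[order(rules$after_wake$min_wake_run), , drop = FALSE]
  for (i in seq_len(nr)) {
    if (r$values[i] == "wake") {
      applicable <- aw$min_wake_run <= r$lengths[i]
      if (any(applicable) && i < nr && r$values[i + 1L] == "sleep") {
        k <- max(aw$rescore_next[applicable])
        k <- min(k, r$lengths[i + 1L])
        mark[starts[i + 1L]:(starts[i + 1L] + k - 1L)] <- TRUE
      }
    } else if (r$values[i] == "sleep" && i > 1L && i < nr &&
               r$values[i - 1L] == "wake" && r$values[i + 1L] == "wake") {
      for (b in seq_len(nrow(rules$bouts))) {
        if (r$lengths[i] <= rules$bouts$max_bout[b] &&
            r$lengths[i - 1L] >= rules$bouts$min_flank[b] &&
            r$lengths[i + 1L] >= rules$bouts$min_flank[b]) {
          mark[starts[i]:ends[i]] <- TRUE
        }
      }
    }
  }
  out <- as.vector(labels)
  out[mark] <- "wake"
  structure(out, s_value = attr(labels, "s_value"), rescored = TRUE)
}

#' Detect the nightly sleep period
#'
#' The period runs from the first minute of the first run of at least
#' `min_run` consecutive sleep-labeled worn minutes to the last minute of the
#' last such run. Detection fails (returned as an invalid value, not an
#' error) when no qualifying run exists, when too much of the candidate
#' period is off-wrist, or when mean ambient light inside the period exceeds
#' `light_threshold`. An externally supplied override (e.g. an expert
#' adjustment) bypasses detection.
#'
#' @param labels labels after [rescore_labels()].
#' @param light optional ambient light vector.
#' @param offwrist optional logical off-wrist vector.
#' @param min_run minimum consecutive sleep minutes anchoring the period
#'   (default 20).
#' @param light_threshold invalidate when mean in-period light exceeds this
#'   (default Inf = disabled).
#' @param max_offwrist_frac invalidate when the in-period off-wrist fraction
#'   exceeds this (default 0.2).
#' @param override optional list(start, end) of 1-based epoch indices.
#' @return list(start, end, valid, reason); indices are 1-based and NA when
#'   invalid.
#' @export
detect_sleep_period <- function(labels, light = NULL, offwrist = NULL,
                                min_run = 20, light_threshold = Inf,
                                max_offwrist_frac = 0.2, override = NULL) {
  invalid <- function(reason) list(start = NA_integer_, end = NA_integer_,
                                   valid = FALSE, reason = reason)
  if (!is.null(override)) {
    return(list(start = as.integer(override$start),
                end = as.integer(override$end), valid = TRUE,
                reason = "manual override"))
  }
  worn <- if (is.null(offwrist)) rep(TRUE, length(labels)) else !offwrist
  is_sleep <- as.vector(labels) == "sleep" & worn
  r <- rle(is_sleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= min_run)
  if (!length(qual)) return(invalid(sprintf("no sleep run >= %d", min_run)))
  start <- starts[qual[1]]
  end <- ends[qual[length(qual)]]
  if (!is.null(offwrist) &&
      mean(offwrist[start:end]) > max_offwrist_frac) {
    return(invalid("off-wrist within period"))
  }
  if (!is.null(light) && is.finite(light_threshold) &&
      mean(light[start:end], na.rm = TRUE) > light_threshold) {
    return(invalid("ambient light during period"))
  }
  list(start = start, end = end, valid = TRUE, reason = NA_character_)
}

#' Compute night-level sleep measures from a detected period
#'
#' Sleep start/end are reported in minutes relative to the reference midnight
#' (negative = before midnight); `sleep_end` marks the end of the last sleep
#' minute, so `duration = sleep_end - sleep_start` equals the period length
#' in minutes. Awakenings are maximal non-sleep runs strictly inside the
#' period that are followed by sleep; "undefined" minutes inside the period
#' count as wake. Efficiency is the percentage of in-period minutes labeled
#' sleep.
#'
#' @param labels rescored labels.
#' @param period result of [detect_sleep_period()].
#' @param reference_midnight `POSIXct` midnight the night is referenced to.
#' @param timestamps per-minute `POSIXct` timestamps of the series.
#' @param participant_id,date stamped onto the record.
#' @return one-row data.frame (a night record): participant_id, date,
#'   sleep_start, sleep_end, duration, awakenings, efficiency, valid,
#'   invalid_reason.
#' @export
compute_night_measures <- function(labels, period, reference_midnight,
                                   timestamps, participant_id = NA_character_,
                                   date = as.Date(NA)) {
  if (!isTRUE(period$valid)) {
    return(data.frame(participant_id = participant_id, date = date,
                      sleep_start = NA_real_, sleep_end = NA_real_,
                      duration = NA_real_, awakenings = NA_integer_,
                      efficiency = NA_real_, valid = FALSE,
                      invalid_reason = period$reason %||% NA_character_,
                      stringsAsFactors = FALSE))
  }
  seg <- as.vector(labels)[period$start:period$end]
  is_sleep <- seg == "sleep"  # undefined inside the period counts as wake
  len <- length(seg)
  r <- rle(is_sleep)
  nr <- length(r$values)
  awak <- sum(!r$values[seq_len(nr) > 1L & seq_len(nr) < nr])
  efficiency <- 100 * sum(is_sleep) / len
  start_min <- as.numeric(difftime(timestamps[period$start],
                                   reference_midnight, units = "mins"))
  data.frame(participant_id = participant_id, date = date,
             sleep_start = start_min, sleep_end = start_min + len,
             duration = len, awakenings = as.integer(awak),
             efficiency = efficiency, valid = TRUE,
             invalid_reason = NA_character_, stringsAsFactors = FALSE)
}

#' Age-group sleep norms
#'
#' Recommended nightly duration and sleep start by age group: ages 6-13,
#' 600 min with start 210 min before midnight; 14-17, 540 min / -150 min;
#' 18 and older, 480 min / -90 min.
#'
#' @return data.frame with age_lo, age_hi, recommended_duration,
#'   recommended_start.
#' @export
nsf_norms <- function() {
  data.frame(age_lo = c(6, 14, 18), age_hi = c(13, 17, Inf),
             recommended_duration = c(600, 540, 480),
             recommended_start = c(-210, -150, -90))
}

#' Subtract the age-group norm from a sleep measure
#'
#' @param value observed minutes (duration, or start relative to midnight).
#' @param measure "duration" or "start".
#' @param age participant age in years (>= 6).
#' @param norms norm table, see [nsf_norms()].
#' @return adjusted minutes (observed minus recommended).
#' @export
adjust_for_age <- function(value, measure = c("duration", "start"), age,
                           norms = nsf_norms()) {
  measure <- match.arg(measure)
  if (is.na(age) || age < min(norms$age_lo)) {
    stop("age below the youngest norm group")
  }
  row <- which(age >= norms$age_lo & age <= norms$age_hi)
  if (length(row) != 1) stop("norms must partition ages")
  col <- paste0("recommended_", measure)
  value - norms[[col]][row]
}

#' Score one night end to end
#'
#' Convenience chain: [score_series()] -> [rescore_labels()] ->
#' [detect_sleep_period()] -> [compute_night_measures()].
#'
#' @param night a [generate_night()] result or a list with `series`,
#'   `reference_midnight`, `date`.
#' @param min_run,light_threshold,max_offwrist_frac,rescoring_enabled
#'   detection/rescoring settings.
#' @param override optional list(start, end) manual period override.
#' @return one-row night record (see [compute_night_measures()]).
#' @export
score_night <- function(night, min_run = 20, light_threshold = Inf,
                        max_offwrist_frac = 0.2, rescoring_enabled = TRUE,
                        override = NULL) {
  series <- night$series
  labels <- score_series(series)
  labels <- rescore_labels(labels, enabled = rescoring_enabled)
  period <- detect_sleep_period(labels, light = series$light,
                                offwrist = series$offwrist,
                                min_run = min_run,
                                light_threshold = light_threshold,
                                max_offwrist_frac = max_offwrist_frac,
                                override = override)
  compute_night_measures(labels, period, night$reference_midnight,
                         series$timestamp,
                         participant_id = series$participant_id[1],
                         date = night$date)
}

#' Score every night of a simulated cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @param ... passed to [score_night()].
#' @return nights table (one row per participant-night).
#' @export
score_cohort_nights <- function(cohort, ...) {
  rows <- lapply(cohort$nights, score_night, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
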