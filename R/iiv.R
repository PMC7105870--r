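# Intra-individual variability: aggregate night records into per
# participant-visit windows (mean, sample SD, CV of each sleep measure over
# the 7 days preceding the visit), with the >= 2-night inclusion filter.

#' Select the valid nights in the week preceding a visit
#'
#' The window is half-open: dates in `[visit_date - span_days, visit_date)`,
#' so the visit date itself is excluded.
#'
#' @param nights night-record data.frame with `date` and `valid` columns.
#' @param visit_date calendar `Date` of the visit.
#' @param span_days window length in days (default 7).
#' @return in-window valid nights ordered by date.
#' @export
select_window <- function(nights, visit_date, span_days = 7) {
  visit_date <- as.Date(visit_date)
  keep <- nights$valid & nights$date >= visit_date - span_days &
    nights$date < visit_date
  out <- nights[keep, , drop = FALSE]
  out[order(out$date), , drop = FALSE]
}

#' Mean, sample SD, and CV of a set of nightly values
#'
#' SD uses the n-1 denominator. CV is `sd / |mean|`; when the mean is within
#' `eps` of zero the CV is undefined and returned as NA with `cv_defined =
#' FALSE` (sleep start is signed, so a raw sd/mean could explode or flip
#' sign).
#'
#' @param values numeric vector of length >= 2.
#' @param eps zero-mean guard for the CV denominator.
#' @return list(mean, sd, cv, cv_defined).
#' @export
summarize_measure <- function(values, eps = 1e-9) {
  if (length(values) < 2) {
    stop("at least 2 nights are required to summarize a window")
  }
  m <- mean(values)
  s <- sd(values)
  if (abs(m) < eps) {
    list(mean = m, sd = s, cv = NA_real_, cv_defined = FALSE)
  } else {
    list(mean = m, sd = s, cv = s / abs(m), cv_defined = TRUE)
  }
}

iiv_measures <- c("sleep_start", "duration", "awakenings", "efficiency")

#' Build per participant-visit window summaries
#'
#' For each participant-visit, summarizes the valid nights in the preceding
#' week: mean, SD, and CV of sleep start, age-adjusted duration, awakenings,
#' and efficiency. Duration is adjusted per-night by the age-group norm
#' before summarizing (a constant offset within an age group, so SD and CV of
#' duration refer to the raw nightly spread); sleep start is left raw by
#' default (`adjust_start = TRUE` applies the start norm the same way).
#' Windows with fewer than `min_nights` nights are returned with `included =
#' FALSE` and NA statistics.
#'
#' @param nights nights table (see [compute_night_measures()]).
#' @param visits data.frame with participant_id, visit, visit_date.
#' @param ages named numeric vector of ages by participant_id.
#' @param norms age-norm table, see [nsf_norms()].
#' @param span_days window length (default 7).
#' @param min_nights inclusion filter (default 2).
#' @param adjust_start also age-adjust sleep start (default FALSE).
#' @return data.frame: participant_id, visit, n_nights, included, then
#'   `{measure}_{mean,sd,cv}` for the four measures.
#' @export
build_window_summaries <- function(nights, visits, ages, norms = nsf_norms(),
                                   span_days = 7, min_nights = 2,
                                   adjust_start = FALSE) {
  stat_cols <- as.vector(outer(iiv_measures, c("mean", "sd", "cv"),
                               function(m, s) paste(m, s, sep = "_")))
  rows <- lapply(seq_len(nrow(visits)), function(i) {
    pid <- visits$participant_id[i]
    sub <- nights[nights$participant_id == pid, , drop = FALSE]
    w <- select_window(sub, visits$visit_date[i], span_days)
    base <- data.frame(participant_id = pid, visit = visits$visit[i],
                       n_nights = nrow(w), included = nrow(w) >= min_nights,
                       stringsAsFactors = FALSE)
    stats <- setNames(rep(NA_real_, length(stat_cols)), stat_cols)
    if (base$included) {
      age <- ages[[pid]]
      vals <- list(
        sleep_start = if (adjust_start) {
          vapply(w$sleep_start, adjust_for_age, 0, measure = "start",
                 age = age, norms = norms)
        } else w$sleep_start,
        duration = vapply(w$duration, adjust_for_age, 0,
                          measure = "duration", age = age, norms = norms),
        awakenings = as.numeric(w$awakenings),
        efficiency = w$efficiency)
      for (m in iiv_measures) {
        s <- summarize_measure(vals[[m]])
        stats[paste0(m, "_mean")] <- s$mean
        stats[paste0(m, "_sd")] <- s$sd
        stats[paste0(m, "_cv")] <- s$cv
      }
    }
    cbind(base, as.data.frame(as.list(stats)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
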