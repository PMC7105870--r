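# Synthetic cohort generator: participant profiles, per-participant sleep
# architecture, minute-level actigraphy nights, wear compliance, and
# caregiver scale scores coupled to realized sleep statistics. Every
# generator is deterministic given its seed, and every night carries its
# ground truth so downstream stages can be validated against a known answer.

#' Default population parameters for the synthetic cohort
#'
#' Moments mirror the demographic and actigraphy summaries of a cohort of
#' school-age-to-adult autistic participants wearing a wrist actigraph at
#' night: age strongly right-skewed with mean 14.5 y and SD 7.9 y (minimum 6),
#' IQ composite 99 (19.6), ADOS calibrated severity 7.6 (1.7), 77.7% male;
#' nightly sleep onset averaging 81 min before midnight, duration around
#' 481 min, and roughly 17.5 brief awakenings per night, which together imply
#' a mean sleep efficiency near 91%.
#'
#' @return Nested list of generator parameters; override any element and pass
#'   the result to the generators.
#' @export
cohort_parameters <- function() {
  list(
    profile = list(
      age_min = 6, age_mean = 14.5, age_sd = 7.91,
      iq_mean = 99.0, iq_sd = 19.55, iq_range = c(40, 160),
      male_frac_asd = 0.777, male_frac_td = 0.74,
      ados_mean = 7.59, ados_sd = 1.74, ados_range = c(1, 10)
    ),
    architecture = list(
      bedtime_mean = -81, bedtime_between_sd = 60, bedtime_within_sd = 45,
      duration_mean = 481, duration_between_sd = 55, duration_within_sd = 45,
      awakening_rate_mean = 17.5, awakening_rate_between_sd = 4.5,
      awakening_rate_quality_slope = 3,
      awakening_length_mean = 2.5,
      onset_consolidation = 30, terminal_consolidation = 20
    ),
    activity = list(
      wake_mu = 150, wake_size = 5,      # daytime/evening wear, zero-crossing counts
      awakening_mu = 100, awakening_size = 5,
      sleep_zero_prob = 0.65, sleep_mu = 3
    ),
    light = list(day_meanlog = log(50), day_sdlog = 0.6,
                 night_meanlog = log(0.5), night_sdlog = 0.6),
    abi = list(mean = 2.6, quality_slope = 1.2, noise_sd = 1.5, range = c(0, 7)),
    behavior = list(
      srs2 = list(mean = 75, quality_slope = 5, noise_sd = 8, range = c(30, 90)),
      abc_irritability = list(mean = 12, quality_slope = 3, noise_sd = 6, range = c(0, 45)),
      abc_hyperactivity = list(mean = 15, quality_slope = 4, noise_sd = 7, range = c(0, 48))
    )
  )
}

#' Default anxiety-score coupling
#'
#' The synthetic anxiety total is a linear function of the caregiver sleep
#' item, the within-window SD of sleep efficiency and the within-window CV of
#' awakenings, plus Gaussian noise, clipped to the instrument range. These
#' three drivers give the prediction protocol a known recovery target.
#'
#' @param intercept,beta_abi_sleep,beta_sd_efficiency,beta_cv_awakenings
#'   regression weights on the anxiety scale.
#' @param noise_sd residual standard deviation (score points, >= 0).
#' @param scale_ranges named list of min/max per instrument.
#' @return A `scale_coupling` list.
#' @export
scale_coupling <- function(intercept = 8, beta_abi_sleep = 2.5,
                           beta_sd_efficiency = 2, beta_cv_awakenings = 15,
                           noise_sd = 5,
                           scale_ranges = list(
                             casi_anx = c(0, 63), srs2 = c(30, 90),
                             abc_irritability = c(0, 45),
                             abc_hyperactivity = c(0, 48))) {
  stopifnot(noise_sd >= 0)
  structure(list(intercept = intercept, beta_abi_sleep = beta_abi_sleep,
                 beta_sd_efficiency = beta_sd_efficiency,
                 beta_cv_awakenings = beta_cv_awakenings,
                 noise_sd = noise_sd, scale_ranges = scale_ranges),
            class = "scale_coupling")
}

clip <- function(x, range) pmin(pmax(x, range[1]), range[2])

#' Generate participant profiles
#'
#' Ages are drawn from a shifted gamma (right-skewed, minimum `age_min`),
#' IQ and ADOS severity from rounded clipped normals, sex from group-specific
#' Bernoulli male fractions. ADOS severity is present only in the ASD group.
#'
#' @param n_asd,n_td non-negative participant counts.
#' @param seed integer seed; identical calls are byte-identical.
#' @param params see [cohort_parameters()].
#' @return data.frame with participant_id, group, age, sex, iq, ados_css.
#' @export
generate_profiles <- function(n_asd, n_td, seed, params = cohort_parameters()) {
  if (n_asd < 0 || n_td < 0) stop("participant counts must be non-negative")
  pp <- params$profile
  n <- n_asd + n_td
  empty <- data.frame(participant_id = character(), group = character(),
                      age = integer(), sex = character(), iq = integer(),
                      ados_css = integer(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  with_seed(seed, {
    group <- c(rep("ASD", n_asd), rep("TD", n_td))
    id <- c(sprintf("ASD%04d", seq_len(n_asd)), sprintf("TD%04d", seq_len(n_td)))
    m <- pp$age_mean - pp$age_min
    shape <- (m / pp$age_sd)^2
    age <- pp$age_min + round(rgamma(n, shape = shape, scale = pp$age_sd^2 / m))
    male_frac <- ifelse(group == "ASD", pp$male_frac_asd, pp$male_frac_td)
    sex <- ifelse(rbinom(n, 1, male_frac) == 1, "male", "female")
    iq <- as.integer(clip(round(rnorm(n, pp$iq_mean, pp$iq_sd)), pp$iq_range))
    ados <- ifelse(group == "ASD",
                   as.integer(clip(round(rnorm(n, pp$ados_mean, pp$ados_sd)),
                                   pp$ados_range)),
                   NA_integer_)
    data.frame(participant_id = id, group = group, age = as.integer(age),
               sex = sex, iq = iq, ados_css = as.integer(ados),
               stringsAsFactors = FALSE)
  })
}

#' Sample a per-participant sleep architecture
#'
#' Draws participant-level mean bedtime, mean duration and awakening rate
#' around the population means, together with the latent sleep-quality scalar
#' that shifts the awakening rate and (via [generate_scales()]) the
#' non-anxiety behavior scales.
#'
#' @param seed integer seed.
#' @param params see [cohort_parameters()].
#' @return A `sleep_architecture` list.
#' @export
sample_architecture <- function(seed, params = cohort_parameters()) {
  ap <- params$architecture
  with_seed(seed, {
    lq <- rnorm(1)
    arch <- list(
      mean_bedtime = rnorm(1, ap$bedtime_mean, ap$bedtime_between_sd),
      bedtime_sd = ap$bedtime_within_sd,
      mean_duration = rnorm(1, ap$duration_mean, ap$duration_between_sd),
      duration_sd = ap$duration_within_sd,
      awakening_rate = max(0.5, rnorm(1, ap$awakening_rate_mean +
                                        ap$awakening_rate_quality_slope * lq,
                                      ap$awakening_rate_between_sd)),
      awakening_length_mean = ap$awakening_length_mean,
      latent_quality = lq
    )
    structure(arch, class = "sleep_architecture")
  })
}

#' Construct a sleep architecture directly
#'
#' @param mean_bedtime minutes relative to midnight (negative = before).
#' @param bedtime_sd,duration_sd night-to-night SDs in minutes (>= 0).
#' @param mean_duration mean nightly sleep duration in minutes (> 0).
#' @param awakening_rate expected wake episodes per night (>= 0).
#' @param awakening_length_mean mean awakening length in minutes (>= 1).
#' @param latent_quality unitless scalar driving scale coupling.
#' @return A `sleep_architecture` list.
#' @export
sleep_architecture <- function(mean_bedtime = -81, bedtime_sd = 45,
                               mean_duration = 481, duration_sd = 45,
                               awakening_rate = 17.5,
                               awakening_length_mean = 2.5,
                               latent_quality = 0) {
  stopifnot(mean_duration > 0, awakening_rate >= 0, bedtime_sd >= 0,
            duration_sd >= 0, awakening_length_mean >= 1)
  structure(list(mean_bedtime = mean_bedtime, bedtime_sd = bedtime_sd,
                 mean_duration = mean_duration, duration_sd = duration_sd,
                 awakening_rate = awakening_rate,
                 awakening_length_mean = awakening_length_mean,
                 latent_quality = latent_quality),
            class = "sleep_architecture")
}

# Draw one night's realized truth (onset, duration, awakening episodes) from
# an architecture. Bedtime/duration are clipped so the sleep interval stays
# inside the 18:00 -> 12:00 recording span. Awakening episodes land
# uniformly inside the interval excluding the consolidated sleep-onset and
# terminal stretches (onset and final waking are consolidated, which is what
# makes them identifiable); placement uses the free-space construction so
# the drawn Poisson count is preserved without overlap.
draw_night_truth <- function(arch, onset_consolidation = 30,
                             terminal_consolidation = 20) {
  bedtime <- round(rnorm(1, arch$mean_bedtime, arch$bedtime_sd))
  bedtime <- clip(bedtime, c(-330, 240))
  duration <- round(rnorm(1, arch$mean_duration, arch$duration_sd))
  duration <- clip(duration, c(120, 690 - bedtime))
  n_awak <- rpois(1, arch$awakening_rate)
  episodes <- data.frame(start = integer(), length = integer())
  win_lo <- bedtime + onset_consolidation
  win_hi <- bedtime + duration - terminal_consolidation
  if (n_awak > 0 && win_hi - win_lo > 4) {
    len <- rgeom(n_awak, prob = 1 / arch$awakening_length_mean) + 1L
    # trim episodes (rarely) if they cannot all fit in the placement window
    while (n_awak > 0 && sum(len[seq_len(n_awak)]) >= win_hi - win_lo - 1) {
      n_awak <- n_awak - 1L
    }
    if (n_awak > 0) {
      len <- len[seq_len(n_awak)]
      free <- (win_hi - win_lo) - sum(len)
      at <- sort(runif(n_awak, 0, free))
      start <- as.integer(round(win_lo + at + cumsum(c(0, len[-n_awak]))))
      episodes <- data.frame(start = start, length = as.integer(len))
    }
  }
  list(sleep_start = bedtime, sleep_end = bedtime + duration,
       duration = duration, episodes = episodes)
}

#' Generate one minute-resolution actigraphy night
#'
#' The recording spans 18:00 on `date` to 12:00 the next day (1080 one-minute
#' epochs). A true sleep interval is drawn from the architecture; awakening
#' episodes are a Poisson count of geometric-length (>= 1 min) bouts placed
#' uniformly inside the interval without overlap. Zero-crossing activity
#' counts are overdispersed negative-binomial draws while awake and
#' zero-inflated low-mean counts while asleep; ambient light is high outside
#' the sleep interval and near zero inside it.
#'
#' @param arch a `sleep_architecture`.
#' @param date calendar `Date` of the evening the night begins.
#' @param seed integer seed.
#' @param participant_id id stamped on the epoch rows.
#' @param params see [cohort_parameters()].
#' @return list with `series` (data.frame: participant_id, timestamp,
#'   activity_zcm, light, offwrist), `truth` (sleep_start/sleep_end/duration
#'   in minutes relative to the reference midnight, plus the episode table),
#'   `date`, and `reference_midnight` (the midnight ending `date`).
#' @export
generate_night <- function(arch, date, seed, participant_id = "P1",
                           params = cohort_parameters()) {
  stopifnot(inherits(arch, "sleep_architecture"))
  date <- as.Date(date)
  act <- params$activity
  lgt <- params$light
  ap <- params$architecture
  with_seed(seed, {
    truth <- draw_night_truth(arch, ap$onset_consolidation,
                              ap$terminal_consolidation)
    ref_midnight <- as.POSIXct(paste(date + 1, "00:00:00"), tz = "UTC")
    minute <- seq(-360L, 719L)  # 18:00 -> 11:59 next day
    n <- length(minute)
    asleep <- minute >= truth$sleep_start & minute < truth$sleep_end
    awakening <- rep(FALSE, n)
    if (nrow(truth$episodes)) {
      for (k in seq_len(nrow(truth$episodes))) {
        e <- truth$episodes[k, ]
        awakening[minute >= e$start & minute < e$start + e$length] <- TRUE
      }
    }
    sleeping <- asleep & !awakening
    activity <- integer(n)
    nw <- sum(!asleep)
    activity[!asleep] <- rnbinom(nw, mu = act$wake_mu, size = act$wake_size)
    na <- sum(awakening)
    activity[awakening] <- rnbinom(na, mu = act$awakening_mu,
                                   size = act$awakening_size)
    ns <- sum(sleeping)
    activity[sleeping] <- ifelse(rbinom(ns, 1, act$sleep_zero_prob) == 1, 0L,
                                 rpois(ns, act$sleep_mu))
    light <- numeric(n)
    light[!asleep] <- rlnorm(nw, lgt$day_meanlog, lgt$day_sdlog)
    light[asleep] <- rlnorm(sum(asleep), lgt$night_meanlog, lgt$night_sdlog)
    series <- data.frame(
      participant_id = participant_id,
      timestamp = ref_midnight + 60 * minute,
      activity_zcm = as.integer(activity),
      light = round(light, 2),
      offwrist = FALSE,
      stringsAsFactors = FALSE
    )
    list(series = series, truth = truth, date = date,
         reference_midnight = ref_midnight)
  })
}

#' Default wear-compliance distribution over nights worn per week
#'
#' Probability of wearing the device 0..7 nights in a visit-preceding week.
#' The 2..7-night mass follows the realized wear pattern of a 139-participant
#' cohort week (21/12/10/9/2/4 participants out of 139); the participants who
#' fell short of two usable nights are split evenly between 0 and 1.
#'
#' @return numeric vector of length 8 (nights 0..7) summing to 1.
#' @export
default_compliance_pattern <- function() {
  c(40.5, 40.5, 21, 12, 10, 9, 2, 4) / 139
}

#' Draw which nights of a week were worn
#'
#' @param n_nights_available nights on offer (typically 7).
#' @param pattern distribution over nights-worn 0..7 (sums to 1).
#' @param seed integer seed.
#' @return sorted integer indices of the worn nights (possibly empty).
#' @export
generate_compliance <- function(n_nights_available,
                                pattern = default_compliance_pattern(),
                                seed = 1) {
  if (length(pattern) != 8 || any(pattern < 0) ||
      abs(sum(pattern) - 1) > 1e-8) {
    stop("pattern must be a distribution over nights-worn 0..7")
  }
  with_seed(seed, {
    worn <- sample(0:7, 1, prob = pattern)
    worn <- min(worn, n_nights_available)
    if (worn == 0) integer(0) else sort(sample.int(n_nights_available, worn))
  })
}

#' Generate caregiver scale scores for one participant-visit
#'
#' The anxiety total is `intercept + b_abi * abi_sleep + b_sdeff *
#' SD(efficiency) + b_cvawk * CV(awakenings) + noise`, where the SD/CV terms
#' come from the realized window summary (what the pipeline can observe), and
#' is clipped to the instrument range. The remaining scales are noisy linear
#' functions of the participant's latent sleep quality.
#'
#' @param profile one-row data.frame from [generate_profiles()].
#' @param realized_window one-row window summary with `efficiency_sd` and
#'   `awakenings_cv` columns (see [build_window_summaries()]).
#' @param abi_sleep ordinal caregiver sleep item for the visit.
#' @param coupling a [scale_coupling()].
#' @param seed integer seed.
#' @param latent_quality participant latent quality (drives non-anxiety
#'   scales).
#' @param params see [cohort_parameters()].
#' @return one-row data.frame: casi_anx, srs2, abc_irritability,
#'   abc_hyperactivity.
#' @export
generate_scales <- function(profile, realized_window, abi_sleep, coupling,
                            seed, latent_quality = 0,
                            params = cohort_parameters()) {
  if (is.null(realized_window) || !nrow(realized_window)) {
    stop("realized window summary is required")
  }
  stopifnot(inherits(coupling, "scale_coupling"))
  with_seed(seed, {
    casi <- coupling$intercept +
      coupling$beta_abi_sleep * abi_sleep +
      coupling$beta_sd_efficiency * realized_window$efficiency_sd +
      coupling$beta_cv_awakenings * realized_window$awakenings_cv +
      rnorm(1, 0, coupling$noise_sd)
    bp <- params$behavior
    one <- function(cfg) {
      clip(cfg$mean + cfg$quality_slope * latent_quality +
             rnorm(1, 0, cfg$noise_sd), cfg$range)
    }
    data.frame(
      casi_anx = clip(casi, coupling$scale_ranges$casi_anx),
      srs2 = round(one(bp$srs2)),
      abc_irritability = round(one(bp$abc_irritability)),
      abc_hyperactivity = round(one(bp$abc_hyperactivity))
    )
  })
}

draw_abi <- function(latent_quality, params, n = 1) {
  ab <- params$abi
  as.integer(clip(round(ab$mean + ab$quality_slope * latent_quality +
                          rnorm(n, 0, ab$noise_sd)), ab$range))
}

#' Simulate a full minute-level cohort
#'
#' Generates profiles, per-participant architectures, worn nights in the week
#' preceding the midpoint (day 28) and endpoint (day 56) visits, minute-level
#' epoch series for each worn night, per-visit caregiver sleep items, and
#' visit scale scores coupled to the realized window statistics of the
#' generated nights. Actigraphy is generated for the ASD group only.
#'
#' @param n_asd,n_td participant counts.
#' @param seed integer seed.
#' @param params see [cohort_parameters()].
#' @param coupling a [scale_coupling()].
#' @param start_date study day 0.
#' @return list: profiles, architectures (named list), visits (data.frame
#'   participant_id/visit/visit_date), nights (named list of
#'   [generate_night()] results), abi (per participant-visit), scales
#'   (per participant-visit), truth_nights (night-level realized truth table).
#' @export
simulate_cohort <- function(n_asd = 139, n_td = 34, seed = 1,
                            params = cohort_parameters(),
                            coupling = scale_coupling(),
                            start_date = as.Date("2016-01-04")) {
  profiles <- generate_profiles(n_asd, n_td, seed, params)
  asd <- profiles[profiles$group == "ASD", , drop = FALSE]
  visit_days <- c(midpoint = 28, endpoint = 56)
  visits <- expand.grid(participant_id = asd$participant_id,
                        visit = names(visit_days),
                        stringsAsFactors = FALSE)
  visits$visit_date <- start_date + visit_days[visits$visit]
  visits <- visits[order(visits$participant_id, visits$visit_date), ]
  architectures <- list()
  nights <- list()
  truth_rows <- list()
  abi_rows <- list()
  for (i in seq_len(nrow(asd))) {
    pid <- asd$participant_id[i]
    pseed <- seed * 1000L + i
    architectures[[pid]] <- sample_architecture(pseed, params)
    lq <- architectures[[pid]]$latent_quality
    abi_pair <- with_seed(pseed + 500L, draw_abi(lq, params, n = 2))
    for (v in seq_along(visit_days)) {
      vname <- names(visit_days)[v]
      vdate <- start_date + visit_days[v]
      worn <- generate_compliance(7, seed = pseed + 10L * v)
      abi_rows[[paste(pid, vname)]] <- data.frame(
        participant_id = pid, visit = vname, abi_sleep = abi_pair[v])
      for (w in worn) {
        ndate <- vdate - 8 + w  # nights [visit-7, visit-1]
        nt <- generate_night(architectures[[pid]], ndate,
                             seed = pseed + 100L * v + w,
                             participant_id = pid, params = params)
        key <- paste(pid, format(ndate))
        nights[[key]] <- nt
        wake_min <- sum(nt$truth$episodes$length)
        truth_rows[[key]] <- data.frame(
          participant_id = pid, date = ndate,
          sleep_start = nt$truth$sleep_start, sleep_end = nt$truth$sleep_end,
          duration = nt$truth$duration,
          awakenings = nrow(nt$truth$episodes),
          efficiency = 100 * (1 - wake_min / nt$truth$duration))
      }
    }
  }
  truth_nights <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  abi <- do.call(rbind, abi_rows)
  rownames(abi) <- NULL
  if (!is.null(truth_nights)) rownames(truth_nights) <- NULL
  cohort <- list(profiles = profiles, architectures = architectures,
                 visits = visits, nights = nights,
                 truth_nights = truth_nights, abi = abi,
                 params = params, coupling = coupling, seed = seed)
  cohort$scales <- cohort_scales(cohort)
  cohort
}

# Scales are coupled to window summaries of the realized (generated) nights,
# not to the latent architecture.
cohort_scales <- function(cohort) {
  tn <- cohort$truth_nights
  if (is.null(tn)) return(NULL)
  tn$valid <- TRUE
  ages <- setNames(cohort$profiles$age, cohort$profiles$participant_id)
  ws <- build_window_summaries(tn, cohort$visits, ages = ages)
  rows <- list()
  for (i in seq_len(nrow(cohort$visits))) {
    pid <- cohort$visits$participant_id[i]
    vname <- cohort$visits$visit[i]
    w <- ws[ws$participant_id == pid & ws$visit == vname, , drop = FALSE]
    if (!nrow(w) || !w$included) next
    abi <- cohort$abi$abi_sleep[cohort$abi$participant_id == pid &
                                  cohort$abi$visit == vname]
    prof <- cohort$profiles[cohort$profiles$participant_id == pid, ]
    sc <- generate_scales(prof, w, abi, cohort$coupling,
                          seed = cohort$seed * 100000L + i,
                          latent_quality =
                            cohort$architectures[[pid]]$latent_quality,
                          params = cohort$params)
    rows[[i]] <- cbind(data.frame(participant_id = pid, visit = vname), sc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a participant-visit feature table directly at night level
#'
#' Fast path for protocol experiments: skips minute-level simulation and draws
#' each worn night's realized start, duration, awakening count, and efficiency
#' straight from the architecture, then computes the window statistics, the
#' caregiver sleep item, and the coupled anxiety score. The result has the
#' same 17-feature layout as [assemble_feature_table()].
#'
#' @param n_participants participants (ASD).
#' @param seed integer seed.
#' @param coupling a [scale_coupling()].
#' @param params see [cohort_parameters()].
#' @param min_nights window inclusion filter (nights, default 2).
#' @return list with `X` (N x 17 numeric matrix), `y` (anxiety),
#'   `participant_id`, and the underlying `windows` data.frame.
#' @export
simulate_feature_table <- function(n_participants = 100, seed = 1,
                                   coupling = scale_coupling(),
                                   params = cohort_parameters(),
                                   min_nights = 2) {
  profiles <- generate_profiles(n_participants, 0, seed, params)
  rows <- list()
  for (i in seq_len(n_participants)) {
    pseed <- seed * 1000L + i
    arch <- sample_architecture(pseed, params)
    lq <- arch$latent_quality
    abi_pair <- with_seed(pseed + 500L, draw_abi(lq, params, n = 2))
    for (v in 1:2) {
      worn <- generate_compliance(7, seed = pseed + 10L * v)
      if (length(worn) < min_nights) next
      nightly <- with_seed(pseed + 100L * v, {
        vals <- lapply(seq_along(worn), function(k) draw_night_truth(arch))
        data.frame(
          sleep_start = vapply(vals, `[[`, 0, "sleep_start"),
          duration = vapply(vals, `[[`, 0, "duration"),
          awakenings = vapply(vals, function(z) nrow(z$episodes), 0),
          efficiency = vapply(vals, function(z)
            100 * (1 - sum(z$episodes$length) / z$duration), 0))
      })
      age <- profiles$age[i]
      nightly$duration_adj <- vapply(nightly$duration, adjust_for_age, 0,
                                     measure = "duration", age = age)
      stat <- function(vals) unlist(summarize_measure(vals)[c("mean", "sd", "cv")])
      feats <- c(
        setNames(stat(nightly$sleep_start),
                 paste0("sleep_start_", c("mean", "sd", "cv"))),
        setNames(stat(nightly$duration_adj),
                 paste0("duration_", c("mean", "sd", "cv"))),
        setNames(stat(nightly$awakenings),
                 paste0("awakenings_", c("mean", "sd", "cv"))),
        setNames(stat(nightly$efficiency),
                 paste0("efficiency_", c("mean", "sd", "cv"))))
      if (any(is.na(feats))) next
      wrow <- data.frame(efficiency_sd = feats[["efficiency_sd"]],
                         awakenings_cv = feats[["awakenings_cv"]])
      sc <- generate_scales(profiles[i, ], wrow, abi_pair[v], coupling,
                            seed = pseed + 900L + v, latent_quality = lq,
                            params = params)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant_id = profiles$participant_id[i],
                   visit = c("midpoint", "endpoint")[v]),
        as.data.frame(as.list(feats)),
        data.frame(abi_sleep = abi_pair[v], age = age,
                   sex = as.integer(profiles$sex[i] == "male"),
                   iq = profiles$iq[i], ados_css = profiles$ados_css[i],
                   casi_anx = sc$casi_anx))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  feat_cols <- setdiff(names(tab), c("participant_id", "visit", "casi_anx"))
  list(X = as.matrix(tab[, feat_cols]), y = tab$casi_anx,
       participant_id = tab$participant_id, windows = tab)
}
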