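# Association analyses: random-intercept mixed models of behavior scales on
# actigraphy statistics with age/sex/IQ covariates, BH false-discovery
# control, covariate-adjusted Spearman correlations, and ASD-vs-TD group
# comparisons.

standardize <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) stop("cannot standardize a constant variable")
  (x - mean(x)) / s
}

#' Mixed-effects association between a behavior scale and one actigraphy
#' statistic
#'
#' Fits `scale ~ actigraphy + age + sex + iq + (1 | participant)` on
#' complete cases after centering and scaling every variable (sex is coded
#' 0/1 first). Inference on the actigraphy fixed effect uses Satterthwaite
#' degrees of freedom. When the random intercept cannot be estimated (e.g.
#' every participant contributes a single visit) the model falls back to
#' ordinary least squares and the result is flagged `degenerate`.
#'
#' @param scale numeric per-visit scale values.
#' @param feature numeric per-visit actigraphy statistic.
#' @param age,sex,iq covariates (sex coded "male"/"female" or 0/1).
#' @param participant participant ids aligning repeated visits.
#' @param scale_name,feature_name labels carried into the result.
#' @return one-row data.frame: scale_name, actigraphy_feature, estimate
#'   (standardized coefficient), p_value, n_obs, n_participants, degenerate.
#' @export
fit_scale_on_actigraphy <- function(scale, feature, age, sex, iq, participant,
                                    scale_name = "scale",
                                    feature_name = "feature") {
  sex_num <- if (is.numeric(sex)) sex else as.integer(sex == "male")
  df <- data.frame(scale = scale, feature = feature, age = age,
                   sex = sex_num, iq = iq,
                   participant = as.character(participant))
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$participant)) < 2) {
    stop("at least 2 participants are required")
  }
  for (v in c("scale", "feature", "age", "sex", "iq")) {
    df[[v]] <- standardize(df[[v]])
  }
  degenerate <- FALSE
  fit <- tryCatch(
    lmerTest::lmer(scale ~ feature + age + sex + iq + (1 | participant),
                   data = df, REML = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) {
    degenerate <- TRUE
    fit <- lm(scale ~ feature + age + sex + iq, data = df)
    co <- summary(fit)$coefficients
    est <- co["feature", "Estimate"]
    p <- co["feature", "Pr(>|t|)"]
  } else {
    co <- summary(fit)$coefficients
    est <- co["feature", "Estimate"]
    p <- co["feature", "Pr(>|t|)"]
  }
  data.frame(scale_name = scale_name, actigraphy_feature = feature_name,
             estimate = unname(est), p_value = unname(p),
             n_obs = nrow(df), n_participants = length(unique(df$participant)),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment within an explicit family
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p_values p-values in \[0, 1\].
#' @param family_label optional label recorded on the result.
#' @return adjusted q-values (same order), attribute `family`.
#' @export
bh_adjust <- function(p_values, family_label = NULL) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  structure(p.adjust(p_values, method = "BH"), family = family_label)
}

#' Run the full scale-by-statistic association grid
#'
#' One mixed-model fit per (behavior scale, actigraphy statistic) pair, with
#' a single BH family spanning the whole grid.
#'
#' @param windows window summaries ([build_window_summaries()]), included
#'   rows only are used.
#' @param scales per participant-visit scale table (columns beyond
#'   participant_id/visit are treated as scales).
#' @param profiles profile table with age, sex, iq.
#' @param fdr reporting threshold recorded on the result (default 0.05).
#' @return tidy data.frame with estimate, p_value, q_value per pair.
#' @export
association_grid <- function(windows, scales, profiles, fdr = 0.05) {
  w <- windows[windows$included, , drop = FALSE]
  dat <- merge(w, scales, by = c("participant_id", "visit"))
  dat <- merge(dat, profiles[, c("participant_id", "age", "sex", "iq")],
               by = "participant_id")
  feat_cols <- as.vector(outer(iiv_measures, c("mean", "sd", "cv"),
                               function(m, s) paste(m, s, sep = "_")))
  scale_cols <- setdiff(colnames(scales), c("participant_id", "visit"))
  rows <- list()
  for (sc in scale_cols) {
    for (fc in feat_cols) {
      rows[[paste(sc, fc)]] <- tryCatch(
        fit_scale_on_actigraphy(
          dat[[sc]], dat[[fc]], dat$age, dat$sex, dat$iq, dat$participant_id,
          scale_name = sc, feature_name = fc),
        error = function(e) data.frame(
          scale_name = sc, actigraphy_feature = fc, estimate = NA_real_,
          p_value = NA_real_, n_obs = 0L, n_participants = 0L,
          degenerate = TRUE, stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- as.vector(bh_adjust(out$p_value[ok],
                                         family_label = "grid"))
  attr(out, "fdr") <- fdr
  out
}

#' Covariate-adjusted Spearman correlation
#'
#' Rank-transforms x, y, and every covariate, residualizes the x and y rank
#' vectors on the covariate ranks by least squares, and reports the Pearson
#' correlation of the residuals with its t-based p-value (df reduced by the
#' number of covariates). With no covariates this reduces to the classical
#' Spearman coefficient.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame of numeric covariates.
#' @param x_name,y_name,timepoint labels carried into the result.
#' @return one-row data.frame: scale_x, scale_y, rho, p_value, n, timepoint.
#' @export
partial_spearman <- function(x, y, covariates = NULL, x_name = "x",
                             y_name = "y", timepoint = NA_character_) {
  df <- data.frame(x = x, y = y)
  k <- 0
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    k <- ncol(covariates)
  }
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < 4) stop("at least 4 complete observations are required")
  if (sd(df$x) == 0 || sd(df$y) == 0) {
    return(data.frame(scale_x = x_name, scale_y = y_name, rho = NA_real_,
                      p_value = NA_real_, n = n, timepoint = timepoint,
                      flagged = "constant input", stringsAsFactors = FALSE))
  }
  rx <- rank(df$x)
  ry <- rank(df$y)
  if (k > 0) {
    Z <- apply(as.matrix(df[, -(1:2), drop = FALSE]), 2, rank)
    rx <- resid(lm(rx ~ Z))
    ry <- resid(lm(ry ~ Z))
  }
  rho <- cor(rx, ry)
  dfree <- n - 2 - k
  tt <- rho * sqrt(dfree / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = dfree)
  data.frame(scale_x = x_name, scale_y = y_name, rho = rho, p_value = p,
             n = n, timepoint = timepoint, flagged = NA_character_,
             stringsAsFactors = FALSE)
}

#' ASD-vs-TD comparison of a scale by linear regression
#'
#' Ordinary least squares of the scale on a group indicator controlling for
#' sex and age.
#'
#' @param scale numeric scale values.
#' @param group factor/character with exactly two non-empty groups; the
#'   second sorted level is the indicator's "1".
#' @param sex,age covariates.
#' @return list(estimate, p_value, n).
#' @export
compare_groups_linear <- function(scale, group, sex, age) {
  sex_num <- if (is.numeric(sex)) sex else as.integer(sex == "male")
  g <- as.character(group)
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("exactly two non-empty groups are required")
  df <- data.frame(scale = scale, g = as.integer(g == lev[2]),
                   sex = sex_num, age = age)
  df <- df[complete.cases(df), , drop = FALSE]
  if (!all(c(0, 1) %in% df$g)) stop("one group is empty after dropping NAs")
  fit <- lm(scale ~ g + sex + age, data = df)
  co <- summary(fit)$coefficients
  list(estimate = unname(co["g", "Estimate"]),
       p_value = unname(co["g", "Pr(>|t|)"]), n = nrow(df))
}

#' Flag more-than-mild caregiver-reported sleep problems
#'
#' @param abi_sleep ordinal sleep-item scores.
#' @param threshold flagging cutoff (default >= 3).
#' @return logical vector.
#' @export
flag_sleep_problem <- function(abi_sleep, threshold = 3) {
  abi_sleep >= threshold
}

#' Chi-squared comparison of flagged proportions between two groups
#'
#' Pearson chi-squared on the 2x2 group-by-flag table, without continuity
#' correction by default.
#'
#' @param flags_group_a,flags_group_b logical flag vectors.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list(statistic, p_value, table).
#' @export
compare_proportions_chisq <- function(flags_group_a, flags_group_b,
                                      correct = FALSE) {
  tab <- rbind(a = c(sum(flags_group_a), sum(!flags_group_a)),
               b = c(sum(flags_group_b), sum(!flags_group_b)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tab)
}
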