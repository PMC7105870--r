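# Orchestration and delimited-text I/O: simulate a cohort to disk, run
# score -> aggregate -> associate -> predict, and write tables, a manifest,
# and a human-readable report.

#' Pipeline configuration
#'
#' Defaults: 7-day visit windows, >= 2-night inclusion, detection run length
#' 20 min, Webster rescoring on, correlation ceiling 0.7, VIF ceiling 10,
#' alpha grid step 0.05, 10 inner folds, 100 inner and 100 outer
#' repetitions, FDR 0.05.
#'
#' @param ... named overrides of any default (nested lists are merged
#'   shallowly).
#' @return config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_asd = 139, n_td = 34,
    window_days = 7, min_nights = 2,
    detection = list(min_run = 20, light_threshold = Inf,
                     max_offwrist_frac = 0.2),
    rescoring = list(enabled = TRUE),
    fdr = 0.05,
    prediction = list(cor_threshold = 0.7, vif_threshold = 10,
                      alpha_step = 0.05, n_inner_folds = 10,
                      n_inner_reps = 100, n_outer_reps = 100,
                      train_fraction = 0.70, lambda_rule = "min_mse")
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

iso_minute <- function(x) format(x, "%Y-%m-%dT%H:%M", tz = "UTC")

#' Write/read minute-epoch series as delimited text
#'
#' Columns: participant_id, timestamp (ISO-8601, minute resolution),
#' activity_zcm, light, offwrist (0/1).
#'
#' @param nights named list of [generate_night()] results, or a single
#'   epoch data.frame.
#' @param path output file.
#' @return `read_epochs()` returns a data.frame with parsed POSIXct
#'   timestamps.
#' @export
write_epochs <- function(nights, path) {
  if (is.data.frame(nights)) {
    df <- nights
  } else {
    df <- do.call(rbind, lapply(nights, `[[`, "series"))
  }
  out <- data.frame(participant_id = df$participant_id,
                    timestamp = iso_minute(df$timestamp),
                    activity_zcm = df$activity_zcm,
                    light = df$light,
                    offwrist = as.integer(df$offwrist))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M",
                             tz = "UTC")
  df$offwrist <- as.logical(df$offwrist)
  df
}

#' Write a delimited results table
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_table <- function(df, path) {
  data.table::fwrite(df, path)
  invisible(path)
}

#' Simulate a cohort to a directory
#'
#' Writes epoch series, profiles, visits, per-visit caregiver sleep items,
#' scale scores, night-level ground truth, and a YAML manifest echoing the
#' configuration and seed.
#'
#' @param dir writable output directory (created if missing).
#' @param config see [pipeline_config()].
#' @param coupling see [scale_coupling()].
#' @return invisibly, the cohort object.
#' @export
simulate_to_dir <- function(dir, config = pipeline_config(),
                            coupling = scale_coupling()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$n_asd, config$n_td, seed = config$seed,
                            coupling = coupling)
  if (length(cohort$nights)) {
    write_epochs(cohort$nights, file.path(dir, "epochs.csv"))
    write_table(cohort$truth_nights, file.path(dir, "truth_nights.csv"))
  } else {
    write_table(data.frame(participant_id = character(),
                           timestamp = character(),
                           activity_zcm = integer(), light = numeric(),
                           offwrist = integer()),
                file.path(dir, "epochs.csv"))
  }
  write_table(cohort$profiles, file.path(dir, "profiles.csv"))
  v <- cohort$visits
  v$visit_date <- format(v$visit_date)
  write_table(v, file.path(dir, "visits.csv"))
  write_table(cohort$abi, file.path(dir, "abi.csv"))
  if (!is.null(cohort$scales)) {
    write_table(cohort$scales, file.path(dir, "scales.csv"))
  }
  manifest <- list(stage = "simulate", seed = config$seed,
                   n_asd = config$n_asd, n_td = config$n_td,
                   coupling = unclass(coupling)[
                     c("intercept", "beta_abi_sleep", "beta_sd_efficiency",
                       "beta_cv_awakenings", "noise_sd")],
                   package_version = as.character(
                     utils::packageVersion("sleepiiv")))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(cohort)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes score -> aggregate -> associate -> predict and (optionally)
#' writes the nights table, window summaries, association grid, importance
#' table, and a plain-text report counting what each stage kept and
#' discarded.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config see [pipeline_config()].
#' @param outdir optional output directory for tables and the report.
#' @return list: nights, windows, associations, feature_table,
#'   preprocessing, protocol, importance, report (character vector).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), outdir = NULL) {
  det <- config$detection
  nights <- score_cohort_nights(cohort, min_run = det$min_run,
                                light_threshold = det$light_threshold,
                                max_offwrist_frac = det$max_offwrist_frac,
                                rescoring_enabled = config$rescoring$enabled)
  ages <- setNames(cohort$profiles$age, cohort$profiles$participant_id)
  windows <- build_window_summaries(nights, cohort$visits, ages = ages,
                                    span_days = config$window_days,
                                    min_nights = config$min_nights)
  associations <- association_grid(windows, cohort$scales, cohort$profiles,
                                   fdr = config$fdr)
  ft <- assemble_feature_table(windows, cohort$abi, cohort$scales,
                               cohort$profiles)
  pp <- preprocess_features(ft$X,
                            cor_threshold = config$prediction$cor_threshold,
                            vif_threshold = config$prediction$vif_threshold)
  pc <- config$prediction
  cfg <- enet_config(alpha_grid = seq(0, 1, by = pc$alpha_step),
                     n_inner_folds = pc$n_inner_folds,
                     n_inner_reps = pc$n_inner_reps,
                     n_outer_reps = pc$n_outer_reps,
                     train_fraction = pc$train_fraction,
                     lambda_rule = pc$lambda_rule, seed = config$seed)
  keep_rows <- ft$participant_id
  protocol <- outer_protocol(pp$X, ft$y, participant_id = keep_rows,
                             config = cfg)
  importance <- feature_importance(protocol)
  report <- c(
    "sleepiiv pipeline report",
    sprintf("nights scored: %d (valid %d, discarded %d)",
            nrow(nights), sum(nights$valid), sum(!nights$valid)),
    sprintf("participant-visit windows: %d (included %d, excluded by <%d-night filter %d)",
            nrow(windows), sum(windows$included), config$min_nights,
            sum(!windows$included)),
    sprintf("association grid: %d models, %d significant at FDR %.2f",
            nrow(associations),
            sum(associations$q_value < config$fdr, na.rm = TRUE),
            config$fdr),
    sprintf("features assembled: %d (rows %d, dropped incomplete %d)",
            ncol(ft$X), nrow(ft$X), ft$n_dropped),
    sprintf("near-zero variance removed: %d (%s)",
            length(pp$removed_nzv),
            if (length(pp$removed_nzv)) paste(pp$removed_nzv, collapse = ", ")
            else "none"),
    sprintf("correlation filter removed: %d (%s)",
            length(pp$removed_cor),
            if (length(pp$removed_cor)) paste(pp$removed_cor, collapse = ", ")
            else "none"),
    sprintf("VIF filter removed: %d; max retained VIF %.2f",
            length(pp$removed_vif), max(pp$vif)),
    sprintf("outer test sets: %d, mean test R^2 %.3f, significant fits %d",
            nrow(protocol$records), mean(protocol$records$r2),
            sum(protocol$records$f_sig)),
    sprintf("top feature: %s (normalized importance %.3f)",
            importance$feature[which.max(importance$normalized)],
            max(importance$normalized)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_table(nights, file.path(outdir, "nights.csv"))
    write_table(windows, file.path(outdir, "windows.csv"))
    write_table(associations, file.path(outdir, "associations.csv"))
    write_table(cbind(s = protocol$records$s, protocol$records[-1]),
                file.path(outdir, "outer_records.csv"))
    write_table(importance, file.path(outdir, "importance.csv"))
    writeLines(report, file.path(outdir, "report.txt"))
    yaml::write_yaml(list(stage = "run", seed = config$seed,
                          config = config[c("window_days", "min_nights",
                                            "fdr")],
                          prediction = config$prediction),
                     file.path(outdir, "manifest.yml"))
  }
  list(nights = nights, windows = windows, associations = associations,
       feature_table = ft, preprocessing = pp, protocol = protocol,
       importance = importance, report = report)
}
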