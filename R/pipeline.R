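#' Full pipeline configuration
#'
#' One bag for every stage's parameters; unknown entries are rejected so a
#' typo in a config file fails loudly before any computation.
#'
#' @param target_rate working sampling rate in samples/s (raw recordings
#'   are resampled to this before event detection).
#' @param wear,ic,step,pendulum,agg,fit stage parameter objects.
#' @param day_seconds day-window length in s (86400 for real days).
#' @param min_wear_hours valid-day wear threshold in equivalent hours.
#' @param default_step prior step duration for the bout gap rule, s.
#' @param seed integer seed recorded in the run manifest.
#' @return list of class `fw_run_config`.
#' @export
run_config <- function(target_rate = 100, wear = wear_params(),
                       ic = ic_params(), step = step_params(),
                       pendulum = pendulum_params(), agg = agg_config(),
                       fit = fit_config(), day_seconds = 86400,
                       min_wear_hours = 18, default_step = 0.7, seed = 1L) {
  structure(list(target_rate = target_rate, wear = wear, ic = ic,
                 step = step, pendulum = pendulum, agg = agg, fit = fit,
                 day_seconds = day_seconds, min_wear_hours = min_wear_hours,
                 default_step = default_step, seed = as.integer(seed)),
            class = "fw_run_config")
}

#' Processing configuration matched to the compressed synthetic week
#'
#' Wear-detection windows are shortened in proportion to the compressed
#' day length so the temperature smoothing does not swallow whole days.
#'
#' @param config the [week_config()] the recording came from.
#' @param ... overrides passed on to [run_config()].
#' @export
week_run_config <- function(config = week_config(), ...) {
  run_config(target_rate = config$rate,
             wear = wear_params(smooth_window_s = 30, min_segment_s = 60,
                                slope_sustain_s = 20),
             day_seconds = config$day_seconds, ...)
}

acc_norm <- function(rec) sqrt(rec$acc_v^2 + rec$acc_ap^2 + rec$acc_ml^2)

#' Run the processing pipeline on one recording
#'
#' Stages: resample to the working rate; wear detection and valid-day
#' classification; step-peak detection on the acceleration norm; candidate
#' bout assembly from step peaks; initial-contact detection within each
#' candidate bout; bout re-assembly from initial contacts; per-step
#' pendulum step lengths; bout summaries; per-subject aggregation.
#'
#' @param rec an `fw_recording`, or a path to the CSV dialect accepted by
#'   [read_recording()].
#' @param config see [run_config()].
#' @param out_dir optional output directory; when given, writes
#'   `bouts.csv`, `days.csv`, `summary.csv` and `manifest.json`.
#' @return list with `bouts` (bout table), `days` (day records), `wear`
#'   (wear intervals) and `summary` (one-row subject summary).
#' @export
run_process <- function(rec, config = run_config(), out_dir = NULL) {
  if (is.character(rec)) rec <- read_recording(rec)
  stopifnot(inherits(rec, "fw_recording"))
  if (rec$rate != config$target_rate)
    rec <- resample_recording(rec, config$target_rate)
  duration <- rec_duration(rec)
  wear <- detect_wear(rec$temperature, rec$temp_rate, config$wear,
                      duration = duration)
  days <- day_wear_summary(wear, rec$start_time, duration,
                           day_seconds = config$day_seconds,
                           min_wear_hours = config$min_wear_hours)
  peaks <- detect_step_peaks(acc_norm(rec), rec$rate, config$step)
  cand <- assemble_bouts(peaks$time, default_step = config$default_step)
  bouts <- bout_table(lapply(cand, function(st) {
    # refine: detect initial contacts inside the candidate window
    pad <- 1.0
    i0 <- max(1L, floor((st[1L] - pad) * rec$rate) + 1L)
    i1 <- min(length(rec$acc_v), ceiling((st[length(st)] + pad) * rec$rate) + 1L)
    if (i1 - i0 < 2L * rec$rate) return(NULL)
    seg <- rec$acc_v[i0:i1]
    ics <- detect_initial_contacts(seg, rec$rate, config$ic)
    if (length(ics) < 2L) return(NULL)
    groups <- assemble_bouts(ics, default_step = config$default_step)
    rows <- lapply(groups, function(g) {
      sl <- estimate_step_lengths(seg, rec$rate, g, config$pendulum)
      off <- (i0 - 1L) / rec$rate
      day <- day_index_of(g[1L] + off, rec$start_time, config$day_seconds)
      summarize_bout(g + off, sl, day_index = min(nrow(days), day))
    })
    do.call(rbind, rows)
  }))
  summary <- build_subject_summary(bouts, days, config$agg)
  summary <- cbind(subject_id = rec$subject_id, summary)
  res <- list(bouts = bouts, days = days, wear = wear, summary = summary)
  if (!is.null(out_dir)) write_process_outputs(res, rec, config, out_dir)
  res
}

# Day index of a time offset, consistent with day_wear_summary: calendar
# days anchor at local midnight, compressed days at the recording start.
day_index_of <- function(t, start_time, day_seconds) {
  off0 <- if (day_seconds == 86400) {
    midnight <- as.POSIXct(format(start_time, "%Y-%m-%d"), tz = "UTC")
    -as.numeric(difftime(start_time, midnight, units = "secs"))
  } else 0
  floor((t - off0) / day_seconds) + 1L
}

bout_table <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), n_steps = integer(0),
                      cadence = numeric(0), mean_step_length = numeric(0),
                      speed = numeric(0), distance = numeric(0),
                      day_index = integer(0)))
  tab <- do.call(rbind, rows)
  tab[order(tab$start), , drop = FALSE]
}

write_process_outputs <- function(res, rec, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bouts_out <- res$bouts
  bouts_out$step_times <- NULL
  bouts_out <- cbind(subject_id = rec$subject_id, bouts_out)
  data.table::fwrite(bouts_out, file.path(out_dir, "bouts.csv"))
  data.table::fwrite(cbind(subject_id = rec$subject_id, res$days),
                     file.path(out_dir, "days.csv"))
  data.table::fwrite(res$summary, file.path(out_dir, "summary.csv"))
  write_manifest(config, out_dir)
  invisible(out_dir)
}

# Reproducibility manifest: config hash, seed, package version.  No
# timestamps, so identical runs produce byte-identical output trees.
write_manifest <- function(config, out_dir) {
  cfg_json <- jsonlite::toJSON(config, force = TRUE, auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(list(config_md5 = hash, seed = config$seed,
                            package = "freewalk",
                            version = as.character(packageVersion("freewalk"))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Fit the gamma power-law models for one metric over a cohort table
#'
#' Fits, separately per sex, the free- and fixed-exponent models of the
#' requested metric on age or reversed SPPB and keeps the AIC-selected
#' one.  Strata with fewer than 10 subjects are skipped with a warning;
#' singleton integer ages are excluded when the covariate is age.
#'
#' @param cohort data.frame (or CSV path) with `sex`, `age`, `sppb` and
#'   metric columns.
#' @param metric metric column name, e.g. `"daily_steps"`.
#' @param covariate `"age"` or `"sppb"`.
#' @param config see [run_config()]; only the `fit` block is used.
#' @param out_dir optional; writes `fit_<metric>_<covariate>.json`, a
#'   percent-change table `pct_<metric>_<covariate>.csv` and a manifest.
#' @return named list of `fw_plgamma_fit` objects (one per fitted sex).
#' @export
run_fit <- function(cohort, metric, covariate = c("age", "sppb"),
                    config = run_config(), out_dir = NULL) {
  covariate <- match.arg(covariate)
  if (is.character(cohort)) cohort <- as.data.frame(data.table::fread(cohort))
  if (!metric %in% names(cohort))
    stop("unknown metric '", metric, "'; available: ",
         paste(setdiff(names(cohort),
                       c("subject_id", "sex", "age", "sppb", "height_cm")),
               collapse = ", "))
  if (covariate == "age") cohort <- exclude_singleton_ages(cohort)
  fits <- list()
  for (s in c("female", "male")) {
    rows <- cohort[cohort$sex == s & !is.na(cohort[[metric]]), , drop = FALSE]
    if (nrow(rows) < 10) {
      warning("stratum '", s, "' has fewer than 10 subjects; skipped")
      next
    }
    x <- transform_covariate(rows[[if (covariate == "age") "age" else "sppb"]],
                             covariate)
    y <- rows[[metric]]
    free <- fit_powerlaw_gamma(x, y, fix_exponent = FALSE, config = config$fit,
                               covariate_kind = covariate)
    fixed <- fit_powerlaw_gamma(x, y, fix_exponent = TRUE, config = config$fit,
                                covariate_kind = covariate)
    fits[[s]] <- select_exponent_model(free, fixed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      lapply(fits, function(f) unclass(f)),
      file.path(out_dir, sprintf("fit_%s_%s.json", metric, covariate)),
      auto_unbox = TRUE, digits = NA)
    data.table::fwrite(percent_change_table(fits, covariate),
                       file.path(out_dir,
                                 sprintf("pct_%s_%s.csv", metric, covariate)))
    write_manifest(config, out_dir)
  }
  fits
}

# Percent-change table at the covariate steps the cohort analyses report:
# ages 70->71, 80->81, 90->91, or SPPB 12->11, 6->5, 1->0.
percent_change_table <- function(fits, covariate) {
  steps <- if (covariate == "age")
    data.frame(from = c(70, 80, 90), to = c(71, 81, 91))
  else data.frame(from = c(12, 6, 1), to = c(11, 5, 0))
  out <- lapply(names(fits), function(s) {
    data.frame(sex = s, from = steps$from, to = steps$to,
               pct_decrease = vapply(seq_len(nrow(steps)), function(i)
                 percent_change(fits[[s]], steps$from[i], steps$to[i]),
                 numeric(1)))
  })
  do.call(rbind, out)
}

#' Export a box plot of a gait metric by age band and sex
#'
#' @param cohort cohort data.frame with `age`, `sex`, `sppb` and the metric.
#' @param metric metric column name.
#' @param file output file (PDF or PNG by extension).
#' @return `file`, invisibly.
#' @export
export_boxplot <- function(cohort, metric, file) {
  g <- assign_groups(cohort$age, cohort$sppb)
  if (grepl("\\.png$", file)) grDevices::png(file, 900, 600)
  else grDevices::pdf(file, 9, 6)
  on.exit(grDevices::dev.off())
  graphics::boxplot(cohort[[metric]] ~ interaction(cohort$sex, g$age_band),
                    las = 2, xlab = "", ylab = metric,
                    col = c("rosybrown2", "steelblue2"))
  invisible(file)
}
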