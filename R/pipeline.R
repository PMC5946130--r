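# Campaign orchestration: one configuration in, one structured report out.

#' Run the full campaign analysis
#'
#' Executes the complete chain on a synthetic scenario (or a pre-generated
#' input bundle): gas and weather generation, frame scoring into an activity
#' series, robust CH4/delta-13C thresholds per channel, coincident peak
#' windows, per-window and pooled Keeling regressions with intercept
#' clustering, weather PCA with sequential-ANOVA regressions of activity,
#' CH4 and delta-13C on the first three PCs, additive decomposition of the
#' activity series, and lagged cross-correlations of activity and tides
#' against the gas series. All randomness flows from the configuration seed;
#' re-running with an identical configuration reproduces the report.
#'
#' @param config a [scenario_config()], or the name of a
#'   [scenario_preset()].
#' @param seed optional seed overriding the configuration's.
#' @param k_mad MAD multiplier for the CH4 threshold (default 2).
#' @param q background/elevated quantile split (default 0.90).
#' @param d13c_mode delta-13C peak rule (`"deviation"` or `"literal"`).
#' @param interval aggregation interval in seconds for regression and
#'   cross-correlation grids (default 300; gas and activity are aggregated
#'   by median per interval).
#' @param max_lag cross-correlation maximum lag in grid samples (default one
#'   day of intervals).
#' @param min_run,min_gap peak-window persistence/merge parameters passed to
#'   [coincident_peaks()].
#' @param frames logical: score a frame sequence into an activity series
#'   (default TRUE; set FALSE to skip the camera chain).
#' @param out_dir optional directory; when given, the report JSON and CSV
#'   side tables are written there.
#' @return an object of class `campaign_report` (a structured list; see
#'   `print` method for a summary).
#' @export
run_campaign <- function(config, seed = NULL, k_mad = 2, q = 0.90,
                         d13c_mode = c("deviation", "literal"),
                         interval = 300, max_lag = NULL,
                         min_run = 30, min_gap = 300,
                         frames = TRUE, out_dir = NULL) {
  d13c_mode <- match.arg(d13c_mode)
  if (is.character(config)) config <- scenario_preset(config, seed = seed)
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(max_lag)) max_lag <- min(86400 / interval,
                                       floor(config$duration / interval / 4))

  gas <- simulate_gas(config)
  weather <- simulate_weather(config)
  tides <- tide_series(config$start, config$start + config$duration,
                       step = interval,
                       constituents = config$tide_constituents)

  nest <- gas[gas$channel == "nest", , drop = FALSE]
  ambient <- gas[gas$channel == "ambient", , drop = FALSE]

  thresholds <- list(
    ch4_nest = mad_threshold(nest$ch4, k = k_mad),
    ch4_ambient = mad_threshold(ambient$ch4, k = k_mad)
  )
  ch4_fl <- flag_ch4_peaks(nest$ch4, thresholds$ch4_nest)
  d13c_fl <- flag_d13c_peaks(nest$d13c, mode = d13c_mode)
  peaks <- coincident_peaks(ch4_fl, d13c_fl, timestamp = nest$timestamp,
                            min_gap = min_gap, min_run = min_run)
  keeling <- keeling_by_peak(peaks, nest$ch4, nest$d13c)
  summary_ch4 <- percentile_summary(nest$ch4, q = q)

  # activity from frames, calibrated against generator truth on a 0-25 scale
  activity <- NULL
  if (frames) {
    fs <- simulate_frames(config)
    # consecutive frames can differ by up to twice the per-frame jitter
    act <- activity_series(fs, max_shift = max(1L, 2L * config$jitter_px))
    truth <- fs$truth$moved_pixels[-1]
    labels <- if (max(truth) > 0) 25 * truth / max(truth) else truth
    cal <- list()
    for (sen in c("day", "night")) {
      sel <- act$sensor == sen
      need <- (if (sen == "day") 1 else 3) + 1
      if (sum(sel) >= need + 2 &&
          length(unique(act$raw_sad[sel])) >= need) {
        cal[[sen]] <- fit_calibration(act$raw_sad[sel], labels[sel],
                                      sensor = sen)
      }
    }
    act$activity <- act$raw_sad
    for (sen in names(cal)) {
      sel <- act$sensor == sen
      act$activity[sel] <- apply_calibration(cal[[sen]], act$raw_sad[sel])
    }
    activity <- act
  }

  # common 5-min (interval) grid
  gas_bins <- aggregate_interval(nest$timestamp, nest$ch4, interval)
  d13c_bins <- aggregate_interval(nest$timestamp, nest$d13c, interval)
  # short campaigns can have constant columns (e.g. no rain fell): drop them
  wvars <- setdiff(names(weather), "timestamp")
  constant <- wvars[vapply(weather[wvars], function(v) sd(v) == 0,
                           logical(1))]
  if (length(constant)) {
    message("constant weather column(s) dropped from PCA: ",
            paste(constant, collapse = ", "))
  }
  pca <- weather_pca(weather[setdiff(names(weather), constant)])
  wt <- as.numeric(weather$timestamp)

  regress_on_pcs <- function(bins) {
    idx <- match(as.numeric(bins$timestamp), wt)
    ok <- !is.na(idx)
    if (sum(ok) <= 4) return(NULL)
    pc_regression_anova(bins$value[ok], pca$scores[idx[ok], , drop = FALSE])
  }
  anova_ch4 <- regress_on_pcs(gas_bins)
  anova_d13c <- regress_on_pcs(d13c_bins)

  anova_activity <- NULL
  decomposition <- NULL
  ccf_activity_ch4 <- NULL
  if (!is.null(activity)) {
    act_bins <- aggregate_interval(activity$timestamp, activity$activity,
                                   interval)
    anova_activity <- regress_on_pcs(act_bins)
    per_day <- as.integer(86400 / interval)
    if (nrow(act_bins) >= 2 * per_day) {
      decomposition <- additive_decompose(act_bins$value, per_day,
                                          trend_method = "polynomial")
    }
    al <- align_series(act_bins$timestamp, act_bins$value,
                       gas_bins$timestamp, gas_bins$value)
    if (length(al$x) - max_lag >= 10) {
      ccf_activity_ch4 <- cross_correlation(al$x, al$y, max_lag = max_lag)
    }
  }

  ccf_tide_ch4 <- tide_gas_ccf(tides, nest, max_lag = max_lag,
                               variable = "ch4", interval = interval)
  ccf_tide_d13c <- tide_gas_ccf(tides, nest, max_lag = max_lag,
                                variable = "d13c", interval = interval)
  ccf_extremum <- function(cc) {
    if (is.null(cc)) return(NULL)
    i <- which.max(abs(cc$r))
    list(lag = cc$lag[i], r = cc$r[i])
  }

  report <- structure(
    list(
      config = config,
      thresholds = thresholds,
      peaks = peaks,
      keeling = keeling,
      summary_ch4 = summary_ch4,
      pca = pca,
      anova = list(activity = anova_activity, ch4 = anova_ch4,
                   d13c = anova_d13c),
      decomposition = decomposition,
      ccf = list(activity_ch4 = ccf_activity_ch4,
                 tide_ch4 = ccf_tide_ch4, tide_d13c = ccf_tide_d13c),
      ccf_extrema = list(activity_ch4 = ccf_extremum(ccf_activity_ch4),
                         tide_ch4 = ccf_extremum(ccf_tide_ch4),
                         tide_d13c = ccf_extremum(ccf_tide_d13c)),
      activity = activity,
      counts = list(nest = nrow(nest), ambient = nrow(ambient),
                    weather = nrow(weather)),
      provenance = list(seed = config$seed,
                        package_version =
                          as.character(utils::packageVersion("antseep")))
    ),
    class = "campaign_report"
  )
  if (!is.null(out_dir)) write_campaign_report(report, out_dir)
  report
}

#' Write a campaign report to disk
#'
#' Serialises the headline numbers to `report.json` and the side tables
#' (peak windows, Keeling fits, percentile summary, PCA loadings) to CSV in
#' `out_dir`.
#'
#' @param report a `campaign_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_campaign_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  head_nums <- list(
    thresholds = report$thresholds,
    n_peak_windows = nrow(report$peaks$windows),
    pooled_intercept = if (!is.null(report$keeling$pooled))
      report$keeling$pooled$intercept else NULL,
    cumulative_variance_3pc =
      report$pca$cumulative_variance[seq_len(min(3,
        length(report$pca$cumulative_variance)))],
    r2 = lapply(Filter(Negate(is.null), report$anova), `[[`, "r2"),
    ccf_extrema = report$ccf_extrema,
    counts = report$counts,
    provenance = report$provenance
  )
  jsonlite::write_json(head_nums, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_series_csv(cbind(report$peaks$windows),
                   file.path(out_dir, "peak_windows.csv"))
  write.csv(report$keeling$per_window,
            file.path(out_dir, "keeling_fits.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$summary_ch4),
            file.path(out_dir, "ch4_summary.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$pca$loadings),
            file.path(out_dir, "pca_loadings.csv"))
  invisible(out_dir)
}

#' @export
print.campaign_report <- function(x, ...) {
  cat("Campaign report\n")
  cat(sprintf("  nest samples: %d; ambient: %d; weather rows: %d\n",
              x$counts$nest, x$counts$ambient, x$counts$weather))
  cat(sprintf("  CH4 thresholds (median + k*MAD): nest %.3f, ambient %.3f ppm\n",
              x$thresholds$ch4_nest, x$thresholds$ch4_ambient))
  cat(sprintf("  coincident peak windows: %d\n", nrow(x$peaks$windows)))
  if (!is.null(x$keeling$pooled)) {
    cat(sprintf("  pooled Keeling intercept: %.1f permil [%.1f, %.1f]\n",
                x$keeling$pooled$intercept, x$keeling$pooled$ci95[1],
                x$keeling$pooled$ci95[2]))
  }
  if (!is.null(x$keeling$clusters)) {
    ctr <- sort(unique(x$keeling$clusters$centre))
    cat("  intercept cluster centres:",
        paste(sprintf("%.1f", ctr), collapse = ", "), "permil\n")
  }
  cv <- x$pca$cumulative_variance
  cat("  weather PCA cumulative variance (3 PCs):",
      paste(round(cv[seq_len(min(3, length(cv)))], 2), collapse = " "), "\n")
  invisible(x)
}
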