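# CH4 / delta-13C anomaly detection and Keeling-plot source attribution.

#' Robust anomaly threshold: median + k * MAD
#'
#' Computes `median(x) + k * median(|x - median(x)|)`. The MAD is raw — no
#' Gaussian consistency constant (1.4826) is applied — which is the literal
#' reading of the "median + 2 MAD" anomaly rule; set `constant = 1.4826` for
#' the scaled convention.
#'
#' @param values numeric series (at least 2 finite values).
#' @param k MAD multiplier (default 2).
#' @param constant multiplier applied to the raw MAD (default 1).
#' @return the threshold, in the units of `values`.
#' @export
mad_threshold <- function(values, k = 2, constant = 1) {
  x <- values[is.finite(values)]
  if (length(x) < 2) {
    stop("need at least 2 finite values", call. = FALSE)
  }
  med <- median(x)
  med + k * constant * median(abs(x - med))
}

#' Flag CH4 peak concentrations
#'
#' Strict exceedance: a sample is a peak when its concentration is greater
#' than (not equal to) the threshold, normally from [mad_threshold()].
#'
#' @param ch4 numeric CH4 series (ppm).
#' @param threshold finite scalar threshold (ppm).
#' @return logical vector.
#' @export
flag_ch4_peaks <- function(ch4, threshold) {
  stop_if_not_scalar_number(threshold, "threshold")
  !is.na(ch4) & ch4 > threshold
}

#' Flag delta-13C-CH4 peak values
#'
#' Two rules are available and must be chosen deliberately:
#' \describe{
#'   \item{`"literal"`}{a sample is a peak when `d13c < low` or `d13c > high`
#'     (defaults -35 / 0 permil). Note that nest-gas series sitting entirely
#'     below -35 permil are then flagged wholesale; the rule is retained for
#'     fidelity to the published wording.}
#'   \item{`"deviation"`}{a sample is a peak when its absolute deviation from
#'     the series median exceeds `k` times the raw MAD — the robust
#'     counterpart of the CH4 rule, and the default used by the pipeline.}
#' }
#'
#' @param d13c numeric delta-13C series (permil VPDB).
#' @param mode `"deviation"` or `"literal"`.
#' @param low,high literal-rule cut-offs (permil).
#' @param k deviation-rule MAD multiplier.
#' @return logical vector.
#' @export
flag_d13c_peaks <- function(d13c, mode = c("deviation", "literal"),
                            low = -35, high = 0, k = 2) {
  mode <- match.arg(mode)
  if (mode == "literal") {
    !is.na(d13c) & (d13c < low | d13c > high)
  } else {
    x <- d13c[is.finite(d13c)]
    if (length(x) < 2) stop("need at least 2 finite values", call. = FALSE)
    med <- median(x)
    madv <- median(abs(x - med))
    !is.na(d13c) & abs(d13c - med) > k * madv
  }
}

#' Coincident CH4 / delta-13C peak windows
#'
#' True anomalies must appear in both the concentration and the isotope
#' series at the same time. This builds maximal runs of jointly flagged
#' samples, keeps those that persist for at least `min_run` samples, and
#' merges qualifying runs separated by less than `min_gap` seconds into one
#' window. The persistence requirement (`min_run`) is what separates genuine
#' degassing episodes from chance coincidences of measurement noise, whose
#' per-sample rate is fixed by the flagging quantile regardless of the noise
#' level; filtering before merging also keeps window boundaries on the
#' episode itself instead of chaining through isolated noise flags nearby.
#'
#' @param ch4_flags,d13c_flags aligned logical vectors (e.g. from
#'   [flag_ch4_peaks()] / [flag_d13c_peaks()]).
#' @param timestamp optional POSIXct/numeric sample times; defaults to a
#'   1-second grid.
#' @param tolerance coincidence tolerance in seconds: each flag series is
#'   dilated by this much before intersecting (default 0, exact
#'   simultaneity).
#' @param min_gap qualifying runs closer than this many seconds are merged
#'   into one window (default 300).
#' @param min_run minimum persistence, in samples, of a joint run
#'   (default 30).
#' @return an object of class `peak_set`: a list with `windows` (data.frame
#'   `start`, `end`, `n`, `n_ch4`, `n_d13c`, `rule`) and `samples` (list of
#'   index vectors of jointly flagged samples per window).
#' @export
coincident_peaks <- function(ch4_flags, d13c_flags, timestamp = NULL,
                             tolerance = 0, min_gap = 300, min_run = 30) {
  n <- length(ch4_flags)
  if (length(d13c_flags) != n) {
    stop("flag series must be aligned (same length)", call. = FALSE)
  }
  if (is.null(timestamp)) timestamp <- seq_len(n)
  secs <- as.numeric(timestamp)
  dt <- if (n > 1) median(diff(secs)) else 1

  dilate <- function(f, w) {
    if (w <= 0 || !any(f)) return(f)
    idx <- which(f)
    out <- logical(length(f))
    for (d in -w:w) {
      j <- idx + d
      j <- j[j >= 1 & j <= length(f)]
      out[j] <- TRUE
    }
    out
  }
  tol_samp <- as.integer(round(tolerance / dt))
  a <- dilate(ch4_flags %in% TRUE, tol_samp)
  b <- dilate(d13c_flags %in% TRUE, tol_samp)
  joint <- a & b

  empty <- function() {
    structure(
      list(windows = data.frame(start = as_utc(numeric(0)),
                                end = as_utc(numeric(0)),
                                n = integer(0), n_ch4 = integer(0),
                                n_d13c = integer(0), rule = character(0),
                                i_start = integer(0), i_end = integer(0)),
           samples = list(), dt = dt, n_samples = n),
      class = "peak_set"
    )
  }
  if (!any(joint)) return(empty())

  r <- rle(joint)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  run_len <- run_end - run_start + 1

  # persistence filter first, then merge qualifying runs into windows
  qual <- run_len >= min_run
  if (!any(qual)) return(empty())
  run_start <- run_start[qual]
  run_end <- run_end[qual]

  grp <- integer(length(run_start))
  g <- 1L
  grp[1] <- g
  for (i in seq_along(run_start)[-1]) {
    gap <- secs[run_start[i]] - secs[run_end[i - 1]]
    if (gap < min_gap) grp[i] <- g else grp[i] <- (g <- g + 1L)
  }
  win_start <- as.integer(tapply(run_start, grp, min))
  win_end <- as.integer(tapply(run_end, grp, max))

  samples <- lapply(seq_along(win_start), function(w) {
    idx <- win_start[w]:win_end[w]
    idx[joint[idx]]
  })
  dt_attr <- dt
  windows <- data.frame(
    start = as_utc(secs[win_start]),
    end = as_utc(secs[win_end]),
    n = vapply(samples, length, integer(1)),
    n_ch4 = vapply(seq_along(win_start), function(w) {
      sum(ch4_flags[win_start[w]:win_end[w]] %in% TRUE)
    }, integer(1)),
    n_d13c = vapply(seq_along(win_start), function(w) {
      sum(d13c_flags[win_start[w]:win_end[w]] %in% TRUE)
    }, integer(1)),
    rule = "both",
    i_start = win_start,
    i_end = win_end,
    stringsAsFactors = FALSE
  )
  structure(list(windows = windows, samples = samples, dt = dt_attr,
                 n_samples = n),
            class = "peak_set")
}

#' Background vs elevated concentration summary at a quantile split
#'
#' Summarises the full series and the subset strictly above its
#' `q`-quantile (type-7, linear interpolation), reporting n, mean, standard
#' error of the mean, min and max — the layout used to compare nest-gas
#' methane with fugitive fault emissions.
#'
#' @param x numeric series (>= 10 finite samples).
#' @param q quantile for the background/elevated split (default 0.90).
#' @return data.frame of class `percentile_summary` with rows `all` and
#'   `above_q`.
#' @export
percentile_summary <- function(x, q = 0.90) {
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("need at least 10 finite samples", call. = FALSE)
  qv <- unname(quantile(x, q, type = 7))
  above <- x[x > qv]
  row <- function(subset, v) {
    data.frame(
      subset = subset,
      n = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
      min = if (length(v)) min(v) else NA_real_,
      max = if (length(v)) max(v) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(row("all", x), row("above_q", above))
  attr(out, "q") <- q
  attr(out, "quantile_value") <- qv
  class(out) <- c("percentile_summary", "data.frame")
  out
}

#' Keeling-plot regression of delta-13C on inverse concentration
#'
#' Ordinary least squares of the isotope ratio on `1/CH4`. Under
#' two-reservoir mass balance (a background reservoir of concentration
#' \eqn{C_a} and signature \eqn{\delta_a} plus an added source of signature
#' \eqn{\delta_s}), the observations satisfy
#' \deqn{\delta_{obs} = \delta_s + C_a(\delta_a - \delta_s)\,/\,C_{obs},}
#' so the intercept estimates the source signature \eqn{\delta_s} exactly in
#' the noiseless case and unbiasedly under symmetric measurement noise.
#'
#' @param ch4 numeric CH4 concentrations (ppm), n >= 3, not all equal.
#' @param d13c numeric delta-13C values (permil), aligned with `ch4`.
#' @param conf confidence level for the intercept interval (default 0.95).
#' @return an object of class `keeling_fit`: list with `intercept` (permil,
#'   the source-signature estimate), `slope` (permil ppm), `r2`, `se`
#'   (intercept SE), `ci95` (t-based interval), `n`, and the underlying
#'   `lm` fit as `model`.
#' @export
keeling_fit <- function(ch4, d13c, conf = 0.95) {
  keep <- is.finite(ch4) & is.finite(d13c)
  ch4 <- ch4[keep]; d13c <- d13c[keep]
  n <- length(ch4)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (any(ch4 <= 0)) stop("CH4 concentrations must be > 0", call. = FALSE)
  x <- 1 / ch4
  if (var(x) == 0) {
    stop("degenerate fit: all CH4 values equal", call. = FALSE)
  }
  fit <- lm(d13c ~ x)
  sm <- summary(fit)
  ci <- confint(fit, "(Intercept)", level = conf)
  structure(
    list(intercept = unname(coef(fit)[1]),
         slope = unname(coef(fit)[2]),
         r2 = sm$r.squared,
         se = sm$coefficients["(Intercept)", "Std. Error"],
         ci95 = unname(ci[1, ]),
         n = n,
         model = fit),
    class = "keeling_fit"
  )
}

#' Fit Keeling regressions per peak window and pooled
#'
#' Convenience wrapper over a [coincident_peaks()] result: fits one Keeling
#' regression per window (windows with fewer than `min_n` usable samples or
#' no concentration spread are dropped with a message) plus one pooled fit
#' over all windows, and clusters the per-window intercepts into `k` groups
#' by one-dimensional k-means when enough windows exist.
#'
#' By default each fit uses every sample inside the detected window
#' (`samples = "window"`): the full degassing episode, spanning the
#' concentration range from near-background to the peak, which is how a
#' Keeling mixing line is meant to be anchored. `samples = "flagged"`
#' restricts the fit to the jointly flagged samples only; note that
#' conditioning on the isotope-deviation flag truncates the delta-13C noise
#' asymmetrically and so pulls the intercept slightly towards the
#' background signature.
#'
#' @param peaks a `peak_set`.
#' @param ch4,d13c the full aligned sample series the peak indices refer to.
#' @param min_n minimum samples per window fit (default 10).
#' @param k number of intercept clusters (default 2: e.g. microbial vs
#'   fault-related end members).
#' @param samples `"window"` (all samples between window start and end) or
#'   `"flagged"` (jointly flagged samples only).
#' @param pad seconds of adjacent series included on each side of a window
#'   in `"window"` mode (default 900). Padding anchors the mixing line with
#'   local background samples, the usual construction of a Keeling plot,
#'   and avoids the truncation bias of fitting flag-selected samples only.
#' @return list with `per_window` (data.frame of intercepts and diagnostics),
#'   `pooled` (a `keeling_fit` or NULL), and `clusters` (data.frame window,
#'   cluster, centre; NULL when fewer than `k + 1` windows).
#' @export
keeling_by_peak <- function(peaks, ch4, d13c, min_n = 10, k = 2,
                            samples = c("window", "flagged"), pad = 900) {
  stopifnot(inherits(peaks, "peak_set"))
  samples <- match.arg(samples)
  member <- if (samples == "flagged") {
    peaks$samples
  } else {
    pad_n <- as.integer(round(pad / (peaks$dt %||% 1)))
    n_tot <- peaks$n_samples %||% length(ch4)
    lapply(seq_len(nrow(peaks$windows)), function(w) {
      seq(max(1L, peaks$windows$i_start[w] - pad_n),
          min(n_tot, peaks$windows$i_end[w] + pad_n))
    })
  }
  fits <- list()
  rows <- list()
  for (w in seq_along(member)) {
    idx <- member[[w]]
    cw <- ch4[idx]; dw <- d13c[idx]
    ok <- sum(is.finite(cw) & is.finite(dw)) >= min_n &&
      length(unique(cw[is.finite(cw)])) > 1
    if (!ok) {
      message("window ", w, " skipped: too few samples or no CH4 spread")
      next
    }
    f <- keeling_fit(cw, dw)
    fits[[length(fits) + 1]] <- f
    rows[[length(rows) + 1]] <- data.frame(
      window = w, intercept = f$intercept, slope = f$slope, r2 = f$r2,
      se = f$se, ci_lo = f$ci95[1], ci_hi = f$ci95[2], n = f$n
    )
  }
  per_window <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window = integer(0), intercept = numeric(0),
               slope = numeric(0), r2 = numeric(0), se = numeric(0),
               ci_lo = numeric(0), ci_hi = numeric(0), n = integer(0))
  all_idx <- unlist(member)
  pooled <- if (length(all_idx) >= 3 &&
                length(unique(ch4[all_idx])) > 1) {
    keeling_fit(ch4[all_idx], d13c[all_idx])
  } else NULL
  clusters <- NULL
  if (nrow(per_window) > k) {
    clusters <- cluster_intercepts(per_window$intercept, k = k)
    clusters$window <- per_window$window
  }
  list(per_window = per_window, pooled = pooled, clusters = clusters)
}

#' Cluster Keeling intercepts into source groups
#'
#' One-dimensional k-means (default two groups) with deterministic
#' initialisation at the `k` evenly spaced order statistics, used to separate
#' source-signature end members (e.g. microbial vs fault-related methane).
#'
#' @param intercepts numeric vector of per-window Keeling intercepts.
#' @param k number of clusters (default 2).
#' @return data.frame with columns `intercept`, `cluster` and `centre`;
#'   clusters are numbered by increasing centre.
#' @export
cluster_intercepts <- function(intercepts, k = 2) {
  if (length(intercepts) <= k) {
    stop("need more intercepts than clusters", call. = FALSE)
  }
  init <- quantile(intercepts, probs = seq(0, 1, length.out = k), type = 7)
  init <- unname(init) + seq(0, k - 1) * 1e-9  # ensure distinct centres
  km <- kmeans(matrix(intercepts, ncol = 1), centers = matrix(init, ncol = 1))
  ord <- order(km$centers)
  relabel <- match(seq_len(k), ord)
  data.frame(
    intercept = intercepts,
    cluster = relabel[km$cluster],
    centre = sort(as.numeric(km$centers))[relabel[km$cluster]]
  )
}

#' Delta notation from isotope ratios
#'
#' `delta = (R_sample / R_standard - 1) * 1000`, in permil relative to the
#' standard (VPDB for carbon).
#'
#' @param r_sample,r_standard isotope ratios (13C/12C); `r_standard > 0`.
#' @return delta value(s) in permil.
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("'r_standard' must be > 0", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' Instrument drift correction from periodic reference-gas runs
#'
#' Reference gas of known composition is measured at intervals (every 8 h in
#' the field protocol). The measured-minus-true offsets at the reference
#' times are interpolated piecewise-linearly over the campaign (constant
#' extrapolation beyond the first/last run) and subtracted from the sample
#' series. Reference runs with offsets outside the plausibility limits are
#' excluded with a warning. With zero measured drift the series is returned
#' unchanged.
#'
#' @param series a `gas_series` data.frame (columns `timestamp`, `ch4`,
#'   `d13c`, ...).
#' @param reference_runs data.frame with columns `timestamp`, `ch4_measured`,
#'   `ch4_true`, `d13c_measured`, `d13c_true`.
#' @param max_ch4_offset,max_d13c_offset plausibility limits on reference
#'   offsets (ppm / permil); runs beyond them are dropped.
#' @return the corrected series (same shape and class as the input).
#' @export
drift_correct <- function(series, reference_runs,
                          max_ch4_offset = 0.5, max_d13c_offset = 5) {
  req <- c("timestamp", "ch4_measured", "ch4_true", "d13c_measured",
           "d13c_true")
  if (!all(req %in% names(reference_runs))) {
    stop("reference_runs needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  off_c <- reference_runs$ch4_measured - reference_runs$ch4_true
  off_d <- reference_runs$d13c_measured - reference_runs$d13c_true
  ok <- abs(off_c) <= max_ch4_offset & abs(off_d) <= max_d13c_offset
  if (!all(ok)) {
    warning(sum(!ok), " reference run(s) outside plausible offset range; ",
            "excluded", call. = FALSE)
  }
  if (!any(ok)) stop("no usable reference runs", call. = FALSE)
  rt <- as.numeric(reference_runs$timestamp)[ok]
  st <- as.numeric(series$timestamp)
  interp <- function(offsets) {
    if (length(rt) == 1) return(rep(offsets, length(st)))
    approx(rt, offsets, xout = st, rule = 2)$y
  }
  out <- series
  out$ch4 <- series$ch4 - interp(off_c[ok])
  out$d13c <- series$d13c - interp(off_d[ok])
  out
}

#' @export
print.keeling_fit <- function(x, ...) {
  cat("Keeling regression (delta-13C on 1/CH4)\n")
  cat(sprintf("  intercept (source signature): %.2f permil  [%.2f, %.2f]\n",
              x$intercept, x$ci95[1], x$ci95[2]))
  cat(sprintf("  slope: %.2f permil ppm, r2 = %.3f, n = %d\n",
              x$slope, x$r2, x$n))
  invisible(x)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Coincident peak set: %d window(s)\n", nrow(x$windows)))
  if (nrow(x$windows)) print(x$windows)
  invisible(x)
}

#' @export
plot.keeling_fit <- function(x, ...) {
  d <- x$model$model
  plot(d$x, d$d13c, xlab = "1 / CH4 (1/ppm)",
       ylab = "delta-13C-CH4 (permil)",
       main = sprintf("Keeling plot: intercept %.1f permil", x$intercept),
       ...)
  abline(x$model, col = "red")
  invisible(x)
}
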