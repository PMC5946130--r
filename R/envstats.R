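# Environmental statistics: weather PCA, principal-component regression with
# sequential ANOVA, additive time-series decomposition, lagged
# cross-correlation, and 2-D Gaussian kernel density of epicentres.

#' Principal components of the weather table
#'
#' Correlation-matrix PCA (centred and scaled) of the measured weather
#' variables via [stats::prcomp], producing composite "weather" axes for the
#' downstream regressions. Component signs are made deterministic by forcing
#' the largest-magnitude loading of each component positive.
#'
#' @param weather a `weather_series` data.frame (a `timestamp` column is
#'   ignored; all remaining numeric columns enter the PCA). Needs >= 7 rows
#'   and no constant column.
#' @return an object of class `weather_pca`: list with `loadings`
#'   (variable x component matrix), `cumulative_variance`,
#'   `center`, `scale`, and `scores` (row x component matrix).
#' @export
weather_pca <- function(weather) {
  vars <- setdiff(names(weather), "timestamp")
  mat <- as.matrix(weather[vars])
  if (!is.numeric(mat)) stop("weather variables must be numeric", call. = FALSE)
  keep <- complete.cases(mat)
  if (sum(keep) < nrow(mat)) {
    message(nrow(mat) - sum(keep), " row(s) with missing values dropped")
  }
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 7) stop("need at least 7 complete rows", call. = FALSE)
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(vars[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  pr <- prcomp(mat, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(
    list(loadings = pr$rotation,
         cumulative_variance = cumsum(pr$sdev^2) / sum(pr$sdev^2),
         center = pr$center, scale = pr$scale, scores = pr$x,
         timestamp = if ("timestamp" %in% names(weather))
           weather$timestamp[keep] else NULL),
    class = "weather_pca"
  )
}

#' Sequential-ANOVA regression of a response on the first three weather PCs
#'
#' Ordinary least squares of `y` on PC-1..PC-3 with a sequential (type-I)
#' ANOVA table: one row per component with its slope estimate, df, mean
#' square and F against the residual mean square, plus the overall r-squared
#' and F test. Rows with missing values are dropped with a message.
#'
#' @param y numeric response aligned with the PC scores (e.g. median ant
#'   activity, CH4, or delta-13C per weather interval).
#' @param pcs matrix (or `weather_pca`) of PC scores; the first three columns
#'   are used.
#' @return an object of class `pc_anova`: list with `table` (term rows +
#'   residual), `r2`, `f`, `df`, `p_overall`, `n`, and the `lm` fit.
#' @export
pc_regression_anova <- function(y, pcs) {
  if (inherits(pcs, "weather_pca")) pcs <- pcs$scores
  pcs <- as.matrix(pcs)[, 1:3, drop = FALSE]
  colnames(pcs) <- c("PC1", "PC2", "PC3")
  if (length(y) != nrow(pcs)) {
    stop("'y' and PC scores must be aligned", call. = FALSE)
  }
  d <- data.frame(y = y, pcs)
  keep <- complete.cases(d)
  if (sum(keep) < nrow(d)) {
    message(nrow(d) - sum(keep), " row(s) with missing values dropped")
  }
  d <- d[keep, , drop = FALSE]
  if (nrow(d) <= 4) stop("need n > 4 complete rows", call. = FALSE)
  fit <- lm(y ~ PC1 + PC2 + PC3, data = d)
  a <- anova(fit)
  sm <- summary(fit)
  tab <- data.frame(
    term = rownames(a),
    estimate = c(coef(fit)[-1], NA_real_),
    df = a$Df,
    ss = a$`Sum Sq`,
    ms = a$`Mean Sq`,
    f = a$`F value`,
    p = a$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  fstat <- sm$fstatistic
  structure(
    list(table = tab,
         r2 = sm$r.squared,
         f = unname(fstat[1]),
         df = unname(fstat[2:3]),
         p_overall = unname(pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
         n = nrow(d),
         model = fit),
    class = "pc_anova"
  )
}

#' Additive decomposition of a regular time series
#'
#' Splits `x` into trend + seasonal + residual. The trend is estimated
#' either by a centred moving average of window `period` (with the usual
#' half-weight ends for even periods) or by a global polynomial smoother in
#' time; the seasonal component is the cycle-position mean of the detrended
#' series, centred to sum to zero over one period; the residual is the exact
#' remainder, so `observed = trend + seasonal + residual` holds wherever all
#' components are defined.
#'
#' @param x numeric series on a regular grid.
#' @param period season length in samples (e.g. samples per day); must not
#'   exceed half the series length.
#' @param trend_method `"moving_average"` or `"polynomial"`.
#' @param poly_degree degree of the polynomial smoother (default 6).
#' @return an object of class `additive_decomposition`: list with
#'   `observed`, `trend`, `seasonal`, `residual`, `period`, `method`.
#' @export
additive_decompose <- function(x, period,
                               trend_method = c("moving_average",
                                                "polynomial"),
                               poly_degree = 6) {
  trend_method <- match.arg(trend_method)
  n <- length(x)
  period <- as.integer(period)
  if (period < 2) stop("'period' must be >= 2 samples", call. = FALSE)
  if (period > n / 2) {
    stop("'period' longer than half the series", call. = FALSE)
  }
  trend <- if (trend_method == "moving_average") {
    w <- if (period %% 2 == 0) {
      c(0.5, rep(1, period - 1), 0.5) / period
    } else {
      rep(1, period) / period
    }
    as.numeric(stats::filter(x, w, sides = 2))
  } else {
    tt <- seq_len(n)
    ok <- is.finite(x)
    fit <- lm(x[ok] ~ poly(tt[ok], poly_degree, raw = FALSE))
    out <- rep(NA_real_, n)
    out[ok] <- fitted(fit)
    out
  }
  detr <- x - trend
  pos <- (seq_len(n) - 1) %% period
  smeans <- tapply(detr, pos, mean, na.rm = TRUE)
  smeans <- smeans - mean(smeans)
  seasonal <- as.numeric(smeans[as.character(pos)])
  residual <- x - trend - seasonal
  structure(
    list(observed = x, trend = trend, seasonal = seasonal,
         residual = residual, period = period, method = trend_method),
    class = "additive_decomposition"
  )
}

#' Lagged cross-correlation of two aligned series
#'
#' Sample cross-correlation function: for lag \eqn{\ell},
#' \deqn{r(\ell) = \frac{1}{n\,s_x s_y}\sum_t (x_t - \bar x)
#'   (y_{t+\ell} - \bar y),}
#' with the sum over the overlapping segment and means/variances taken from
#' the full series (the standard sample-CCF convention; the 1/n
#' normalisation guarantees \eqn{|r| \le 1} at every lag). With this sign
#' convention, if `y` leads `x` by `k` samples (`y[t] = x[t+k]`) the maximum
#' appears at lag `-k`.
#'
#' @param x,y numeric series of equal length, with `n - max_lag >= 10`.
#' @param max_lag maximum lag in samples.
#' @return an object of class `cross_correlation`: data.frame with columns
#'   `lag` (samples) and `r`.
#' @export
cross_correlation <- function(x, y, max_lag) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must be aligned", call. = FALSE)
  if (n - max_lag < 10) {
    stop("series too short for this 'max_lag'", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("series must be complete", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(mean((x - mx)^2))
  sy <- sqrt(mean((y - my)^2))
  if (sx == 0 || sy == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  lags <- seq(-max_lag, max_lag)
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      s <- sum((x[seq_len(n - l)] - mx) * (y[seq_len(n - l) + l] - my))
    } else {
      s <- sum((x[seq(1 - l, n)] - mx) * (y[seq_len(n + l)] - my))
    }
    s / (n * sx * sy)
  }, numeric(1))
  structure(data.frame(lag = lags, r = r),
            class = c("cross_correlation", "data.frame"))
}

# Silverman-type normal-reference bandwidth (SD scale) for one margin of a
# 2-D kernel estimate.
silverman_bw <- function(v) {
  n <- length(v)
  1.06 * min(sd(v), IQR(v) / 1.34) * n^(-1 / 6)
}

#' 2-D Gaussian kernel density of epicentres
#'
#' Product-Gaussian kernel density surface on a regular grid, computed with
#' [MASS::kde2d]; bandwidths default to a Silverman-type normal-reference
#' rule per dimension. Degenerate automatic bandwidths (constant coordinate
#' or zero IQR) fall back to a diagonal bandwidth from the coordinate range
#' with a warning. The returned surface is renormalised to integrate to 1
#' over the grid (trapezoidal quadrature).
#'
#' @param points two-column matrix or data.frame of coordinates
#'   (lon/lat or x/y); >= 2 rows.
#' @param bandwidth `"silverman"` or a numeric vector of 1 or 2 kernel SDs.
#' @param n grid resolution per axis (default 64).
#' @param lims optional `c(xmin, xmax, ymin, ymax)`; defaults to the point
#'   range extended by 3 bandwidths.
#' @return an object of class `kde2d_grid`: list with `x`, `y` (axes), `z`
#'   (density matrix) and `h` (kernel SDs used).
#' @export
gaussian_kde2d <- function(points, bandwidth = "silverman", n = 64,
                           lims = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) < 2 || nrow(pts) < 2) {
    stop("'points' must have >= 2 rows and 2 columns", call. = FALSE)
  }
  px <- pts[, 1]; py <- pts[, 2]
  if (identical(bandwidth, "silverman")) {
    h <- c(silverman_bw(px), silverman_bw(py))
  } else {
    h <- rep_len(as.numeric(bandwidth), 2L)
  }
  bad <- !is.finite(h) | h <= 0
  if (any(bad)) {
    fallback <- pmax(c(diff(range(px)), diff(range(py))) / 10, 1e-3)
    h[bad] <- fallback[bad]
    warning("degenerate automatic bandwidth; diagonal fallback used",
            call. = FALSE)
  }
  if (is.null(lims)) {
    lims <- c(range(px) + c(-3, 3) * h[1], range(py) + c(-3, 3) * h[2])
  }
  # MASS::kde2d uses h/4 as the Gaussian SD, so pass 4 * SD
  kd <- MASS::kde2d(px, py, h = 4 * h, n = n, lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  wx <- rep(1, length(kd$x)); wx[c(1, length(wx))] <- 0.5
  wy <- rep(1, length(kd$y)); wy[c(1, length(wy))] <- 0.5
  integral <- sum(outer(wx, wy) * kd$z) * dx * dy
  structure(list(x = kd$x, y = kd$y, z = kd$z / integral, h = h),
            class = "kde2d_grid")
}

#' @export
print.weather_pca <- function(x, ...) {
  cat("Weather PCA (correlation matrix)\n")
  k <- min(3, ncol(x$loadings))
  print(round(x$loadings[, seq_len(k), drop = FALSE], 2))
  cat("Cumulative variance explained:",
      paste(round(x$cumulative_variance[seq_len(k)], 2), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
print.pc_anova <- function(x, ...) {
  cat("Sequential (type-I) ANOVA of response on weather PCs\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, 3)
  tab[c("ss", "ms", "f")] <- lapply(tab[c("ss", "ms", "f")], round, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall r2 = %.2f; F(%d,%d) = %.2f, p = %.3g\n",
              x$r2, x$df[1], x$df[2], x$f, x$p_overall))
  invisible(x)
}

#' @export
plot.additive_decomposition <- function(x, ...) {
  op <- par(mfrow = c(4, 1), mar = c(2, 4, 1, 1))
  on.exit(par(op))
  for (comp in c("observed", "trend", "seasonal", "residual")) {
    plot(x[[comp]], type = "l", ylab = comp, xlab = "", ...)
  }
  invisible(x)
}

#' @export
plot.cross_correlation <- function(x, ...) {
  plot(x$lag, x$r, type = "h", xlab = "lag (samples)", ylab = "r",
       ylim = c(-1, 1), ...)
  abline(h = 0)
  invisible(x)
}
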