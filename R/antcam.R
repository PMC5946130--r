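# Ant-activity estimation from fixed-camera frames: register consecutive
# frames by maximising mutual information over integer translations, sum the
# masked absolute difference image, and map the raw sums onto activity
# categories with a per-sensor polynomial calibration.

bin_index <- function(x, lo, hi, bins) {
  if (hi <= lo) return(rep(1L, length(x)))
  pmin(bins, pmax(1L, 1L + floor((x - lo) / (hi - lo) * bins)))
}

#' Mutual information of two equally sized grayscale images
#'
#' Computes the Shannon mutual information (in bits) of the joint intensity
#' histogram of two images, using `bins` equal-width intensity bins spanning
#' the pooled intensity range of the pair. MI is maximal when the images are
#' in register, which is what the camera-jitter compensation exploits.
#'
#' @param a,b numeric matrices of identical dimension.
#' @param bins number of histogram bins per image (>= 2; default 64).
#' @return mutual information in bits (non-negative scalar).
#' @export
mutual_information <- function(a, b, bins = 64L) {
  if (!identical(dim(a), dim(b))) {
    stop("'a' and 'b' must have identical dimensions", call. = FALSE)
  }
  if (bins < 2) stop("'bins' must be >= 2", call. = FALSE)
  lo <- min(a, b)
  hi <- max(a, b)
  ia <- bin_index(as.numeric(a), lo, hi, bins)
  ib <- bin_index(as.numeric(b), lo, hi, bins)
  n <- length(ia)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / n
  pa <- tabulate(ia, nbins = bins) / n
  pb <- tabulate(ib, nbins = bins) / n
  nz <- joint > 0
  jm <- matrix(joint, bins, bins)
  outer_p <- outer(pa, pb)
  sum(jm[nz] * log2(jm[nz] / outer_p[nz]))
}

# Overlap submatrices of ref and cur for candidate shift (dx, dy), where the
# shift means cur[r + dy, c + dx] corresponds to ref[r, c]. NULL if empty.
overlap_pair <- function(ref, cur, dx, dy) {
  nr <- nrow(ref); nc <- ncol(ref)
  r <- max(1, 1 - dy):min(nr, nr - dy)
  c <- max(1, 1 - dx):min(nc, nc - dx)
  if (length(r) < 1 || length(c) < 1 || r[1] > r[length(r)] ||
      c[1] > c[length(c)]) {
    return(NULL)
  }
  list(ref = ref[r, c, drop = FALSE],
       cur = cur[r + dy, c + dx, drop = FALSE])
}

#' Recover the integer camera translation between two frames
#'
#' Exhaustively searches integer shifts in
#' `[-max_shift, max_shift]` x `[-max_shift, max_shift]` and returns the one
#' maximising the mutual information between the shifted current frame and
#' the reference, computed on their overlap. Ties (within 1e-12 bits) are
#' broken by the smallest Euclidean shift norm, then lexicographically by
#' `dx` then `dy`. The returned `(dx, dy)` is the translation of the scene
#' content in the current frame relative to the reference: columns move right
#' by `dx`, rows move down by `dy`.
#'
#' @param ref,cur frames (numeric matrices of identical dimension).
#' @param max_shift search radius in pixels (>= 0).
#' @param bins histogram bins for [mutual_information()].
#' @return integer vector `c(dx, dy)` with attribute `"mi"` (bits at optimum).
#' @export
register_translation <- function(ref, cur, max_shift = 5L, bins = 64L) {
  if (!identical(dim(ref), dim(cur))) {
    stop("'ref' and 'cur' must have identical dimensions", call. = FALSE)
  }
  if (max_shift < 0) stop("'max_shift' must be >= 0", call. = FALSE)
  best <- c(0L, 0L)
  best_mi <- -Inf
  for (dy in seq(-max_shift, max_shift)) {
    for (dx in seq(-max_shift, max_shift)) {
      ov <- overlap_pair(ref, cur, dx, dy)
      if (is.null(ov)) next
      mi <- mutual_information(ov$ref, ov$cur, bins = bins)
      if (mi > best_mi + 1e-12) {
        best_mi <- mi
        best <- c(dx, dy)
      } else if (abs(mi - best_mi) <= 1e-12) {
        cand <- c(dx, dy)
        if (sum(cand^2) < sum(best^2) ||
            (sum(cand^2) == sum(best^2) &&
             (cand[1] < best[1] ||
              (cand[1] == best[1] && cand[2] < best[2])))) {
          best <- cand
        }
      }
    }
  }
  structure(as.integer(best), mi = best_mi)
}

#' Raw activity: masked sum of absolute frame differences
#'
#' Sums `|cur - prev|` over the pixels inside the nest mask, after aligning
#' the current frame to the previous one by the supplied integer shift
#' (typically from [register_translation()]). Pixels whose counterpart is
#' lost to the shift are excluded, as is everything outside the mask, so
#' moving grass or sky cannot contribute.
#'
#' @param prev,cur frames (numeric matrices of identical dimension).
#' @param mask logical (or 0/1) matrix of the same dimension; `TRUE` pixels
#'   are inside the nest region. Must contain at least one `TRUE` pixel.
#' @param shift integer `c(dx, dy)` translation of `cur` relative to `prev`.
#' @return non-negative scalar sum of absolute differences (raw SAD).
#' @export
activity_raw <- function(prev, cur, mask, shift = c(0L, 0L)) {
  if (!identical(dim(prev), dim(cur)) || !identical(dim(prev), dim(mask))) {
    stop("'prev', 'cur' and 'mask' must have identical dimensions",
         call. = FALSE)
  }
  mask <- mask != 0
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  dx <- as.integer(shift[1]); dy <- as.integer(shift[2])
  ov <- overlap_pair(prev, cur, dx, dy)
  if (is.null(ov)) stop("shift leaves no frame overlap", call. = FALSE)
  nr <- nrow(prev); nc <- ncol(prev)
  r <- max(1, 1 - dy):min(nr, nr - dy)
  c <- max(1, 1 - dx):min(nc, nc - dx)
  m <- mask[r, c, drop = FALSE]
  sum(abs(ov$cur - ov$ref)[m])
}

#' Fit a per-sensor polynomial activity calibration
#'
#' Maps raw SAD values onto manually assigned activity categories by
#' least-squares polynomial regression. The raw values are first centred and
#' scaled (mean/SD over the calibration period) to avoid numerical issues
#' with high-order terms; the centring constants are stored in the model so
#' that [apply_calibration()] reproduces the mapping exactly. By convention
#' the daytime sensor uses a first-order and the nighttime sensor a
#' third-order polynomial; activity categories are non-negative reals on a
#' 0-25 scale.
#'
#' @param raw numeric raw SAD values.
#' @param labels numeric activity categories, time-aligned with `raw`.
#' @param sensor `"day"` or `"night"`.
#' @param degree polynomial degree; defaults to 1 (day) or 3 (night).
#' @return an object of class `antcam_calibration` with elements `sensor`,
#'   `degree`, `coefficients` (ascending powers), `center_mean`, `center_sd`
#'   and `residual_ss`.
#' @export
fit_calibration <- function(raw, labels, sensor = c("day", "night"),
                            degree = NULL) {
  sensor <- match.arg(sensor)
  if (is.null(degree)) degree <- if (sensor == "day") 1L else 3L
  if (length(raw) != length(labels)) {
    stop("'raw' and 'labels' must be aligned (same length)", call. = FALSE)
  }
  keep <- is.finite(raw) & is.finite(labels)
  raw <- raw[keep]; labels <- labels[keep]
  if (length(unique(raw)) < degree + 1) {
    stop("need at least degree + 1 distinct raw values", call. = FALSE)
  }
  center_mean <- mean(raw)
  center_sd <- sd(raw)
  if (!is.finite(center_sd) || center_sd <= 0) {
    stop("raw values have zero variance; cannot centre/scale", call. = FALSE)
  }
  z <- (raw - center_mean) / center_sd
  fit <- lm(labels ~ poly(z, degree, raw = TRUE))
  structure(
    list(sensor = sensor, degree = as.integer(degree),
         coefficients = unname(coef(fit)),
         center_mean = center_mean, center_sd = center_sd,
         residual_ss = sum(fit$residuals^2)),
    class = "antcam_calibration"
  )
}

#' Apply a fitted activity calibration to raw SAD values
#'
#' Evaluates the calibration polynomial at the centred/scaled raw values
#' (Horner scheme); deterministic given the model.
#'
#' @param model an `antcam_calibration` from [fit_calibration()].
#' @param raw numeric raw SAD values.
#' @return numeric activity values on the category scale.
#' @export
apply_calibration <- function(model, raw) {
  stopifnot(inherits(model, "antcam_calibration"))
  z <- (raw - model$center_mean) / model$center_sd
  co <- model$coefficients
  acc <- rep(co[length(co)], length(z))
  for (i in rev(seq_len(length(co) - 1))) {
    acc <- acc * z + co[i]
  }
  acc
}

#' Score a frame sequence into an activity series
#'
#' Runs the full per-frame chain on a [simulate_frames()] sequence (or any
#' list with the same structure): each frame is registered to its
#' predecessor, the masked absolute-difference sum is computed on the aligned
#' overlap, and — when calibrations are supplied — mapped onto the activity
#' scale with the sensor-appropriate model.
#'
#' @param fs a `frame_sequence` (see [simulate_frames()]).
#' @param max_shift registration search radius in pixels.
#' @param bins histogram bins for mutual information.
#' @param calibration optional named list with elements `day` and/or `night`,
#'   each an `antcam_calibration`.
#' @return data.frame with columns `timestamp`, `sensor`, `dx`, `dy`,
#'   `raw_sad` and (if calibrated) `activity`; one row per frame after the
#'   first.
#' @export
activity_series <- function(fs, max_shift = 2L, bins = 64L,
                            calibration = NULL) {
  stopifnot(inherits(fs, "frame_sequence"))
  n <- length(fs$frames)
  if (n < 2) stop("need at least two frames", call. = FALSE)
  raw <- numeric(n - 1)
  dxs <- integer(n - 1)
  dys <- integer(n - 1)
  for (i in 2:n) {
    sh <- register_translation(fs$frames[[i - 1]], fs$frames[[i]],
                               max_shift = max_shift, bins = bins)
    raw[i - 1] <- activity_raw(fs$frames[[i - 1]], fs$frames[[i]],
                               fs$mask, shift = sh)
    dxs[i - 1] <- sh[1]; dys[i - 1] <- sh[2]
  }
  out <- data.frame(timestamp = fs$timestamp[-1], sensor = fs$sensor[-1],
                    dx = dxs, dy = dys, raw_sad = raw,
                    stringsAsFactors = FALSE)
  if (!is.null(calibration)) {
    out$activity <- NA_real_
    for (sen in c("day", "night")) {
      if (!is.null(calibration[[sen]])) {
        sel <- out$sensor == sen
        out$activity[sel] <- apply_calibration(calibration[[sen]],
                                               out$raw_sad[sel])
      }
    }
  }
  out
}

#' @export
print.antcam_calibration <- function(x, ...) {
  cat(sprintf("Activity calibration (%s sensor, degree %d)\n",
              x$sensor, x$degree))
  cat("  coefficients (ascending):",
      paste(signif(x$coefficients, 4), collapse = ", "), "\n")
  cat(sprintf("  centring: mean %.3g, sd %.3g; residual SS %.3g\n",
              x$center_mean, x$center_sd, x$residual_ss))
  invisible(x)
}
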