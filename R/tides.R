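# Solid-earth tides as a harmonic constituent sum. The artifact needs the
# tidal phase structure (semidiurnal/diurnal periodicity) for correlation
# tests against gas series, not geodetic accuracy, so an equilibrium-style
# harmonic model replaces a full lunisolar ephemeris with Love numbers.

#' Default tidal constituents
#'
#' The four largest constituents of the equilibrium tide with amplitudes
#' relative to M2 (lunar semidiurnal = 1): S2 (solar semidiurnal), K1
#' (lunisolar diurnal) and O1 (lunar diurnal), with the standard relative
#' potential amplitudes and zero phase. With these defaults the spectrum is
#' dominated by the semidiurnal band (12-12.5 h).
#'
#' @return data.frame with columns `name`, `period_h` (hours), `amplitude`
#'   (relative units) and `phase` (radians).
#' @export
default_tide_constituents <- function() {
  data.frame(
    name = c("M2", "S2", "K1", "O1"),
    period_h = c(12.4206, 12.0000, 23.9345, 25.8193),
    amplitude = c(1.000, 0.465, 0.584, 0.415),
    phase = c(0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Harmonic earth-tide displacement series
#'
#' \deqn{d(t) = \sum_i A_i \cos(2\pi t / T_i + \phi_i)} evaluated on a
#' regular grid; deterministic.
#'
#' @param start,end series limits (POSIXct or coercible, UTC).
#' @param step sampling step in seconds (> 0; default 60).
#' @param constituents data.frame as in [default_tide_constituents()].
#' @return data.frame of class `tide_series` with columns `timestamp` and
#'   `displacement` (relative vertical units).
#' @export
tide_series <- function(start, end, step = 60,
                        constituents = default_tide_constituents()) {
  if (step <= 0) stop("'step' must be > 0", call. = FALSE)
  if (!nrow(constituents)) stop("need at least one constituent", call. = FALSE)
  start <- as_utc(start)
  end <- as_utc(end)
  t <- seq(0, as.numeric(end) - as.numeric(start), by = step)
  disp <- numeric(length(t))
  for (i in seq_len(nrow(constituents))) {
    disp <- disp + constituents$amplitude[i] *
      cos(2 * pi * t / (constituents$period_h[i] * 3600) +
            constituents$phase[i])
  }
  structure(data.frame(timestamp = start + t, displacement = disp),
            class = c("tide_series", "data.frame"))
}

#' Cross-correlate an earth-tide series with a gas series
#'
#' Aggregates the gas channel to the common grid (median per `interval`),
#' interpolates the tide displacement onto the same grid, and delegates to
#' [cross_correlation()].
#'
#' @param tides a `tide_series`.
#' @param gas a `gas_series` (or any data.frame with `timestamp` and the
#'   chosen `variable`); only the `channel == "nest"` rows are used when a
#'   `channel` column is present.
#' @param max_lag maximum lag in grid samples.
#' @param variable gas column to correlate (`"ch4"` or `"d13c"`).
#' @param interval common grid interval in seconds (default 300).
#' @return a `cross_correlation` with attribute `interval` (seconds per lag
#'   step).
#' @export
tide_gas_ccf <- function(tides, gas, max_lag, variable = "ch4",
                         interval = 300) {
  g <- gas
  if ("channel" %in% names(g)) g <- g[g$channel == "nest", , drop = FALSE]
  gb <- aggregate_interval(g$timestamp, g[[variable]], interval = interval)
  td <- approx(as.numeric(tides$timestamp), tides$displacement,
               xout = as.numeric(gb$timestamp), rule = 1)$y
  keep <- is.finite(td) & is.finite(gb$value)
  out <- cross_correlation(td[keep], gb$value[keep], max_lag = max_lag)
  attr(out, "interval") <- interval
  out
}
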