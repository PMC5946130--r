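# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-stream seed from a campaign seed; stays inside 32-bit range so
# set.seed() accepts it on all platforms.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 10007) %% 2147483647L)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# NA-safe multi-format timestamp parsing: tries each format in turn and
# leaves unparseable entries NA instead of erroring.
parse_utc <- function(x, formats = c("%Y-%m-%dT%H:%M:%OSZ",
                                     "%Y-%m-%dT%H:%M:%OS",
                                     "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%d %H:%M")) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  left <- !is.na(x)
  for (f in formats) {
    if (!any(left)) break
    got <- as.POSIXct(as.character(x[left]), tz = "UTC", format = f)
    hit <- !is.na(got)
    out[which(left)[hit]] <- got[hit]
    left[left] <- !hit
  }
  out
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

#' Aggregate a timestamped series onto a regular grid
#'
#' Bins samples into intervals of `interval` seconds (left-closed, anchored at
#' the epoch) and summarises each bin, by default with the median. Used to
#' bring 1-Hz gas data and frame-wise activity onto the weather grid before
#' regression and cross-correlation.
#'
#' @param timestamp POSIXct (or numeric seconds) sample times.
#' @param value numeric values, same length as `timestamp`.
#' @param interval bin width in seconds (default 300, i.e. 5 min).
#' @param fun summary function applied per bin (default [stats::median]).
#' @return data.frame with columns `timestamp` (bin start, POSIXct UTC) and
#'   `value`, one row per non-empty bin, ordered in time.
#' @export
aggregate_interval <- function(timestamp, value, interval = 300, fun = median) {
  if (length(timestamp) != length(value)) {
    stop("'timestamp' and 'value' must have the same length", call. = FALSE)
  }
  secs <- as.numeric(timestamp)
  keep <- is.finite(secs) & is.finite(value)
  secs <- secs[keep]
  value <- value[keep]
  if (!length(secs)) {
    return(data.frame(timestamp = as_utc(numeric(0)), value = numeric(0)))
  }
  bin <- floor(secs / interval) * interval
  agg <- tapply(value, bin, fun)
  out <- data.frame(
    timestamp = as_utc(as.numeric(names(agg))),
    value = as.numeric(agg)
  )
  out[order(out$timestamp), , drop = FALSE]
}

# Inner-join two regular series on their timestamps (numeric match on epoch
# seconds); returns list(x =, y =, timestamp =).
align_series <- function(t1, x1, t2, x2) {
  k1 <- as.numeric(t1)
  k2 <- as.numeric(t2)
  common <- intersect(k1, k2)
  common <- sort(common)
  list(
    timestamp = as_utc(common),
    x = x1[match(common, k1)],
    y = x2[match(common, k2)]
  )
}
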