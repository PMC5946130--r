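# CSV / PNG interchange. Time series travel as RFC-4180 CSV with ISO-8601
# UTC timestamps; frames as 8-bit grayscale PNG named frame_<epoch-ms>_<D|N>.png.

iso_utc <- function(t) format(as_utc(t), "%Y-%m-%dT%H:%M:%OS3Z")

#' Write a timestamped series to CSV
#'
#' Writes any of the package's series data.frames with the `timestamp`
#' column rendered as ISO-8601 UTC.
#'
#' @param x data.frame with a `timestamp` column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  out <- as.data.frame(x)
  if ("timestamp" %in% names(out)) out$timestamp <- iso_utc(out$timestamp)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a timestamped series from CSV
#'
#' Counterpart of [write_series_csv()]; parses ISO-8601 UTC timestamps.
#' Rows whose timestamp fails to parse are dropped and counted in a message.
#'
#' @param path CSV file path.
#' @return data.frame with a POSIXct `timestamp` column.
#' @export
read_series_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if ("timestamp" %in% names(d)) {
    ts <- parse_utc(d$timestamp)
    bad <- is.na(ts) & !is.na(d$timestamp)
    if (any(bad)) {
      message(sum(bad), " row(s) with malformed timestamps dropped")
    }
    d <- d[!bad, , drop = FALSE]
    d$timestamp <- ts[!bad]
  }
  d
}

#' Write a frame sequence as grayscale PNG files
#'
#' Files are named `frame_<epoch-ms>_<D|N>.png` (D = day sensor, N = night);
#' the mask is written as `mask.png` (nonzero = inside the nest region).
#'
#' @param fs a `frame_sequence` (see [simulate_frames()]).
#' @param dir output directory (created if needed).
#' @return character vector of frame file paths, invisibly.
#' @export
write_frames <- function(fs, dir) {
  stopifnot(inherits(fs, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ms <- round(as.numeric(fs$timestamp) * 1000)
  flag <- ifelse(fs$sensor == "day", "D", "N")
  paths <- file.path(dir, sprintf("frame_%013.0f_%s.png", ms, flag))
  for (i in seq_along(fs$frames)) {
    png::writePNG(fs$frames[[i]] / 255, paths[i])
  }
  png::writePNG(fs$mask * 1, file.path(dir, "mask.png"))
  invisible(paths)
}

#' Read a directory of frame PNGs into a frame sequence
#'
#' Expects the naming convention of [write_frames()]. Files whose name does
#' not parse to a timestamp are dropped and counted. Frames are returned in
#' time order with intensities on the 0-255 scale.
#'
#' @param dir directory containing `frame_*.png` and optionally `mask.png`.
#' @return a `frame_sequence` (with `truth = NULL` for field data).
#' @export
read_frames <- function(dir) {
  files <- list.files(dir, pattern = "^frame_.*\\.png$", full.names = TRUE)
  if (!length(files)) stop("no frame PNGs in ", dir, call. = FALSE)
  base <- basename(files)
  m <- regmatches(base, regexec("^frame_([0-9]+)_([DN])\\.png$", base))
  ok <- lengths(m) == 3
  if (any(!ok)) {
    message(sum(!ok), " frame file(s) with unparseable names dropped")
  }
  files <- files[ok]
  m <- m[ok]
  ms <- as.numeric(vapply(m, `[`, "", 2))
  sensor <- ifelse(vapply(m, `[`, "", 3) == "D", "day", "night")
  ord <- order(ms)
  frames <- lapply(files[ord], function(p) {
    px <- png::readPNG(p)
    if (length(dim(px)) == 3) px <- px[, , 1]
    px * 255
  })
  mask_path <- file.path(dir, "mask.png")
  mask <- if (file.exists(mask_path)) {
    mp <- png::readPNG(mask_path)
    if (length(dim(mp)) == 3) mp <- mp[, , 1]
    mp != 0
  } else {
    matrix(TRUE, nrow(frames[[1]]), ncol(frames[[1]]))
  }
  structure(
    list(frames = frames,
         timestamp = as_utc(ms[ord] / 1000),
         sensor = sensor[ord], mask = mask, truth = NULL),
    class = "frame_sequence"
  )
}

hf305_gas_aliases <- list(
  timestamp = c("timestamp", "datetime", "date.time", "date_time"),
  ch4 = c("ch4", "ch4.ppm", "ch4_ppm"),
  d13c = c("d13c", "d13c.ch4", "d13c_ch4", "d13cch4"),
  channel = c("channel", "source", "type")
)

hf305_weather_aliases <- list(
  timestamp = c("timestamp", "datetime", "date.time", "date_time"),
  temperature = c("temperature", "airt", "temp"),
  pressure = c("pressure", "bar", "airpressure"),
  dewpoint = c("dewpoint", "dewp"),
  humidity = c("humidity", "rh"),
  rainfall = c("rainfall", "prec", "rain"),
  windspeed = c("windspeed", "wspd", "wind")
)

hf305_activity_aliases <- list(
  timestamp = c("timestamp", "datetime", "date.time", "date_time"),
  activity = c("activity", "act", "category"),
  raw_sad = c("raw_sad", "sad", "raw")
)

match_schema <- function(d, aliases, optional = character(0)) {
  nm <- tolower(names(d))
  out <- list()
  for (field in names(aliases)) {
    hit <- which(nm %in% aliases[[field]])
    if (!length(hit)) {
      if (field %in% optional) next
      stop("missing column '", field, "' (accepted names: ",
           paste(aliases[[field]], collapse = ", "),
           "); expected schema: ",
           paste(names(aliases), collapse = ", "), call. = FALSE)
    }
    out[[field]] <- d[[hit[1]]]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read archived campaign tables (HF305 dialect)
#'
#' Reads the archived campaign CSV layout into the package's typed series.
#' Column names are matched case-insensitively against a small alias table
#' (e.g. `datetime`/`timestamp`, `ch4`/`ch4.ppm`); unknown layouts raise an
#' error listing the expected schema. Timestamps are parsed as UTC; rows with
#' malformed timestamps are dropped and counted in a message, and the number
#' of rows read is reported.
#'
#' @param path CSV file path.
#' @param what table type: `"gas"`, `"weather"` or `"activity"`.
#' @return a data.frame typed as `gas_series`, `weather_series`, or an
#'   activity table.
#' @export
read_hf305 <- function(path, what = c("gas", "weather", "activity")) {
  what <- match.arg(what)
  d <- read.csv(path, stringsAsFactors = FALSE)
  aliases <- switch(what,
                    gas = hf305_gas_aliases,
                    weather = hf305_weather_aliases,
                    activity = hf305_activity_aliases)
  optional <- switch(what, gas = "channel", activity = "raw_sad",
                     character(0))
  out <- match_schema(d, aliases, optional = optional)
  ts <- parse_utc(out$timestamp)
  bad <- is.na(ts)
  if (any(bad)) {
    message(sum(bad), " row(s) with malformed timestamps rejected")
  }
  out <- out[!bad, , drop = FALSE]
  out$timestamp <- ts[!bad]
  if (what == "gas" && is.null(out$channel)) out$channel <- "nest"
  message(nrow(out), " ", what, " rows read from ", basename(path))
  class(out) <- c(switch(what, gas = "gas_series",
                         weather = "weather_series", "data.frame"),
                  "data.frame")
  out
}
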