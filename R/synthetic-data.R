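#' Describe one episodic methane source injection
#'
#' A source event adds a transient CH4 excess with a fixed isotopic signature
#' on top of the atmospheric background. Under two-reservoir mass balance the
#' mixed isotope ratio at any instant is the concentration-weighted mean of
#' background and source signatures, which is what makes the Keeling-plot
#' intercept recover `d13c_source`.
#'
#' @param d13c_source source signature in permil VPDB (e.g. -69 for microbial
#'   decomposition, -37 for fault-related thermogenic/abiotic methane).
#' @param start event onset in seconds since the campaign start.
#' @param duration event length in seconds (> 0).
#' @param peak_excess maximum added CH4 in ppm (>= 0).
#' @param shape pulse shape: `"boxcar"`, `"triangular"` or `"gaussian"`.
#' @return an object of class `source_event`.
#' @seealso [scenario_config()], [simulate_gas()]
#' @export
source_event <- function(d13c_source, start, duration, peak_excess,
                         shape = c("gaussian", "boxcar", "triangular")) {
  shape <- match.arg(shape)
  stop_if_not_scalar_number(d13c_source, "d13c_source")
  stop_if_not_scalar_number(start, "start")
  stop_if_not_scalar_number(duration, "duration")
  stop_if_not_scalar_number(peak_excess, "peak_excess")
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  if (peak_excess < 0) stop("'peak_excess' must be >= 0", call. = FALSE)
  structure(
    list(d13c_source = d13c_source, start = start, duration = duration,
         peak_excess = peak_excess, shape = shape),
    class = "source_event"
  )
}

#' Describe a catalogued micro-earthquake
#'
#' @param time event time (POSIXct or anything [as.POSIXct()] accepts, UTC).
#' @param magnitude local (Richter) magnitude.
#' @param depth focal depth in km (>= 0).
#' @param distance epicentral distance from the nest in km (>= 0).
#' @param lat,lon epicentre coordinates in degrees.
#' @return an object of class `quake_event`.
#' @export
quake_event <- function(time, magnitude, depth, distance, lat = NA_real_,
                        lon = NA_real_) {
  if (depth < 0) stop("'depth' must be >= 0", call. = FALSE)
  if (distance < 0) stop("'distance' must be >= 0", call. = FALSE)
  structure(
    list(time = as_utc(time), magnitude = magnitude, depth = depth,
         distance = distance, lat = lat, lon = lon),
    class = "quake_event"
  )
}

default_weather_params <- function() {
  list(
    temp_mean = 16.2,        # degC, campaign mean
    temp_amplitude = 9,      # degC, diurnal half-range
    temp_noise_sd = 1.2,     # degC
    pressure_mean = 988,     # hPa
    pressure_amplitude = 2.24, # hPa, slow synoptic swing
    pressure_noise_sd = 0.3, # hPa
    humidity_mean = 70,      # %
    humidity_coupling = -2.5, # % per degC of temperature anomaly
    humidity_noise_sd = 3,   # %
    wind_mean = 1.67,        # km/h
    wind_noise_sd = 1.0,     # km/h
    rain_prob = 0.004,       # per 5-min interval
    rain_mean = 0.3          # mm, conditional mean
  )
}

#' Configure a synthetic nest-monitoring campaign
#'
#' A `scenario_config` is the single generative description of a campaign:
#' gas chemistry (background + episodic sources + instrument noise), weather,
#' tidal constituents, an earthquake catalogue, and camera-frame parameters.
#' Identical configurations (including `seed`) generate bit-identical data.
#'
#' Defaults emulate an 8-day, 1-Hz nest campaign: atmospheric background
#' 1.82 ppm CH4, background delta-13C-CH4 of -47 permil (a conventional
#' modern-atmosphere value; configurable), CH4 instrument noise 0.005 ppm and
#' delta-13C noise 0.8 permil (instrument-precision level).
#'
#' @param duration campaign length in seconds (default 8 days).
#' @param gas_rate gas sampling rate in Hz (default 1).
#' @param background_ch4 atmospheric background CH4 in ppm (> 0).
#' @param background_d13c background delta-13C-CH4 in permil VPDB.
#' @param sources list of [source_event()] objects.
#' @param ch4_noise_sd,d13c_noise_sd i.i.d. Gaussian measurement noise SDs
#'   (ppm / permil; >= 0).
#' @param ch4_floor concentrations driven below this floor by noise are
#'   clipped to it (ppm).
#' @param weather_interval weather logging interval in seconds (default 300).
#' @param weather named list of weather-model parameters; see
#'   [simulate_weather()] for their meaning. Missing entries take defaults.
#' @param tide_constituents data.frame of harmonic constituents
#'   (columns `name`, `period_h`, `amplitude`, `phase`); defaults to
#'   [default_tide_constituents()].
#' @param quake_list list of [quake_event()] objects.
#' @param frame_rate camera frame rate in Hz.
#' @param frame_size frame side length in pixels (square frames, >= 16).
#' @param n_ants number of simulated ants (bright moving blobs).
#' @param jitter_px maximum per-frame camera translation in pixels.
#' @param day_start,day_end hours (UTC) delimiting the daytime sensor.
#' @param start campaign start time (POSIXct UTC).
#' @param seed integer seed controlling every random stream.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(duration = 8 * 86400,
                            gas_rate = 1,
                            background_ch4 = 1.82,
                            background_d13c = -47,
                            sources = list(),
                            ch4_noise_sd = 0.005,
                            d13c_noise_sd = 0.8,
                            ch4_floor = 0.001,
                            weather_interval = 300,
                            weather = list(),
                            tide_constituents = default_tide_constituents(),
                            quake_list = list(
                              quake_event("2016-08-09 12:00:00",
                                          magnitude = 0.8, depth = 3,
                                          distance = 20,
                                          lat = 50.4, lon = 7.4)
                            ),
                            frame_rate = 1,
                            frame_size = 64L,
                            n_ants = 5L,
                            jitter_px = 1L,
                            day_start = 6, day_end = 21,
                            start = as.POSIXct("2016-08-04 00:00:00",
                                               tz = "UTC"),
                            seed = 1L) {
  stop_if_not_scalar_number(duration, "duration")
  stop_if_not_scalar_number(gas_rate, "gas_rate")
  stop_if_not_scalar_number(background_ch4, "background_ch4")
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  if (gas_rate <= 0) stop("'gas_rate' must be > 0", call. = FALSE)
  if (background_ch4 <= 0) stop("'background_ch4' must be > 0", call. = FALSE)
  if (ch4_noise_sd < 0 || d13c_noise_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (frame_size < 16) {
    stop("'frame_size' must be >= 16 to hold the nest mask", call. = FALSE)
  }
  if (!all(vapply(sources, inherits, logical(1), "source_event"))) {
    stop("'sources' must be a list of source_event objects", call. = FALSE)
  }
  w <- default_weather_params()
  w[names(weather)] <- weather
  structure(
    list(duration = duration, gas_rate = gas_rate,
         background_ch4 = background_ch4, background_d13c = background_d13c,
         sources = sources, ch4_noise_sd = ch4_noise_sd,
         d13c_noise_sd = d13c_noise_sd, ch4_floor = ch4_floor,
         weather_interval = weather_interval, weather = w,
         tide_constituents = tide_constituents, quake_list = quake_list,
         frame_rate = frame_rate, frame_size = as.integer(frame_size),
         n_ants = as.integer(n_ants), jitter_px = as.integer(jitter_px),
         day_start = day_start, day_end = day_end,
         start = as_utc(start), seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# Eight overnight injection events, one per campaign night, all inside the
# 17:39-06:54 UTC window in which significant nest-gas peaks occur.
overnight_events <- function(d13c_source, peak_excess = NULL) {
  hours <- c(18.0, 26.2, 20.8, 23.5, 19.4, 28.6, 22.1, 18.9)
  if (is.null(peak_excess)) {
    peak_excess <- c(0.5, 0.7, 0.9, 1.1, 0.6, 0.8, 1.0, 1.2)
  }
  d13c_source <- rep_len(d13c_source, 8L)
  peak_excess <- rep_len(peak_excess, 8L)
  lapply(seq_len(8L), function(i) {
    source_event(d13c_source = d13c_source[i],
                 start = ((i - 1) * 24 + hours[i]) * 3600,
                 duration = 3600,
                 peak_excess = peak_excess[i],
                 shape = "gaussian")
  })
}

#' Named campaign scenario presets
#'
#' Shipped presets define the reference study conditions used throughout the
#' test-suite and examples:
#' \describe{
#'   \item{`"microbial-default"`}{8-day, 1-Hz campaign with eight overnight
#'     injection events of microbial methane (source signature -69 permil)
#'     and instrument-level noise.}
#'   \item{`"fault-default"`}{same schedule with fault-related methane
#'     (source signature -37 permil).}
#'   \item{`"two-source"`}{four microbial and four fault-related events,
#'     interleaved, for intercept-clustering exercises.}
#'   \item{`"null-default"`}{1-day campaign with no sources: background and
#'     instrument noise only, for false-positive calibration.}
#' }
#'
#' @param name preset name.
#' @param seed optional integer seed overriding the preset default.
#' @param ... further arguments overriding [scenario_config()] defaults.
#' @return a [scenario_config()] object.
#' @export
scenario_preset <- function(name = c("microbial-default", "fault-default",
                                     "two-source", "null-default"),
                            seed = NULL, ...) {
  name <- match.arg(name)
  args <- switch(
    name,
    "microbial-default" = list(sources = overnight_events(-69)),
    "fault-default" = list(sources = overnight_events(-37)),
    "two-source" = list(
      sources = overnight_events(rep(c(-69, -37), 4L))
    ),
    "null-default" = list(sources = list(), duration = 86400)
  )
  dots <- list(...)
  args[names(dots)] <- dots
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(scenario_config, args)
}

# CH4 excess (ppm) contributed by one event at offsets `t` (seconds).
event_excess <- function(ev, t) {
  u <- t - ev$start
  inside <- u >= 0 & u <= ev$duration
  out <- numeric(length(t))
  if (!any(inside)) return(out)
  ui <- u[inside]
  out[inside] <- switch(
    ev$shape,
    boxcar = rep(ev$peak_excess, length(ui)),
    triangular = ev$peak_excess * (1 - abs(2 * ui / ev$duration - 1)),
    gaussian = ev$peak_excess *
      exp(-((ui - ev$duration / 2)^2) / (2 * (ev$duration / 6)^2))
  )
  out
}

#' Simulate nest and ambient gas series under two-reservoir mixing
#'
#' Generates the 1-Hz (configurable) nest-gas channel and a sparse ambient
#' channel. The noiseless nest concentration is the background plus the sum
#' of the configured source excesses; the noiseless isotope ratio follows
#' exact two-reservoir mass balance,
#' \deqn{\delta_{obs}(t) = \frac{C_a\,\delta_a + \sum_i C_{x,i}(t)\,
#'   \delta_{s,i}}{C_a + \sum_i C_{x,i}(t)},}
#' so that for a single source the points \eqn{(1/C_{obs}, \delta_{obs})}
#' lie exactly on the Keeling line with intercept \eqn{\delta_s}.
#' I.i.d. Gaussian noise is then added per channel. The ambient channel
#' (background + noise only) is sampled for 15 minutes every 4 hours,
#' matching the analyser's valve schedule.
#'
#' @param config a [scenario_config()].
#' @return a data.frame of class `gas_series` with columns `timestamp`
#'   (POSIXct UTC), `ch4` (ppm), `d13c` (permil) and `channel`
#'   (`"nest"`/`"ambient"`). Ground truth is attached as attribute `truth`:
#'   a list with per-sample noiseless `ch4_true`/`d13c_true`, the per-sample
#'   total `excess`, and an `events` table with the scheduled windows.
#' @export
simulate_gas <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- floor(config$duration * config$gas_rate)
  t <- (seq_len(n) - 1) / config$gas_rate
  ca <- config$background_ch4
  da <- config$background_d13c

  num <- rep(ca * da, n)
  excess <- numeric(n)
  for (ev in config$sources) {
    ex <- event_excess(ev, t)
    excess <- excess + ex
    num <- num + ex * ev$d13c_source
  }
  ch4_true <- ca + excess
  d13c_true <- num / ch4_true

  nest <- with_seed(stream_seed(config$seed, 1L), {
    data.frame(
      ch4 = ch4_true + rnorm(n, 0, config$ch4_noise_sd),
      d13c = d13c_true + rnorm(n, 0, config$d13c_noise_sd)
    )
  })
  clipped <- nest$ch4 < config$ch4_floor
  if (any(clipped)) {
    message(sum(clipped), " nest CH4 samples clipped at the ",
            config$ch4_floor, " ppm floor")
    nest$ch4[clipped] <- config$ch4_floor
  }

  # ambient intake: 15 min every 4 h
  amb_idx <- which((t %% 14400) < 900)
  na <- length(amb_idx)
  amb <- with_seed(stream_seed(config$seed, 2L), {
    data.frame(
      ch4 = ca + rnorm(na, 0, config$ch4_noise_sd),
      d13c = da + rnorm(na, 0, config$d13c_noise_sd)
    )
  })
  amb$ch4[amb$ch4 < config$ch4_floor] <- config$ch4_floor

  out <- rbind(
    data.frame(timestamp = config$start + t, ch4 = nest$ch4,
               d13c = nest$d13c, channel = "nest",
               stringsAsFactors = FALSE),
    data.frame(timestamp = config$start + t[amb_idx], ch4 = amb$ch4,
               d13c = amb$d13c, channel = "ambient",
               stringsAsFactors = FALSE)
  )
  events <- if (length(config$sources)) {
    data.frame(
      start = config$start + vapply(config$sources, `[[`, 0, "start"),
      end = config$start + vapply(config$sources, `[[`, 0, "start") +
        vapply(config$sources, `[[`, 0, "duration"),
      d13c_source = vapply(config$sources, `[[`, 0, "d13c_source"),
      peak_excess = vapply(config$sources, `[[`, 0, "peak_excess"),
      shape = vapply(config$sources, `[[`, "", "shape"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(start = config$start[0], end = config$start[0],
               d13c_source = numeric(0), peak_excess = numeric(0),
               shape = character(0))
  }
  attr(out, "truth") <- list(ch4_true = ch4_true, d13c_true = d13c_true,
                             excess = excess, events = events)
  attr(out, "config") <- config
  class(out) <- c("gas_series", "data.frame")
  out
}

#' Simulate weather at the nest site
#'
#' Six variables on a regular grid: temperature is a diurnal sinusoid
#' (afternoon maximum) plus noise; relative humidity is linearly
#' anti-correlated with the temperature anomaly; dew point follows the
#' one-eighth rule from temperature and humidity; pressure swings slowly on a
#' synoptic (3.5-day) period; rainfall is sparse and non-negative; wind speed
#' has a weak diurnal cycle. Parameter defaults reflect an August lowland
#' campaign (mean 16.2 degC, mean pressure 988 hPa, mean wind 1.67 km/h).
#'
#' @param config a [scenario_config()]; weather parameters are taken from
#'   `config$weather` (see [default_weather_params()] names).
#' @return a data.frame of class `weather_series` with columns `timestamp`,
#'   `temperature` (degC), `pressure` (hPa), `dewpoint` (degC),
#'   `humidity` (%), `rainfall` (mm) and `windspeed` (km/h).
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$duration < config$weather_interval) {
    stop("'duration' must be >= 'weather_interval'", call. = FALSE)
  }
  w <- config$weather
  t <- seq(0, config$duration - config$weather_interval,
           by = config$weather_interval)
  h <- (as.numeric(config$start) %% 86400) / 3600 + t / 3600
  n <- length(t)
  with_seed(stream_seed(config$seed, 3L), {
    temperature <- w$temp_mean +
      w$temp_amplitude * cos(2 * pi * (h - 15) / 24) +
      rnorm(n, 0, w$temp_noise_sd)
    humidity <- w$humidity_mean +
      w$humidity_coupling * (temperature - w$temp_mean) +
      rnorm(n, 0, w$humidity_noise_sd)
    humidity <- pmin(100, pmax(0, humidity))
    dewpoint <- temperature - (100 - humidity) / 5
    pressure <- w$pressure_mean +
      w$pressure_amplitude * sin(2 * pi * h / 84) +
      rnorm(n, 0, w$pressure_noise_sd)
    windspeed <- pmax(0, w$wind_mean +
                        0.5 * cos(2 * pi * (h - 14) / 24) +
                        rnorm(n, 0, w$wind_noise_sd))
    rainfall <- rbinom(n, 1, w$rain_prob) * rexp(n, 1 / w$rain_mean)
    out <- data.frame(
      timestamp = config$start + t,
      temperature = temperature, pressure = pressure, dewpoint = dewpoint,
      humidity = humidity, rainfall = rainfall, windspeed = windspeed
    )
    class(out) <- c("weather_series", "data.frame")
    out
  })
}

# Torus-wrapped integer translation of a matrix: content moves `dx` columns
# right and `dy` rows down, i.e. out[r + dy, c + dx] == m[r, c].
shift_matrix <- function(m, dx, dy) {
  nr <- nrow(m)
  nc <- ncol(m)
  rows <- ((seq_len(nr) - 1 - dy) %% nr) + 1
  cols <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  m[rows, cols, drop = FALSE]
}

circular_mask <- function(size, radius_frac = 0.35) {
  ctr <- (size + 1) / 2
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)
  d2 <= (radius_frac * size)^2
}

#' Simulate a camera frame sequence with moving ants and camera jitter
#'
#' Frames are 8-bit-range grayscale matrices: a static textured background,
#' `n_ants` bright 3x3 blobs performing random walks confined to a circular
#' nest mask, and a per-frame global integer translation (camera jitter,
#' uniform on `[-jitter_px, jitter_px]` per axis, torus-wrapped). A day/night
#' sensor flag follows the configured schedule. Ground truth — per-frame
#' jitter and the number of pixels changed by blob motion between consecutive
#' unjittered scenes — is returned alongside, enabling exact validation of
#' registration and activity estimation.
#'
#' @param config a [scenario_config()].
#' @param n_frames number of frames (default `duration * frame_rate`).
#' @param jitter optional `n_frames` x 2 integer matrix of (dx, dy) camera
#'   shifts overriding the random jitter (first frame is conventionally
#'   unshifted when jitter is random).
#' @return a list of class `frame_sequence` with elements `frames` (list of
#'   matrices), `timestamp`, `sensor` (`"day"`/`"night"`), `mask` (logical
#'   matrix), and `truth` (data.frame with `jitter_dx`, `jitter_dy`,
#'   `moved_pixels`).
#' @export
simulate_frames <- function(config, n_frames = NULL, jitter = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_ants < 0) stop("'n_ants' must be >= 0", call. = FALSE)
  s <- config$frame_size
  if (is.null(n_frames)) n_frames <- max(1L, floor(config$duration * config$frame_rate))
  n_frames <- as.integer(n_frames)
  mask <- circular_mask(s)
  if (sum(mask) < 9L) {
    stop("'frame_size' too small: nest mask would be degenerate",
         call. = FALSE)
  }

  with_seed(stream_seed(config$seed, 4L), {
    bg <- 60 + 40 * outer(sin(2 * pi * seq_len(s) / 17),
                          cos(2 * pi * seq_len(s) / 23)) +
      matrix(runif(s * s, 0, 20), s, s)
    bg <- round(pmin(pmax(bg, 0), 255))

    inside <- which(mask, arr.ind = TRUE)
    # keep blob centres one pixel away from the frame border
    inside <- inside[inside[, 1] > 1 & inside[, 1] < s &
                       inside[, 2] > 1 & inside[, 2] < s, , drop = FALSE]
    n_ants <- config$n_ants
    pos <- if (n_ants > 0) {
      inside[sample.int(nrow(inside), n_ants, replace = TRUE), , drop = FALSE]
    } else {
      matrix(integer(0), 0, 2)
    }

    if (is.null(jitter)) {
      j <- config$jitter_px
      if (j > 0) {
        jit <- cbind(
          c(0L, sample(seq(-j, j), n_frames - 1, replace = TRUE)),
          c(0L, sample(seq(-j, j), n_frames - 1, replace = TRUE))
        )
      } else {
        jit <- matrix(0L, n_frames, 2)
      }
    } else {
      jit <- matrix(as.integer(jitter), n_frames, 2)
    }

    paint <- function(scene, pos) {
      for (a in seq_len(nrow(pos))) {
        r <- pos[a, 1]; c <- pos[a, 2]
        scene[(r - 1):(r + 1), (c - 1):(c + 1)] <- 220
      }
      scene
    }

    frames <- vector("list", n_frames)
    moved <- integer(n_frames)
    prev_scene <- NULL
    for (i in seq_len(n_frames)) {
      if (i > 1 && n_ants > 0) {
        for (a in seq_len(n_ants)) {
          step <- sample(-2:2, 2, replace = TRUE)
          cand <- pos[a, ] + step
          ok <- cand[1] > 1 && cand[1] < s && cand[2] > 1 && cand[2] < s &&
            mask[cand[1], cand[2]]
          if (ok) pos[a, ] <- cand
        }
      }
      scene <- paint(bg, pos)
      moved[i] <- if (i == 1) 0L else sum(scene != prev_scene)
      prev_scene <- scene
      frames[[i]] <- shift_matrix(scene, jit[i, 1], jit[i, 2])
    }

    timestamp <- config$start + (seq_len(n_frames) - 1) / config$frame_rate
    hour <- (as.numeric(timestamp) %% 86400) / 3600
    sensor <- ifelse(hour >= config$day_start & hour < config$day_end,
                     "day", "night")
    structure(
      list(frames = frames, timestamp = timestamp, sensor = sensor,
           mask = mask,
           truth = data.frame(jitter_dx = jit[, 1], jitter_dy = jit[, 2],
                              moved_pixels = moved)),
      class = "frame_sequence"
    )
  })
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic campaign configuration\n")
  cat(sprintf("  duration: %.1f days at %g Hz gas sampling\n",
              x$duration / 86400, x$gas_rate))
  cat(sprintf("  background: %.2f ppm CH4, %.1f permil d13C\n",
              x$background_ch4, x$background_d13c))
  cat(sprintf("  sources: %d; noise: %.3f ppm / %.2f permil; seed %d\n",
              length(x$sources), x$ch4_noise_sd, x$d13c_noise_sd, x$seed))
  invisible(x)
}
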