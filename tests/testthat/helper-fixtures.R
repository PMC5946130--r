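# Shared fixture builders. Everything is generated in code under fixed seeds.

# Tiny noiseless single-source scenario for mass-balance arithmetic.
noiseless_boxcar <- function(background_ch4 = 1.9, background_d13c = -47,
                             d13c_source = -69, peak_excess = 1) {
  scenario_config(
    duration = 600, gas_rate = 1,
    background_ch4 = background_ch4, background_d13c = background_d13c,
    sources = list(source_event(d13c_source, start = 100, duration = 200,
                                peak_excess = peak_excess,
                                shape = "boxcar")),
    ch4_noise_sd = 0, d13c_noise_sd = 0, seed = 1
  )
}

# Exact two-reservoir mixing samples across a concentration sweep.
mixing_samples <- function(ca = 1.82, da = -47, ds = -69,
                           excess = seq(0.05, 1.2, length.out = 40)) {
  ch4 <- ca + excess
  d13c <- (ca * da + excess * ds) / ch4
  data.frame(ch4 = ch4, d13c = d13c)
}

# Small random frame pair (iid uniform intensities).
random_frame <- function(n = 16, max_val = 255) {
  matrix(runif(n * n, 0, max_val), n, n)
}

# Independent OLS oracle via the normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Independent type-7 quantile (linear interpolation between order stats).
quantile7_oracle <- function(x, q) {
  xs <- sort(x)
  h <- (length(xs) - 1) * q
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  xs[lo] + (h - floor(h)) * (xs[hi] - xs[lo])
}

# Independent median oracle from sorted order statistics.
median_oracle <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
}

# Independent MI oracle: explicit joint-table enumeration with table().
mi_oracle <- function(a, b, bins) {
  lo <- min(a, b); hi <- max(a, b)
  cut_idx <- function(x) {
    if (hi <= lo) return(rep(1L, length(x)))
    pmin(bins, pmax(1L, 1L + floor((x - lo) / (hi - lo) * bins)))
  }
  ia <- factor(cut_idx(as.numeric(a)), levels = seq_len(bins))
  ib <- factor(cut_idx(as.numeric(b)), levels = seq_len(bins))
  jt <- table(ia, ib) / length(ia)
  pa <- rowSums(jt); pb <- colSums(jt)
  s <- 0
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    if (jt[i, j] > 0) {
      s <- s + jt[i, j] * log2(jt[i, j] / (pa[i] * pb[j]))
    }
  }
  as.numeric(s)
}

# Direct-summation CCF oracle (full-series moments, 1/n normalisation).
ccf_oracle <- function(x, y, max_lag) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(mean((x - mx)^2)); sy <- sqrt(mean((y - my)^2))
  sapply(seq(-max_lag, max_lag), function(l) {
    s <- 0
    for (t in seq_len(n)) {
      if (t + l >= 1 && t + l <= n) {
        s <- s + (x[t] - mx) * (y[t + l] - my)
      }
    }
    s / (n * sx * sy)
  })
}

run_peak_chain <- function(preset, seed, samples = "window") {
  cfg <- scenario_preset(preset, seed = seed)
  g <- simulate_gas(cfg)
  nest <- g[g$channel == "nest", ]
  pk <- coincident_peaks(
    flag_ch4_peaks(nest$ch4, mad_threshold(nest$ch4)),
    flag_d13c_peaks(nest$d13c),
    timestamp = nest$timestamp
  )
  list(nest = nest, peaks = pk,
       keeling = keeling_by_peak(pk, nest$ch4, nest$d13c, samples = samples))
}
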