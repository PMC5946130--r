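test_that("mad_threshold computes median + k * raw MAD", {
  expect_equal(mad_threshold(rep(2.1, 20)), 2.1)          # MAD = 0
  expect_equal(mad_threshold(c(1, 2, 3, 4, 100)), 5)      # median 3, MAD 1
  # reordering invariance
  set.seed(1)
  x <- rnorm(101)
  expect_equal(mad_threshold(x), mad_threshold(sample(x)))
  # bounded under <= 25% contamination with huge values
  xc <- c(x, rep(1e6, 25))
  expect_lt(mad_threshold(xc), mad_threshold(x) + 10)
  expect_error(mad_threshold(c(NA_real_, NaN)), "finite")
  # scaled-MAD convention available as a documented switch
  expect_equal(mad_threshold(c(1, 2, 3, 4, 100), constant = 1.4826),
               3 + 2 * 1.4826)
})

test_that("peak flags implement the strict rules as written", {
  x <- c(1.9, 2.0, 2.5)
  expect_equal(flag_ch4_peaks(x, 3), c(FALSE, FALSE, FALSE))
  expect_equal(flag_ch4_peaks(x, min(x) - 1e-9), c(TRUE, TRUE, TRUE))
  expect_equal(flag_ch4_peaks(x, 2.0), c(FALSE, FALSE, TRUE))  # strict >

  # literal delta rule: < -35 or > 0 permil
  d <- c(-34, -36, 1, -0.5)
  expect_equal(flag_d13c_peaks(d, mode = "literal"),
               c(FALSE, TRUE, TRUE, FALSE))

  # deviation rule flags symmetric excursions beyond k * MAD
  dd <- c(rep(-50, 50), -60, -40)
  fl <- flag_d13c_peaks(dd, mode = "deviation", k = 2)
  expect_true(fl[51] && fl[52])
  expect_false(any(fl[1:50]))
})

test_that("coincident_peaks builds, merges and filters joint windows", {
  # disjoint flag sets: empty
  a <- c(rep(TRUE, 5), rep(FALSE, 15))
  b <- c(rep(FALSE, 15), rep(TRUE, 5))
  expect_equal(nrow(coincident_peaks(a, b, min_run = 1)$windows), 0L)

  # identical flag sets: windows equal the runs of the set
  f <- rep(FALSE, 100)
  f[11:25] <- TRUE
  f[61:80] <- TRUE
  ps <- coincident_peaks(f, f, min_run = 5, min_gap = 10)
  expect_equal(nrow(ps$windows), 2L)
  expect_equal(ps$windows$i_start, c(11L, 61L))
  expect_equal(ps$windows$i_end, c(25L, 80L))
  expect_equal(ps$samples[[1]], 11:25)

  # runs closer than min_gap merge into one window
  g <- rep(FALSE, 100)
  g[11:25] <- TRUE
  g[30:44] <- TRUE
  merged <- coincident_peaks(g, g, min_run = 5, min_gap = 10)
  expect_equal(nrow(merged$windows), 1L)
  expect_equal(merged$windows$i_start, 11L)
  expect_equal(merged$windows$i_end, 44L)

  # persistence: windows without a joint run >= min_run are dropped
  h <- rep(FALSE, 100)
  h[c(11, 13, 15)] <- TRUE
  expect_equal(nrow(coincident_peaks(h, h, min_run = 5)$windows), 0L)

  # tolerance dilation lets near-coincident flags intersect
  p <- rep(FALSE, 50); p[20:30] <- TRUE
  q <- rep(FALSE, 50); q[23:33] <- TRUE
  exact <- coincident_peaks(p, q, min_run = 9)
  expect_equal(nrow(exact$windows), 0L)  # exact overlap 23:30 is only 8 long
  tol <- coincident_peaks(p, q, tolerance = 3, min_run = 11)
  expect_equal(nrow(tol$windows), 1L)
})

test_that("synthetic eight-event scenario yields eight coincident windows", {
  chain <- run_peak_chain("microbial-default", seed = 42)
  expect_equal(nrow(chain$peaks$windows), 8L)
  # windows land on the scheduled injections
  truth <- attr(simulate_gas(scenario_preset("microbial-default", seed = 42)),
                "truth")$events
  truth <- truth[order(truth$start), ]
  expect_true(all(chain$peaks$windows$start >= truth$start - 300))
  expect_true(all(chain$peaks$windows$end <= truth$end + 300))
})

test_that("percentile_summary splits at the type-7 quantile with strict membership", {
  # ten equal values: nothing is strictly above the quantile
  ps0 <- percentile_summary(rep(2, 10))
  expect_equal(ps0$n, c(10L, 0L))

  ps <- percentile_summary(1:100, q = 0.9)
  expect_equal(ps$n[ps$subset == "above_q"], 10L)  # type-7 q90 = 90.1
  expect_equal(ps$mean[ps$subset == "above_q"], mean(91:100))
  expect_equal(ps$mean[ps$subset == "all"], 50.5)
  expect_equal(ps$se[ps$subset == "all"], sd(1:100) / 10)

  # conservation: n_all = n_above + n_below_or_equal, on random data
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(50 + i)
    s <- percentile_summary(x, q = 0.9)
    qv <- attr(s, "quantile_value")
    expect_equal(qv, quantile7_oracle(x, 0.9))
    expect_equal(s$n[1], s$n[2] + sum(x <= qv))
    expect_equal(s$min[1], min(x))
    expect_equal(s$max[1], max(x))
  }
})

test_that("keeling_fit recovers exact mixing intercepts and matches OLS oracle", {
  # analytic two-component mixing: intercept equals the source signature
  for (ds in c(-69, -37)) {
    mx <- mixing_samples(ds = ds)
    kf <- suppressWarnings(keeling_fit(mx$ch4, mx$d13c))
    expect_equal(kf$intercept, ds, tolerance = 1e-9)
    expect_equal(kf$r2, 1, tolerance = 1e-12)
    expect_true(kf$ci95[1] <= kf$intercept && kf$intercept <= kf$ci95[2])
  }

  # normal-equations oracle on noisy data
  set.seed(3)
  for (i in 1:10) {
    ch4 <- runif(30, 1.8, 3)
    d13c <- -50 + rnorm(30)
    kf <- keeling_fit(ch4, d13c)
    beta <- ols_oracle(1 / ch4, d13c)
    expect_equal(unname(c(kf$intercept, kf$slope)), unname(beta),
                 tolerance = 1e-9)
  }
  expect_error(keeling_fit(c(2, 2), c(-50, -50)), "at least 3")
  expect_error(keeling_fit(c(2, 2, 2), c(-50, -51, -49)), "degenerate")
})

test_that("keeling intercept is unbiased under symmetric noise", {
  set.seed(4)
  mx <- mixing_samples(ds = -69, excess = seq(0.1, 1.2, length.out = 50))
  ints <- replicate(200, {
    keeling_fit(mx$ch4, mx$d13c + rnorm(50, 0, 0.8))$intercept
  })
  one_ci <- keeling_fit(mx$ch4, mx$d13c + rnorm(50, 0, 0.8))$ci95
  expect_lt(abs(mean(ints) - (-69)), diff(one_ci))
})

test_that("keeling_by_peak fits per window, pools, and clusters two sources", {
  chain <- run_peak_chain("two-source", seed = 8)
  kb <- chain$keeling
  expect_equal(nrow(kb$per_window), 8L)
  expect_false(is.null(kb$clusters))
  centres <- sort(unique(kb$clusters$centre))
  expect_equal(length(centres), 2L)
  expect_lt(abs(centres[1] - (-69)), 2)
  expect_lt(abs(centres[2] - (-37)), 2)
  # four windows per source
  expect_equal(sort(as.integer(table(kb$clusters$cluster))), c(4L, 4L))
})

test_that("detected-episode Keeling fits cover the configured signature across seeds", {
  covered <- 0L
  runs <- 0L
  for (preset in c("microbial-default", "fault-default")) {
    ds <- if (preset == "microbial-default") -69 else -37
    for (s in 1:12) {
      kf <- run_peak_chain(preset, seed = s)$keeling$pooled
      runs <- runs + 1L
      if (kf$ci95[1] <= ds && ds <= kf$ci95[2]) covered <- covered + 1L
    }
  }
  expect_gte(covered / runs, 0.9)
})

test_that("delta notation formula is exact", {
  expect_equal(delta_from_ratio(0.0112372, 0.0112372), 0)
  expect_equal(delta_from_ratio(0.99 * 0.0112372, 0.0112372), -10)
  expect_equal(delta_from_ratio(1.001 * 0.0112372, 0.0112372), 1)
  expect_error(delta_from_ratio(1, 0), "r_standard")
})

test_that("drift correction removes reference-run offsets", {
  cfg <- scenario_config(duration = 4 * 3600, sources = list(),
                         ch4_noise_sd = 0, d13c_noise_sd = 0, seed = 6)
  g <- simulate_gas(cfg)
  nest <- g[g$channel == "nest", ]

  refs <- data.frame(
    timestamp = nest$timestamp[c(1, nrow(nest))],
    ch4_measured = c(2.0, 2.0), ch4_true = c(2.0, 2.0),
    d13c_measured = c(-40, -40), d13c_true = c(-40, -40)
  )
  expect_equal(drift_correct(nest, refs)$ch4, nest$ch4)  # zero drift: no-op

  # constant +0.05 ppm offset is subtracted everywhere
  refs$ch4_measured <- refs$ch4_true + 0.05
  corr <- drift_correct(nest, refs)
  expect_equal(corr$ch4, nest$ch4 - 0.05)

  # linear drift injected into the measurements is removed
  secs <- as.numeric(nest$timestamp - cfg$start, units = "secs")
  drift <- 0.1 * secs / max(secs)
  drifted <- nest
  drifted$ch4 <- nest$ch4 + drift
  refs2 <- data.frame(
    timestamp = nest$timestamp[c(1, nrow(nest))],
    ch4_measured = 2.0 + c(0, 0.1), ch4_true = c(2.0, 2.0),
    d13c_measured = c(-40, -40), d13c_true = c(-40, -40)
  )
  fixed <- drift_correct(drifted, refs2)
  expect_lt(max(abs(fixed$ch4 - nest$ch4)), 1e-9)

  # implausible reference runs are excluded with a warning
  refs3 <- refs2
  refs3$ch4_measured[2] <- 5
  expect_warning(drift_correct(drifted, refs3), "plausible")
})
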