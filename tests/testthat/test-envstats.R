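make_weather_table <- function(n = 120, seed = 10) {
  # boost the rain probability so short tables still have rainfall variance
  cfg <- scenario_config(duration = n * 300, seed = seed,
                         weather = list(rain_prob = 0.1))
  simulate_weather(cfg)
}

test_that("weather_pca agrees with the correlation-matrix eigendecomposition", {
  w <- make_weather_table()
  p <- weather_pca(w)
  mat <- scale(as.matrix(w[setdiff(names(w), "timestamp")]))
  ev <- eigen(cor(mat))
  # eigenvalue spectrum matches variance shares
  expect_equal(p$cumulative_variance,
               cumsum(ev$values) / sum(ev$values), tolerance = 1e-10)
  # loadings match eigenvectors up to sign
  for (j in 1:6) {
    expect_equal(abs(p$loadings[, j]), abs(ev$vectors[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # deterministic sign: largest-magnitude loading positive
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  # orthonormal loadings; reconstruction reproduces the scaled data
  expect_equal(t(p$loadings) %*% p$loadings, diag(6),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(p$scores %*% t(p$loadings), unclass(mat),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("weather_pca PC-1 captures a shared variance direction and errors on constants", {
  set.seed(11)
  n <- 100
  shared <- rnorm(n)
  tab <- data.frame(a = shared + rnorm(n, 0, 0.05),
                    b = -shared + rnorm(n, 0, 0.05),
                    c = rnorm(n), d = rnorm(n), e = rnorm(n), f = rnorm(n))
  p <- weather_pca(tab)
  expect_gt(sum(abs(p$loadings[c("a", "b"), 1])), 1.2)
  tab$c <- 1
  expect_error(weather_pca(tab), "c")
})

test_that("pc_regression_anova is sequential and exact on constructed responses", {
  w <- make_weather_table(n = 200, seed = 12)
  p <- weather_pca(w)
  # y = 2 * PC1 exactly
  y <- 2 * p$scores[, 1]
  a <- suppressWarnings(pc_regression_anova(y, p))
  expect_equal(a$r2, 1, tolerance = 1e-12)
  expect_equal(a$table$estimate[1], 2, tolerance = 1e-10)
  expect_lt(a$table$ms[2], 1e-18)
  expect_lt(a$table$ms[3], 1e-18)

  # sequential SS identity: term SSs + residual SS = total SS
  set.seed(13)
  y2 <- rnorm(nrow(p$scores))
  a2 <- pc_regression_anova(y2, p)
  expect_equal(sum(a2$table$ss), sum((y2 - mean(y2))^2), tolerance = 1e-10)
  expect_equal(a2$table$df[4], a2$n - 3 - 1)
  expect_true(a2$r2 >= 0 && a2$r2 <= 1)

  # independent-noise response: r2 near 0, F near 1 on average over seeds
  set.seed(14)
  stats <- replicate(200, {
    yy <- rnorm(nrow(p$scores))
    aa <- pc_regression_anova(yy, p)
    c(aa$r2, mean(aa$table$f[1:3]))
  })
  expect_lt(mean(stats[1, ]), 0.05)
  expect_lt(abs(mean(stats[2, ]) - 1), 0.25)
})

test_that("additive decomposition satisfies its identities and recovers components", {
  # repeated sinusoid: seasonal carries the cycle, trend flat, residual ~ 0
  period <- 48
  x <- rep(sin(2 * pi * seq_len(period) / period), 6)
  d <- additive_decompose(x, period, trend_method = "moving_average")
  ok <- !is.na(d$trend)
  expect_equal(d$observed[ok],
               (d$trend + d$seasonal + d$residual)[ok], tolerance = 1e-12)
  expect_lt(max(abs(d$trend[ok])), 1e-10)
  expect_lt(max(abs(d$residual[ok])), 1e-10)
  expect_equal(d$seasonal[seq_len(period)],
               sin(2 * pi * seq_len(period) / period), tolerance = 1e-10)
  # seasonal sums to ~0 over one period
  expect_lt(abs(sum(d$seasonal[seq_len(period)])), 1e-10)

  # pure linear ramp: trend is the ramp, seasonal ~ 0
  ramp <- seq(0, 10, length.out = 6 * period)
  dr <- additive_decompose(ramp, period, trend_method = "polynomial",
                           poly_degree = 2)
  expect_lt(max(abs(dr$seasonal)), 1e-8)
  expect_equal(dr$trend, ramp, tolerance = 1e-6)

  # ramp + daily square wave + noise: components recovered within noise
  set.seed(15)
  square <- rep(c(rep(2, period / 2), rep(-2, period / 2)), 8)
  xt <- seq(0, 5, length.out = 8 * period) + square + rnorm(8 * period, 0, 0.3)
  dd <- additive_decompose(xt, period, trend_method = "polynomial",
                           poly_degree = 3)
  expect_equal(dd$observed, dd$trend + dd$seasonal + dd$residual,
               tolerance = 1e-12)
  expect_lt(max(abs(dd$seasonal[seq_len(period)] - square[seq_len(period)])),
            4 * 0.3)
  expect_lt(sd(dd$residual), 0.6)

  expect_error(additive_decompose(x, period = 4 * period), "half")
})

test_that("cross_correlation matches its convention, the oracle, and stats::ccf", {
  set.seed(16)
  x <- rnorm(80)
  # self-correlation at lag 0 is exactly 1
  cc <- cross_correlation(x, x, max_lag = 5)
  expect_equal(cc$r[cc$lag == 0], 1)
  expect_true(all(abs(cc$r) <= 1 + 1e-12))

  # shift identity: y[t] = x[t + k] peaks at lag -k
  for (k in 1:4) {
    n <- length(x)
    y <- c(x[(1 + k):n], rnorm(k))
    cs <- cross_correlation(x, y, max_lag = 6)
    expect_equal(cs$lag[which.max(cs$r)], -k)
  }

  # direct-summation oracle and stats::ccf agreement on random pairs
  for (i in 1:5) {
    a <- rnorm(60)
    b <- rnorm(60)
    got <- cross_correlation(a, b, max_lag = 8)
    expect_equal(got$r, ccf_oracle(a, b, 8), tolerance = 1e-12)
    ref <- ccf(a, b, lag.max = 8, plot = FALSE, demean = TRUE)
    # stats::ccf(a, b) at lag k estimates cor(a[t+k], b[t]) = our r(-k)
    expect_equal(got$r, rev(drop(ref$acf)), tolerance = 1e-10)
  }
  expect_error(cross_correlation(rep(1, 50), rnorm(50), 3), "variance")
  expect_error(cross_correlation(rnorm(20), rnorm(20), 15), "short")
})

test_that("gaussian_kde2d integrates to one and finds the right modes", {
  set.seed(17)
  # single tight cluster: unimodal, peaked at the centroid
  pts <- cbind(rnorm(200, 5, 0.1), rnorm(200, -3, 0.1))
  kd <- gaussian_kde2d(pts, n = 48)
  wx <- rep(1, length(kd$x)); wx[c(1, length(wx))] <- 0.5
  wy <- rep(1, length(kd$y)); wy[c(1, length(wy))] <- 0.5
  integral <- sum(outer(wx, wy) * kd$z) * diff(kd$x[1:2]) * diff(kd$y[1:2])
  expect_equal(integral, 1, tolerance = 1e-3)
  peak <- which(kd$z == max(kd$z), arr.ind = TRUE)
  expect_lt(abs(kd$x[peak[1]] - mean(pts[, 1])), 0.1)
  expect_lt(abs(kd$y[peak[2]] - mean(pts[, 2])), 0.1)

  # direct double-sum oracle at a few grid nodes (product Gaussian kernel)
  h <- kd$h
  for (ij in list(c(10, 12), c(24, 24), c(40, 30))) {
    direct <- mean(dnorm((kd$x[ij[1]] - pts[, 1]) / h[1]) *
                     dnorm((kd$y[ij[2]] - pts[, 2]) / h[2])) / (h[1] * h[2])
    expect_equal(kd$z[ij[1], ij[2]], direct, tolerance = 3e-3)
  }

  # two well-separated clusters: two local maxima along the x profile
  pts2 <- rbind(cbind(rnorm(150, 0, 0.2), rnorm(150, 0, 0.2)),
                cbind(rnorm(150, 6, 0.2), rnorm(150, 0, 0.2)))
  kd2 <- gaussian_kde2d(pts2, n = 64)
  prof <- apply(kd2$z, 1, max)
  is_peak <- which(diff(sign(diff(prof))) == -2) + 1
  expect_equal(length(is_peak), 2L)

  # degenerate bandwidth falls back to a diagonal bandwidth with a warning
  pts3 <- cbind(rep(1, 30), rnorm(30))
  expect_warning(kd3 <- gaussian_kde2d(pts3), "bandwidth")
  expect_true(all(is.finite(kd3$z)))
})
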