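# Windowing, filtering, decimation and the four connectivity estimators.

test_that("windowing uses floor division and drops the remainder", {
  set.seed(500)
  r <- recording(matrix(rnorm(2 * 256), 2), 250)
  expect_length(split_windows(r, 128), 2L)

  r2 <- recording(matrix(rnorm(2 * 127), 2), 250)
  expect_warning(w <- split_windows(r2, 128), "no windows")
  expect_length(w, 0L)

  r3 <- recording(matrix(rnorm(2 * 1000), 2), 250)
  w3 <- split_windows(r3, 128)
  expect_length(w3, 7L)
  expect_true(all(vapply(w3, function(x) ncol(x$data), integer(1)) == 128L))
})

test_that("absolute Pearson weights match the covariance-formula oracle", {
  x <- c(1.2, -0.7, 0.3, 2.1, -1.5, 0.9, 0.1, -0.4)
  y <- c(0.5, -1.1, 0.8, 1.9, -0.9, 1.3, -0.2, 0.2)
  r <- recording(rbind(x, y), 100)
  w <- pearson_abs(r)
  oracle <- abs(sum((x - mean(x)) * (y - mean(y))) /
                  sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_equal(w$weights[1, 2], oracle)
  expect_false(w$directed)

  expect_equal(pearson_abs(recording(rbind(x, x), 1))$weights[1, 2], 1)
  expect_equal(pearson_abs(recording(rbind(x, -x), 1))$weights[1, 2], 1)
})

test_that("zero-variance channels are rejected by name", {
  r <- recording(rbind(rnorm(10), rep(1, 10)), 1,
                 channel_labels = c("Fp1", "Cz"))
  expect_error(pearson_abs(r), "Cz")
})

test_that("estimators are invariant to channel offset; Pearson to rescaling", {
  set.seed(501)
  x <- rnorm(64); y <- 0.5 * x + rnorm(64)
  base <- pearson_abs(recording(rbind(x, y), 1))$weights[1, 2]
  expect_equal(pearson_abs(recording(rbind(x + 5, y - 2), 1))$weights[1, 2],
               base)
  expect_equal(pearson_abs(recording(rbind(3 * x, 0.1 * y), 1))$weights[1, 2],
               base)
  gb <- granger_neglog10p(recording(rbind(x, y), 1))$weights
  gs <- granger_neglog10p(recording(rbind(x + 10, y + 3), 1))$weights
  expect_equal(gs, gb)
})

test_that("Granger weights recover the causal direction and the F oracle", {
  set.seed(502)
  n <- 512
  x <- rnorm(n + 1)
  y <- numeric(n + 1)
  for (t in 2:(n + 1)) y[t] <- 0.8 * x[t - 1] + rnorm(1)
  r <- recording(rbind(x, y), 1, channel_labels = c("x", "y"))
  w <- granger_neglog10p(r, order = 1)
  expect_true(w$directed)
  expect_gt(w$weights[1, 2], w$weights[2, 1])

  # independent oracle: F statistic from restricted/unrestricted residual SS
  # (same estimation window as the estimator: t = 2..n+1 with lag 1)
  yt <- y[2:(n + 1)]; yl <- y[1:n]; xl <- x[1:n]
  rss_r <- sum(resid(lm(yt ~ yl))^2)
  rss_f <- sum(resid(lm(yt ~ yl + xl))^2)
  fstat <- (rss_r - rss_f) / (rss_f / (length(yt) - 3))
  p_oracle <- pf(fstat, 1, length(yt) - 3, lower.tail = FALSE)
  expect_equal(w$weights[1, 2], -log10(p_oracle), tolerance = 1e-8)
})

test_that("mutual information matches independence and the Gaussian closed form", {
  set.seed(503)
  r_ind <- recording(rbind(runif(1024), runif(1024)), 1)
  mi0 <- mutual_information(r_ind, k = 3)$weights[1, 2]
  expect_lt(mi0, 0.05)

  rho <- 0.9
  x <- rnorm(4096); y <- rho * x + sqrt(1 - rho^2) * rnorm(4096)
  w <- mutual_information(recording(rbind(x, y), 1), k = 3)$weights
  expect_lt(abs(w[1, 2] - (-0.5 * log(1 - rho^2))), 0.1)
  expect_identical(w[1, 2], w[2, 1])
})

test_that("transfer entropy matches the linear-Gaussian identity and is directed", {
  set.seed(504)
  n <- 4096
  x <- rnorm(n + 1); y <- numeric(n + 1)
  for (t in 2:(n + 1)) y[t] <- 0.4 * y[t - 1] + 0.5 * x[t - 1] + rnorm(1)
  r <- recording(rbind(x, y), 1)
  w <- transfer_entropy(r, history = 1, k = 3)$weights

  yt <- y[2:(n + 1)]; yl <- y[1:n]; xl <- x[1:n]
  rss_r <- sum(resid(lm(yt ~ yl))^2)
  rss_f <- sum(resid(lm(yt ~ yl + xl))^2)
  te_oracle <- 0.5 * log(rss_r / rss_f)
  expect_lt(abs(w[1, 2] - te_oracle), 0.1)
  expect_false(isTRUE(all.equal(w[1, 2], w[2, 1])))
  expect_gt(w[1, 2], w[2, 1])

  r0 <- recording(rbind(rnorm(4096), rnorm(4096)), 1)
  expect_lt(transfer_entropy(r0)$weights[1, 2], 0.05)
})

test_that("band-pass filtering passes the band and stops the rest", {
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)[-1]
  rms <- function(x) sqrt(mean(x^2))
  tone <- function(f) sin(2 * pi * f * t)
  r10 <- recording(rbind(tone(10), tone(10)), fs)
  out10 <- bandpass_filter(r10, "alpha")
  expect_gt(rms(out10$data[1, ]) / rms(r10$data[1, ]), 0.9)

  r2 <- recording(rbind(tone(2), tone(2)), fs)
  out2 <- bandpass_filter(r2, "alpha")
  expect_lt(rms(out2$data[1, ]) / rms(r2$data[1, ]), 0.1)

  z <- recording(matrix(0, 2, 500), fs)
  expect_equal(bandpass_filter(z, c(8, 13))$data, matrix(0, 2, 500))

  expect_error(bandpass_filter(r2, c(30, 200)), "Nyquist|high")
  expect_error(bandpass_filter(r2, "sigma"), "unknown band")
})

test_that("stride decimation keeps every k-th sample and rescales the rate", {
  set.seed(505)
  r <- recording(matrix(rnorm(2 * 1280), 2), 256)
  d <- decimate_by_stride(r, 128)
  expect_identical(ncol(d$data), 10L)
  expect_equal(d$sampling_rate, 2)
  expect_equal(d$data[1, ], r$data[1, seq(1, 1280, by = 128)])

  expect_identical(decimate_by_stride(r, 1)$data, r$data)
  expect_error(decimate_by_stride(r, 2000), "exceeds")
})

test_that("reconstruction yields one matrix per window with group structure", {
  set.seed(506)
  r <- recording(matrix(rnorm(4 * 300), 4), 100)
  g <- reconstruct_networks(r, metric = "pearson", tau = 100)
  expect_s3_class(g, "network_group")
  expect_length(g, 3L)
  expect_false(g$members[[1]]$directed)
  gd <- reconstruct_networks(r, metric = "granger", tau = 100)
  expect_true(gd$members[[1]]$directed)
})
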