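test_that("window enumeration matches floor((T - w)/step) + 1", {
  ws <- window_spec(12, 1, "hamming", 2.4)
  expect_identical(nrow(enumerate_windows(212, ws)), 201L)
  expect_identical(nrow(enumerate_windows(12, ws)), 1L)
  ws2 <- window_spec(10, 1, "rectangular", 2)
  # enumeration oracle: count the starts directly
  expect_identical(nrow(enumerate_windows(100, ws2)),
                   length(seq(0, 100 - 10, by = 1)))
  w <- enumerate_windows(20, ws)
  expect_true(all(w[, "end"] - w[, "start"] == 12))
  expect_identical(unname(w[1, "start"]), 0L)
  expect_error(enumerate_windows(10, ws), "window width")
})

test_that("the 1/w high-pass removes drift and keeps in-band structure", {
  tr <- 2.4; n <- 212
  const <- roi_signals(cbind(a = rep(3, n) + 1e-9 * rnorm(n)), tr)
  expect_lt(max(abs(highpass_roi(const)$data)), 1e-6)

  # FFT oracle: 0.0098 Hz (below 1/28.8) suppressed, 0.0708 Hz preserved
  s <- roi_signals(cbind(lo = bin_sinusoid(5, n, tr),
                         hi = bin_sinusoid(36, n, tr)), tr)
  h <- highpass_roi(s)
  expect_lt(fft_amplitude(h$data[, 1], 5), 0.20)
  expect_gt(fft_amplitude(h$data[, 2], 36), 0.90)
})

test_that("tapered windowed correlation matches the weighted-Pearson oracle", {
  set.seed(5)
  tr <- 2.4
  x <- matrix(rnorm(40 * 4), 40, 4)
  s <- roi_signals(x, tr)
  ws <- window_spec(12, 1, "hamming", tr)
  dfc <- windowed_fc(s, ws)

  # independent oracle with explicit sum-of-weights formulas
  wts <- 0.54 - 0.46 * cos(2 * pi * (0:11) / 11)
  wts <- wts / sum(wts)
  oracle_r <- function(seg, i, j) {
    xi <- seg[, i] - sum(wts * seg[, i])
    xj <- seg[, j] - sum(wts * seg[, j])
    sum(wts * xi * xj) / sqrt(sum(wts * xi^2) * sum(wts * xj^2))
  }
  max_err <- 0
  for (k in seq_len(nrow(dfc$values))) {
    seg <- x[k:(k + 11), ]
    m <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      m <- m + 1
      max_err <- max(max_err, abs(tanh(dfc$values[k, m]) - oracle_r(seg, i, j)))
    }
  }
  expect_lt(max_err, 1e-10)
})

test_that("a full-length rectangular window degenerates to static FC", {
  set.seed(7)
  s <- roi_signals(matrix(rnorm(50 * 5), 50, 5), 2.4)
  ws <- window_spec(50, 1, "rectangular", 2.4)
  dfc <- windowed_fc(s, ws)
  expect_identical(nrow(dfc$values), 1L)
  expect_equal(unname(dfc$values[1, ]),
               unname(vectorize_fc(fisher_z(pearson_fc(s)))),
               tolerance = 1e-14)
})

test_that("duplicated regions pin every window at the clipped z ceiling", {
  set.seed(8)
  x <- rnorm(30)
  s <- roi_signals(cbind(x, x), 2.4)
  dfc <- windowed_fc(s, window_spec(12, 1, "hamming", 2.4))
  expect_true(all(abs(dfc$values - atanh(1 - 1e-7)) < 1e-8))
})

test_that("the 1/w low-pass smooths the connectivity series", {
  tr <- 2.4
  ws <- window_spec(12, 1, "hamming", tr)
  W <- 201
  const <- dfc_series(matrix(2, W, 3), ws, 0:(W - 1), c("a", "b", "c"))
  lc <- lowpass_fc_series(const)
  expect_true(lc$lowpass_applied)
  expect_equal(unname(lc$values), matrix(2, W, 3), tolerance = 1e-9)
  expect_error(lowpass_fc_series(lc), "already applied")

  # FFT oracle: slow component (bin 4 ~ period 120 s) survives, the
  # alternating window-to-window component dies
  slow <- bin_sinusoid(4, W, tr)
  alt <- cos(pi * (0:(W - 1)))
  d <- dfc_series(cbind(slow, alt, alt), ws, 0:(W - 1), c("a", "b", "c"))
  dl <- lowpass_fc_series(d)
  expect_gt(fft_amplitude(dl$values[, 1], 4), 0.90)
  expect_lt(max(abs(dl$values[, 2])), 0.15)

  # very short series fall back to FFT masking
  short <- dfc_series(matrix(rnorm(18), 6, 3), ws, 0:5, c("a", "b", "c"))
  expect_message(lowpass_fc_series(short), "FFT mask")
})

test_that("variability metrics follow their closed forms", {
  ws <- window_spec(12, 1, "hamming", 2.4)
  lab <- c("a", "b", "c")

  # constant series: str = c, sd = 0, alff = 0
  d <- dfc_series(matrix(1.3, 40, 3), ws, 0:39, lab, lowpass_applied = TRUE)
  sm <- summarize_dfc(d)
  expect_equal(sm$str, rep(1.3, 3))
  expect_equal(sm$sd, rep(0, 3))
  expect_equal(sm$alff, rep(0, 3))

  # hand formula: sd of (0,1,0,1) with denominator n-1 is sqrt(1/3);
  # the ALFF band is widened so the 4-point series has bins to average
  d2 <- dfc_series(matrix(c(0, 1, 0, 1), 4, 3), ws, 0:3, lab,
                   lowpass_applied = TRUE)
  sd2 <- summarize_dfc(d2, alff_band_hz = 0.2)$sd
  expect_equal(sd2, rep(sqrt(1/3), 3), tolerance = 1e-6)
  expect_equal(sd2, rep(0.57735, 3), tolerance = 1e-5)

  # FFT linearity: doubling an in-band amplitude doubles ALFF-FC
  W <- 100
  f_inband <- 2 / (W * 2.4)  # bin 2, inside (0, 1/28.8]
  base <- sin(2 * pi * f_inband * (0:(W - 1)) * 2.4)
  d3 <- dfc_series(cbind(0.5 + base, 0.5 + 2 * base, base), ws, 0:(W - 1),
                   lab, lowpass_applied = TRUE)
  sm3 <- summarize_dfc(d3)
  expect_equal(sm3$alff[2], 2 * sm3$alff[1], tolerance = 1e-9)

  expect_error(summarize_dfc(dfc_series(matrix(1, 2, 3), ws, 0:1, lab,
                                        lowpass_applied = TRUE),
                             alff_band_hz = 0.2),
               "at least 3")
  expect_error(summarize_dfc(dfc_series(matrix(1, 5, 3), ws, 0:4, lab)),
               "lowpass")
})

test_that("metrics respond to constant offsets as mean/deviation statistics", {
  set.seed(11)
  ws <- window_spec(12, 1, "hamming", 2.4)
  vals <- matrix(rnorm(60 * 3), 60, 3)
  d <- dfc_series(vals, ws, 0:59, c("a", "b", "c"), lowpass_applied = TRUE)
  d_shift <- dfc_series(vals + 5, ws, 0:59, c("a", "b", "c"),
                        lowpass_applied = TRUE)
  a <- summarize_dfc(d); b <- summarize_dfc(d_shift)
  expect_equal(b$str, a$str + 5, tolerance = 1e-12)
  expect_equal(b$sd, a$sd, tolerance = 1e-12)
  expect_equal(b$alff, a$alff, tolerance = 1e-10)
})

test_that("region permutation permutes connection metrics consistently", {
  set.seed(13)
  x <- matrix(rnorm(80 * 5), 80, 5)
  s <- roi_signals(x, 2.4, region_labels = c("A", "B", "C", "D", "E"))
  perm <- c(3, 1, 5, 2, 4)
  sp <- roi_signals(x[, perm], 2.4, region_labels = c("A", "B", "C", "D", "E")[perm])
  sm <- dfc_pipeline(s)$summary
  smp <- dfc_pipeline(sp)$summary
  # match by pair label irrespective of orientation
  canon <- function(df) {
    parts <- strsplit(df$connection, "--")
    df$connection <- vapply(parts, function(p) paste(sort(p), collapse = "--"), "")
    df[order(df$connection), ]
  }
  a <- canon(sm); b <- canon(smp)
  expect_equal(a$connection, b$connection)
  expect_equal(a$sd, b$sd, tolerance = 1e-10)
  expect_equal(a$str, b$str, tolerance = 1e-10)
})

test_that("wider windows damp the variability of white-noise DFC", {
  set.seed(17)
  x <- matrix(rnorm(300 * 15), 300, 15)  # 105 connections
  s <- roi_signals(x, 2.4)
  med_sd <- sapply(c(8, 12, 20), function(w) {
    ws <- window_spec(w, 1, "hamming", 2.4)
    d <- lowpass_fc_series(windowed_fc(highpass_roi(s, ws$cutoff_hz), ws))
    median(summarize_dfc(d)$sd)
  })
  expect_true(all(diff(med_sd) < 0))
})
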