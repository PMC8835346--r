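test_that("initial volume discard trims exactly the dummy scans", {
  s <- rand_signals(217, 3)
  expect_identical(nrow(discard_initial(s, 5)$data), 212L)
  expect_identical(discard_initial(s, 0), s)
  expect_error(discard_initial(rand_signals(10, 2), 10), "cannot discard")
})

test_that("framewise displacement follows the Power convention", {
  zero <- motion_trace(matrix(0, 10, 6))
  expect_identical(compute_fd(zero)$fd, rep(0, 10))

  # a 0.2 mm x-translation step between frames 4 and 5
  p <- matrix(0, 10, 6)
  p[5:10, 1] <- 0.2
  fd <- compute_fd(motion_trace(p))$fd
  expect_equal(fd[5], 0.2)
  expect_equal(fd[-5], rep(0, 9))

  # a 0.004 rad rotation on a 50 mm sphere is also 0.2 mm of arc
  p <- matrix(0, 10, 6)
  p[5:10, 4] <- 0.004
  expect_equal(compute_fd(motion_trace(p))$fd[5], 0.2)

  # FD depends only on differences: constant offsets are invisible
  set.seed(4)
  p <- matrix(rnorm(60), 10, 6)
  shifted <- sweep(p, 2, rnorm(6), "+")
  expect_equal(compute_fd(motion_trace(p))$fd,
               compute_fd(motion_trace(shifted))$fd)

  p[3, 2] <- NA
  expect_error(compute_fd(motion_trace(p)), "frame 3")
})

test_that("scrubbing replaces only flagged frames by spline interpolation", {
  n <- 30
  lin <- roi_signals(cbind(a = as.numeric(1:n), b = 2 * (1:n) + 3), 2.4)
  fd <- rep(0, n)

  out <- scrub_interpolate(lin, fd)
  expect_identical(out$data, lin$data)
  expect_length(attr(out, "flagged"), 0)

  # natural cubic spline through collinear points is the line itself
  fd[10] <- 0.5
  out <- scrub_interpolate(lin, fd)
  expect_identical(attr(out, "flagged"), 10L)
  expect_equal(out$data[10, ], c(a = 10, b = 23))
  expect_identical(out$data[-10, ], lin$data[-10, ])  # untouched elsewhere

  # flagged run at the end takes the nearest surviving value
  fd <- rep(0, n); fd[c(29, 30)] <- 0.5
  out <- scrub_interpolate(lin, fd)
  expect_equal(unname(out$data[29, 1]), 28)
  expect_equal(unname(out$data[30, 1]), 28)

  expect_warning(scrub_interpolate(lin, rep(0.5, n)), "unusable")
})

test_that("scrubbing is idempotent", {
  set.seed(9)
  s <- rand_signals(40, 3)
  fd <- rep(0, 40); fd[c(7, 20, 21)] <- 0.4
  once <- scrub_interpolate(s, fd)
  twice <- scrub_interpolate(once, fd)
  expect_identical(twice$data, once$data)
})

test_that("Friston-24 expansion uses a zero-padded one-volume lag", {
  set.seed(2)
  p <- matrix(rnorm(30), 5, 6)
  f24 <- friston24(p)
  expect_identical(dim(f24), c(5L, 24L))
  expect_identical(unname(f24[1, 7:12]), rep(0, 6))
  expect_identical(unname(f24[2:5, 7:12]), unname(p[1:4, ]))
  expect_identical(unname(f24[, 13:18]), unname(p^2))
})

test_that("nuisance regression matches the normal-equations oracle", {
  set.seed(8)
  n <- 60
  mot <- motion_trace(matrix(rnorm(n * 6, sd = 0.05), n, 6))
  extra <- matrix(rnorm(n * 2), n, 2)
  s <- rand_signals(n, 4, seed = 8)
  out <- regress_nuisance(s, mot, extra)

  # independent oracle: residuals via explicit pseudoinverse
  X <- cbind(1, friston24(mot$params), extra)
  resid_oracle <- s$data - X %*% (solve(crossprod(X)) %*% crossprod(X, s$data))
  expect_equal(unname(out$data), unname(resid_oracle), tolerance = 1e-8)

  # residuals orthogonal to every design column
  Xn <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  expect_lt(max(abs(crossprod(Xn, out$data))), 1e-8)

  # a signal equal to a motion regressor is annihilated
  s2 <- roi_signals(cbind(mot$params[, 1], rnorm(n)), 2.4)
  out2 <- regress_nuisance(s2, mot)
  expect_lt(max(abs(out2$data[, 1])), 1e-10)

  # regression is idempotent
  expect_equal(regress_nuisance(out, mot, extra)$data, out$data,
               tolerance = 1e-10)

  # collinear columns are dropped with a warning, not an error
  expect_warning(regress_nuisance(s, mot, cbind(extra, extra[, 1])),
                 "collinear")
})

test_that("detrend/band-pass keeps the resting-state band and kills the rest", {
  tr <- 2.4; n <- 212
  ramp <- roi_signals(cbind(a = 5 * (1:n) + 2), tr)
  expect_lt(max(abs(detrend_bandpass(ramp)$data)), 1e-8)

  # FFT oracle at exact bins: 0.0393 Hz is in band, 0.2005 Hz far above
  s <- roi_signals(cbind(inband = bin_sinusoid(20, n, tr),
                         above = bin_sinusoid(102, n, tr)), tr)
  f <- detrend_bandpass(s)
  expect_gt(fft_amplitude(f$data[, 1], 20), 0.95)
  expect_lt(fft_amplitude(f$data[, 2], 102), 0.10)
  expect_lt(abs(mean(f$data[, 1])) / sd(f$data[, 1]), 1e-8)

  expect_error(detrend_bandpass(s, 0.01, 0.30), "Nyquist")
})

test_that("ROI extraction averages voxels within atlas labels", {
  # constant image, one label everywhere
  img <- array(7, dim = c(2, 2, 1, 5))
  atlas <- array(1L, dim = c(2, 2, 1))
  out <- extract_roi_signals(img, atlas, tr_seconds = 2)
  expect_identical(unname(out$data[, 1]), rep(7, 5))

  # two labels carrying known series
  a <- sin(1:5); b <- cos(1:5)
  img <- array(0, dim = c(2, 1, 1, 5))
  img[1, 1, 1, ] <- a; img[2, 1, 1, ] <- b
  atlas <- array(c(1L, 2L), dim = c(2, 1, 1))
  out <- extract_roi_signals(img, atlas, tr_seconds = 2)
  expect_equal(unname(out$data), unname(cbind(a, b)))

  # brute-force per-voxel averaging oracle on a random image
  set.seed(6)
  img <- array(rnorm(4 * 3 * 2 * 6), dim = c(4, 3, 2, 6))
  atlas <- array(sample(0:3, 24, replace = TRUE), dim = c(4, 3, 2))
  out <- extract_roi_signals(img, atlas, tr_seconds = 2)
  for (lab in sort(unique(atlas[atlas != 0]))) {
    oracle <- sapply(1:6, function(t) {
      vol <- img[, , , t]
      mean(vol[atlas == lab])
    })
    expect_equal(unname(out$data[, match(sprintf("roi%d", lab),
                                         out$region_labels)]),
                 oracle, tolerance = 1e-12)
  }
})

test_that("ROI extraction reads NIfTI files and the header TR", {
  dir <- withr::local_tempdir()
  set.seed(10)
  img <- array(rnorm(2 * 2 * 2 * 4), dim = c(2, 2, 2, 4))
  atlas <- array(rep(1:2, each = 4), dim = c(2, 2, 2))
  img_path <- file.path(dir, "bold.nii.gz")
  atlas_path <- file.path(dir, "atlas.nii.gz")
  img_n <- RNifti::asNifti(img)
  RNifti::pixdim(img_n) <- c(3, 3, 3, 2.4)
  RNifti::writeNifti(img_n, img_path)
  RNifti::writeNifti(RNifti::asNifti(atlas), atlas_path)
  out <- extract_roi_signals(img_path, atlas_path)
  expect_equal(out$tr_seconds, 2.4, tolerance = 1e-6)  # float32 header
  expect_equal(unname(out$data[, 1]),
               sapply(1:4, function(t) mean(img[, , , t][atlas == 1])))
})

test_that("the full preprocessing chain runs in the fixed stage order", {
  set.seed(12)
  n <- 217
  mot <- motion_trace(cbind(
    apply(matrix(rnorm(n * 3, sd = 0.01), n, 3), 2, cumsum),
    apply(matrix(rnorm(n * 3, sd = 1e-4), n, 3), 2, cumsum)))
  s <- rand_signals(n, 3, seed = 12)
  out <- preprocess_subject(s, mot)
  expect_identical(nrow(out$signals$data), 212L)
  expect_identical(nrow(out$motion$params), 212L)
  expect_false(is.na(out$mean_fd))
  expect_true(out$usable)
  # per-region centring survives the chain
  expect_lt(max(abs(colMeans(out$signals$data)) /
                  apply(out$signals$data, 2, sd)), 1e-6)
})
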