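#' Sliding-window specification
#'
#' Describes the sliding temporal window used to build dynamic FC: width
#' and step in TR units, taper shape, and the repetition time.  The
#' derived quantities `width_seconds = width_tr * tr_seconds` and
#' `cutoff_hz = 1 / width_seconds` define the 1/w filtering scheme: ROI
#' signals are high-pass filtered at 1/w before windowing, and the
#' windowed connectivity series are low-pass filtered at 1/w afterwards,
#' suppressing fluctuations the window cannot resolve.  The defaults (12
#' TR Hamming window, 1 TR step, TR 2.4 s) give a 28.8 s window and a
#' 0.0347 Hz cutoff.
#'
#' @param width_tr window width in TRs (>= 3), default 12.
#' @param step_tr window step in TRs, default 1.
#' @param taper `"hamming"` or `"rectangular"`.
#' @param tr_seconds repetition time in seconds, default 2.4.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width_tr = 12L, step_tr = 1L,
                        taper = c("hamming", "rectangular"),
                        tr_seconds = 2.4) {
  taper <- match.arg(taper)
  width_tr <- as.integer(width_tr)
  step_tr <- as.integer(step_tr)
  stopifnot(width_tr >= 3L, step_tr >= 1L, tr_seconds > 0)
  structure(list(width_tr = width_tr, step_tr = step_tr, taper = taper,
                 tr_seconds = tr_seconds,
                 width_seconds = width_tr * tr_seconds,
                 cutoff_hz = 1 / (width_tr * tr_seconds)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> width %d TR (%.4g s), step %d TR, %s taper, 1/w = %.4g Hz\n",
              x$width_tr, x$width_seconds, x$step_tr, x$taper, x$cutoff_hz))
  invisible(x)
}

# symmetric Hamming coefficients, a0 = 0.54
hamming_taper <- function(w) {
  0.54 - 0.46 * cos(2 * pi * (0:(w - 1)) / (w - 1))
}

taper_weights <- function(spec) {
  switch(spec$taper,
         hamming = hamming_taper(spec$width_tr),
         rectangular = rep(1, spec$width_tr))
}

#' Dynamic FC series container
#'
#' Windows x connections matrix of Fisher-z connectivity vectors in the
#' canonical pair order of [vectorize_fc()].
#'
#' @param values windows x M numeric matrix.
#' @param spec the [window_spec()] used.
#' @param window_starts 0-based window start indices.
#' @param region_labels region names behind the connection columns.
#' @param lowpass_applied has the 1/w low-pass been applied yet?
#' @param subject_id subject identifier.
#' @return An object of class `dfc_series`.
#' @export
dfc_series <- function(values, spec, window_starts, region_labels,
                       lowpass_applied = FALSE, subject_id = "subj") {
  values <- as.matrix(values)
  stopifnot(inherits(spec, "window_spec"),
            nrow(values) == length(window_starts))
  colnames(values) <- connection_labels(region_labels)
  structure(list(values = values, window_spec = spec,
                 window_starts = as.integer(window_starts),
                 region_labels = region_labels,
                 lowpass_applied = isTRUE(lowpass_applied),
                 subject_id = subject_id),
            class = "dfc_series")
}

#' @export
print.dfc_series <- function(x, ...) {
  cat(sprintf("<dfc_series> subject %s: %d windows x %d connections (low-pass %s)\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              ifelse(x$lowpass_applied, "applied", "pending")))
  invisible(x)
}

#' High-pass filter ROI signals at the window cutoff
#'
#' Zero-phase order-2 Butterworth high-pass at `cutoff_hz` (1/w for the
#' window in use), removing drift slower than the sliding window can
#' track; residual means are subtracted so the output is centred.
#'
#' @param signals a [roi_signals()] object.
#' @param cutoff_hz cutoff in Hz; default `1/28.8` Hz matching the 12-TR,
#'   TR 2.4 s window.
#' @return The filtered [roi_signals()].
#' @export
highpass_roi <- function(signals, cutoff_hz = 1 / 28.8) {
  stopifnot(inherits(signals, "roi_signals"))
  x <- butter_filtfilt(signals$data, signals$tr_seconds, cutoff_hz, "high")
  x <- sweep(x, 2L, colMeans(x))
  colnames(x) <- signals$region_labels
  signals$data <- x
  signals
}

#' Enumerate sliding windows
#'
#' Returns the 0-based half-open `[start, end)` index pairs of every
#' window of `width_tr` samples stepped by `step_tr`:
#' `floor((T - w)/step) + 1` windows in total (201 for 212 volumes with
#' a 12-TR window and 1-TR step).
#'
#' @param n_timepoints number of time points T.
#' @param spec a [window_spec()].
#' @return Integer matrix with columns `start` and `end` (0-based,
#'   half-open), one row per window.
#' @export
enumerate_windows <- function(n_timepoints, spec) {
  stopifnot(inherits(spec, "window_spec"))
  w <- spec$width_tr
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < w) {
    stop("enumerate_windows: ", n_timepoints, " time points < window width ", w)
  }
  starts <- seq.int(0L, n_timepoints - w, by = spec$step_tr)
  cbind(start = starts, end = starts + w)
}

#' Tapered windowed functional connectivity
#'
#' Slides the window over the (high-pass filtered) ROI signals and, in
#' each window, computes the taper-weighted Pearson correlation between
#' every region pair, then Fisher z-transforms with clipping.  Each
#' region's in-window segment is demeaned by its taper-weighted mean and
#' the correlation uses the taper weights:
#' \deqn{r_{ij} = \frac{\sum_t w_t x'_i(t) x'_j(t)}
#'   {\sqrt{\sum_t w_t x'_i(t)^2 \sum_t w_t x'_j(t)^2}}}
#' with \eqn{x' = x - \sum_t w_t x(t) / \sum_t w_t}.  With a rectangular
#' taper spanning the whole series this reduces exactly to
#' `fisher_z(pearson_fc(signals))`.
#'
#' Regions with zero in-window variance yield `NaN` for their pairs in
#' that window (counted in attribute `n_nan_windows`).
#'
#' @param signals a [roi_signals()] object (high-pass filtered per the
#'   pipeline order).
#' @param spec a [window_spec()].
#' @return A [dfc_series()] (low-pass still pending).
#' @export
windowed_fc <- function(signals, spec) {
  stopifnot(inherits(signals, "roi_signals"), inherits(spec, "window_spec"))
  x <- signals$data
  wins <- enumerate_windows(nrow(x), spec)
  wts <- taper_weights(spec)
  wts <- wts / sum(wts)
  n <- ncol(x)
  m <- n * (n - 1L) / 2L
  out <- matrix(NA_real_, nrow(wins), m)
  n_nan <- 0L
  for (k in seq_len(nrow(wins))) {
    seg <- x[(wins[k, "start"] + 1L):wins[k, "end"], , drop = FALSE]
    mu <- colSums(seg * wts)
    segc <- sweep(seg, 2L, mu)
    cc <- crossprod(segc, segc * wts)      # weighted covariance (up to scale)
    v <- diag(cc)
    denom <- sqrt(outer(v, v))
    r <- cc / denom
    if (any(v <= 0)) {
      r[v <= 0, ] <- NaN
      r[, v <= 0] <- NaN
      n_nan <- n_nan + 1L
    }
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    z <- atanh(r)
    out[k, ] <- t(z)[lower.tri(z)]
  }
  res <- dfc_series(out, spec, wins[, "start"], signals$region_labels,
                    lowpass_applied = FALSE, subject_id = signals$subject_id)
  attr(res, "n_nan_windows") <- n_nan
  res
}

#' Low-pass filter the connectivity time series at 1/w
#'
#' Applies a zero-phase order-2 Butterworth low-pass to each connection's
#' window-time series, sampled at `step_tr * tr_seconds`, removing
#' fluctuations faster than the window length can support.  Series too
#' short for the IIR warm-up fall back to FFT-mask filtering with a
#' message.
#'
#' @param dfc a [dfc_series()] with `lowpass_applied = FALSE`.
#' @param cutoff_hz cutoff in Hz; defaults to the spec's `1/w`.
#' @return The filtered [dfc_series()] with `lowpass_applied = TRUE`.
#' @export
lowpass_fc_series <- function(dfc, cutoff_hz = NULL) {
  stopifnot(inherits(dfc, "dfc_series"))
  if (dfc$lowpass_applied) stop("lowpass_fc_series: low-pass already applied")
  if (is.null(cutoff_hz)) cutoff_hz <- dfc$window_spec$cutoff_hz
  dt <- dfc$window_spec$step_tr * dfc$window_spec$tr_seconds
  vals <- dfc$values
  if (nrow(vals) < 12L) {
    message("lowpass_fc_series: ", nrow(vals),
            " windows too short for IIR filtering; using FFT mask")
    vals <- fft_mask_filter(vals, dt, cutoff_hz, "low")
  } else {
    vals <- butter_filtfilt(vals, dt, cutoff_hz, "low")
  }
  colnames(vals) <- colnames(dfc$values)
  dfc$values <- vals
  dfc$lowpass_applied <- TRUE
  dfc
}

#' Temporal-variability summary of a dynamic FC series
#'
#' Collapses each connection's window-time series into the three
#' variability metrics:
#' \describe{
#'   \item{str}{DFC strength — the temporal mean.}
#'   \item{sd}{DFC standard deviation — sample SD (denominator W - 1).}
#'   \item{alff}{ALFF-FC — the mean single-sided FFT amplitude over
#'     frequency bins in (0, 1/w], DC excluded, after mean removal.}
#' }
#' `str` shifts one-for-one under a constant offset of the series while
#' `sd` and `alff` are invariant to it; `alff` is linear in the amplitude
#' of any in-band oscillation.
#'
#' @param dfc a [dfc_series()] with the 1/w low-pass already applied and
#'   at least 3 windows.
#' @param alff_band_hz upper edge of the ALFF band; defaults to the
#'   spec's `1/w`.
#' @return A data frame with columns `connection`, `str`, `sd`, `alff`.
#' @export
summarize_dfc <- function(dfc, alff_band_hz = NULL) {
  stopifnot(inherits(dfc, "dfc_series"))
  if (!dfc$lowpass_applied) {
    stop("summarize_dfc: apply lowpass_fc_series() first (pipeline order)")
  }
  vals <- dfc$values
  n_w <- nrow(vals)
  if (n_w < 3L) stop("summarize_dfc: need at least 3 windows")
  if (is.null(alff_band_hz)) alff_band_hz <- dfc$window_spec$cutoff_hz
  dt <- dfc$window_spec$step_tr * dfc$window_spec$tr_seconds
  bad_rows <- !stats::complete.cases(vals)
  if (any(bad_rows)) {
    message("summarize_dfc: ", sum(bad_rows),
            " window(s) contain non-finite values; excluded from metrics")
    vals <- vals[!bad_rows, , drop = FALSE]
    n_w <- nrow(vals)
    if (n_w < 3L) stop("summarize_dfc: fewer than 3 usable windows")
  }
  str <- colMeans(vals)
  sdv <- apply(vals, 2L, stats::sd)
  freqs <- (seq_len(n_w) - 1) / (n_w * dt)
  band <- which(freqs > 0 & freqs <= alff_band_hz + 1e-12 & freqs <= 1 / (2 * dt))
  if (length(band) == 0) stop("summarize_dfc: no FFT bins in the ALFF band")
  centred <- sweep(vals, 2L, str)
  amp <- 2 * Mod(stats::mvfft(centred)) / n_w
  alff <- colMeans(amp[band, , drop = FALSE])
  data.frame(connection = colnames(vals), str = str, sd = sdv, alff = alff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-call dynamic FC for a subject
#'
#' Runs the fixed 1/w filtering order: high-pass the ROI signals at 1/w,
#' slide the tapered window, low-pass the connectivity series at 1/w,
#' and summarize.
#'
#' @param signals a preprocessed [roi_signals()] object.
#' @param spec a [window_spec()].
#' @return A list with `dfc` (the filtered [dfc_series()]) and `summary`
#'   (from [summarize_dfc()]).
#' @export
dfc_pipeline <- function(signals, spec = window_spec(tr_seconds = signals$tr_seconds)) {
  hp <- highpass_roi(signals, spec$cutoff_hz)
  dfc <- windowed_fc(hp, spec)
  dfc <- lowpass_fc_series(dfc)
  list(dfc = dfc, summary = summarize_dfc(dfc))
}
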