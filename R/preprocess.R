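#' Discard leading volumes
#'
#' Drops the first `n_discard` time points of an ROI signal matrix to
#' remove pre-steady-state magnetization volumes (e.g. 217 acquired
#' volumes minus 5 dummies leaves 212 for analysis).
#'
#' @param signals a [roi_signals()] object.
#' @param n_discard number of leading volumes to drop (default 5).
#' @return The trimmed [roi_signals()], with `n_discarded` updated.
#' @export
discard_initial <- function(signals, n_discard = 5L) {
  stopifnot(inherits(signals, "roi_signals"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("discard_initial: n_discard must be >= 0")
  if (n_discard >= nrow(signals$data)) {
    stop("discard_initial: cannot discard ", n_discard, " of ",
         nrow(signals$data), " volumes")
  }
  if (n_discard == 0L) return(signals)
  signals$data <- signals$data[-seq_len(n_discard), , drop = FALSE]
  signals$n_discarded <- signals$n_discarded + n_discard
  signals
}

#' Framewise displacement (Power convention)
#'
#' FD at frame t is the sum of absolute backward differences of the six
#' rigid-body parameters, with rotations (radians) converted to arc
#' length on a sphere of radius `sphere_radius_mm`:
#' \deqn{FD_t = \sum_{m=1}^{3} |\Delta d_{m,t}| + R \sum_{m=4}^{6} |\Delta \theta_{m,t}|}
#' The first frame has FD 0 by convention.  FD depends only on parameter
#' differences, so it is invariant to constant offsets.
#'
#' @param motion a [motion_trace()] object (>= 2 frames).
#' @param sphere_radius_mm rotation-to-displacement radius, default 50 mm.
#' @return The [motion_trace()] with `fd` and `mean_fd` filled in.
#' @export
compute_fd <- function(motion, sphere_radius_mm = 50) {
  stopifnot(inherits(motion, "motion_trace"))
  p <- motion$params
  if (nrow(p) < 2L) stop("compute_fd: need at least 2 frames")
  bad <- which(!is.finite(p), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("compute_fd: non-finite motion parameter at frame ", bad[1, 1])
  }
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  motion$fd <- fd
  motion$mean_fd <- mean(fd)
  motion
}

#' Scrub high-motion frames by spline interpolation
#'
#' Frames whose framewise displacement exceeds `threshold_mm` are
#' replaced, per region, by a natural cubic spline interpolated through
#' the surviving frames; the time grid is preserved (no frames are
#' deleted), which keeps the sliding-window count intact.  Flagged frames
#' before the first (or after the last) clean frame take the nearest
#' clean value.  Non-flagged frames are never altered.
#'
#' @param signals a [roi_signals()] object.
#' @param fd framewise-displacement series aligned with the signal rows
#'   (e.g. from [compute_fd()]).
#' @param threshold_mm scrubbing threshold, default 0.2 mm.
#' @param max_flagged_frac above this fraction of flagged frames the
#'   subject is marked unusable (attribute `usable = FALSE`) with a
#'   warning; default 0.5.
#' @return The scrubbed [roi_signals()]; attribute `flagged` holds the
#'   indices of replaced frames, attribute `usable` the quality flag.
#' @export
scrub_interpolate <- function(signals, fd, threshold_mm = 0.2,
                              max_flagged_frac = 0.5) {
  stopifnot(inherits(signals, "roi_signals"))
  x <- signals$data
  if (length(fd) != nrow(x)) {
    stop("scrub_interpolate: fd length ", length(fd),
         " does not match ", nrow(x), " signal rows")
  }
  flagged <- which(fd > threshold_mm)
  usable <- TRUE
  if (length(flagged) > max_flagged_frac * nrow(x)) {
    warning("scrub_interpolate: ", length(flagged), "/", nrow(x),
            " frames flagged; subject marked unusable")
    usable <- FALSE
  }
  if (length(flagged) > 0 && length(flagged) < nrow(x)) {
    good <- setdiff(seq_len(nrow(x)), flagged)
    interior <- flagged[flagged > min(good) & flagged < max(good)]
    before <- flagged[flagged < min(good)]
    after <- flagged[flagged > max(good)]
    for (j in seq_len(ncol(x))) {
      if (length(interior) > 0) {
        sf <- stats::splinefun(good, x[good, j], method = "natural")
        x[interior, j] <- sf(interior)
      }
      if (length(before) > 0) x[before, j] <- x[min(good), j]
      if (length(after) > 0) x[after, j] <- x[max(good), j]
    }
  }
  signals$data <- x
  attr(signals, "flagged") <- flagged
  attr(signals, "usable") <- usable
  signals
}

#' Friston 24-parameter motion expansion
#'
#' The six realignment parameters, their one-volume backward lags
#' (first row zero-padded), and the squares of both sets.
#'
#' @param params time x 6 motion parameter matrix.
#' @return time x 24 design block.
#' @export
friston24 <- function(params) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6L)
  lagged <- rbind(0, params[-nrow(params), , drop = FALSE])
  out <- cbind(params, lagged, params^2, lagged^2)
  colnames(out) <- c(paste0("rp", 1:6), paste0("rp_lag", 1:6),
                     paste0("rp_sq", 1:6), paste0("rp_lag_sq", 1:6))
  out
}

#' Nuisance regression of motion and physiological signals
#'
#' Regresses each region's time course on an intercept, the Friston-24
#' motion expansion, and any extra regressor columns (typically white
#' matter and cerebrospinal fluid mean signals supplied externally),
#' returning least-squares residuals.  Collinear design columns are
#' dropped with a warning rather than failing.
#'
#' @param signals a [roi_signals()] object.
#' @param motion a [motion_trace()] aligned with the signal rows, or
#'   `NULL` to omit motion regressors.
#' @param extra_regressors optional time x q numeric matrix of additional
#'   nuisance columns.
#' @return The [roi_signals()] with `data` replaced by residuals.
#' @export
regress_nuisance <- function(signals, motion = NULL, extra_regressors = NULL) {
  stopifnot(inherits(signals, "roi_signals"))
  n <- nrow(signals$data)
  design <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(motion)) {
    if (nrow(motion$params) != n) {
      stop("regress_nuisance: motion rows (", nrow(motion$params),
           ") do not align with signal rows (", n, ")")
    }
    design <- cbind(design, friston24(motion$params))
  }
  if (!is.null(extra_regressors)) {
    extra_regressors <- as.matrix(extra_regressors)
    if (nrow(extra_regressors) != n) {
      stop("regress_nuisance: extra regressor rows do not align")
    }
    if (is.null(colnames(extra_regressors))) {
      colnames(extra_regressors) <- paste0("extra", seq_len(ncol(extra_regressors)))
    }
    design <- cbind(design, extra_regressors)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    kept <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), kept)]
    warning("regress_nuisance: dropping collinear column(s): ",
            paste(dropped, collapse = ", "))
    design <- design[, kept, drop = FALSE]
    qrd <- qr(design)
  }
  signals$data <- qr.resid(qrd, signals$data)
  signals
}

# Zero-phase order-2 Butterworth filtering, one column at a time.
# type "pass" takes a length-2 band in Hz; "high"/"low" a single cutoff.
# Columns are demeaned and reflection-padded before filtering to tame
# the start/end transients of the IIR passes; the mean is restored for
# low-pass filters (which must preserve DC).
butter_filtfilt <- function(x, tr_seconds, cutoff_hz, type) {
  nyq <- 1 / (2 * tr_seconds)
  wn <- cutoff_hz / nyq
  if (any(wn >= 1)) stop("filter cutoff at or above the Nyquist frequency (",
                         format(nyq), " Hz)")
  if (any(wn <= 0)) stop("filter cutoff must be positive")
  bf <- signal::butter(2, wn, type = type)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- min(n - 1L, 12L)  # ~3x the filter length, MATLAB-style edge pad
  apply(x, 2L, function(col) {
    mu <- mean(col)
    xc <- col - mu
    pad <- c(rev(xc[2:(p + 1)]), xc, rev(xc[(n - p):(n - 1)]))
    y <- signal::filtfilt(bf, pad)[(p + 1):(p + n)]
    if (identical(type, "low")) y + mu else y
  })
}

# FFT-mask fallback for series too short for IIR warm-up: zero all bins
# outside the pass band (used by lowpass_fc_series on very short series).
fft_mask_filter <- function(x, dt, cutoff_hz, type = c("low", "high")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  n <- nrow(x)
  freqs <- (seq_len(n) - 1) / (n * dt)
  freqs <- pmin(freqs, 1 / dt - freqs)  # two-sided
  keep <- if (type == "low") freqs <= cutoff_hz else freqs >= cutoff_hz
  apply(x, 2L, function(col) {
    mu <- mean(col)
    f <- stats::fft(col - mu)
    f[!keep] <- 0
    out <- Re(stats::fft(f, inverse = TRUE)) / n
    if (type == "low") out + mu else out
  })
}

#' Detrend and band-pass filter ROI signals
#'
#' Removes a per-region linear trend, then applies a zero-phase
#' (forward-backward) order-2 Butterworth band-pass, the standard
#' resting-state 0.01-0.08 Hz band by default.  Residual means are
#' removed after filtering so each region's output is centred.
#'
#' @param signals a [roi_signals()] object.
#' @param low_hz lower band edge in Hz (0 for pure low-pass), default 0.01.
#' @param high_hz upper band edge in Hz, must be below Nyquist, default 0.08.
#' @return The filtered [roi_signals()].
#' @export
detrend_bandpass <- function(signals, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(signals, "roi_signals"))
  nyq <- 1 / (2 * signals$tr_seconds)
  if (high_hz >= nyq) {
    stop("detrend_bandpass: high_hz (", high_hz, ") >= Nyquist (", nyq, ")")
  }
  if (low_hz < 0 || low_hz >= high_hz) {
    stop("detrend_bandpass: need 0 <= low_hz < high_hz")
  }
  x <- signals$data
  tt <- seq_len(nrow(x))
  x <- stats::lm.fit(cbind(1, tt), x)$residuals
  x <- if (low_hz > 0) {
    butter_filtfilt(x, signals$tr_seconds, c(low_hz, high_hz), "pass")
  } else {
    butter_filtfilt(x, signals$tr_seconds, high_hz, "low")
  }
  x <- sweep(x, 2L, colMeans(x))
  colnames(x) <- signals$region_labels
  signals$data <- x
  signals
}

#' Extract mean ROI time courses from a 4D image and labelled atlas
#'
#' Averages the voxel time series of a 4D NIfTI image within each
#' integer label of an atlas volume on the same voxel grid (e.g. the
#' 90-region AAL parcellation without cerebellum).  Regions are ordered
#' by ascending atlas label; a label with no voxels yields an all-`NaN`
#' column and a warning.
#'
#' @param image_4d path to a 4D NIfTI image, or an array.
#' @param atlas path to an integer-labelled 3D NIfTI atlas, or an array
#'   with matching spatial dimensions.
#' @param tr_seconds repetition time; when `NULL`, taken from the image
#'   header.
#' @param subject_id subject identifier.
#' @return A [roi_signals()] object with one column per atlas label,
#'   labelled `"roi<label>"`.
#' @export
extract_roi_signals <- function(image_4d, atlas, tr_seconds = NULL,
                                subject_id = "subj") {
  if (is.character(image_4d)) {
    img <- RNifti::readNifti(image_4d)
    if (is.null(tr_seconds)) {
      tr_seconds <- RNifti::pixdim(img)[4]
    }
    img <- as.array(img)
  } else {
    img <- as.array(image_4d)
  }
  if (is.character(atlas)) atlas <- as.array(RNifti::readNifti(atlas))
  atlas <- as.array(atlas)
  if (length(dim(img)) != 4L) stop("extract_roi_signals: image must be 4D")
  if (!identical(dim(img)[1:3], dim(atlas)[1:3])) {
    stop("extract_roi_signals: image and atlas voxel grids differ")
  }
  if (is.null(tr_seconds)) stop("extract_roi_signals: tr_seconds required")
  labels <- sort(unique(as.vector(atlas)))
  labels <- labels[labels != 0]
  n_t <- dim(img)[4]
  vox <- matrix(img, ncol = n_t)  # voxels x time
  atlas_vec <- as.vector(atlas)
  out <- matrix(NaN, n_t, length(labels))
  for (i in seq_along(labels)) {
    sel <- atlas_vec == labels[i]
    if (!any(sel)) {
      warning("extract_roi_signals: empty atlas label ", labels[i])
      next
    }
    out[, i] <- colMeans(vox[sel, , drop = FALSE])
  }
  empty <- colSums(is.finite(out)) == 0
  if (any(empty)) {
    warning("extract_roi_signals: label(s) with no voxels: ",
            paste(labels[empty], collapse = ", "))
  }
  roi_signals(out, tr_seconds = tr_seconds, subject_id = subject_id,
              region_labels = sprintf("roi%g", labels))
}

#' Full temporal preprocessing for one subject
#'
#' Applies the fixed pipeline order: discard leading volumes, nuisance
#' regression (Friston-24 motion expansion plus optional external
#' regressors), linear detrend with band-pass filtering, then
#' framewise-displacement scrubbing by spline interpolation.  Mean FD is
#' computed on the pre-scrub FD series (after volume discard) and
#' attached for use as a statistical covariate.
#'
#' @param signals a [roi_signals()] object (raw, pre-discard).
#' @param motion a [motion_trace()] aligned with the raw volumes, or `NULL`.
#' @param n_discard leading volumes to drop, default 5.
#' @param low_hz,high_hz band-pass edges in Hz.
#' @param fd_threshold_mm scrubbing threshold, default 0.2 mm.
#' @param extra_regressors optional nuisance columns aligned with the raw
#'   volumes.
#' @return A list with elements `signals` (preprocessed [roi_signals()]),
#'   `motion` (trimmed, with FD), `flagged` (scrubbed frame indices),
#'   `mean_fd`, and `usable`.
#' @export
preprocess_subject <- function(signals, motion = NULL, n_discard = 5L,
                               low_hz = 0.01, high_hz = 0.08,
                               fd_threshold_mm = 0.2,
                               extra_regressors = NULL) {
  signals <- discard_initial(signals, n_discard)
  if (!is.null(motion) && n_discard > 0) {
    motion$params <- motion$params[-seq_len(n_discard), , drop = FALSE]
  }
  if (!is.null(extra_regressors) && n_discard > 0) {
    extra_regressors <- as.matrix(extra_regressors)[-seq_len(n_discard), ,
                                                    drop = FALSE]
  }
  signals <- regress_nuisance(signals, motion, extra_regressors)
  signals <- detrend_bandpass(signals, low_hz, high_hz)
  flagged <- integer(0)
  mean_fd <- NA_real_
  usable <- TRUE
  if (!is.null(motion)) {
    motion <- compute_fd(motion)
    mean_fd <- motion$mean_fd
    signals <- scrub_interpolate(signals, motion$fd, fd_threshold_mm)
    flagged <- attr(signals, "flagged")
    usable <- attr(signals, "usable")
  }
  list(signals = signals, motion = motion, flagged = flagged,
       mean_fd = mean_fd, usable = usable)
}
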