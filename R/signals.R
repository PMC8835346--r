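#' ROI signal container
#'
#' Bundle one subject's region-of-interest (ROI) BOLD time series with its
#' sampling interval and bookkeeping.  The data matrix is time (rows) by
#' region (columns); region order is fixed across a cohort and carried in
#' `region_labels`.
#'
#' @param data numeric matrix, time points in rows, regions in columns.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @param subject_id character scalar identifying the subject.
#' @param region_labels character vector of region names; defaults to
#'   `"R001"`, `"R002"`, ... in column order.
#' @param n_discarded number of leading volumes already removed.
#' @return An object of class `roi_signals`.
#' @export
roi_signals <- function(data, tr_seconds, subject_id = "subj",
                        region_labels = NULL, n_discarded = 0L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    stop("roi_signals: non-finite values in signal matrix")
  }
  if (is.null(region_labels)) {
    region_labels <- if (!is.null(colnames(data))) colnames(data)
                     else default_region_labels(ncol(data))
  }
  stopifnot(length(region_labels) == ncol(data),
            is.numeric(tr_seconds), tr_seconds > 0)
  colnames(data) <- region_labels
  structure(list(subject_id = as.character(subject_id),
                 data = data,
                 tr_seconds = as.numeric(tr_seconds),
                 region_labels = as.character(region_labels),
                 n_discarded = as.integer(n_discarded)),
            class = "roi_signals")
}

default_region_labels <- function(n) sprintf("R%03d", seq_len(n))

#' @export
print.roi_signals <- function(x, ...) {
  cat(sprintf("<roi_signals> subject %s: %d volumes x %d regions, TR %.3g s (%d discarded)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds,
              x$n_discarded))
  invisible(x)
}

#' @export
dim.roi_signals <- function(x) dim(x$data)

#' Head-motion parameter container
#'
#' Holds an SPM realignment-parameter (`rp_*.txt`) style matrix of six
#' rigid-body motion parameters per volume: three translations in mm
#' followed by three rotations in radians.  Framewise displacement is
#' attached by [compute_fd()].
#'
#' @param params numeric matrix, time points x 6 (translations mm,
#'   rotations rad).
#' @return An object of class `motion_trace` with elements `params`, `fd`
#'   (filled by [compute_fd()]) and `mean_fd`.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  storage.mode(params) <- "double"
  if (ncol(params) != 6L) {
    stop("motion_trace: expected 6 motion parameters per volume, got ",
         ncol(params))
  }
  structure(list(params = params, fd = NULL, mean_fd = NA_real_),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d volumes; mean FD %s mm\n", nrow(x$params),
              ifelse(is.na(x$mean_fd), "not computed",
                     formatC(x$mean_fd, digits = 4))))
  invisible(x)
}

#' Read ROI signals from a delimited text file
#'
#' Expects a header row of region labels and one row per time point.
#' Both tab- and comma-separated layouts are accepted (chosen from the
#' file extension, `.csv` implying comma).
#'
#' @param path file path.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return A [roi_signals()] object.
#' @export
read_roi_signals <- function(path, tr_seconds,
                             subject_id = sub("\\.[^.]+$", "", basename(path))) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  roi_signals(as.matrix(tab), tr_seconds = tr_seconds,
              subject_id = subject_id, region_labels = colnames(tab))
}

#' Write ROI signals as a tab-separated table
#'
#' @param signals a [roi_signals()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi_signals <- function(signals, path) {
  utils::write.table(signals$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an SPM-style realignment parameter file
#'
#' Whitespace-delimited, six columns per volume: x/y/z translation (mm)
#' then pitch/roll/yaw rotation (rad).
#'
#' @param path file path.
#' @return A [motion_trace()] object.
#' @export
read_motion <- function(path) {
  params <- as.matrix(utils::read.table(path, header = FALSE))
  motion_trace(params)
}

#' Write motion parameters in SPM rp text format
#'
#' @param motion a [motion_trace()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(motion$params, digits = 10, scientific = FALSE),
                     path, sep = "  ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
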