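#' Connectivity matrix container
#'
#' A symmetric region-by-region matrix of functional connectivity values
#' with the diagonal stored as exactly zero (self-connections are never
#' features).  `scale` records whether values are raw Pearson `r` or
#' Fisher z.
#'
#' @param values symmetric numeric matrix; the diagonal is forced to 0.
#' @param scale `"r"` or `"fisher_z"`.
#' @param region_labels region names in matrix order.
#' @return An object of class `fc_matrix`.
#' @export
fc_matrix <- function(values, scale = c("r", "fisher_z"),
                      region_labels = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("fc_matrix: matrix must be square")
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-9) {
    stop("fc_matrix: asymmetry ", format(asym), " exceeds 1e-9")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(region_labels)) region_labels <- default_region_labels(ncol(values))
  dimnames(values) <- list(region_labels, region_labels)
  structure(list(values = values, scale = scale,
                 region_labels = region_labels),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d x %d, scale=%s\n", nrow(x$values),
              ncol(x$values), x$scale))
  invisible(x)
}

#' Static functional connectivity by full-length Pearson correlation
#'
#' Computes the product-moment correlation between every pair of region
#' time courses over the full scan, the classical static FC (SFC) matrix.
#' Regions with zero temporal variance yield `NaN` rows/columns and a
#' warning.
#'
#' @param signals a [roi_signals()] object (at least 3 time points).
#' @return An [fc_matrix()] on the `r` scale.
#' @export
pearson_fc <- function(signals) {
  x <- signals$data
  if (nrow(x) < 3L) stop("pearson_fc: need at least 3 time points")
  sds <- apply(x, 2L, stats::sd)
  degenerate <- sds == 0
  r <- suppressWarnings(stats::cor(x))
  if (any(degenerate)) {
    warning("pearson_fc: zero-variance region(s): ",
            paste(signals$region_labels[degenerate], collapse = ", "))
    r[degenerate, ] <- NaN
    r[, degenerate] <- NaN
  }
  diag(r) <- 0
  fc_matrix(r, scale = "r", region_labels = signals$region_labels)
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies `atanh` elementwise off the diagonal, first clipping `|r|` to
#' `1 - 1e-7` so that perfectly correlated pairs map to a large finite
#' value rather than infinity.  The transform is odd and strictly
#' increasing, so rank order (and sign) of connections is preserved.
#'
#' @param matrix an [fc_matrix()] on the `r` scale.
#' @param clip clipping bound applied to `|r|` before `atanh`.
#' @return An [fc_matrix()] on the `fisher_z` scale.
#' @export
fisher_z <- function(matrix, clip = 1 - 1e-7) {
  stopifnot(inherits(matrix, "fc_matrix"))
  if (matrix$scale != "r") stop("fisher_z: input must be on the r scale")
  r <- matrix$values
  n_clipped <- sum(abs(r) > clip & upper.tri(r), na.rm = TRUE)
  if (n_clipped > 0) {
    message("fisher_z: clipped ", n_clipped, " |r| value(s) to ", format(clip))
  }
  z <- atanh(pmin(pmax(r, -clip), clip))
  diag(z) <- 0
  fc_matrix(z, scale = "fisher_z", region_labels = matrix$region_labels)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Connection features are the N(N-1)/2 unique region pairs taken in
#' row-major upper-triangle order: pair (i, j) with i < j, i in the outer
#' loop — (1,2), (1,3), ..., (1,N), (2,3), ...  With the 90-region AAL
#' parcellation this yields the canonical 4,005-dimensional connection
#' vector.  This ordering is used for every downstream feature matrix and
#' written into output headers; [devectorize_fc()] inverts it exactly.
#'
#' @param matrix an [fc_matrix()] (or plain symmetric matrix).
#' @return Numeric vector of length N(N-1)/2, named by pair labels
#'   `"<region_i>--<region_j>"`.
#' @export
vectorize_fc <- function(matrix) {
  if (inherits(matrix, "fc_matrix")) {
    m <- matrix$values
    labels <- matrix$region_labels
  } else {
    m <- as.matrix(matrix)
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-9) {
      stop("vectorize_fc: matrix asymmetric beyond 1e-9")
    }
    labels <- if (is.null(colnames(m))) default_region_labels(ncol(m)) else colnames(m)
  }
  # row-major upper triangle == column-major lower triangle of the transpose
  v <- t(m)[lower.tri(m)]
  names(v) <- connection_labels(labels)
  v
}

#' @rdname vectorize_fc
#' @param vector a connection vector produced by [vectorize_fc()].
#' @param region_labels region names; inferred from the vector length when
#'   omitted.
#' @param scale scale tag for the rebuilt matrix.
#' @export
devectorize_fc <- function(vector, region_labels = NULL,
                           scale = c("fisher_z", "r")) {
  scale <- match.arg(scale)
  m_len <- length(vector)
  n <- (1 + sqrt(1 + 8 * m_len)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("devectorize_fc: length ", m_len, " is not N(N-1)/2 for integer N")
  }
  n <- as.integer(round(n))
  if (is.null(region_labels)) region_labels <- default_region_labels(n)
  m <- matrix(0, n, n)
  mt <- t(m)
  mt[lower.tri(mt)] <- vector
  m <- t(mt)
  m <- m + t(m)
  fc_matrix(m, scale = scale, region_labels = region_labels)
}

#' Pair labels for the canonical connection ordering
#'
#' @param region_labels region names.
#' @return Character vector of `"<i>--<j>"` labels in row-major
#'   upper-triangle order.
#' @export
connection_labels <- function(region_labels) {
  n <- length(region_labels)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  # (row=j, col=i) of the transpose enumerates (i, j), i < j, row-major
  sprintf("%s--%s", region_labels[idx[, "col"]], region_labels[idx[, "row"]])
}

#' Write a connectivity matrix as TSV
#'
#' @param matrix an [fc_matrix()].
#' @param path output path.
#' @export
write_fc_matrix <- function(matrix, path) {
  utils::write.table(matrix$values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
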