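#' Across-connection variance of each window
#'
#' For every window, the sample variance (denominator M - 1) across the
#' M connection values of that window's vector.  Peaks of this series
#' mark windows where the connectivity pattern is most pronounced; they
#' are used to pick clustering exemplars.
#'
#' @param dfc a [dfc_series()] (or plain windows x M matrix).
#' @return Numeric vector of length W.
#' @export
fc_variance_per_window <- function(dfc) {
  vals <- if (inherits(dfc, "dfc_series")) dfc$values else as.matrix(dfc)
  apply(vals, 1L, stats::var)
}

#' Select exemplar windows at local maxima of FC variance
#'
#' Subsamples the window dimension by keeping only windows that are
#' strict local maxima of the across-connection variance series
#' (`v[t-1] < v[t] > v[t+1]`; endpoints and plateaus excluded).  This
#' thins the heavy autocorrelation induced by 1-TR stepping before
#' k-means.  If no strict interior maximum exists (monotone or flat
#' series) the single global-maximum window is returned instead, with a
#' message.
#'
#' @param variance_series numeric vector from [fc_variance_per_window()].
#' @return Integer vector of selected window indices (1-based).
#' @export
select_exemplars <- function(variance_series) {
  v <- as.numeric(variance_series)
  w <- length(v)
  if (w < 3L) stop("select_exemplars: need at least 3 windows")
  interior <- 2:(w - 1)
  is_max <- v[interior] > v[interior - 1] & v[interior] > v[interior + 1]
  idx <- interior[is_max]
  if (length(idx) == 0) {
    message("select_exemplars: no strict local maxima; falling back to global maximum")
    idx <- which.max(v)
  }
  idx
}

#' k-means clustering with the L1 (Manhattan) distance
#'
#' A k-means variant internally consistent with the L1 objective: the
#' assignment step minimizes Manhattan distance to the centroids (ties
#' broken toward the lowest state index) and the update step sets each
#' centroid to the component-wise median of its members, the exact L1
#' minimizer.  Iteration stops at a label fixpoint or `max_iter`.  With
#' random initialization the algorithm restarts `n_restarts` times
#' (centroids drawn as distinct instances) and keeps the solution with
#' the lowest objective `sum_i L1(x_i, c_{label(i)})`.  Clusters that
#' empty out are reseeded to the instance currently farthest from its
#' assigned centroid.
#'
#' @param data instances x M numeric matrix.
#' @param k number of clusters (<= number of distinct instances).
#' @param n_restarts random restarts; ignored when `init_centroids` is
#'   given.  Default 1.
#' @param seed RNG seed for restarts/reseeding.
#' @param init_centroids optional k x M matrix of starting centroids
#'   (e.g. exemplar-stage centroids for full-data assignment).
#' @param max_iter iteration cap per restart, default 300.
#' @param single_pass if `TRUE`, perform one assignment pass from
#'   `init_centroids` without updating them.
#' @return A list of class `kmeans_l1` with `centroids` (k x M),
#'   `labels`, `objective`, `objective_trace` (per-iteration objective of
#'   the winning restart, non-increasing), and `iterations`.
#' @export
kmeans_l1 <- function(data, k, n_restarts = 1L, seed = 1L,
                      init_centroids = NULL, max_iter = 300L,
                      single_pass = FALSE) {
  data <- as.matrix(data)
  n <- nrow(data)
  k <- as.integer(k)
  if (k < 1L) stop("kmeans_l1: k must be >= 1")
  if (is.null(init_centroids) && k > n) {
    stop("kmeans_l1: k (", k, ") exceeds instance count (", n, ")")
  }
  if (!is.null(init_centroids)) {
    init_centroids <- as.matrix(init_centroids)
    stopifnot(nrow(init_centroids) == k, ncol(init_centroids) == ncol(data))
    n_restarts <- 1L
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cent <- if (is.null(init_centroids)) {
      data[sample.int(n, k), , drop = FALSE]
    } else {
      init_centroids
    }
    fit <- kmeans_l1_fit(data, cent, max_iter, single_pass)
    fit$labels <- fit$labels + 1L  # 0-based in the compiled core
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best$centroids <- unname(best$centroids)
  class(best) <- "kmeans_l1"
  best
}

#' @export
print.kmeans_l1 <- function(x, ...) {
  cat(sprintf("<kmeans_l1> k=%d, n=%d, objective %.6g (%d iterations)\n",
              nrow(x$centroids), length(x$labels), x$objective, x$iterations))
  invisible(x)
}

#' Elbow-criterion selection of the number of states
#'
#' Runs [kmeans_l1()] for each candidate k and records the cluster
#' validity index, the ratio of within-cluster distance (mean L1
#' distance of an instance to its centroid) to between-cluster distance
#' (mean pairwise L1 distance between centroids).  The elbow is the
#' interior k maximizing the discrete second difference (curvature)
#' `v[k-1] - 2 v[k] + v[k+1]` of the validity curve; ties break toward
#' the lower k.  Candidates with non-finite validity (e.g. coincident
#' centroids) are skipped with a message.
#'
#' @param data instances x M matrix.
#' @param k_range candidate cluster counts, default `2:20`.
#' @param n_restarts restarts per candidate, default 50.
#' @param seed RNG seed.
#' @return A list with `chosen_k` and `validity_curve` (named numeric
#'   vector over `k_range`).
#' @export
elbow_select_k <- function(data, k_range = 2:20, n_restarts = 50L, seed = 1L) {
  data <- as.matrix(data)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(data)) {
    k_range <- k_range[k_range <= nrow(data)]
  }
  if (length(k_range) < 3L) {
    stop("elbow_select_k: need at least 3 feasible candidate k values")
  }
  validity <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    fit <- kmeans_l1(data, k_range[i], n_restarts = n_restarts,
                     seed = seed + k_range[i])
    validity[i] <- validity_index(data, fit$centroids, fit$labels)
  }
  bad <- !is.finite(validity)
  if (any(bad)) {
    message("elbow_select_k: skipping k with non-finite validity: ",
            paste(k_range[bad], collapse = ", "))
  }
  chosen_k <- elbow_from_curve(validity[!bad])
  list(chosen_k = chosen_k, validity_curve = validity)
}

#' @rdname elbow_select_k
#' @param centroids,labels a clustering of `data`.
#' @export
validity_index <- function(data, centroids, labels) {
  data <- as.matrix(data)
  centroids <- as.matrix(centroids)
  within <- mean(rowSums(abs(data - centroids[labels, , drop = FALSE])))
  k <- nrow(centroids)
  if (k < 2L) return(Inf)
  pairs <- utils::combn(k, 2L)
  between <- mean(apply(pairs, 2L, function(p) {
    sum(abs(centroids[p[1], ] - centroids[p[2], ]))
  }))
  within / between
}

#' @rdname elbow_select_k
#' @param validity_curve named numeric vector (names = k) of validity
#'   values; used directly, e.g. to re-select k from a persisted curve.
#' @export
elbow_from_curve <- function(validity_curve) {
  ks <- as.integer(names(validity_curve))
  v <- as.numeric(validity_curve)
  if (length(v) < 3L) stop("elbow_from_curve: need at least 3 points")
  curv <- v[seq_len(length(v) - 2)] - 2 * v[seq(2, length(v) - 1)] +
    v[seq(3, length(v))]
  ks[1 + which.max(curv)]  # interior points only; which.max ties -> lowest k
}

#' Fit a connectivity state model from a cohort of DFC series
#'
#' The two-stage exemplar scheme: (1) pool each subject's exemplar
#' windows (local maxima of FC variance), cluster them with many random
#' restarts — selecting k by the elbow criterion unless `k` is fixed —
#' and (2) use the exemplar centroids to initialize a single clustering
#' of all windows of all subjects ([assign_states()]).
#'
#' @param dfc_list list of [dfc_series()], one per subject/session.
#' @param k fixed number of states, or `NULL` to select via
#'   [elbow_select_k()].
#' @param k_range candidate k values for the elbow search.
#' @param n_restarts exemplar-stage random restarts, default 500.
#' @param elbow_restarts restarts per candidate k during the elbow
#'   search (kept smaller for tractability), default 50.
#' @param seed RNG seed.
#' @return An object of class `state_model` with elements `k`,
#'   `centroids`, `validity_curve`, `chosen_k`, `exemplar_index`
#'   (per-subject window indices), and `rng_seed`.
#' @export
fit_state_model <- function(dfc_list, k = NULL, k_range = 2:20,
                            n_restarts = 500L, elbow_restarts = 50L,
                            seed = 1L) {
  stopifnot(length(dfc_list) >= 1)
  exemplar_index <- lapply(dfc_list, function(d) {
    select_exemplars(fc_variance_per_window(d))
  })
  names(exemplar_index) <- vapply(dfc_list, function(d) d$subject_id, "")
  exemplars <- do.call(rbind, Map(function(d, idx) {
    d$values[idx, , drop = FALSE]
  }, dfc_list, exemplar_index))
  validity_curve <- NULL
  chosen_k <- k
  if (is.null(k)) {
    sel <- elbow_select_k(exemplars, k_range = k_range,
                          n_restarts = elbow_restarts, seed = seed)
    chosen_k <- sel$chosen_k
    validity_curve <- sel$validity_curve
  }
  chosen_k <- as.integer(chosen_k)
  fit <- kmeans_l1(exemplars, chosen_k, n_restarts = n_restarts, seed = seed)
  structure(list(k = chosen_k, centroids = fit$centroids,
                 validity_curve = validity_curve, chosen_k = chosen_k,
                 exemplar_index = exemplar_index,
                 exemplar_objective = fit$objective, rng_seed = seed),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k=%d over %d features; %d exemplar windows from %d subjects\n",
              x$k, ncol(x$centroids),
              sum(lengths(x$exemplar_index)), length(x$exemplar_index)))
  invisible(x)
}

#' Assign every window of every subject to a state
#'
#' Pools all windows, runs one [kmeans_l1()] initialized at the
#' exemplar-stage centroids (iterated to convergence by default, or a
#' single nearest-centroid pass with `single_pass = TRUE`), stores the
#' final centroids back into the model, and splits the labels per
#' subject in window order.
#'
#' @param dfc_list list of [dfc_series()], as passed to
#'   [fit_state_model()].
#' @param model a `state_model`.
#' @param single_pass assign by nearest centroid without re-estimating
#'   centroids.
#' @return A list with `model` (centroids updated), `sequences` (list of
#'   `state_sequence` objects), and `labels` (pooled label vector).
#' @export
assign_states <- function(dfc_list, model, single_pass = FALSE) {
  stopifnot(inherits(model, "state_model"))
  all_vals <- do.call(rbind, lapply(dfc_list, function(d) d$values))
  if (ncol(all_vals) != ncol(model$centroids)) {
    stop("assign_states: feature dimension mismatch (",
         ncol(all_vals), " vs ", ncol(model$centroids), ")")
  }
  fit <- kmeans_l1(all_vals, model$k, init_centroids = model$centroids,
                   seed = model$rng_seed, single_pass = single_pass)
  model$centroids <- fit$centroids
  counts <- vapply(dfc_list, function(d) nrow(d$values), 0L)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  sequences <- Map(function(d, a, b) {
    structure(list(subject_id = d$subject_id,
                   labels = fit$labels[a:b],
                   window_starts = d$window_starts),
              class = "state_sequence")
  }, dfc_list, starts, ends)
  names(sequences) <- vapply(dfc_list, function(d) d$subject_id, "")
  list(model = model, sequences = sequences, labels = fit$labels)
}

#' Match estimated state labels to reference labels
#'
#' Cluster labels are arbitrary up to permutation.  This finds, by
#' exhaustive search over the k! permutations (k is small), the
#' relabelling of `estimated` that maximizes agreement with `reference`,
#' e.g. to compare recovered window states against a synthetic cohort's
#' ground truth.
#'
#' @param estimated,reference integer label vectors of equal length.
#' @param k number of states.
#' @return A list with `labels` (the relabelled `estimated`), `perm`
#'   (`perm[old]` = new label), and `agreement` (fraction matching).
#' @export
match_state_labels <- function(estimated, reference, k) {
  stopifnot(length(estimated) == length(reference))
  k <- as.integer(k)
  estimated <- as.integer(estimated)
  if (k > 8) stop("match_state_labels: exhaustive matching limited to k <= 8")
  perms <- all_permutations(k)
  best <- NULL
  best_score <- -1
  for (p in perms) {
    score <- sum(p[estimated] == reference)
    if (score > best_score) {
      best_score <- score
      best <- p
    }
  }
  list(labels = best[estimated], perm = best,
       agreement = best_score / length(reference))
}

all_permutations <- function(k) {
  k <- as.integer(k)
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' State transition probabilities
#'
#' Counts transitions between consecutive window labels within one
#' subject (self-transitions included: a k-state model has k x k
#' transition kinds) and row-normalizes to probabilities.  States never
#' occupied as a transition source get an all-zero row and are flagged
#' unvisited.
#'
#' @param seq a `state_sequence` or plain integer label vector.
#' @param k number of states (>= max label).
#' @return A list of class `transition_matrix` with `probs`, `counts`,
#'   and logical `visited` per state.
#' @export
transition_probability <- function(seq, k) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else as.integer(seq)
  k <- as.integer(k)
  if (length(labels) >= 1 && max(labels) > k) {
    stop("transition_probability: label ", max(labels), " exceeds k = ", k)
  }
  counts <- matrix(0L, k, k)
  if (length(labels) >= 2) {
    from <- labels[-length(labels)]
    to <- labels[-1]
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  }
  row_tot <- rowSums(counts)
  visited <- row_tot > 0
  probs <- counts / ifelse(row_tot == 0, 1, row_tot)
  structure(list(probs = probs, counts = counts, visited = visited),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d states (%d visited)\n",
              nrow(x$probs), sum(x$visited)))
  print(round(x$probs, 3))
  invisible(x)
}
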