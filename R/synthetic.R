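#' Block-structured state covariance matrices
#'
#' Builds k symmetric positive-definite region covariance matrices
#' representing latent connectivity states that range from a
#' hypo-connected pattern (state 1, near-diagonal) to a hyper-connected
#' pattern (state k, dense high-correlation blocks).  Regions are tiled
#' into consecutive blocks of `block_size`; within-block correlation for
#' state s is `within_r * (s - 1) / (k - 1)` (and `within_r` itself when
#' k = 1).  Unit variances, so the matrices are correlation matrices.
#'
#' @param n_regions number of regions.
#' @param k number of states; states are distinct, so `within_r > 0` is
#'   required when k > 1.
#' @param block_size regions per block; the last block may be shorter.
#' @param within_r within-block correlation of the most connected state,
#'   in `[0, 1)`.
#' @return List of k covariance matrices; construction is checked to be
#'   positive definite (minimum eigenvalue > 0) and fails hard naming
#'   the offending state.
#' @export
make_state_covariances <- function(n_regions, k, block_size, within_r) {
  stopifnot(n_regions >= 1, k >= 1, block_size >= 1,
            within_r >= 0, within_r < 1)
  if (k > 1 && within_r == 0) {
    stop("make_state_covariances: within_r = 0 cannot produce k > 1 distinct states")
  }
  block_of <- ceiling(seq_len(n_regions) / block_size)
  same_block <- outer(block_of, block_of, "==")
  out <- vector("list", k)
  for (s in seq_len(k)) {
    r_s <- if (k == 1) within_r else within_r * (s - 1) / (k - 1)
    sigma <- ifelse(same_block, r_s, 0)
    diag(sigma) <- 1
    ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) {
      stop("make_state_covariances: state ", s,
           " is not positive definite (min eigenvalue ", format(ev), ")")
    }
    out[[s]] <- sigma
  }
  out
}

#' Pattern-distinct state covariance matrices
#'
#' An alternative state family in which each state correlates a
#' *different* block of regions (state s: correlation `r` among regions
#' `((s-1)*b+1):(s*b)` with `b = floor(n_regions/k)`, identity
#' elsewhere).  States then differ in connectivity *pattern* rather than
#' overall magnitude, making them maximally separable in connection
#' space; this is the recommended family for state-recovery validation,
#' where magnitude-ramp states (see [make_state_covariances()]) place
#' windows on a one-dimensional continuum that short windows cannot
#' resolve.
#'
#' @param n_regions number of regions.
#' @param k number of states (`k * 2 <= n_regions` recommended).
#' @param r within-block correlation in `(0, 1)`.
#' @return List of k positive-definite correlation matrices.
#' @export
make_pattern_covariances <- function(n_regions, k, r = 0.9) {
  stopifnot(r > 0, r < 1, k >= 1, n_regions >= k)
  bs <- n_regions %/% k
  lapply(seq_len(k), function(s) {
    sigma <- diag(n_regions)
    idx <- ((s - 1) * bs + 1):(s * bs)
    sigma[idx, idx] <- r
    diag(sigma) <- 1
    sigma
  })
}

#' Simulate a Markov state sequence
#'
#' Draws a realization of the first-order Markov chain defined by the
#' row-stochastic transition matrix `tp`, the inverse problem of
#' transition-probability estimation.  The first state is uniform over
#' the states.
#'
#' @param n_steps sequence length (>= 1).
#' @param tp square matrix with rows summing to 1 (tolerance 1e-9).
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (so a cohort-level seed governs reproducibility).
#' @return Integer vector of state labels in `1..nrow(tp)`.
#' @export
simulate_state_sequence <- function(n_steps, tp, seed = NULL) {
  tp <- as.matrix(tp)
  if (nrow(tp) != ncol(tp)) stop("simulate_state_sequence: tp must be square")
  if (any(abs(rowSums(tp) - 1) > 1e-9)) {
    stop("simulate_state_sequence: rows of tp must sum to 1")
  }
  if (any(tp < 0)) stop("simulate_state_sequence: negative transition probability")
  stopifnot(n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(tp)
  seq_out <- integer(n_steps)
  seq_out[1] <- sample.int(k, 1L)
  if (n_steps > 1) {
    for (t in 2:n_steps) {
      seq_out[t] <- sample.int(k, 1L, prob = tp[seq_out[t - 1], ])
    }
  }
  seq_out
}

#' Synthetic cohort specification
#'
#' All generative settings for a simulated resting-state cohort with
#' known latent connectivity states.  Defaults mirror a two-group study
#' of 17 patients and 22 controls scanned for 217 volumes at TR 2.4 s
#' over 90 regions, with 12 patients rescanned post-treatment.
#'
#' Group and treatment effects are planted through the covariance of a
#' designated connection: across states, that connection's correlation
#' takes values `r_s`; for a subject with effect scale `e`, the values
#' become `mean(r_s) + e * (r_s - mean(r_s))`, so `e > 1` inflates the
#' between-state variability of the connection (raising its DFC-SD and
#' ALFF-FC) without changing its mean level much.  Patients draw
#' per-subject scales around `group_effect`, controls sit at 1, and
#' post-treatment sessions sit around `post_effect`.  Patients'
#' transition matrix additionally shifts `tp_effect` of probability mass
#' from the self-transition of state 2 into the 2 -> 3 transition (when
#' k >= 3).  Clinical scores are affine functions of the subject's
#' effect scale plus Gaussian noise, giving downstream correlation tests
#' a known positive sign.
#'
#' @param n_regions regions, default 90.
#' @param n_volumes acquired volumes, default 217 (5 to be discarded).
#' @param tr_seconds repetition time, default 2.4 s.
#' @param n_patients,n_controls,n_paired cohort sizes, default 17/22/12.
#' @param k_true latent states, default 4.
#' @param block_size,within_r passed to [make_state_covariances()]
#'   (defaults: blocks of 10, top correlation 0.6).
#' @param state_covariances optional list overriding the constructed
#'   covariances.
#' @param true_tp row-stochastic k x k matrix; default 0.88 on the
#'   diagonal with the remainder spread evenly.
#' @param noise_sd white observation noise SD on top of unit-variance
#'   state signals, default 0.3.
#' @param group_effect patients' mean effect scale, default 2.
#' @param post_effect post-treatment mean effect scale, default 1.
#' @param tp_effect probability mass moved into the designated patient
#'   transition, default 0.08.
#' @param designated_connection region index pair carrying the planted
#'   variability effect, default `c(1, 2)`.
#' @param spike_frac fraction of volumes receiving a motion spike with
#'   framewise displacement above 0.2 mm, default 0.02.
#' @param seed RNG seed; identical specs (including seed) give
#'   bit-identical cohorts.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_regions = 90L, n_volumes = 217L,
                                  tr_seconds = 2.4,
                                  n_patients = 17L, n_controls = 22L,
                                  n_paired = 12L,
                                  k_true = 4L, block_size = 10L,
                                  within_r = 0.6,
                                  state_covariances = NULL,
                                  true_tp = NULL, noise_sd = 0.3,
                                  group_effect = 2, post_effect = 1,
                                  tp_effect = 0.08,
                                  designated_connection = c(1L, 2L),
                                  spike_frac = 0.02, seed = 1L) {
  if (is.null(state_covariances)) {
    state_covariances <- make_state_covariances(n_regions, k_true,
                                                block_size, within_r)
  }
  k_true <- length(state_covariances)
  if (is.null(true_tp)) {
    true_tp <- matrix(if (k_true > 1) 0.12 / (k_true - 1) else 0,
                      k_true, k_true)
    diag(true_tp) <- if (k_true > 1) 0.88 else 1
  }
  true_tp <- as.matrix(true_tp)
  if (any(abs(rowSums(true_tp) - 1) > 1e-12)) {
    stop("synthetic_cohort_spec: true_tp rows must sum to 1 (tol 1e-12)")
  }
  for (s in seq_len(k_true)) {
    sig <- state_covariances[[s]]
    if (max(abs(sig - t(sig))) > 1e-12 ||
        min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("synthetic_cohort_spec: state covariance ", s,
           " is not symmetric positive-definite")
    }
  }
  stopifnot(n_paired <= n_patients, n_volumes > 0,
            length(designated_connection) == 2,
            max(designated_connection) <= n_regions)
  structure(list(n_regions = as.integer(n_regions),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 n_paired = as.integer(n_paired),
                 k_true = as.integer(k_true),
                 state_covariances = state_covariances,
                 true_tp = true_tp, noise_sd = noise_sd,
                 group_effect = group_effect, post_effect = post_effect,
                 tp_effect = tp_effect,
                 designated_connection = as.integer(designated_connection),
                 spike_frac = spike_frac, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# Per-subject state covariances: the designated connection's across-state
# correlation deviations are scaled by the subject's effect size.
subject_covariances <- function(spec, effect_scale) {
  i <- spec$designated_connection[1]
  j <- spec$designated_connection[2]
  r_s <- vapply(spec$state_covariances, function(sig) sig[i, j], 0)
  m <- mean(r_s)
  lapply(seq_len(spec$k_true), function(s) {
    sig <- spec$state_covariances[[s]]
    sig[i, j] <- sig[j, i] <- m + effect_scale * (r_s[s] - m)
    ev <- min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) {
      stop("subject_covariances: effect scale ", format(effect_scale),
           " makes state ", s, " non-positive-definite")
    }
    sig
  })
}

subject_tp <- function(spec, is_patient) {
  tp <- spec$true_tp
  if (is_patient && spec$tp_effect > 0 && spec$k_true >= 3) {
    shift <- min(spec$tp_effect, tp[2, 2])
    tp[2, 3] <- tp[2, 3] + shift
    tp[2, 2] <- tp[2, 2] - shift
  }
  tp
}

simulate_subject_signals <- function(spec, covariances, tp) {
  states <- simulate_state_sequence(spec$n_volumes, tp)
  chols <- lapply(covariances, chol)
  z <- matrix(stats::rnorm(spec$n_volumes * spec$n_regions),
              spec$n_volumes, spec$n_regions)
  x <- matrix(0, spec$n_volumes, spec$n_regions)
  for (s in unique(states)) {
    rows <- states == s
    x[rows, ] <- z[rows, , drop = FALSE] %*% chols[[s]]
  }
  if (spec$noise_sd > 0) {
    x <- x + spec$noise_sd * matrix(stats::rnorm(length(x)), nrow(x))
  }
  list(signals = x, states = states)
}

simulate_subject_motion <- function(spec) {
  n <- spec$n_volumes
  transl <- apply(matrix(stats::rnorm(n * 3, sd = 0.01), n, 3), 2L, cumsum)
  rot <- apply(matrix(stats::rnorm(n * 3, sd = 2e-4), n, 3), 2L, cumsum)
  n_spikes <- stats::rbinom(1L, n - 2L, spec$spike_frac)
  if (n_spikes > 0) {
    at <- sample(2:(n - 1), n_spikes)
    idx <- cbind(at, sample.int(3L, n_spikes, replace = TRUE))
    transl[idx] <- transl[idx] + stats::runif(n_spikes, 0.25, 0.5)
  }
  motion_trace(cbind(transl, rot))
}

clinical_scores <- function(effect_scale) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  list(thi = clip(30 + 20 * effect_scale + stats::rnorm(1, sd = 6), 0, 100),
       tdi = as.integer(clip(round(1 + 1.5 * effect_scale +
                                     stats::rnorm(1, sd = 0.6)), 0, 6)),
       vas = clip(2 + 2 * effect_scale + stats::rnorm(1, sd = 0.8), 0, 10),
       khq = clip(20 + 14 * effect_scale + stats::rnorm(1, sd = 6), 0, 42),
       hearing_left_db = 28 + stats::rnorm(1, sd = 6),
       hearing_right_db = 22 + 10 * effect_scale + stats::rnorm(1, sd = 5))
}

#' Simulate a full synthetic cohort
#'
#' Generates, per subject and session, a latent Markov state sequence at
#' volume resolution, ROI signals drawn from the state-specific
#' multivariate normal plus white noise, a motion trace with occasional
#' translation spikes, and a metadata record with clinical scores tied
#' to the subject's planted effect (see [synthetic_cohort_spec()]).
#' Controls carry no tinnitus scale scores.  The generator is fully
#' deterministic given the spec.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with `subjects`
#'   (each holding `signals` ([roi_signals()]), `motion`
#'   ([motion_trace()]), `record` (one-row data frame),
#'   `true_states`, and `effect_scale`) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  subjects <- list()
  add_subject <- function(id, group, session, effect_scale, tp) {
    covs <- if (effect_scale == 1) spec$state_covariances
            else subject_covariances(spec, effect_scale)
    sim <- simulate_subject_signals(spec, covs, tp)
    motion <- simulate_subject_motion(spec)
    age <- round(clip_range(stats::rnorm(1, 47, 11), 18, 70))
    sex <- sample(c("M", "F"), 1L, prob = c(0.35, 0.65))
    scores <- if (group == "patient") clinical_scores(effect_scale)
              else list(thi = NA_real_, tdi = NA_integer_, vas = NA_real_,
                        khq = NA_real_,
                        hearing_left_db = 24 + stats::rnorm(1, sd = 5),
                        hearing_right_db = 24 + stats::rnorm(1, sd = 5))
    record <- data.frame(subject_id = id, group = group, session = session,
                         age = age, sex = sex, mean_fd = NA_real_,
                         thi = scores$thi, tdi = scores$tdi,
                         vas = scores$vas, khq = scores$khq,
                         hearing_left_db = scores$hearing_left_db,
                         hearing_right_db = scores$hearing_right_db,
                         stringsAsFactors = FALSE)
    list(signals = roi_signals(sim$signals, spec$tr_seconds,
                               subject_id = paste(id, session, sep = "_")),
         motion = motion, record = record, true_states = sim$states,
         effect_scale = effect_scale)
  }
  for (i in seq_len(spec$n_controls)) {
    id <- sprintf("C%02d", i)
    subjects[[paste0(id, "_none")]] <-
      add_subject(id, "control", "none", 1, spec$true_tp)
  }
  patient_scale <- numeric(spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    id <- sprintf("P%02d", i)
    patient_scale[i] <- 1 + (spec$group_effect - 1) * stats::runif(1, 0.7, 1.3)
    subjects[[paste0(id, "_pre")]] <-
      add_subject(id, "patient", "pre", patient_scale[i],
                  subject_tp(spec, TRUE))
  }
  for (i in seq_len(spec$n_paired)) {
    id <- sprintf("P%02d", i)
    post_scale <- 1 + (spec$post_effect - 1) * stats::runif(1, 0.7, 1.3)
    subjects[[paste0(id, "_post")]] <-
      add_subject(id, "patient", "post", post_scale, spec$true_tp)
  }
  structure(list(subjects = subjects, spec = spec),
            class = "synthetic_cohort")
}

clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
print.synthetic_cohort <- function(x, ...) {
  recs <- cohort_records(x)
  cat(sprintf("<synthetic_cohort> %d scans (%d patients, %d controls, %d post sessions); %d volumes x %d regions\n",
              length(x$subjects), x$spec$n_patients, x$spec$n_controls,
              sum(recs$session == "post"), x$spec$n_volumes,
              x$spec$n_regions))
  invisible(x)
}

#' Metadata table of a cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @return Data frame with one row per scan session.
#' @export
cohort_records <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) s$record))
}

#' Majority state label of each window
#'
#' Collapses a volume-resolution state sequence to window resolution by
#' majority vote within each window (ties go to the lowest state label).
#' Latent state dwell is generated at volume resolution; windows are a
#' measurement construct and inherit the majority label for evaluating
#' recovered window labels against ground truth.
#'
#' @param labels volume-level state labels.
#' @param windows 0-based half-open window index matrix from
#'   [enumerate_windows()].
#' @return Integer vector, one label per window.
#' @export
majority_window_labels <- function(labels, windows) {
  apply(windows, 1L, function(w) {
    seg <- labels[(w[1] + 1L):w[2]]
    which.max(tabulate(seg))
  })
}

#' Write a cohort to disk in plain-text formats
#'
#' Per scan: a time x region TSV of signals (`<id>_<session>.tsv`) and
#' an SPM-style `rp_<id>_<session>.txt` motion file; plus one
#' `metadata.csv` covering all sessions.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$subjects)) {
    s <- cohort$subjects[[nm]]
    write_roi_signals(s$signals, file.path(dir, paste0(nm, ".tsv")))
    write_motion(s$motion, file.path(dir, paste0("rp_", nm, ".txt")))
  }
  utils::write.csv(cohort_records(cohort), file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}
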