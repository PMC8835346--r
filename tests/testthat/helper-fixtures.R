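# Shared fixture builders.  Everything is generated in code at test time.

# small random ROI signal set
rand_signals <- function(n_t = 40, n_r = 4, tr = 2.4, seed = 1) {
  set.seed(seed)
  roi_signals(matrix(rnorm(n_t * n_r), n_t, n_r), tr_seconds = tr)
}

# sinusoid at an exact FFT bin so amplitude can be read off the spectrum
bin_sinusoid <- function(bin, n, tr) sin(2 * pi * (bin / (n * tr)) * (0:(n - 1)) * tr)

# single-sided amplitude at FFT bin k (0-based) of a series
fft_amplitude <- function(x, bin) {
  n <- length(x)
  2 * Mod(stats::fft(x - mean(x)))[bin + 1] / n
}

# cohort for state-recovery experiments: pattern-orthogonal states,
# long dwell times, low noise ("well-separated" regime)
recovery_cohort <- function(seed, n_sub = 6, n_volumes = 305, k_true = 3,
                            r = 0.9, noise_sd = 0.05, diag_tp = 0.95,
                            n_regions = 12) {
  tp <- matrix((1 - diag_tp) / (k_true - 1), k_true, k_true)
  diag(tp) <- diag_tp
  spec <- synthetic_cohort_spec(
    n_regions = n_regions, n_volumes = n_volumes, n_patients = 0,
    n_controls = n_sub, n_paired = 0,
    state_covariances = make_pattern_covariances(n_regions, k_true, r),
    true_tp = tp, noise_sd = noise_sd, seed = seed)
  simulate_cohort(spec)
}

# run the DFC + clustering chain on a recovery cohort and score it
# against ground truth
run_recovery <- function(seed, ...) {
  cohort <- recovery_cohort(seed, ...)
  k_true <- cohort$spec$k_true
  feats <- cohort_dfc(cohort)
  model <- fit_state_model(feats$dfc_list, k = k_true, n_restarts = 20,
                           seed = seed)
  asg <- assign_states(feats$dfc_list, model)
  truth_all <- unlist(feats$truth)
  matched <- match_state_labels(asg$labels, truth_all, k_true)
  tp_err <- vapply(feats$dfc_list |> names(), function(nm) {
    lab <- matched$perm[asg$sequences[[nm]]$labels]
    max(abs(transition_probability(lab, k_true)$probs - cohort$spec$true_tp))
  }, 0)
  list(ari = mclust::adjustedRandIndex(asg$labels, truth_all),
       tp_max_err = max(tp_err),
       n_windows = nrow(feats$dfc_list[[1]]$values))
}

# well-separated clusters at random positions in connection space
cluster_cloud <- function(seed, k_true = 4, m = 66, n_per = 40, sep = 3,
                          noise = 0.5) {
  set.seed(seed)
  cents <- matrix(rnorm(k_true * m), k_true, m) * sep / sqrt(m)
  do.call(rbind, lapply(seq_len(k_true), function(s) {
    matrix(rnorm(n_per * m, sd = noise / sqrt(m)), n_per, m) +
      matrix(cents[s, ], n_per, m, byrow = TRUE)
  }))
}

# one replicate of the group-difference experiment: simulate a cohort,
# compute per-scan DFC-SD, fit the covariate GLM, BH-correct
calibration_replicate <- function(seed, group_effect, n_patients = 13,
                                  n_controls = 13, n_volumes = 185,
                                  n_regions = 8) {
  spec <- synthetic_cohort_spec(
    n_regions = n_regions, n_volumes = n_volumes, n_patients = n_patients,
    n_controls = n_controls, n_paired = 0, k_true = 3, block_size = 4,
    within_r = 0.6, noise_sd = 0.3, group_effect = group_effect,
    tp_effect = 0, seed = seed)
  cohort <- simulate_cohort(spec)
  feats <- cohort_dfc(cohort)
  sd_mat <- do.call(rbind, lapply(feats$summaries, function(sm) {
    stats::setNames(sm$sd, sm$connection)
  }))
  recs <- feats$records
  recs$mean_fd <- vapply(cohort$subjects, function(s) {
    compute_fd(s$motion)$mean_fd
  }, 0)
  covs <- cbind(age = recs$age, sex = as.numeric(recs$sex == "M"),
                mean_fd = recs$mean_fd)
  res <- glm_group_compare(sd_mat, as.numeric(recs$group == "patient"), covs)
  q <- fdr_correct(res$p)
  # designated connection (regions 1, 2) is the first feature in
  # row-major upper-triangle order
  c(any_sig = any(q < 0.05, na.rm = TRUE), designated_sig = q[1] < 0.05)
}
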