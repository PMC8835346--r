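test_that("the covariate GLM reduces to the pooled two-sample t-test", {
  set.seed(1)
  n <- 24
  grp <- rep(0:1, each = n / 2)
  y <- matrix(rnorm(n * 6), n, 6)
  res <- glm_group_compare(y, grp)
  for (j in 1:6) {
    oracle <- t.test(y[grp == 1, j], y[grp == 0, j], var.equal = TRUE)
    expect_equal(res$t[j], unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(res$p[j], oracle$p.value, tolerance = 1e-10)
  }

  # a covariate orthogonal to both group and feature changes nothing
  # (beyond one residual degree of freedom)
  cov_orth <- qr.resid(qr(cbind(1, grp, y[, 1])), rnorm(n))
  res_cov <- glm_group_compare(y[, 1, drop = FALSE], grp,
                               cbind(c1 = cov_orth))
  b0 <- res$t[1] / sqrt(attr(res, "df"))
  b1 <- res_cov$t[1] / sqrt(attr(res_cov, "df"))
  expect_equal(b1, b0, tolerance = 1e-8)

  # constant feature: no effect, no evidence
  resc <- glm_group_compare(matrix(1, n, 1), grp)
  expect_identical(resc$t, 0)
  expect_identical(resc$p, 1)
})

test_that("paired comparison equals the paired t-test without covariates", {
  set.seed(2)
  n <- 15
  pre <- matrix(rnorm(n * 4), n, 4)
  post <- pre + matrix(rnorm(n * 4, mean = 0.3), n, 4)
  res <- paired_compare(pre, post)
  for (j in 1:4) {
    oracle <- t.test(post[, j], pre[, j], paired = TRUE)
    expect_equal(res$t[j], unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(res$p[j], oracle$p.value, tolerance = 1e-10)
  }

  # identical sessions: exactly zero
  res0 <- paired_compare(pre, pre)
  expect_identical(res0$t, rep(0, 4))

  # constant shift: zero residual variance handled as an infinite-t
  # sentinel with p ~ 0
  resd <- paired_compare(pre[, 1, drop = FALSE], pre[, 1, drop = FALSE] + 2)
  expect_identical(resd$t, Inf)
  expect_identical(resd$p, 0)

  # unpaired subjects excluded by rowname with a warning
  rownames(pre) <- paste0("s", 1:n)
  post2 <- post; rownames(post2) <- paste0("s", c(1:(n - 1), n + 5))
  expect_warning(res2 <- paired_compare(pre, post2), "unpaired")
  expect_equal(attr(res2, "df"), n - 2)
})

test_that("BH correction reproduces hand-computed q-values", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(rep(0.01, 10)), rep(0.01, 10))
  # hand computation: sorted (0.005, 0.01, 0.03, 0.04), m = 4
  expect_equal(fdr_correct(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  # NaN propagates and shrinks the effective m
  q <- fdr_correct(c(0.01, NaN, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], c(0.02, 0.04))
  # monotone: q ordering follows p ordering
  set.seed(3)
  p <- runif(50)
  q <- fdr_correct(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
  expect_error(fdr_correct(c(0.1, 1.2)), "outside")
})

test_that("clinical correlations use the right coefficient and routing", {
  set.seed(4)
  x <- rnorm(12)
  expect_equal(correlate_clinical(x, x)$estimate, 1)

  # monotone but nonlinear: rank correlation saturates, Pearson does not
  y <- exp(x)
  expect_equal(correlate_clinical(x, y, "spearman")$estimate, 1)
  expect_lt(correlate_clinical(x, y, "pearson")$estimate, 1)

  # definitional rank-formula oracle on 6 untied points
  m6 <- c(2.1, 0.3, 1.4, 3.3, 0.9, 2.8)
  s6 <- c(10, 2, 7, 12, 1, 9)
  d <- rank(m6) - rank(s6)
  rho_oracle <- 1 - 6 * sum(d^2) / (6 * 35)
  expect_equal(correlate_clinical(m6, s6, "spearman")$estimate, rho_oracle,
               tolerance = 1e-12)

  # TDI is ordinal: Spearman is forced regardless of the requested method
  out <- correlate_clinical(x, round(y), method = "pearson",
                            score_name = "tdi")
  expect_identical(out$method, "spearman")

  expect_warning(out0 <- correlate_clinical(x, rep(1, 12)), "zero variance")
  expect_true(is.nan(out0$estimate))
})

test_that("demographic comparisons route by type and normality", {
  records <- data.frame(
    subject_id = c(paste0("P", 1:17), paste0("C", 1:22)),
    group = rep(c("patient", "control"), c(17, 22)),
    session = rep(c("pre", "none"), c(17, 22)),
    sex = c(rep("M", 7), rep("F", 10), rep("M", 6), rep("F", 16)),
    age = c(rnorm(17, 47, 10), rnorm(22, 47, 10)),
    stringsAsFactors = FALSE)
  # 2x2 chi-square oracle (uncorrected): n(ad - bc)^2 / row/col products,
  # which is 0.834 for a 7/10 vs 6/16 sex split
  out <- scale_compare(records, "two_sample", "sex")
  chi_oracle <- 39 * (7 * 16 - 10 * 6)^2 / (17 * 22 * 13 * 26)
  expect_equal(out$statistic, chi_oracle, tolerance = 1e-12)
  expect_equal(out$statistic, 0.834, tolerance = 1e-3)

  set.seed(5)
  out_age <- scale_compare(records, "two_sample", "age")
  expect_identical(out_age$test, "two_sample_t")

  # paired design with identical values: t = 0, p = 1
  paired <- data.frame(
    subject_id = rep(paste0("P", 1:8), 2),
    group = "patient", session = rep(c("pre", "post"), each = 8),
    thi = rep(rnorm(8, 50, 10), 2), tdi = rep(c(3, 4, 2, 5, 3, 4, 1, 2), 2),
    stringsAsFactors = FALSE)
  out_same <- scale_compare(paired, "paired", "thi")
  expect_identical(out_same$statistic, 0)
  expect_identical(out_same$p, 1)

  # the TDI route always reports a signed-rank statistic
  paired$tdi[paired$session == "post"] <- paired$tdi[paired$session == "post"] -
    c(1, 1, 0, 2, 1, 1, 0, 1)
  out_tdi <- scale_compare(paired, "paired", "tdi")
  expect_identical(out_tdi$test, "wilcoxon_signed_rank")
})

test_that("TP cell comparisons find a planted transition shift", {
  k <- 4
  base <- matrix(0.1 / 3, k, k); diag(base) <- 0.9
  shifted <- base
  shifted[2, 3] <- shifted[2, 3] + 0.15
  shifted[2, 2] <- shifted[2, 2] - 0.15
  set.seed(6)
  tp_a <- lapply(1:15, function(i)
    transition_probability(simulate_state_sequence(400, base), k))
  tp_b <- lapply(1:15, function(i)
    transition_probability(simulate_state_sequence(400, shifted), k))
  res <- compare_tp(c(tp_a, tp_b), group = rep(0:1, each = 15))
  expect_identical(nrow(res), 16L)  # N x N transition kinds
  expect_false(attr(res, "corrected"))
  # the planted cell (and its row-sum counterpart 2->2, which must move
  # in the opposite direction) dominate every untouched cell
  planted <- res$from == 2 & res$to == 3
  counter <- res$from == 2 & res$to == 2
  expect_lt(res$p[planted], min(res$p[!planted & !counter]))
  expect_gt(res$t[planted], 0)
  expect_lt(res$t[counter], 0)

  # identical matrices in both groups: no effect anywhere
  res0 <- compare_tp(rep(list(base), 10), group = rep(0:1, each = 5))
  expect_true(all(res0$t == 0))
})
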