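#' Connection-wise GLM group comparison with covariates
#'
#' Fits, per feature (connection metric, TP cell, ...), the linear model
#' `feature ~ intercept + group + covariates` by least squares and
#' reports the t statistic on the group coefficient with its two-sided
#' p-value (df = n - rank).  Continuous covariates (age, mean FD) are
#' mean-centred and sex is entered as a single indicator so the group
#' coefficient keeps its interpretation as an adjusted group difference.
#' With no covariates the statistic is algebraically the pooled-variance
#' two-sample t.  Collinear covariates are dropped with a warning.
#' Features with zero residual variance report t = 0, p = 1 when the
#' group effect is also zero, and an infinite-t sentinel with p = 0
#' otherwise.
#'
#' @param features subjects x features numeric matrix.
#' @param group length-n indicator (0/1, logical, or two-level factor);
#'   the reported effect direction is level 2 minus level 1.
#' @param covariates optional subjects x c numeric matrix (no missing
#'   values).
#' @return A data frame of class `group_stat_result` with columns
#'   `feature`, `t`, `p`, `direction` and attributes `df`, `model`,
#'   `n_features`.
#' @export
glm_group_compare <- function(features, group, covariates = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  g <- encode_indicator(group)
  if (length(g) != n) stop("glm_group_compare: group length mismatch")
  X <- cbind(intercept = 1, group = g)
  X <- add_covariates(X, covariates, n)
  res <- fit_feature_glm(features, X, coef_name = "group")
  structure(res, class = c("group_stat_result", class(res)),
            model = paste("feature ~ intercept + group",
                          if (ncol(X) > 2) "+ covariates" else ""),
            df = attr(res, "df"), n_features = ncol(features))
}

encode_indicator <- function(group) {
  if (is.factor(group) || is.character(group)) {
    lev <- unique(as.character(group))
    if (length(lev) != 2) stop("group must have exactly 2 levels")
    as.numeric(as.character(group) == lev[2])
  } else {
    as.numeric(group)
  }
}

add_covariates <- function(X, covariates, n) {
  if (is.null(covariates)) return(X)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) stop("covariate rows do not match subjects")
  if (anyNA(covariates)) stop("missing covariate values are not allowed")
  covariates <- apply(covariates, 2L, function(col) col - mean(col))
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  }
  cbind(X, covariates)
}

# Shared per-feature least-squares machinery: t on one design column.
fit_feature_glm <- function(features, X, coef_name) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    kept <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), kept)]
    if (coef_name %in% dropped) {
      stop("design column of interest ('", coef_name, "') is collinear")
    }
    warning("dropping collinear design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, kept, drop = FALSE]
    qrx <- qr(X)
  }
  n <- nrow(X)
  df <- n - qrx$rank
  if (df < 1) stop("no residual degrees of freedom (n = ", n, ", rank = ",
                   qrx$rank, ")")
  coefs <- qr.coef(qrx, features)
  resid <- qr.resid(qrx, features)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  j <- match(coef_name, colnames(X))
  var_scale <- xtx_inv[j, j]
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * var_scale)
  beta <- coefs[j, ]
  # perfectly fitted features (zero residual variance up to round-off):
  # no effect -> t = 0, p = 1; a non-zero effect with zero noise is an
  # infinite-t sentinel with p = 0
  feat_scale <- pmax(sqrt(colMeans(features^2)), 1)
  zero_resid <- sqrt(sigma2) <= 1e-10 * feat_scale
  eff_zero <- abs(beta) <= 1e-8 * feat_scale
  tstat <- ifelse(zero_resid,
                  ifelse(eff_zero, 0, sign(beta) * Inf),
                  beta / se)
  p <- ifelse(is.infinite(tstat), 0, 2 * stats::pt(-abs(tstat), df))
  p[zero_resid & eff_zero] <- 1
  out <- data.frame(
    feature = if (is.null(colnames(features)))
      paste0("f", seq_len(ncol(features))) else colnames(features),
    t = unname(tstat), p = unname(p),
    direction = ifelse(tstat > 0, "positive",
                       ifelse(tstat < 0, "negative", "none")),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df") <- df
  out
}

#' Covariate-adjusted paired comparison
#'
#' Regresses per-feature difference scores (post minus pre) on an
#' intercept plus optional covariates; the t statistic on the intercept
#' tests the mean within-subject change.  With no covariates this is the
#' classical paired t-test.  Rows must be aligned by subject; rows named
#' in only one matrix are dropped with a warning.
#'
#' @param features_pre,features_post subject-aligned feature matrices
#'   (matching rownames are used for pairing when present).
#' @param covariates optional subjects x c matrix.
#' @return A `group_stat_result` data frame (see [glm_group_compare()]).
#' @export
paired_compare <- function(features_pre, features_post, covariates = NULL) {
  features_pre <- as.matrix(features_pre)
  features_post <- as.matrix(features_post)
  if (!is.null(rownames(features_pre)) && !is.null(rownames(features_post))) {
    common <- intersect(rownames(features_pre), rownames(features_post))
    dropped <- setdiff(union(rownames(features_pre), rownames(features_post)),
                       common)
    if (length(dropped) > 0) {
      warning("paired_compare: unpaired subject(s) excluded: ",
              paste(dropped, collapse = ", "))
      if (!is.null(covariates)) {
        covariates <- as.matrix(covariates)[match(common, rownames(features_pre)), ,
                                            drop = FALSE]
      }
    }
    features_pre <- features_pre[common, , drop = FALSE]
    features_post <- features_post[common, , drop = FALSE]
  }
  if (nrow(features_pre) != nrow(features_post)) {
    stop("paired_compare: pre/post subject counts differ and rownames absent")
  }
  diffs <- features_post - features_pre
  X <- cbind(intercept = rep(1, nrow(diffs)))
  X <- add_covariates(X, covariates, nrow(diffs))
  res <- fit_feature_glm(diffs, X, coef_name = "intercept")
  structure(res, class = c("group_stat_result", class(res)),
            model = "post - pre ~ intercept + covariates",
            df = attr(res, "df"), n_features = ncol(diffs))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted values `q(i) = min_{j >= i} m p(j) / j` over the
#' sorted p-values, mapped back to input order; `NaN`/`NA` entries are
#' propagated and excluded from the effective m.  q never falls below
#' its p and preserves the p-value ordering.
#'
#' @param p vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of adjusted q-values, same length and order.
#' @export
fdr_correct <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("fdr_correct: p-values outside [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Clinical correlation between an imaging metric and a symptom score
#'
#' Pearson product-moment or Spearman rank correlation with a two-sided
#' p-value from the t approximation, on pairwise-complete observations.
#' Ordinal loudness ratings (TDI, a 0-6 level scale) are automatically
#' routed to Spearman regardless of `method` when `score_name = "tdi"`.
#'
#' @param metric,score numeric vectors per subject.
#' @param method `"pearson"` or `"spearman"`.
#' @param score_name optional score label; `"tdi"` forces Spearman.
#' @return A list with `estimate`, `p`, `method`, `n`.
#' @export
correlate_clinical <- function(metric, score,
                               method = c("pearson", "spearman"),
                               score_name = NULL) {
  method <- match.arg(method)
  if (!is.null(score_name) && tolower(score_name) == "tdi") {
    method <- "spearman"
  }
  ok <- is.finite(metric) & is.finite(score)
  metric <- metric[ok]
  score <- score[ok]
  n <- length(metric)
  if (n < 4) stop("correlate_clinical: need at least 4 complete pairs")
  if (stats::sd(metric) == 0 || stats::sd(score) == 0) {
    warning("correlate_clinical: zero variance; correlation undefined")
    return(list(estimate = NaN, p = NaN, method = method, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(metric, score, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value, method = method, n = n)
}

#' Demographic and clinical scale comparisons
#'
#' Reproduces the usual cohort-table tests: continuous variables are
#' gated per group by a Shapiro-Wilk normality test (alpha 0.05) and
#' compared by Student's t (two-sample pooled-variance, or paired) when
#' normal, otherwise by the Wilcoxon test (signed-rank when paired, rank
#' sum otherwise).  The ordinal TDI loudness scale always takes the
#' Wilcoxon route.  Categorical variables (sex) use an uncorrected
#' Pearson chi-square test on the 2 x 2 contingency table.
#'
#' @param records data frame of subject metadata with at least `group`,
#'   `session`, `subject_id` and the requested variable.
#' @param design `"two_sample"` (patient vs control, pre/none sessions)
#'   or `"paired"` (patient pre vs post).
#' @param variable column name to compare.
#' @return A list with `test`, `statistic`, `p`, `n` (per-group or pair
#'   count), and `normal` (Shapiro p-values, continuous only).
#' @export
scale_compare <- function(records, design = c("two_sample", "paired"),
                          variable) {
  design <- match.arg(design)
  stopifnot(variable %in% names(records))
  if (design == "two_sample") {
    a <- records[records$group == "patient" &
                   records$session %in% c("pre", "none"), variable]
    b <- records[records$group == "control", variable]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (is.character(a) || is.factor(a) || is.character(b)) {
      tab <- table(c(rep("patient", length(a)), rep("control", length(b))),
                   c(as.character(a), as.character(b)))
      ct <- stats::chisq.test(tab, correct = FALSE)
      return(list(test = "chi_square", statistic = unname(ct$statistic),
                  p = ct$p.value, n = c(length(a), length(b))))
    }
    if (length(a) < 3 || length(b) < 3) stop("scale_compare: n < 3 per group")
    sw <- c(patient = stats::shapiro.test(a)$p.value,
            control = stats::shapiro.test(b)$p.value)
    use_t <- all(sw > 0.05) && tolower(variable) != "tdi"
    if (use_t) {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      list(test = "two_sample_t", statistic = unname(ht$statistic),
           p = ht$p.value, n = c(length(a), length(b)), normal = sw)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
      list(test = "wilcoxon_rank_sum", statistic = unname(ht$statistic),
           p = ht$p.value, n = c(length(a), length(b)), normal = sw)
    }
  } else {
    pre <- records[records$group == "patient" & records$session == "pre", ]
    post <- records[records$group == "patient" & records$session == "post", ]
    common <- intersect(pre$subject_id, post$subject_id)
    a <- pre[match(common, pre$subject_id), variable]
    b <- post[match(common, post$subject_id), variable]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]
    b <- b[keep]
    if (length(a) < 3) stop("scale_compare: fewer than 3 complete pairs")
    d <- b - a
    if (stats::sd(d) == 0) {
      # degenerate: identical pairs (t = 0) or a constant shift (|t| = Inf)
      return(list(test = "paired_t",
                  statistic = if (all(d == 0)) 0 else sign(d[1]) * Inf,
                  p = if (all(d == 0)) 1 else 0, n = length(a),
                  normal = c(diff = NA_real_)))
    }
    sw <- c(diff = stats::shapiro.test(d)$p.value)
    use_t <- all(sw > 0.05) && tolower(variable) != "tdi"
    if (use_t) {
      ht <- stats::t.test(b, a, paired = TRUE)
      list(test = "paired_t", statistic = unname(ht$statistic),
           p = ht$p.value, n = length(a), normal = sw)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE,
                                                exact = FALSE))
      list(test = "wilcoxon_signed_rank", statistic = unname(ht$statistic),
           p = ht$p.value, n = length(a), normal = sw)
    }
  }
}

#' Group or paired comparison of transition probabilities
#'
#' Applies [glm_group_compare()] (between designs) or [paired_compare()]
#' (within designs) to every cell of the k x k transition-probability
#' matrix.  Cells arising from unvisited source states are treated as
#' missing; a cell missing in more than half the subjects is skipped
#' with a message, otherwise subjects missing that cell are excluded
#' pairwise.  Following common practice for the small number of TP
#' cells, no FDR correction is applied by default and the result is
#' flagged `corrected = FALSE`.
#'
#' @param tp_list list of [transition_probability()] results (or k x k
#'   matrices), one per subject, in the row order of `group` /
#'   the pairing.
#' @param group two-level indicator for between designs, or `NULL` for
#'   paired designs.
#' @param pre_index,post_index row indices into `tp_list` pairing
#'   sessions for the paired design.
#' @param covariates optional covariate matrix (aligned with `tp_list`
#'   rows for between designs, with pairs for paired designs).
#' @param fdr apply BH correction across cells (default `FALSE`).
#' @return A data frame with columns `from`, `to`, `t`, `p` (and `q` if
#'   `fdr`), `n_used`; attribute `corrected` records the flag.
#' @export
compare_tp <- function(tp_list, group = NULL, pre_index = NULL,
                       post_index = NULL, covariates = NULL, fdr = FALSE) {
  mats <- lapply(tp_list, function(tp) {
    if (inherits(tp, "transition_matrix")) {
      m <- tp$probs
      m[!tp$visited, ] <- NA_real_
      m
    } else {
      as.matrix(tp)
    }
  })
  k <- nrow(mats[[1]])
  flat <- t(vapply(mats, as.vector, numeric(k * k)))  # subjects x k^2
  cells <- expand.grid(from = seq_len(k), to = seq_len(k))
  # as.vector() is column-major: cell (from, to) sits at (to-1)*k + from
  colnames(flat) <- sprintf("tp_%d_%d", cells$from, cells$to)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    y <- flat[, i]
    ok <- is.finite(y)
    if (mean(ok) < 0.5) {
      message("compare_tp: cell ", cells$from[i], "->", cells$to[i],
              " missing for >50% of subjects; skipped")
      next
    }
    if (!is.null(group)) {
      use <- ok
      res <- glm_group_compare(matrix(y[use], ncol = 1),
                               encode_indicator(group)[use],
                               if (is.null(covariates)) NULL
                               else as.matrix(covariates)[use, , drop = FALSE])
      n_used <- sum(use)
    } else {
      stopifnot(!is.null(pre_index), !is.null(post_index))
      use <- is.finite(y[pre_index]) & is.finite(y[post_index])
      if (sum(use) < 3) {
        message("compare_tp: cell ", cells$from[i], "->", cells$to[i],
                " has <3 complete pairs; skipped")
        next
      }
      res <- paired_compare(matrix(y[pre_index][use], ncol = 1),
                            matrix(y[post_index][use], ncol = 1),
                            if (is.null(covariates)) NULL
                            else as.matrix(covariates)[use, , drop = FALSE])
      n_used <- sum(use)
    }
    rows[[i]] <- data.frame(from = cells$from[i], to = cells$to[i],
                            t = res$t, p = res$p, n_used = n_used)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (isTRUE(fdr)) out$q <- fdr_correct(out$p)
  attr(out, "corrected") <- isTRUE(fdr)
  out
}
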