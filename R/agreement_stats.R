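# Measurement-agreement and test-retest statistics: repeated-measures
# Bland-Altman limits of agreement, bias t tests with Bonferroni
# correction, Levene variance comparisons, and exact Wilcoxon signed-rank
# test-retest comparisons.

#' Repeated-measures Bland-Altman agreement between two timing methods
#'
#' Differences d = A - B are matched on (subject, repetition, hand,
#' subtest). Because the true value changes between repetitions (practice
#' effect), the standard deviation of the differences combines the
#' within-subject and between-subject components estimated from a one-way
#' ANOVA of d on subject: within = residual mean square, between =
#' max(0, (MS_subject - MS_residual) / m_h) with m_h the harmonic mean of
#' per-subject difference counts. The 95\% limits of agreement are
#' bias +/- 1.96 * sd_diff. With one observation per subject this reduces
#' exactly to the classic Bland-Altman computation (sample SD of the
#' differences); a single subject falls back to the plain SD with a
#' warning.
#'
#' @param table An [times_table()].
#' @param pair Character vector of two method names, difference is
#'   `pair[1] - pair[2]`.
#' @param field `"total"`, `"start"` or `"end"` (selects `total_s`, ...).
#' @return An `agreement_result` with `bias_s`, `sd_diff_s`, `loa_low_s`,
#'   `loa_high_s`, per-subject means, and component variances.
#' @export
bland_altman_repeated <- function(table, pair, field = c("total", "start",
                                                         "end")) {
  field <- match.arg(field)
  col <- paste0(field, "_s")
  table <- as.data.frame(table)
  key <- c("subject_id", "repetition", "hand", "subtest")
  a <- table[table$method == pair[1], c(key, col)]
  b <- table[table$method == pair[2], c(key, col)]
  if (!nrow(a) || !nrow(b))
    mjt_stop(sprintf("no rows for method '%s'",
                     pair[c(!nrow(a), !nrow(b))][1]), "mjt_missing_method")
  m <- merge(a, b, by = key, suffixes = c("_a", "_b"))
  missing_a <- nrow(b) - nrow(m); missing_b <- nrow(a) - nrow(m)
  if (nrow(m) < nrow(a) || nrow(m) < nrow(b)) {
    um <- if (nrow(m) < nrow(a)) a else b
    miss <- um[!do.call(paste, um[key]) %in% do.call(paste, m[key]), ]
    mjt_stop(sprintf("method/field missing for subject %s repetition %s",
                     miss$subject_id[1], miss$repetition[1]),
             "mjt_missing_method")
  }
  d <- m[[paste0(col, "_a")]] - m[[paste0(col, "_b")]]
  subj <- factor(m$subject_id)
  bias <- mean(d)
  n_i <- as.numeric(table(subj))
  k <- nlevels(subj)
  subject_means <- tapply(d, subj, mean)
  if (k == 1L) {
    warning("single subject: between-subject variance undefined, using plain SD")
    var_within <- stats::var(d); var_between <- 0
    sd_diff <- sd(d)
  } else if (all(n_i == 1)) {
    var_within <- 0; var_between <- stats::var(d)   # classic Bland-Altman
    sd_diff <- sd(d)
  } else {
    av <- suppressWarnings(anova(aov(d ~ subj)))  # mean squares only
    ms_subj <- av["subj", "Mean Sq"]
    ms_resid <- av["Residuals", "Mean Sq"]
    m_h <- k / sum(1 / n_i)
    var_within <- ms_resid
    var_between <- max(0, (ms_subj - ms_resid) / m_h)
    sd_diff <- sqrt(var_within + var_between)
  }
  structure(list(method_pair = pair, field = field,
                 bias_s = bias, sd_diff_s = sd_diff,
                 loa_low_s = bias - 1.96 * sd_diff,
                 loa_high_s = bias + 1.96 * sd_diff,
                 var_within = var_within, var_between = var_between,
                 n_subjects = k, n_obs = length(d),
                 subject_means = as.numeric(subject_means),
                 t_stat = NA_real_, p_bias = NA_real_,
                 p_bias_adj = NA_real_, degenerate = FALSE),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %s - %s (%s time)\n", x$method_pair[1],
              x$method_pair[2], x$field))
  cat(sprintf("  bias %.3f s, SD of differences %.3f s\n  95%% LoA [%.3f, %.3f] s (%d subjects, %d differences)\n",
              x$bias_s, x$sd_diff_s, x$loa_low_s, x$loa_high_s,
              x$n_subjects, x$n_obs))
  if (!is.na(x$p_bias))
    cat(sprintf("  bias t test: t = %.3f, p = %.4g (Bonferroni-adjusted %.4g)%s\n",
                x$t_stat, x$p_bias, x$p_bias_adj,
                if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Test whether the agreement bias differs from zero
#'
#' One-sample t test of the per-subject mean differences against 0, with
#' Bonferroni adjustment over `m_comparisons` method pairs. A zero-variance
#' set of subject means with nonzero bias is degenerate (t infinite, p 0,
#' flagged); all-zero means give t = 0, p = 1.
#'
#' @param result An [bland_altman_repeated()] result.
#' @param m_comparisons Bonferroni family size (default 3: the three
#'   method pairs compared per subtest/hand/time-type).
#' @return The `agreement_result` with `t_stat`, `p_bias`, `p_bias_adj`
#'   and `degenerate` filled in.
#' @export
bias_t_test <- function(result, m_comparisons = 3) {
  stopifnot(inherits(result, "agreement_result"))
  x <- result$subject_means
  if (length(x) < 2L)
    mjt_stop("bias t test needs at least 2 subjects", "mjt_contract")
  if (sd(x) == 0) {
    if (mean(x) == 0) { result$t_stat <- 0; result$p_bias <- 1 }
    else {
      result$t_stat <- sign(mean(x)) * Inf
      result$p_bias <- 0
      result$degenerate <- TRUE
    }
  } else {
    tt <- t.test(x, mu = 0)
    result$t_stat <- unname(tt$statistic)
    result$p_bias <- tt$p.value
  }
  result$p_bias_adj <- min(1, m_comparisons * result$p_bias)
  result
}

#' Pairwise Levene tests for equality of difference variances
#'
#' Classic Levene test (mean-centred absolute deviations, one-way F) for
#' every pair of difference samples, Bonferroni-adjusted with family size
#' `m_comparisons` (default: the number of pairs).
#'
#' @param diff_sets Named list of numeric difference samples (each length
#'   >= 3).
#' @param m_comparisons Bonferroni family size; default is the number of
#'   pairs.
#' @return Data frame with columns `set_a`, `set_b`, `F`, `p`, `p_adj`.
#' @export
levene_equal_variance <- function(diff_sets, m_comparisons = NULL) {
  stopifnot(is.list(diff_sets), length(diff_sets) >= 2L)
  if (any(vapply(diff_sets, length, integer(1)) < 3L))
    mjt_stop("every difference set needs at least 3 values", "mjt_contract")
  if (is.null(names(diff_sets)))
    names(diff_sets) <- paste0("set", seq_along(diff_sets))
  pairs <- utils::combn(length(diff_sets), 2)
  if (is.null(m_comparisons)) m_comparisons <- ncol(pairs)
  out <- data.frame(set_a = character(0), set_b = character(0),
                    F = numeric(0), p = numeric(0), p_adj = numeric(0))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    y <- c(diff_sets[[i1]], diff_sets[[i2]])
    g <- factor(rep(c(1, 2), c(length(diff_sets[[i1]]),
                               length(diff_sets[[i2]]))))
    lt <- car::leveneTest(y, g, center = mean)
    out <- rbind(out, data.frame(
      set_a = names(diff_sets)[i1], set_b = names(diff_sets)[i2],
      F = lt[1, "F value"], p = lt[1, "Pr(>F)"],
      p_adj = min(1, m_comparisons * lt[1, "Pr(>F)"])))
  }
  out
}

#' Wilcoxon signed-rank comparison of first and second repetitions
#'
#' Paired two-sided Wilcoxon signed-rank test of `rep1 - rep2`. Zero
#' differences are dropped and ties mid-ranked; the p value is exact (by
#' the distribution of the positive-rank sum over all sign assignments,
#' computed by dynamic programming, valid with ties) for up to 25 nonzero
#' differences, and a tie-corrected normal approximation with continuity
#' correction above that. Summary statistics are the median and IQR of
#' `rep1 - rep2`.
#'
#' @param rep1,rep2 Paired numeric vectors (length >= 5).
#' @param m_comparisons Bonferroni family size (default 3: the three
#'   subtests compared per hand and method).
#' @return A `retest_result` with `median_diff_s`, `iqr_s`, `p_wilcoxon`,
#'   `p_adj`, `n_nonzero` and `statistic` (positive-rank sum).
#' @export
wilcoxon_retest <- function(rep1, rep2, m_comparisons = 3) {
  stopifnot(length(rep1) == length(rep2), length(rep1) >= 5L)
  d <- rep1 - rep2
  med <- median(d); iqr <- IQR(d)
  dn <- d[d != 0]
  n <- length(dn)
  if (n == 0L) {
    p <- 1; w <- 0
  } else {
    r <- rank(abs(dn))
    w <- sum(r[dn > 0])
    p <- if (n <= 25L) signed_rank_exact_p(r, w)
         else signed_rank_normal_p(r, w)
  }
  structure(list(median_diff_s = med, iqr_s = iqr, p_wilcoxon = p,
                 p_adj = min(1, m_comparisons * p),
                 statistic = w, n_nonzero = n),
            class = "retest_result")
}

#' @export
print.retest_result <- function(x, ...) {
  cat(sprintf("<retest_result> median difference %.3f s (IQR %.3f s), V = %g, p = %.4g (adjusted %.4g)\n",
              x$median_diff_s, x$iqr_s, x$statistic, x$p_wilcoxon, x$p_adj))
  invisible(x)
}

# internal: exact two-sided p for the positive-rank sum w given the
# (possibly mid-ranked) ranks r, by dynamic programming over the 2^n sign
# assignments. Ranks are doubled so mid-ranks (x.5) become integers; the
# distribution of 2*W is built by convolving (1 + z^(2 r_i)).
signed_rank_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  cnt <- numeric(total + 1L)   # cnt[s + 1] = #assignments with 2W = s
  cnt[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), cnt[seq_len(total + 1L - ri)])
    cnt <- cnt + shifted
  }
  probs <- cnt / sum(cnt)
  w2 <- as.integer(round(2 * w))
  p_le <- sum(probs[seq_len(w2 + 1L)])
  p_ge <- sum(probs[seq.int(w2 + 1L, total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

# internal: tie-corrected normal approximation with continuity correction
# (matching the standard large-sample signed-rank z)
signed_rank_normal_p <- function(r, w) {
  n <- length(r)
  mu <- n * (n + 1) / 4
  tie_table <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_table^3 - tie_table) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}
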