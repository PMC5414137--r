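panel_2x2 <- function(d_by_subject) {
  # two methods whose differences per (subject, repetition) are given
  rows <- list()
  for (s in seq_along(d_by_subject)) for (r in seq_along(d_by_subject[[s]])) {
    base <- 10 + s
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = paste0("S", s), repetition = r, hand = "most",
      subtest = "card", method = c("kinect", "ground_truth"),
      start_s = 0, end_s = c(base + d_by_subject[[s]][r], base),
      total_s = c(base + d_by_subject[[s]][r], base))
  }
  times_table(do.call(rbind, rows))
}

test_that("identical methods give zero bias and zero-width limits of agreement", {
  tbl <- panel_2x2(list(c(0, 0), c(0, 0), c(0, 0)))
  res <- bland_altman_repeated(tbl, c("kinect", "ground_truth"), "total")
  expect_equal(res$bias_s, 0)
  expect_equal(res$sd_diff_s, 0)
  expect_equal(c(res$loa_low_s, res$loa_high_s), c(0, 0))
})

test_that("repeated-measures SD combines ANOVA variance components", {
  # 2 subjects x 2 reps, d = {1,1} and {3,3}: bias 2; MS_resid 0,
  # MS_subject 4, harmonic mean 2 -> between variance 2, sd sqrt(2)
  tbl <- panel_2x2(list(c(1, 1), c(3, 3)))
  res <- bland_altman_repeated(tbl, c("kinect", "ground_truth"), "total")
  expect_equal(res$bias_s, 2)
  expect_equal(res$var_within, 0)
  expect_equal(res$var_between, 2)
  expect_equal(res$sd_diff_s, sqrt(2))
  expect_equal(res$loa_low_s, 2 - 1.96 * sqrt(2))
  expect_equal(res$loa_high_s, 2 + 1.96 * sqrt(2))
})

test_that("one observation per subject reduces exactly to classic Bland-Altman", {
  set.seed(17)
  d <- rnorm(12, 0.3, 0.4)
  tbl <- panel_2x2(as.list(d))   # every subject has a single repetition
  res <- bland_altman_repeated(tbl, c("kinect", "ground_truth"), "total")
  expect_equal(res$bias_s, mean(d))
  expect_equal(res$sd_diff_s, sd(d))
  expect_equal(res$loa_high_s, mean(d) + 1.96 * sd(d))
})

test_that("LoA width identity 3.92 * sd holds on random panels", {
  set.seed(23)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    tbl <- panel_2x2(lapply(seq_len(k), function(s) rnorm(2, rnorm(1), 0.5)))
    res <- bland_altman_repeated(tbl, c("kinect", "ground_truth"), "total")
    expect_equal(res$loa_high_s - res$loa_low_s, 3.92 * res$sd_diff_s)
  }
})

test_that("missing subject-repetition pairs and single subjects are handled", {
  tbl <- panel_2x2(list(c(1, 1), c(2, 2)))
  tbl <- tbl[!(tbl$subject_id == "S2" & tbl$repetition == 2 &
                 tbl$method == "kinect"), ]
  err <- tryCatch(
    bland_altman_repeated(times_table(tbl), c("kinect", "ground_truth"),
                          "total"),
    error = identity)
  expect_s3_class(err, "mjt_missing_method")
  expect_match(conditionMessage(err), "S2")
  expect_warning(
    one <- bland_altman_repeated(panel_2x2(list(c(1, 2))),
                                 c("kinect", "ground_truth"), "total"),
    "single subject")
  expect_equal(one$sd_diff_s, sd(c(1, 2)))
})

test_that("bias t test matches the closed form and flags degeneracy", {
  mk <- function(subject_means) {
    res <- bland_altman_repeated(panel_2x2(lapply(subject_means, rep, 2)),
                                 c("kinect", "ground_truth"), "total")
    res
  }
  r0 <- bias_t_test(mk(c(0, 0, 0)))
  expect_identical(r0$t_stat, 0)
  expect_identical(r0$p_bias, 1)
  r1 <- bias_t_test(mk(c(1, 1, 1)))
  expect_true(is.infinite(r1$t_stat))
  expect_true(r1$degenerate)
  expect_identical(r1$p_bias, 0)
  x <- c(0.1, 0.2, 0.3, 0.2)
  r2 <- bias_t_test(mk(x), m_comparisons = 3)
  t_oracle <- mean(x) / (sd(x) / sqrt(4))            # closed form
  p_oracle <- 2 * pt(-abs(t_oracle), df = 3)
  expect_equal(r2$t_stat, t_oracle)
  expect_equal(r2$p_bias, p_oracle)
  expect_equal(r2$p_bias_adj, min(1, 3 * p_oracle))
})

test_that("pairwise Levene tests detect unequal variances, Bonferroni-capped", {
  set.seed(29)
  a <- rnorm(50, 0, 1)
  res_same <- levene_equal_variance(list(a = a, b = a))
  expect_lt(res_same$F, 1e-9)
  expect_gt(res_same$p, 0.99)
  b <- rnorm(50, 0, 10)
  res_diff <- levene_equal_variance(list(a = a, b = b), m_comparisons = 3)
  expect_lt(res_diff$p_adj, 0.05)
  three <- levene_equal_variance(list(a = a, b = b, c = rnorm(50, 0, 1)))
  expect_identical(nrow(three), 3L)
  expect_equal(three$p_adj, pmin(1, 3 * three$p))
  expect_error(levene_equal_variance(list(a = a, b = c(1, 2))),
               class = "mjt_contract")
})

test_that("wilcoxon retest: medians, IQR, exact p for clean patterns", {
  r <- wilcoxon_retest(c(5, 6, 7, 8, 9), c(5, 6, 7, 8, 9))
  expect_identical(r$p_wilcoxon, 1)
  expect_identical(r$median_diff_s, 0)
  # n = 6, all differences positive and untied: two-sided p = 2/64
  r6 <- wilcoxon_retest(c(10, 11, 12, 13, 14, 15) + (1:6) / 10,
                        c(10, 11, 12, 13, 14, 15))
  expect_equal(r6$p_wilcoxon, 2 / 64)
  expect_equal(r6$p_adj, 6 / 64)
})

test_that("exact signed-rank p equals sign-pattern enumeration for n <= 12", {
  set.seed(41)
  for (i in 1:12) {
    n <- sample(5:12, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3, 0), n, TRUE)  # ties and zeros
    if (all(d == 0)) d[1] <- 1
    r <- wilcoxon_retest(d + 10, rep(10, n))
    expect_equal(r$p_wilcoxon, enum_signed_rank_p(d), tolerance = 1e-12,
                 label = paste("d =", paste(d, collapse = ",")))
  }
})

test_that("large-sample path approximates the exact distribution", {
  set.seed(43)
  d <- c(rnorm(30, 0.3))     # n = 30 > 25: normal approximation
  r <- wilcoxon_retest(d + 1, rep(1, 30))
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  expect_equal(r$p_wilcoxon, ref, tolerance = 1e-10)
})

test_that("parameter recovery on a simulated panel", {
  tbl <- simulate_times_panel(200, bias_s = 0.2, sd_within_s = 0.3,
                              sd_between_s = 0.1, practice_effect_s = 1,
                              seed = 99)
  res <- bland_altman_repeated(tbl, c("kinect", "ground_truth"), "total")
  expect_lt(abs(res$bias_s - 0.2), 0.05)
  expect_lt(abs(res$sd_diff_s - sqrt(0.3^2 + 0.1^2)) / sqrt(0.3^2 + 0.1^2),
            0.10)
  # the practice effect shows up in the retest comparison
  gt <- tbl[tbl$method == "ground_truth", ]
  w <- wilcoxon_retest(gt$total_s[gt$repetition == 1],
                       gt$total_s[gt$repetition == 2])
  expect_equal(w$median_diff_s, 1, tolerance = 0.15)
  expect_lt(w$p_adj, 0.05)
})
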