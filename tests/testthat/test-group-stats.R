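test_that("single-factor RM ANOVA equals the squared paired t", {
  # hand-computed example: differences (1,2,2) give t = 5, so F = 25, df (1,2)
  d <- data.frame(subject = factor(rep(1:3, 2)),
                  A = factor(rep(c("x", "y"), each = 3)),
                  value = c(1, 2, 3, 2, 4, 5))
  res <- rm_anova_within(d, within = "A")
  expect_equal(res$F, 25, tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(1, 2))
  tt <- paired_t(c(1, 2, 3), c(2, 4, 5))
  expect_equal(tt$t, -5)
  expect_equal(tt$df, 2)
  expect_equal(res$F, tt$t^2, tolerance = 1e-10)

  # identity holds on random data too
  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    d <- data.frame(subject = factor(rep(seq_len(n), 2)),
                    A = factor(rep(c("x", "y"), each = n)), value = c(x, y))
    expect_equal(rm_anova_within(d, within = "A")$F, paired_t(x, y)$t^2,
                 tolerance = 1e-10)
  }
})

test_that("two-factor decomposition matches brute-force and aov oracles", {
  set.seed(21)
  for (i in 1:10) {
    d <- random_rm_table()
    res <- rm_anova_within(d, within = c("A", "B"))
    bf <- bf_rm_anova(d, within = c("A", "B"))
    expect_equal(res$F, bf$F, tolerance = 1e-8)
    expect_equal(res$eta_sq_partial, bf$eta, tolerance = 1e-8)
    expect_equal(res$df1, bf$df1)
    expect_equal(res$df2, bf$df2)
    fit <- summary(stats::aov(value ~ A * B + Error(subject / (A * B)), data = d))
    aovF <- vapply(fit[2:4], function(s) s[[1]]$`F value`[1], numeric(1))
    expect_equal(res$F, unname(aovF), tolerance = 1e-8)
  }
})

test_that("sums of squares partition conserves the total", {
  set.seed(33)
  for (i in 1:10) {
    d <- random_rm_table(n_subj = 5)
    res <- rm_anova_within(d, within = c("A", "B"))
    s <- factor(d$subject)
    ss_s <- sum(table(s)[1] * 0) + sum(tapply(d$value, s, function(v)
      length(v) * (mean(v) - mean(d$value))^2))
    expect_equal(sum(res$ss) + sum(res$ss_error) + ss_s,
                 sum((d$value - mean(d$value))^2), tolerance = 1e-8)
  }
})

test_that("null and degenerate designs behave per contract", {
  # value depends only on subject: effect SS 0, F 0 against positive error SS
  d <- expand.grid(subject = factor(1:4), A = factor(c("x", "y")))
  d$value <- as.numeric(d$subject)
  d$value <- d$value + c(0.1, -0.1, 0.2, -0.2, -0.1, 0.1, -0.2, 0.2) # noise, no A effect mean
  dn <- d; dn$value <- as.numeric(dn$subject)
  res <- rm_anova_within(dn, within = "A")
  expect_equal(res$ss, 0)
  expect_equal(res$F, 0)

  # missing cell -> unbalanced; single subject -> insufficient
  expect_error(rm_anova_within(d[-1, ], within = "A"), "unbalanced")
  expect_error(rm_anova_within(d[d$subject == 1, ], within = "A"),
               "insufficient")
})

test_that("paired t handles trivial, degenerate, and error cases", {
  x <- rnorm(8)
  t0 <- paired_t(x, x)
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  expect_error(paired_t(1, 1), "insufficient")
  expect_error(paired_t(1:3, 1:2), "equal length")
  # zero-variance nonzero-mean differences: infinite t flagged with p = 0
  dz <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(is.infinite(dz$t) && dz$t > 0)
  expect_equal(dz$p, 0)
  expect_true(dz$degenerate)
  # agreement with t.test on regular input
  y <- rnorm(8)
  tt <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
})

test_that("Bonferroni adjustment caps at 1 and validates m", {
  expect_equal(bonferroni_adjust(0.02, 3), 0.06)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(0.3, 1), 0.3)
  expect_error(bonferroni_adjust(0.1, 0), "m")
  expect_error(bonferroni_adjust(1.2, 2), "\\[0, 1\\]")
  expect_equal(bonferroni_adjust(0.02, 3),
               p.adjust(0.02, "bonferroni", n = 3))
})

test_that("pairwise posthocs cover all level pairs with the stated correction", {
  set.seed(3)
  d <- expand.grid(subject = factor(1:10),
                   subsystem = factor(c("MT", "Core", "FT")))
  d$value <- rnorm(nrow(d)) + (d$subsystem == "FT") * 2
  ph <- pairwise_paired_t(d, within = "subsystem", m = 3)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_bonferroni, pmin(1, 3 * ph$p_raw))
  expect_equal(ph$df, rep(9, 3))
  ft_rows <- ph[ph$level_a == "FT" | ph$level_b == "FT", ]
  expect_true(all(ft_rows$p_bonferroni < 0.05))
})
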