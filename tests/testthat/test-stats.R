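test_that("Shapiro-Wilk wrapper screens normality", {
  bimodal <- c(rep(0, 25), rep(100, 25))
  expect_lt(shapiro_wilk(bimodal)$p.value, 0.01)
  withr::with_seed(1, {
    expect_gt(shapiro_wilk(rnorm(50))$p.value, 0.05)
  })
  expect_error(shapiro_wilk(c(1, 2)))
  expect_error(shapiro_wilk(rep(3, 10)))
})

test_that("ordinary one-way ANOVA matches a from-scratch computation", {
  df <- tibble::tibble(
    condition = rep(c("a", "b", "c"), each = 4),
    subject = paste0("s", 1:12),
    value = c(6.1, 5.8, 6.4, 6.0, 7.2, 7.8, 7.1, 7.5, 5.1, 4.8, 5.3, 5.0)
  )
  fit <- anova_oneway(df, value, condition)
  # sums of squares by hand
  gm <- mean(df$value)
  means <- tapply(df$value, df$condition, mean)
  ss_b <- sum(4 * (means - gm)^2)
  ss_w <- sum((df$value - means[df$condition])^2)
  f_manual <- (ss_b / 2) / (ss_w / 9)
  p_manual <- pf(f_manual, 2, 9, lower.tail = FALSE)
  g <- glance(fit)
  expect_equal(g$statistic, f_manual, tolerance = 1e-6)
  expect_equal(g$p.value, p_manual, tolerance = 1e-6)
  expect_equal(g$df1, 2)
  expect_equal(g$df2, 9)
})

test_that("two-group ordinary ANOVA F equals the squared pooled t", {
  withr::with_seed(14, {
    df <- tibble::tibble(
      condition = rep(c("a", "b"), each = 6),
      subject = paste0("s", 1:12),
      value = c(rnorm(6, 0), rnorm(6, 1))
    )
    f_stat <- glance(anova_oneway(df, value, condition))$statistic
    t_pooled <- t.test(value ~ condition, data = df, var.equal = TRUE)$statistic
    expect_equal(f_stat, unname(t_pooled)^2, tolerance = 1e-10)
  })
})

test_that("repeated-measures ANOVA partitions the within-subject error", {
  # fixed small dataset, manual RM decomposition as the oracle
  df <- tibble::tibble(
    condition = rep(c("t0", "t1", "t2"), each = 4),
    subject = rep(paste0("m", 1:4), times = 3),
    value = c(10, 12, 11, 13, 14, 15, 13, 16, 12, 13, 12, 15)
  )
  fit <- anova_oneway(df, value, condition, subject = subject,
                      repeated = TRUE)
  k <- 3; n <- 4
  gm <- mean(df$value)
  cond_means <- tapply(df$value, df$condition, mean)
  subj_means <- tapply(df$value, df$subject, mean)
  ss_cond <- n * sum((cond_means - gm)^2)
  ss_subj <- k * sum((subj_means - gm)^2)
  ss_tot <- sum((df$value - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_manual <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  g <- glance(fit)
  expect_equal(g$statistic, f_manual, tolerance = 1e-8)
  expect_equal(g$df1, k - 1)
  expect_equal(g$df2, (k - 1) * (n - 1))
  expect_equal(g$p.value,
               pf(f_manual, k - 1, (k - 1) * (n - 1), lower.tail = FALSE),
               tolerance = 1e-8)

  # identical values per subject across conditions: F = 0, p = 1
  flat <- tibble::tibble(
    condition = rep(c("t0", "t1", "t2"), each = 3),
    subject = rep(paste0("m", 1:3), times = 3),
    value = rep(c(5, 7, 9), times = 3)
  )
  gf <- glance(anova_oneway(flat, value, condition, subject = subject,
                            repeated = TRUE))
  expect_equal(gf$statistic, 0)
  expect_equal(gf$p.value, 1)

  # Greenhouse-Geisser shrinks the degrees of freedom and never lowers p
  gg <- glance(anova_oneway(df, value, condition, subject = subject,
                            repeated = TRUE,
                            sphericity = "greenhouse-geisser"))
  expect_lte(gg$df1, k - 1)
  expect_gte(gg$df1, 1)
  expect_gte(gg$p.value, g$p.value - 1e-12)
  expect_equal(gg$statistic, g$statistic)   # F itself is unchanged

  # unbalanced paired design is an error
  expect_error(
    anova_oneway(df[-1, ], value, condition, subject = subject,
                 repeated = TRUE),
    class = "gliavasc_unbalanced_design")
  expect_error(anova_oneway(df[df$condition == "t0", ], value, condition))
})

test_that("Tukey HSD matches stats::TukeyHSD and orders outlier contrasts", {
  withr::with_seed(23, {
    df <- tibble::tibble(
      condition = rep(c("a", "b", "c"), each = 5),
      subject = paste0("s", 1:15),
      value = c(rnorm(5, 0), rnorm(5, 0.3), rnorm(5, 4))
    )
    fit <- anova_oneway(df, value, condition)
    tk <- tukey_hsd(fit)
    ref <- TukeyHSD(aov(value ~ factor(condition), data = df))[[1]]
    expect_equal(sort(tk$adj.p.value), sort(unname(ref[, "p adj"])),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # the outlier group's two contrasts carry the smallest adjusted p
    ord <- tk[order(tk$adj.p.value), ]
    expect_true(all(grepl("c", ord$contrast[1:2])))

    # adjusted p >= unadjusted p computed from the same pooled error
    mse <- tidy(fit)$meansq[2]
    dfe <- tidy(fit)$df[2]
    means <- tapply(df$value, df$condition, mean)
    t_raw <- abs(means["a"] - means["b"]) / sqrt(2 * mse / 5)
    pair_p <- 2 * pt(-t_raw, dfe)
    ab <- tk$adj.p.value[tk$contrast %in% c("b-a", "a-b")]
    expect_gte(ab + 1e-12, unname(pair_p))
  })

  # identical groups: adjusted p ~ 1
  same <- tibble::tibble(
    condition = rep(c("a", "b"), each = 4),
    subject = paste0("s", 1:8),
    value = rep(c(1, 2, 3, 4), 2)
  )
  expect_gt(tukey_hsd(anova_oneway(same, value, condition))$adj.p.value, 0.99)
})

test_that("repeated-measures Tukey uses the within-subject error", {
  df <- tibble::tibble(
    condition = rep(c("t0", "t1", "t2"), each = 4),
    subject = rep(paste0("m", 1:4), times = 3),
    value = c(10, 12, 11, 13, 14, 15, 13, 16, 12, 13, 12, 15)
  )
  fit <- anova_oneway(df, value, condition, subject = subject,
                      repeated = TRUE)
  tk <- tukey_hsd(fit)
  expect_equal(nrow(tk), 3)
  # oracle for one contrast from the RM mean square
  mse <- tidy(fit)$meansq[2]
  dfe <- tidy(fit)$df[2]
  means <- tapply(df$value, df$condition, mean)
  q <- abs(means["t1"] - means["t0"]) / sqrt(mse / 4)
  p_manual <- ptukey(q, 3, dfe, lower.tail = FALSE)
  expect_equal(tk$adj.p.value[tk$contrast == "t1-t0"], unname(p_manual),
               tolerance = 1e-10)
})

test_that("Welch t matches the closed-form statistic and its pooled limit", {
  a <- c(5.1, 4.9, 5.6, 5.3, 5.0)
  b <- c(6.2, 6.8, 6.0, 6.6)
  res <- welch_t(a, b)
  se2 <- var(a) / 5 + var(b) / 4
  t_manual <- (mean(a) - mean(b)) / sqrt(se2)
  df_manual <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 4)^2 / 3)
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$df, df_manual, tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(-abs(t_manual), df_manual),
               tolerance = 1e-12)

  expect_equal(welch_t(a, a)$statistic, 0)
  expect_equal(welch_t(a, a)$p.value, 1)

  withr::with_seed(29, {
    x <- rnorm(8); y <- rnorm(8)
    y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)   # equalise variances
    pooled <- t.test(x, y, var.equal = TRUE)$statistic
    expect_equal(welch_t(x, y)$statistic, unname(pooled), tolerance = 1e-10)
  })
  expect_error(welch_t(1, c(2, 3)))
})

test_that("percent change reproduces printed worked examples", {
  expect_equal(round(percent_change(226.9, 334.9), 1), 47.6)
  expect_equal(round(percent_change(704.8, 1089), 1), 54.5)
  expect_equal(round(percent_change(1089, 842.8), 1), -22.6)
  expect_equal(percent_change(5, 5), 0)
  # antisymmetry identity: pc(a, b) = -pc(b, a) * b / a
  withr::with_seed(2, {
    a <- runif(20, 1, 100); b <- runif(20, 1, 100)
    expect_equal(percent_change(a, b), -percent_change(b, a) * b / a,
                 tolerance = 1e-12)
  })
  expect_error(percent_change(0, 5))
  expect_error(percent_change(-2, 5))
})
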