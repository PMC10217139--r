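#' Shapiro-Wilk normality test
#'
#' Thin tidy wrapper used to screen every measurement group before the
#' parametric group tests.
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @return One-row tibble: `test`, `statistic`, `p.value`, `n`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) abort("Shapiro-Wilk requires at least 3 values")
  if (length(unique(values)) == 1) abort("sample is constant")
  fit <- shapiro.test(values)
  tibble(test = "shapiro_wilk",
         statistic = unname(fit$statistic),
         p.value = fit$p.value,
         n = length(values))
}

#' One-way ANOVA (ordinary or repeated measures)
#'
#' Ordinary one-way ANOVA for independent groups (the confocal design) or
#' repeated-measures one-way ANOVA with within-subject error partitioning
#' (the intravital design, where the same animals are imaged across
#' conditions). Repeated designs must be balanced: every subject measured
#' once in every condition. No sphericity correction is applied by default.
#' When the between-condition sum of squares is exactly zero the test is
#' reported as `F = 0`, `p = 1`.
#'
#' @param data A data frame.
#' @param value,condition,subject Column names (tidy-eval) holding the
#'   measurement, the condition label, and (for repeated designs) the
#'   subject id.
#' @param repeated Use the repeated-measures design.
#' @param sphericity For repeated designs: `"none"` (default, the standard
#'   workflow) or `"greenhouse-geisser"`, which rescales both degrees of
#'   freedom by the Greenhouse-Geisser epsilon estimated from the
#'   double-centred covariance of the subject-by-condition matrix.
#' @return A `glia_anova` object; `tidy()` gives the ANOVA table,
#'   `glance()` the one-row summary.
#' @export
anova_oneway <- function(data, value, condition, subject = NULL,
                         repeated = FALSE,
                         sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  df <- tibble(
    value = dplyr::pull(data, {{ value }}),
    condition = factor(dplyr::pull(data, {{ condition }}))
  )
  if (nlevels(df$condition) < 2) {
    abort("at least two conditions are required")
  }
  if (any(table(df$condition) < 2)) {
    abort("every condition needs at least two observations")
  }
  if (repeated) {
    subj_quo <- rlang::enquo(subject)
    if (rlang::quo_is_null(subj_quo)) {
      abort("repeated design requires `subject`")
    }
    df$subject <- factor(dplyr::pull(data, !!subj_quo))
    tab <- table(df$subject, df$condition)
    if (any(tab != 1)) {
      abort("repeated design must be balanced: one value per subject per condition",
            class = "gliavasc_unbalanced_design")
    }
    fit <- aov(value ~ condition + Error(subject), data = df)
    s <- summary(fit)
    within <- s[["Error: Within"]][[1]]
    ss <- within[["Sum Sq"]]
    dfree <- within[["Df"]]
    f <- within[["F value"]][1]
    p <- within[["Pr(>F)"]][1]
    if (ss[1] <= 1e-12 * max(1, sum(ss))) {
      f <- 0
      p <- 1
    }
    dfree_out <- dfree
    if (sphericity == "greenhouse-geisser" && is.finite(f) && f > 0) {
      wide <- tapply(df$value, list(df$subject, df$condition), mean)
      S <- stats::cov(wide)
      k <- ncol(S)
      Sc <- sweep(S, 1, rowMeans(S))
      Sc <- sweep(Sc, 2, colMeans(S))
      Sc <- Sc + mean(S)
      eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
      eps <- min(max(eps, 1 / (k - 1)), 1)
      dfree_out <- dfree * eps
      p <- pf(f, dfree_out[1], dfree_out[2], lower.tail = FALSE)
    }
    out <- list(
      fit = fit, repeated = TRUE, data = df,
      table = tibble(term = c("condition", "residuals"),
                     df = dfree_out, sumsq = ss, meansq = ss / dfree,
                     statistic = c(f, NA), p.value = c(p, NA)),
      test = "rm_oneway_anova"
    )
  } else {
    fit <- aov(value ~ condition, data = df)
    s <- summary(fit)[[1]]
    ss <- s[["Sum Sq"]]
    dfree <- s[["Df"]]
    f <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
    if (ss[1] <= 1e-12 * max(1, sum(ss))) {
      f <- 0
      p <- 1
    }
    out <- list(
      fit = fit, repeated = FALSE, data = df,
      table = tibble(term = c("condition", "residuals"),
                     df = dfree, sumsq = ss, meansq = ss / dfree,
                     statistic = c(f, NA), p.value = c(p, NA)),
      test = "oneway_anova"
    )
  }
  structure(out, class = "glia_anova")
}

#' @export
print.glia_anova <- function(x, ...) {
  cat(sprintf("<glia_anova> %s: F(%.4g, %.4g) = %.4g, p = %.4g\n",
              x$test, x$table$df[1], x$table$df[2],
              x$table$statistic[1], x$table$p.value[1]))
  invisible(x)
}

#' @export
tidy.glia_anova <- function(x, ...) x$table

#' @export
glance.glia_anova <- function(x, ...) {
  tibble(test = x$test,
         statistic = x$table$statistic[1],
         df1 = x$table$df[1],
         df2 = x$table$df[2],
         p.value = x$table$p.value[1])
}

#' Tukey HSD multiple comparisons
#'
#' All pairwise condition comparisons with studentized-range adjusted
#' p-values. For ordinary designs this wraps [stats::TukeyHSD()]; for
#' repeated-measures designs the comparisons use the within-subject error
#' mean square with `(n-1)(k-1)` degrees of freedom.
#'
#' @param x A `glia_anova` from [anova_oneway()].
#' @param conf.level Confidence level for the intervals.
#' @return Tibble: `contrast`, `estimate`, `conf.low`, `conf.high`,
#'   `adj.p.value`.
#' @export
tukey_hsd <- function(x, conf.level = 0.95) {
  stopifnot(inherits(x, "glia_anova"))
  df <- x$data
  k <- nlevels(df$condition)
  if (k < 2) abort("at least two conditions are required")
  if (!x$repeated) {
    tk <- TukeyHSD(x$fit, conf.level = conf.level)$condition
    return(tibble(contrast = rownames(tk),
                  estimate = tk[, "diff"],
                  conf.low = tk[, "lwr"],
                  conf.high = tk[, "upr"],
                  adj.p.value = tk[, "p adj"]))
  }
  means <- tapply(df$value, df$condition, mean)
  n <- nlevels(df$subject)
  mse <- x$table$meansq[2]
  dfe <- x$table$df[2]
  lev <- levels(df$condition)
  pairs <- utils::combn(seq_len(k), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[2]; j <- pr[1]
    diff <- means[i] - means[j]
    se <- sqrt(mse / n)
    q <- abs(diff) / se
    p <- ptukey(q, k, dfe, lower.tail = FALSE)
    crit <- qtukey(conf.level, k, dfe) * se
    c(diff, diff - crit, diff + crit, p)
  })
  tibble(contrast = apply(pairs, 2, function(pr) {
           paste(lev[pr[2]], lev[pr[1]], sep = "-")
         }),
         estimate = rows[1, ],
         conf.low = rows[2, ],
         conf.high = rows[3, ],
         adj.p.value = pmin(rows[4, ], 1))
}

#' Welch two-sample t test
#'
#' Two-sided t test assuming unequal variances (Welch-Satterthwaite df),
#' the pairwise comparison used for independent-group (confocal) data.
#'
#' @param a,b Numeric samples, each `n >= 2`.
#' @return One-row tibble: `test`, `statistic`, `df`, `p.value`,
#'   `estimate`, `conf.low`, `conf.high`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample needs at least two values")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(test = "welch_t", statistic = 0, df = NA_real_,
                    p.value = 1, estimate = 0,
                    conf.low = 0, conf.high = 0))
    }
    abort("both samples are constant; t statistic undefined")
  }
  fit <- t.test(a, b, var.equal = FALSE)
  tibble(test = "welch_t",
         statistic = unname(fit$statistic),
         df = unname(fit$parameter),
         p.value = fit$p.value,
         estimate = unname(diff(rev(fit$estimate))),
         conf.low = fit$conf.int[1],
         conf.high = fit$conf.int[2])
}

#' Percent change relative to a baseline
#'
#' `100 * (value - baseline) / baseline`; the sign carries the direction.
#' Report tables display it to one decimal; the returned value keeps full
#' precision.
#'
#' @param baseline Strictly positive baseline value(s).
#' @param value Comparison value(s).
#' @return Signed percent change.
#' @examples
#' percent_change(226.9, 334.9) # +47.6
#' @export
percent_change <- function(baseline, value) {
  if (any(baseline <= 0)) abort("baseline must be strictly positive")
  100 * (value - baseline) / baseline
}
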