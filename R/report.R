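#' Build a group-statistics report
#'
#' Aggregates per-image measurements to per-subject means, screens each
#' condition with Shapiro-Wilk, runs the omnibus one-way ANOVA (repeated
#' measures for paired designs, ordinary otherwise), follows up with the
#' appropriate pairwise procedure (Tukey HSD for paired/intravital data,
#' Welch t tests for independent/confocal data), and reports percent
#' changes of each condition mean against the baseline condition.
#'
#' @param measurements A data frame with columns `condition`, `subject` and
#'   `value` (multiple rows per subject are averaged first).
#' @param conditions Optional condition order; default order of appearance.
#'   The first condition is the baseline unless `baseline` is given.
#' @param baseline Baseline condition label for percent changes.
#' @param paired Paired (repeated-measures) design: the same subjects
#'   across all conditions.
#' @param pairwise `"auto"` (Tukey if paired, Welch otherwise), `"tukey"`
#'   or `"welch"`.
#' @return A `glia_report`; `tidy()` returns the per-condition summary,
#'   `glance()` the omnibus test row, and `autoplot()` the group bar plot
#'   with per-subject points.
#' @export
build_report <- function(measurements, conditions = NULL, baseline = NULL,
                         paired = FALSE,
                         pairwise = c("auto", "tukey", "welch")) {
  pairwise <- match.arg(pairwise)
  req <- c("condition", "subject", "value")
  if (!all(req %in% names(measurements))) {
    abort("`measurements` needs columns condition, subject, value")
  }
  conditions <- conditions %||% unique(as.character(measurements$condition))
  if (!all(measurements$condition %in% conditions)) {
    abort("measurements contain conditions not declared in `conditions`")
  }
  baseline <- baseline %||% conditions[1]
  if (!baseline %in% conditions) abort("baseline must be one of the conditions")

  per_subject <- measurements |>
    dplyr::mutate(condition = factor(.data$condition, levels = conditions)) |>
    dplyr::group_by(.data$condition, .data$subject) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")

  if (paired) {
    tab <- table(per_subject$subject, per_subject$condition)
    if (any(tab != 1)) {
      abort("paired design flagged but subjects do not match across conditions",
            class = "gliavasc_unbalanced_design")
    }
  }

  summary_tbl <- per_subject |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
                     .groups = "drop")

  normality <- per_subject |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      result = list(tryCatch(shapiro_wilk(.data$value),
                             error = function(e) {
                               tibble(test = "shapiro_wilk",
                                      statistic = NA_real_,
                                      p.value = NA_real_,
                                      n = dplyr::n())
                             })),
      .groups = "drop") |>
    tidyr::unnest("result")

  omnibus <- NULL
  pairwise_tbl <- NULL
  if (length(conditions) >= 2 && all(summary_tbl$n >= 2)) {
    omnibus <- anova_oneway(per_subject, value, condition,
                            subject = subject, repeated = paired)
    method <- if (pairwise == "auto") {
      if (paired) "tukey" else "welch"
    } else {
      pairwise
    }
    if (method == "tukey") {
      pairwise_tbl <- tukey_hsd(omnibus)
    } else {
      prs <- utils::combn(conditions, 2)
      pairwise_tbl <- purrr::map_dfr(seq_len(ncol(prs)), function(i) {
        a <- per_subject$value[per_subject$condition == prs[2, i]]
        b <- per_subject$value[per_subject$condition == prs[1, i]]
        res <- welch_t(a, b)
        dplyr::mutate(res,
                      contrast = paste(prs[2, i], prs[1, i], sep = "-"),
                      .before = 1)
      })
    }
  } else {
    warn("fewer than two conditions with n >= 2: group tests skipped")
  }

  base_mean <- summary_tbl$mean[summary_tbl$condition == baseline]
  pct <- summary_tbl |>
    dplyr::filter(.data$condition != baseline) |>
    dplyr::mutate(baseline = baseline,
                  percent_change = percent_change(base_mean, .data$mean)) |>
    dplyr::select("condition", "baseline", "percent_change")

  structure(list(summary = summary_tbl, normality = normality,
                 omnibus = omnibus, pairwise = pairwise_tbl,
                 percent_change = pct, baseline = baseline,
                 paired = paired, per_subject = per_subject),
            class = "glia_report")
}

#' @export
print.glia_report <- function(x, ...) {
  cat(sprintf("<glia_report> %s design, baseline '%s'\n",
              if (x$paired) "paired" else "independent", x$baseline))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s n=%d  mean %.4g +/- %.4g\n",
                as.character(s$condition[i]), s$n[i], s$mean[i], s$sd[i]))
  }
  if (!is.null(x$omnibus)) {
    g <- glance(x$omnibus)
    cat(sprintf("  omnibus %s: F(%d, %d) = %.4g, p = %.4g\n",
                g$test, g$df1, g$df2, g$statistic, g$p.value))
  }
  if (nrow(x$percent_change) > 0) {
    for (i in seq_len(nrow(x$percent_change))) {
      cat(sprintf("  %s vs %s: %+.1f%%\n",
                  as.character(x$percent_change$condition[i]),
                  x$percent_change$baseline[i],
                  x$percent_change$percent_change[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.glia_report <- function(x, ...) x$summary

#' @export
glance.glia_report <- function(x, ...) {
  if (is.null(x$omnibus)) {
    return(tibble(test = NA_character_, statistic = NA_real_,
                  df1 = NA_integer_, df2 = NA_integer_, p.value = NA_real_))
  }
  glance(x$omnibus)
}

#' @export
autoplot.glia_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.15) +
    ggplot2::geom_jitter(data = object$per_subject,
                         ggplot2::aes(y = .data$value),
                         width = 0.08, size = 2, shape = 21, fill = "black") +
    ggplot2::labs(x = NULL, y = "per-subject mean") +
    ggplot2::theme_minimal()
}
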