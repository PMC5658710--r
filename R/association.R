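# Test-set association summaries: median dichotomization of the predicted PC,
# Kaplan-Meier / log-rank, Pearson correlation, Welch t and chi-square, each
# paired with its display (KM step plot, scatter, boxplot, barplot).

association_summary <- function(test, statistic, p_value, effect = NA_real_,
                                group_sizes = NULL, extra = list()) {
  out <- tibble::tibble(test = test, statistic = statistic,
                        p_value = p_value, effect = effect,
                        n = if (is.null(group_sizes)) NA_integer_ else sum(group_sizes))
  attr(out, "group_sizes") <- group_sizes
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("association_summary", class(out))
  out
}

summary_as_list <- function(s) {
  gs <- attr(s, "group_sizes")
  list(test = s$test, statistic = s$statistic, p_value = s$p_value,
       effect = if (is.na(s$effect)) NULL else s$effect,
       group_sizes = if (is.null(gs)) NULL else as.list(gs))
}

#' Split PC scores into low/high groups at the median
#'
#' Samples with `pc_score <= median` are labelled `"low"`, the rest `"high"`
#' (the `<=` side of ties is fixed so the rule is deterministic; with distinct
#' values the low group has `ceiling(n/2)` members).
#'
#' @param predictions Tibble with a `pc_score` column (e.g. from [project()]).
#' @return The input with an added `group` factor (`low`, `high`).
#' @export
dichotomize_at_median <- function(predictions) {
  s <- predictions$pc_score
  if (length(s) < 2L) stop_superpca("need at least 2 samples to dichotomize")
  if (all(s == s[1L])) stop_superpca("cannot dichotomize constant scores")
  med <- stats::median(s)
  g <- factor(ifelse(s <= med, "low", "high"), levels = c("low", "high"))
  if (any(table(g) == 0L)) {
    # can only happen when > half the scores tie at the maximum
    g <- factor(ifelse(s < med, "low", "high"), levels = c("low", "high"))
  }
  dplyr::mutate(predictions, group = g)
}

#' Kaplan-Meier curves and log-rank test for dichotomized PC groups
#'
#' Product-limit survival estimates per group and the two-group log-rank
#' chi-square (1 df, hypergeometric variance with ties pooled at each event
#' time), computed with the survival package.
#'
#' @param outcome Survival outcome tibble (`sample_id`, `time`, `event`).
#' @param groups Factor of `"low"`/`"high"` labels aligned with `outcome`.
#' @return An `association_summary` tibble (test `"logrank"`; no effect
#'   column) carrying the fitted `survfit` object in attribute `"survfit"`.
#' @export
km_logrank <- function(outcome, groups) {
  outcome <- validate_outcome(outcome, "survival")
  groups <- factor(groups, levels = c("low", "high"))
  if (length(groups) != nrow(outcome)) stop_superpca("groups and outcome lengths differ")
  sizes <- table(groups)
  if (any(sizes == 0L)) stop_superpca("both groups must be non-empty")
  if (sum(outcome$event) == 0) stop_superpca("no events: all observations censored")
  srv <- survival::Surv(outcome$time, outcome$event)
  sd <- survival::survdiff(srv ~ groups)
  stat <- sd$chisq
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  fit <- survival::survfit(srv ~ groups)
  association_summary("logrank", statistic = stat, p_value = p,
                      group_sizes = c(low = unname(sizes["low"]), high = unname(sizes["high"])),
                      extra = list(survfit = fit, groups = groups, outcome = outcome))
}

#' Pearson correlation summary between outcome and PC score
#'
#' @param values Continuous outcome values.
#' @param pc_scores PC scores for the same samples.
#' @return `association_summary` with test `"pearson"`, the t statistic
#'   \eqn{r\sqrt{n-2}/\sqrt{1-r^2}}, its two-sided p and effect = r.
#' @export
pearson_summary <- function(values, pc_scores) {
  if (length(values) != length(pc_scores)) stop_superpca("input lengths differ")
  if (length(values) < 3L) stop_superpca("Pearson summary needs at least 3 samples")
  if (stats::sd(values) == 0 || stats::sd(pc_scores) == 0) {
    stop_superpca("constant input: correlation undefined")
  }
  ct <- stats::cor.test(pc_scores, values, method = "pearson")
  association_summary("pearson", statistic = unname(ct$statistic),
                      p_value = ct$p.value, effect = unname(ct$estimate),
                      group_sizes = c(n = length(values)))
}

#' Two-sample t-test summary for a dichotomized PC or binary classes
#'
#' Welch's unequal-variance t by default (`var_equal = TRUE` switches to the
#' pooled test). The effect is the mean difference, second level minus first
#' (high - low, or class1 - class0).
#'
#' @param values Numeric vector (outcome values or PC scores).
#' @param groups Two-level factor aligned with `values`.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return `association_summary` with test `"t_test"`.
#' @export
ttest_summary <- function(values, groups, var_equal = FALSE) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2L) stop_superpca("t-test needs exactly 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop_superpca("each group needs at least 2 samples (got ",
                  paste(sizes, collapse = " and "), ")")
  }
  lv <- levels(groups)
  a <- values[groups == lv[2L]]
  b <- values[groups == lv[1L]]
  tt <- stats::t.test(a, b, var.equal = var_equal)
  association_summary("t_test", statistic = unname(tt$statistic),
                      p_value = tt$p.value, effect = mean(a) - mean(b),
                      group_sizes = stats::setNames(as.integer(sizes), lv),
                      extra = list(df = unname(tt$parameter)))
}

#' Chi-square summary of predicted groups versus observed binary outcome
#'
#' Pearson chi-square on the 2x2 table of median group against observed
#' class, without continuity correction by default (the correction materially
#' changes small-sample p-values; switch it on with `correct = TRUE`). The
#' effect is the odds ratio `ad/bc`; 0.5 is added to every cell only when a
#' zero cell would make it degenerate (reported via a message).
#'
#' @param groups Factor of `"low"`/`"high"` predicted groups.
#' @param labels Observed 0/1 outcome labels, same samples.
#' @param correct Apply Yates' continuity correction.
#' @return `association_summary` with test `"chi_square"`.
#' @export
chisq_summary <- function(groups, labels, correct = FALSE) {
  groups <- factor(groups, levels = c("low", "high"))
  labels <- factor(labels, levels = c(0, 1))
  if (length(groups) != length(labels)) stop_superpca("input lengths differ")
  tab <- table(groups, labels)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    stop_superpca("2x2 table has an empty margin; both groups and both classes are required")
  }
  cs <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  t2 <- tab
  if (any(tab == 0L)) {
    message("zero cell in the 2x2 table: adding 0.5 to every cell for the odds ratio")
    t2 <- tab + 0.5
  }
  or <- (t2[1L, 1L] * t2[2L, 2L]) / (t2[1L, 2L] * t2[2L, 1L])
  association_summary("chi_square", statistic = unname(cs$statistic),
                      p_value = cs$p.value, effect = or,
                      group_sizes = c(low = sum(tab[1L, ]), high = sum(tab[2L, ])),
                      extra = list(table = tab))
}

# ---- plotting -------------------------------------------------------------

km_plot_data <- function(fit) {
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  strata <- sub("^groups=", "", strata)
  tibble::tibble(time = fit$time, surv = fit$surv, n_censor = fit$n.censor,
                 group = strata)
}

#' Plot Kaplan-Meier curves for an association summary
#'
#' @param summary `association_summary` from [km_logrank()].
#' @return A ggplot: per-group step curves with censoring ticks and the
#'   log-rank p-value annotated.
#' @export
plot_km <- function(summary) {
  fit <- attr(summary, "survfit")
  if (is.null(fit)) stop_superpca("summary carries no survival fit; use km_logrank()")
  d <- km_plot_data(fit)
  d0 <- d |> dplyr::group_by(.data$group) |>
    dplyr::summarise(.groups = "drop") |>
    dplyr::mutate(time = 0, surv = 1, n_censor = 0L)
  d <- dplyr::bind_rows(d0[, names(d)], d)
  cens <- d[d$n_censor > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = "PC group",
                  title = "Kaplan-Meier by median-dichotomized PC",
                  subtitle = sprintf("log-rank chi-square = %.3g, p = %.3g",
                                     summary$statistic, summary$p_value)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of outcome against predicted PC with Pearson annotation
#'
#' @param values Continuous outcome values.
#' @param pc_scores PC scores.
#' @param summary `association_summary` from [pearson_summary()].
#' @return A ggplot with a least-squares line and r / p annotated.
#' @export
plot_scatter <- function(values, pc_scores, summary) {
  d <- tibble::tibble(pc = pc_scores, y = values)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pc, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Predicted principal component", y = "Outcome",
                  title = "Outcome vs predicted PC",
                  subtitle = sprintf("Pearson r = %.3f, p = %.3g",
                                     summary$effect, summary$p_value)) +
    ggplot2::theme_minimal()
}

#' Boxplot of values by group with t-test annotation
#'
#' @param values Numeric vector.
#' @param groups Two-level factor.
#' @param summary `association_summary` from [ttest_summary()].
#' @return A ggplot.
#' @export
plot_box <- function(values, groups, summary) {
  d <- tibble::tibble(value = values, group = groups)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value, fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Value",
                  title = "Distribution by group",
                  subtitle = sprintf("t = %.3g, p = %.3g", summary$statistic, summary$p_value)) +
    ggplot2::theme_minimal()
}

#' Grouped bar plot of predicted groups against observed classes
#'
#' @param groups Predicted `"low"`/`"high"` groups.
#' @param labels Observed 0/1 labels.
#' @param summary `association_summary` from [chisq_summary()].
#' @return A ggplot with two bars per observed class and the chi-square p
#'   annotated.
#' @export
plot_bar <- function(groups, labels, summary) {
  d <- tibble::tibble(group = factor(groups, levels = c("low", "high")),
                      class = factor(labels, levels = c(0, 1)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, fill = .data$group)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "Observed class", y = "Samples", fill = "PC group",
                  title = "Predicted PC group vs observed class",
                  subtitle = sprintf("chi-square = %.3g, p = %.3g",
                                     summary$statistic, summary$p_value)) +
    ggplot2::theme_minimal()
}

#' Render and write the summary plot for a pipeline run
#'
#' Chooses the plot matching the run's outcome type and summary style
#' (KM for survival, scatter or boxplot for continuous, boxplot or barplot for
#' binary) and writes it as both PNG and SVG.
#'
#' @param run A `superpc_run` from [run_superpc()].
#' @param out_dir Directory for the image files.
#' @return Character vector of the written file paths, invisibly.
#' @export
render_summary_plots <- function(run, out_dir) {
  stopifnot(inherits(run, "superpc_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  type <- run$config$outcome_type
  style <- run$config$summary_style
  gp <- autoplot(run)
  stem <- switch(type,
    survival = "km",
    continuous = if (style == "continuous") "scatter" else "boxplot",
    binary = if (style == "continuous") "boxplot" else "barplot")
  paths <- file.path(out_dir, paste0(stem, c(".png", ".svg")))
  save_plot_both(gp, paths[1L], paths[2L])
  invisible(paths)
}

save_plot_both <- function(gp, png_path, svg_path, width = 6, height = 4.5) {
  grDevices::png(png_path, width = width, height = height, units = "in", res = 150)
  print(gp)
  grDevices::dev.off()
  grDevices::svg(svg_path, width = width, height = height)
  print(gp)
  grDevices::dev.off()
  invisible(c(png_path, svg_path))
}
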