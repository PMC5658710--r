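# S3 methods for the fitted objects: broom-style tidy()/glance(), autoplot()
# and compact print methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a fitted supervised-PC model
#'
#' @param x A `superpc_model`.
#' @param ... Unused.
#' @return Tibble with one row per selected feature: `feature_id`, `loading`,
#'   `center`.
#' @export
tidy.superpc_model <- function(x, ...) {
  tibble::tibble(feature_id = x$feature_ids,
                 loading = unname(x$loadings),
                 center = unname(x$center))
}

#' @rdname tidy.superpc_model
#' @return For `glance()`: a one-row tibble with `threshold`, `n_features`,
#'   `outcome_type`.
#' @export
glance.superpc_model <- function(x, ...) {
  tibble::tibble(threshold = x$threshold,
                 n_features = length(x$feature_ids),
                 outcome_type = x$outcome_type %||% NA_character_)
}

#' @export
print.superpc_model <- function(x, ...) {
  cat("Supervised-PC model:", length(x$feature_ids), "selected feature(s),",
      "threshold", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x A `superpc_cv`.
#' @param ... Unused.
#' @return Long tibble of per-fold held-out statistics
#'   (`threshold`, `fold`, `n_features`, `statistic`).
#' @export
tidy.superpc_cv <- function(x, ...) x$stats

#' @rdname tidy.superpc_cv
#' @export
glance.superpc_cv <- function(x, ...) {
  tibble::tibble(optimal_threshold = x$optimal_threshold, K = x$K,
                 n_thresholds = nrow(x$curve), objective = x$objective)
}

#' @export
print.superpc_cv <- function(x, ...) {
  cat("Cross-validated threshold selection (", x$K, " folds, ",
      nrow(x$curve), " thresholds)\n", sep = "")
  cat("optimal threshold:", format(x$optimal_threshold, digits = 4), "\n")
  invisible(x)
}

#' CV curve plot: mean held-out statistic against threshold
#'
#' @param object A `superpc_cv`.
#' @param ... Unused.
#' @return A ggplot with per-fold points, the mean curve, and the selected
#'   threshold marked.
#' @export
autoplot.superpc_cv <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$threshold, y = .data$mean_statistic)) +
    ggplot2::geom_point(data = object$stats,
                        ggplot2::aes(y = .data$statistic), alpha = 0.35, size = 1) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$optimal_threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Screening threshold on |score|",
                  y = "Held-out LR statistic",
                  title = "Cross-validated threshold selection") +
    ggplot2::theme_minimal()
}

#' @export
print.association_summary <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4), sep = "")
  if (!is.na(x$effect)) cat(", effect =", format(x$effect, digits = 4))
  cat("\n")
  invisible(x)
}

#' Tidy a full pipeline run
#'
#' @param x A `superpc_run`.
#' @param ... Unused.
#' @return The test-set predictions tibble (`sample_id`, `pc_score`, and
#'   `group` when dichotomized).
#' @export
tidy.superpc_run <- function(x, ...) x$predictions

#' @rdname tidy.superpc_run
#' @return For `glance()`: one row with the selected threshold, feature count
#'   and the test-set association test/statistic/p-value/effect.
#' @export
glance.superpc_run <- function(x, ...) {
  tibble::tibble(optimal_threshold = x$cv$optimal_threshold,
                 n_selected = length(x$model$feature_ids),
                 n_train = x$config$n_train,
                 n_test = x$config$n_test,
                 test = x$summary$test,
                 statistic = x$summary$statistic,
                 p_value = x$summary$p_value,
                 effect = x$summary$effect)
}

#' @export
print.superpc_run <- function(x, ...) {
  cat("Supervised-PC run (", x$config$outcome_type, " outcome): ",
      x$config$n_train, " train / ", x$config$n_test, " test samples\n", sep = "")
  print(x$model)
  print(x$summary)
  invisible(x)
}

#' Summary plot for a pipeline run
#'
#' Dispatches to the figure matching the run's outcome type and summary
#' style: Kaplan-Meier curves (survival), scatter or boxplot (continuous),
#' boxplot or grouped bar plot (binary).
#'
#' @param object A `superpc_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.superpc_run <- function(object, ...) {
  type <- object$config$outcome_type
  style <- object$config$summary_style
  s <- object$summary
  preds <- object$predictions
  out <- object$outcome_test
  switch(type,
    survival = plot_km(s),
    continuous = if (style == "continuous") {
      plot_scatter(out$value, preds$pc_score, s)
    } else {
      plot_box(out$value, preds$group, s)
    },
    binary = if (style == "continuous") {
      plot_box(preds$pc_score,
               factor(ifelse(out$label == 1, "class1", "class0")), s)
    } else {
      plot_bar(preds$group, out$label, s)
    })
}
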