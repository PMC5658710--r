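# The supervised-PC engine: train/test split, threshold grid over |s_j|,
# feature screening, leading-PC fit/projection, and k-fold cross-validated
# threshold selection.

#' Split samples into training and test sets
#'
#' Draws a seeded, optionally stratified train/test partition. The training
#' set has `round(train_prop * n)` samples; stratified splits (by event
#' indicator for survival, class label for binary) preserve each stratum's
#' proportion to within one sample via largest-remainder allocation.
#'
#' @param outcome Outcome tibble (provides `sample_id` and the stratification
#'   variable).
#' @param outcome_type `"survival"`, `"continuous"` or `"binary"`.
#' @param train_prop Training proportion in (0, 1).
#' @param seed Integer seed; the split is reproducible given the seed and the
#'   caller's RNG state is left untouched.
#' @param stratify Stratify by event/class (ignored for continuous outcomes).
#' @return Tibble (`sample_id`, `set`) with `set` in \{"train", "test"\}.
#' @export
split_train_test <- function(outcome, outcome_type, train_prop = 0.67,
                             seed = NULL, stratify = TRUE) {
  outcome_type <- match_outcome_type(outcome_type)
  outcome <- validate_outcome(outcome, outcome_type)
  assert_scalar_number(train_prop, "train_prop")
  if (train_prop <= 0 || train_prop >= 1) stop_superpca("train_prop must lie strictly in (0, 1)")
  n <- nrow(outcome)
  if (n < 4L) stop_superpca("need at least 4 samples to split")
  n_train <- round(train_prop * n)
  if (n_train < 1L || n_train > n - 1L) {
    stop_superpca("train_prop = ", train_prop, " yields an empty train or test set for n = ", n)
  }
  strata <- stratum_variable(outcome, outcome_type, stratify)
  if (length(unique(strata)) > 1L) {
    tab <- table(strata)
    if (any(tab < 2L)) stop_superpca("every stratum needs at least 2 samples for a stratified split")
    # largest-remainder: per-stratum targets sum exactly to n_train
    target <- train_prop * as.numeric(tab)
    base <- floor(target)
    left <- n_train - sum(base)
    if (left > 0) {
      extra <- order(target - base, decreasing = TRUE)[seq_len(left)]
      base[extra] <- base[extra] + 1L
    } else if (left < 0) {
      cut <- order(target - base, decreasing = FALSE)[seq_len(-left)]
      base[cut] <- base[cut] - 1L
    }
    per_stratum <- stats::setNames(as.integer(base), names(tab))
    train_ids <- with_seed_or_not(seed, {
      unlist(lapply(names(tab), function(s) {
        ids <- outcome$sample_id[strata == s]
        sample(ids, per_stratum[[s]])
      }), use.names = FALSE)
    })
  } else {
    train_ids <- with_seed_or_not(seed, sample(outcome$sample_id, n_train))
  }
  tibble::tibble(sample_id = outcome$sample_id,
                 set = ifelse(outcome$sample_id %in% train_ids, "train", "test"))
}

stratum_variable <- function(outcome, outcome_type, stratify) {
  if (!stratify || outcome_type == "continuous") return(rep("all", nrow(outcome)))
  as.character(switch(outcome_type, survival = outcome$event, binary = outcome$label))
}

#' Build a threshold grid over absolute scores
#'
#' Returns `n_thresholds` candidate screening thresholds equally spaced on the
#' quantile scale of the absolute training scores, between the 0 and 0.95
#' quantiles (linear-interpolation quantiles, R type 7). The 0.95 cap keeps
#' the top of the grid from emptying the selected-feature set; duplicated
#' quantiles are collapsed, so the grid is strictly increasing.
#'
#' @param scores Score tibble from [score_features()].
#' @param n_thresholds Number of grid points (before deduplication), >= 2.
#' @return Strictly increasing numeric vector of thresholds.
#' @export
make_threshold_grid <- function(scores, n_thresholds = 20) {
  a <- abs(scores$score)
  if (length(unique(a)) < 2L) stop_superpca("all absolute scores are equal; no grid to build")
  if (!is.numeric(n_thresholds) || length(n_thresholds) != 1L || n_thresholds < 2L) {
    stop_superpca("n_thresholds must be an integer >= 2")
  }
  probs <- seq(0, 0.95, length.out = as.integer(n_thresholds))
  grid <- unique(stats::quantile(a, probs, type = 7, names = FALSE))
  if (length(grid) < 2L) stop_superpca("threshold grid collapsed to fewer than 2 distinct values")
  grid
}

#' Screen features by absolute score
#'
#' @param scores Score tibble.
#' @param threshold Non-negative cutoff; features with `|score| > threshold`
#'   (strictly) are kept, in input order.
#' @return Character vector of selected feature IDs.
#' @export
screen_features <- function(scores, threshold) {
  assert_scalar_number(threshold, "threshold", lower = 0)
  keep <- scores$feature_id[abs(scores$score) > threshold]
  if (length(keep) == 0L) stop_superpca("threshold ", threshold, " removes all features")
  keep
}

#' Fit the leading principal component of screened features
#'
#' Centers each (already screened) feature by its training mean — no variance
#' scaling — and extracts the leading principal direction over features via a
#' singular-value decomposition. The loading vector has unit Euclidean norm
#' and its sign is fixed so the entry of largest magnitude is positive, making
#' the fit deterministic across linear-algebra backends.
#'
#' @param expression_train Expression tibble restricted to the selected
#'   features (>= 1 feature, >= 2 samples).
#' @param outcome_type Optional outcome type stored on the model.
#' @param threshold Optional screening threshold stored on the model.
#' @return A `superpc_model`: list with `feature_ids`, `center`, `loadings`
#'   (unit norm, named), `threshold`, `outcome_type`.
#' @seealso [project()] to compute per-sample PC scores.
#' @export
fit_pc <- function(expression_train, outcome_type = NULL, threshold = NA_real_) {
  x <- expression_matrix(expression_train)
  if (ncol(x) < 2L) stop_superpca("PC fit needs at least 2 training samples")
  center <- rowMeans(x)
  xc <- x - center
  if (nrow(x) == 1L) {
    w <- 1
  } else {
    w <- svd(t(xc), nu = 0L, nv = 1L)$v[, 1L]
  }
  i_max <- which.max(abs(w))
  if (w[i_max] < 0) w <- -w
  structure(list(feature_ids = rownames(x),
                 center = stats::setNames(center, rownames(x)),
                 loadings = stats::setNames(w, rownames(x)),
                 threshold = threshold,
                 outcome_type = outcome_type),
            class = "superpc_model")
}

#' Project samples onto a fitted principal component
#'
#' Computes the per-sample PC score
#' \eqn{\mathrm{score}_i = \sum_j w_j (x_{ji} - c_j)} using the training
#' centering vector \eqn{c} and unit-norm loadings \eqn{w}. Projecting the
#' training matrix reproduces the fitted training scores exactly (same
#' arithmetic path).
#'
#' @param model A `superpc_model` from [fit_pc()].
#' @param expression_new Expression tibble containing every selected feature
#'   (extra features are ignored).
#' @return Tibble (`sample_id`, `pc_score`).
#' @export
project <- function(model, expression_new) {
  stopifnot(inherits(model, "superpc_model"))
  x <- expression_matrix(expression_new)
  miss <- setdiff(model$feature_ids, rownames(x))
  if (length(miss) > 0L) {
    stop_superpca("expression is missing selected feature(s): ", paste(miss, collapse = ", "))
  }
  xc <- x[model$feature_ids, , drop = FALSE] - model$center
  tibble::tibble(sample_id = colnames(x),
                 pc_score = as.numeric(crossprod(xc, model$loadings)))
}

#' @export
predict.superpc_model <- function(object, newdata, ...) {
  project(object, newdata)
}

#' Generate a seeded cross-validation fold assignment
#'
#' Uniform fold sizes (within one), stratified by event indicator (survival)
#' or class label (binary) by default so every fold sees events/both classes
#' when the data permit.
#'
#' @inheritParams split_train_test
#' @param k Number of folds, >= 2.
#' @return Tibble (`sample_id`, `fold`) with attribute `K`.
#' @export
make_folds <- function(outcome, outcome_type, k = 10, seed = NULL, stratify = TRUE) {
  outcome_type <- match_outcome_type(outcome_type)
  outcome <- validate_outcome(outcome, outcome_type)
  n <- nrow(outcome)
  if (!is.numeric(k) || length(k) != 1L || k < 2L) stop_superpca("k must be an integer >= 2")
  k <- as.integer(k)
  if (k > n) stop_superpca("k = ", k, " exceeds the number of samples (", n, ")")
  strata <- stratum_variable(outcome, outcome_type, stratify)
  fold <- integer(n)
  with_seed_or_not(seed, {
    offset <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      # rotate the fold labels between strata so small strata do not all
      # pile into fold 1
      labels <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      fold[idx] <- labels[sample.int(length(idx))]
      offset <- offset + length(idx)
    }
  })
  validate_folds(tibble::tibble(sample_id = outcome$sample_id, fold = fold))
}

# Held-out association strength: likelihood-ratio statistic of the outcome on
# the projected PC (Cox LR for survival, Gaussian LR for continuous, logistic
# LR for binary). Returns 0 when the PC carries no usable signal (constant
# scores, non-convergence) so the CV curve stays total.
#' Likelihood-ratio statistic of an outcome on a PC score
#'
#' The cross-validation objective: twice the log-likelihood gain of the
#' one-predictor model over the null model for the outcome type at hand.
#'
#' @param pc_scores Numeric vector of per-sample PC scores.
#' @param outcome Outcome tibble for the same samples, in the same order.
#' @param outcome_type `"survival"`, `"continuous"` or `"binary"`.
#' @return Single non-negative number (0 for degenerate inputs).
#' @export
lr_statistic <- function(pc_scores, outcome, outcome_type) {
  outcome_type <- match_outcome_type(outcome_type)
  if (length(pc_scores) != nrow(outcome)) stop_superpca("pc_scores and outcome lengths differ")
  if (length(pc_scores) < 2L || stats::sd(pc_scores) == 0) return(0)
  out <- tryCatch(switch(outcome_type,
    survival = {
      if (sum(outcome$event) == 0) return(0)
      fit <- survival::coxph(survival::Surv(outcome$time, outcome$event) ~ pc_scores,
                             ties = "breslow")
      2 * (fit$loglik[2L] - fit$loglik[1L])
    },
    continuous = {
      y <- outcome$value
      n <- length(y)
      rss0 <- sum((y - mean(y))^2)
      if (rss0 == 0) return(0)
      fit <- stats::lm(y ~ pc_scores)
      rss1 <- sum(stats::residuals(fit)^2)
      if (rss1 <= 0) return(Inf)
      n * log(rss0 / rss1)
    },
    binary = {
      fit <- suppressWarnings(stats::glm(outcome$label ~ pc_scores, family = stats::binomial()))
      fit$null.deviance - fit$deviance
    }), error = function(e) 0)
  if (!is.finite(out) || out < 0) out <- max(0, out, na.rm = TRUE)
  out
}

#' Cross-validate the screening threshold
#'
#' For each fold and each candidate threshold: scores are recomputed on the
#' out-of-fold training samples only, features are screened at the threshold,
#' the leading PC is fitted on the out-of-fold samples, the held-in fold is
#' projected, and the held-out likelihood-ratio statistic of the outcome on
#' the projected PC is recorded. The optimal threshold maximizes the mean
#' statistic over folds; ties break toward the larger threshold (fewer genes).
#' A threshold that empties the screened set contributes statistic 0 for that
#' fold. Held-in samples are never touched during scoring, screening,
#' centering or loading estimation.
#'
#' @param expression_train Training expression tibble.
#' @param outcome_train Training outcome tibble (same samples).
#' @param outcome_type Outcome type.
#' @param grid Threshold grid from [make_threshold_grid()].
#' @param folds Fold assignment tibble (`sample_id`, `fold`) covering exactly
#'   the training samples, e.g. from [make_folds()] or [read_fold_ids()].
#' @param binary_stat Passed to [score_features()] for binary outcomes.
#' @return A `superpc_cv` object: `stats` (tibble threshold x fold:
#'   `statistic`, `n_features`), `curve` (per-threshold mean and full-train
#'   feature count), `optimal_threshold`, `folds`, `K`, `objective`.
#' @export
cross_validate_threshold <- function(expression_train, outcome_train, outcome_type,
                                     grid, folds, binary_stat = c("score", "wald")) {
  outcome_type <- match_outcome_type(outcome_type)
  binary_stat <- match.arg(binary_stat)
  expression_train <- validate_expression(expression_train)
  outcome_train <- validate_outcome(outcome_train, outcome_type)
  train_ids <- expression_samples(expression_train)
  folds <- validate_folds(folds, train_ids)
  outcome_train <- outcome_train[match(train_ids, outcome_train$sample_id), , drop = FALSE]
  k <- attr(folds, "K")
  if (k > length(train_ids)) stop_superpca("more folds than training samples")
  sizes <- table(factor(folds$fold, levels = seq_len(k)))
  if (any(sizes < 2L) || any(length(train_ids) - sizes < 2L)) {
    stop_superpca("every fold must leave at least 2 samples held in and held out")
  }
  if (!is.numeric(grid) || length(grid) < 1L || is.unsorted(grid, strictly = TRUE)) {
    stop_superpca("grid must be a strictly increasing numeric vector")
  }
  per_fold <- purrr::map(seq_len(k), function(f) {
    in_fold <- folds$sample_id[folds$fold == f]
    oof <- setdiff(train_ids, in_fold)
    expr_oof <- expression_train[, c("feature_id", oof), drop = FALSE]
    out_oof <- outcome_train[match(oof, outcome_train$sample_id), , drop = FALSE]
    if (outcome_type == "survival" && sum(out_oof$event) == 0) {
      stop_superpca("fold ", f, " leaves no events in its training portion; ",
                    "use stratified folds or fewer folds")
    }
    sc <- suppressWarnings(score_features(expr_oof, out_oof, outcome_type,
                                          binary_stat = binary_stat))
    out_in <- outcome_train[match(in_fold, outcome_train$sample_id), , drop = FALSE]
    purrr::map_dfr(grid, function(th) {
      sel <- sc$feature_id[sc$abs_score > th]
      if (length(sel) == 0L) {
        message("fold ", f, ": threshold ", signif(th, 4), " empties the screened set; statistic 0")
        return(tibble::tibble(threshold = th, fold = f, n_features = 0L, statistic = 0))
      }
      model <- fit_pc(expr_oof[match(sel, expr_oof$feature_id), , drop = FALSE],
                      outcome_type = outcome_type, threshold = th)
      pc <- project(model, expression_train[, c("feature_id", in_fold), drop = FALSE])
      tibble::tibble(threshold = th, fold = f, n_features = length(sel),
                     statistic = lr_statistic(pc$pc_score, out_in, outcome_type))
    })
  })
  stats_tbl <- dplyr::bind_rows(per_fold)
  full_scores <- suppressWarnings(score_features(expression_train, outcome_train,
                                                 outcome_type, binary_stat = binary_stat))
  curve <- stats_tbl |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(mean_statistic = mean(.data$statistic), .groups = "drop") |>
    dplyr::mutate(n_features_full_train =
                    vapply(.data$threshold,
                           function(th) sum(full_scores$abs_score > th), integer(1L))) |>
    dplyr::select("threshold", "n_features_full_train", "mean_statistic")
  best <- max(curve$mean_statistic)
  optimal <- max(curve$threshold[curve$mean_statistic == best])
  structure(list(stats = stats_tbl, curve = curve, optimal_threshold = optimal,
                 folds = folds, K = k, objective = "likelihood_ratio"),
            class = "superpc_cv")
}

#' Run the full supervised-PC pipeline
#'
#' End to end: train/test split, per-feature scoring on the training set,
#' threshold grid, k-fold cross-validated threshold selection, final PC fit at
#' the optimal threshold on all training data, projection of the test samples,
#' and an association summary of the test-set PC with the observed outcome.
#' Every random step is driven by `seed`, and the realized fold assignment is
#' part of the result (and written to `folds.tsv` when `out_dir` is given), so
#' a re-run supplying that fold file reproduces the analysis bit for bit.
#'
#' @inheritParams split_train_test
#' @param expression Expression tibble (features x samples).
#' @param outcome Outcome tibble covering the expression's samples.
#' @param n_thresholds Size of the threshold grid.
#' @param n_folds Number of CV folds (ignored when `folds` is supplied).
#' @param folds Optional pre-existing fold assignment (tibble or path to a
#'   fold-ID file). Its sample set then *defines* the training set, so a run
#'   is replicable from the fold file alone; mutually exclusive with seeded
#'   fold generation.
#' @param summary_style `"default"` picks the figure-style pairing for the
#'   outcome type (KM + log-rank for survival, scatter + Pearson for
#'   continuous, bar + chi-square for binary); `"dichotomized"` forces the
#'   median-split summary, `"continuous"` the continuous-PC summary
#'   (scatter/box + t-test).
#' @param binary_stat Screening statistic for binary outcomes.
#' @param allow_intersection Keep the expression/outcome sample intersection
#'   instead of failing on a mismatch.
#' @param out_dir Optional output directory; when given, writes `scores.tsv`,
#'   `cv_curve.tsv`, `folds.tsv`, `model.json`, `predictions.tsv`,
#'   `summary.json`, `run-manifest.json` and the summary plot (PNG + SVG).
#' @return A `superpc_run`: list with `model`, `cv`, `split`, `scores`,
#'   `predictions` (test samples with PC score and median group),
#'   `summary` (an `association_summary` tibble) and `config`.
#' @examples
#' sim <- simulate_dataset("continuous", n_samples = 60, n_genes = 40,
#'                         n_signal = 8, effect = 2, seed = 11)
#' run <- run_superpc(sim$expression, sim$outcome, "continuous",
#'                    n_thresholds = 5, n_folds = 3, seed = 11)
#' glance(run)
#' @export
run_superpc <- function(expression, outcome,
                        outcome_type = c("survival", "continuous", "binary"),
                        train_prop = 0.67, n_thresholds = 20, n_folds = 10,
                        folds = NULL, seed = NULL, stratify = TRUE,
                        summary_style = c("default", "dichotomized", "continuous"),
                        binary_stat = c("score", "wald"),
                        allow_intersection = FALSE, out_dir = NULL) {
  outcome_type <- match.arg(outcome_type)
  summary_style <- match.arg(summary_style)
  binary_stat <- match.arg(binary_stat)
  aligned <- align_samples(expression, outcome, outcome_type,
                           allow_intersection = allow_intersection)
  expression <- aligned$expression
  outcome <- aligned$outcome
  all_ids <- expression_samples(expression)

  if (is.character(folds)) folds <- read_fold_ids(folds)
  if (!is.null(folds)) {
    folds <- validate_folds(folds)
    extra <- setdiff(folds$sample_id, all_ids)
    if (length(extra) > 0L) {
      stop_superpca("fold assignment names unknown sample(s): ", paste(extra, collapse = ", "))
    }
    train_ids <- folds$sample_id
    test_ids <- setdiff(all_ids, train_ids)
    if (length(test_ids) == 0L) stop_superpca("fold assignment covers every sample; no test set remains")
    split <- tibble::tibble(sample_id = all_ids,
                            set = ifelse(all_ids %in% train_ids, "train", "test"))
  } else {
    split <- split_train_test(outcome, outcome_type, train_prop = train_prop,
                              seed = seed, stratify = stratify)
    train_ids <- split$sample_id[split$set == "train"]
    test_ids <- split$sample_id[split$set == "test"]
    fold_seed <- if (is.null(seed)) NULL else (as.integer(seed) %% 1000003L) + 1L
    folds <- make_folds(outcome[match(train_ids, outcome$sample_id), , drop = FALSE],
                        outcome_type, k = n_folds, seed = fold_seed, stratify = stratify)
  }

  expr_train <- expression[, c("feature_id", train_ids), drop = FALSE]
  expr_test <- expression[, c("feature_id", test_ids), drop = FALSE]
  out_train <- outcome[match(train_ids, outcome$sample_id), , drop = FALSE]
  out_test <- outcome[match(test_ids, outcome$sample_id), , drop = FALSE]

  scores <- suppressWarnings(score_features(expr_train, out_train, outcome_type,
                                            binary_stat = binary_stat))
  grid <- make_threshold_grid(scores, n_thresholds)
  cv <- cross_validate_threshold(expr_train, out_train, outcome_type, grid, folds,
                                 binary_stat = binary_stat)
  sel <- screen_features(scores, cv$optimal_threshold)
  model <- fit_pc(expr_train[match(sel, expr_train$feature_id), , drop = FALSE],
                  outcome_type = outcome_type, threshold = cv$optimal_threshold)
  predictions <- project(model, expr_test)
  style <- resolve_style(outcome_type, summary_style)
  if (style == "dichotomized") {
    predictions <- dichotomize_at_median(predictions)
  }
  summary <- summarize_association(predictions, out_test, outcome_type, style)

  config <- list(outcome_type = outcome_type, train_prop = train_prop,
                 n_thresholds = n_thresholds, n_folds = cv$K, seed = seed,
                 stratify = stratify, summary_style = style,
                 binary_stat = binary_stat, n_samples = length(all_ids),
                 n_train = length(train_ids), n_test = length(test_ids),
                 n_features = nrow(expression))
  run <- structure(list(model = model, cv = cv, split = split, scores = scores,
                        predictions = predictions, outcome_test = out_test,
                        summary = summary, config = config),
                   class = "superpc_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

resolve_style <- function(outcome_type, summary_style) {
  if (summary_style != "default") return(summary_style)
  switch(outcome_type, survival = "dichotomized", continuous = "continuous",
         binary = "dichotomized")
}

summarize_association <- function(predictions, outcome_test, outcome_type, style) {
  switch(outcome_type,
    survival = km_logrank(outcome_test, predictions$group),
    continuous = if (style == "continuous") {
      pearson_summary(outcome_test$value, predictions$pc_score)
    } else {
      ttest_summary(outcome_test$value, predictions$group)
    },
    binary = if (style == "continuous") {
      ttest_summary(predictions$pc_score,
                    factor(ifelse(outcome_test$label == 1, "class1", "class0"),
                           levels = c("class0", "class1")))
    } else {
      chisq_summary(predictions$group, outcome_test$label)
    })
}

# Serialize a run to its on-disk artifact set.
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_scores(run$scores, p("scores.tsv"))
  write_table_auto(run$cv$folds, p("folds.tsv"))
  write_table_auto(cv_curve_table(run$cv), p("cv_curve.tsv"))
  preds <- run$predictions
  if (!"group" %in% names(preds)) preds$group <- NA_character_
  write_table_auto(preds, p("predictions.tsv"))
  jsonlite::write_json(list(threshold = run$model$threshold,
                            outcome_type = run$model$outcome_type,
                            sign_convention = "largest-magnitude loading positive",
                            selected_features = run$model$feature_ids,
                            center = as.list(run$model$center),
                            loadings = as.list(run$model$loadings)),
                       p("model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summary_as_list(run$summary), p("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(run$config,
                list(package_version = as.character(utils::packageVersion("superpca")),
                     optimal_threshold = run$cv$optimal_threshold,
                     cv_objective = run$cv$objective,
                     fold_file = "folds.tsv"))
  jsonlite::write_json(manifest, p("run-manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  try(render_summary_plots(run, out_dir = out_dir), silent = TRUE)
  invisible(out_dir)
}

# Wide per-threshold table: threshold, n_features_full_train, fold_1..K, mean
cv_curve_table <- function(cv) {
  wide <- cv$stats |>
    dplyr::select("threshold", "fold", "statistic") |>
    tidyr::pivot_wider(names_from = "fold", values_from = "statistic",
                       names_prefix = "fold_")
  dplyr::left_join(cv$curve, wide, by = "threshold") |>
    dplyr::relocate("mean_statistic", .after = dplyr::last_col())
}
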