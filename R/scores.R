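# Univariate screening scores: the per-feature association statistic s_j that
# drives feature selection. All three are closed-form statistics evaluated at
# the null (no iterative model fitting), so screening is deterministic and
# cheap even for tens of thousands of features.

#' Per-feature univariate association scores
#'
#' Computes the signed screening statistic `s_j` for every feature of an
#' expression matrix against a clinical outcome:
#'
#' * **survival** — Cox partial-likelihood score test at \eqn{\beta = 0}:
#'   \eqn{z_j = U_j / \sqrt{I_j}} with \eqn{U_j} the sum over observed events
#'   of the feature value minus its risk-set mean, and \eqn{I_j} the summed
#'   risk-set variance (Breslow handling of tied event times). Positive scores
#'   mean higher expression goes with higher hazard.
#' * **continuous** — the t-statistic of the univariate least-squares slope,
#'   \eqn{t_j = r_j \sqrt{n-2} / \sqrt{1 - r_j^2}} with \eqn{r_j} the Pearson
#'   correlation between feature and outcome.
#' * **binary** — logistic score test at slope 0 with the intercept fixed at
#'   \eqn{\mathrm{logit}(\bar y)}: \eqn{U_j = \sum_i x_{ij} (y_i - \bar y)},
#'   \eqn{I_j = \bar y (1 - \bar y) \sum_i (x_{ij} - \bar x_j)^2},
#'   \eqn{z_j = U_j / \sqrt{I_j}}. Positive scores mean higher expression goes
#'   with class 1. `binary_stat = "wald"` instead fits a per-feature logistic
#'   regression and reports the Wald z of the slope.
#'
#' Constant features get score 0 with a warning (screening then drops them);
#' the score and t statistics are invariant to positive rescaling and to
#' location shifts of a feature.
#'
#' @param expression Expression tibble (`feature_id` + one numeric column per
#'   sample), as from [read_expression()] or [simulate_dataset()].
#' @param outcome Outcome tibble covering exactly the expression's samples
#'   (columns `sample_id` plus `time`/`event`, `value`, or `label`).
#' @param outcome_type `"survival"`, `"continuous"` or `"binary"`.
#' @param binary_stat Statistic for binary outcomes: `"score"` (closed-form
#'   score test, default) or `"wald"` (iteratively fitted logistic Wald z).
#' @return A tibble with one row per feature, in input order: `feature_id`,
#'   `score`, `abs_score`, and diagnostics `numerator` (`U_j`) and
#'   `information` (`I_j`) where the statistic has that decomposition.
#' @examples
#' sim <- simulate_dataset("binary", n_samples = 30, n_genes = 10,
#'                         n_signal = 3, effect = 2, seed = 7)
#' score_features(sim$expression, sim$outcome, "binary")
#' @export
score_features <- function(expression, outcome,
                           outcome_type = c("survival", "continuous", "binary"),
                           binary_stat = c("score", "wald")) {
  outcome_type <- match.arg(outcome_type)
  binary_stat <- match.arg(binary_stat)
  expression <- validate_expression(expression)
  outcome <- validate_outcome(outcome, outcome_type)
  ids <- expression_samples(expression)
  if (!setequal(ids, outcome$sample_id) || length(ids) != nrow(outcome)) {
    stop_superpca("outcome must cover exactly the expression samples")
  }
  outcome <- outcome[match(ids, outcome$sample_id), , drop = FALSE]
  x <- expression_matrix(expression)
  res <- switch(outcome_type,
    survival = score_survival_matrix(x, outcome$time, outcome$event),
    continuous = score_continuous_matrix(x, outcome$value),
    binary = if (binary_stat == "score") {
      score_binary_matrix(x, outcome$label)
    } else {
      score_binary_wald_matrix(x, outcome$label)
    })
  tibble::tibble(feature_id = rownames(x),
                 score = unname(res$score),
                 abs_score = abs(unname(res$score)),
                 numerator = unname(res$numerator),
                 information = unname(res$information))
}

#' @rdname score_features
#' @export
score_survival <- function(expression, outcome) {
  score_features(expression, outcome, "survival")
}

#' @rdname score_features
#' @export
score_continuous <- function(expression, outcome) {
  score_features(expression, outcome, "continuous")
}

#' @rdname score_features
#' @export
score_binary <- function(expression, outcome, binary_stat = c("score", "wald")) {
  score_features(expression, outcome, "binary", binary_stat = binary_stat)
}

warn_constant <- function(const, ids) {
  if (any(const)) {
    shown <- utils::head(ids[const], 5L)
    warning(sum(const), " constant feature(s) scored 0: ",
            paste(shown, collapse = ", "),
            if (sum(const) > 5L) ", ..." else "", call. = FALSE)
  }
}

# Cox score test at beta = 0, Breslow ties. x: features x samples.
score_survival_matrix <- function(x, time, event) {
  n <- ncol(x)
  if (n < 2L) stop_superpca("survival scoring needs at least 2 samples")
  if (any(time <= 0)) stop_superpca("survival times must be strictly positive")
  if (sum(event) < 1) stop_superpca("no events observed")
  ord <- order(time)
  xs <- x[, ord, drop = FALSE]
  ts <- time[ord]
  es <- event[ord]
  # suffix sums over samples: s1[, i] = sum_{j >= i} x_j, ditto squares
  s1 <- xs
  s2 <- xs^2
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      s1[, i] <- s1[, i + 1L] + xs[, i]
      s2[, i] <- s2[, i + 1L] + xs[, i]^2
    }
  }
  # first index of each tied time block: risk set = {j : t_j >= t_i}
  first_tied <- match(ts, ts)
  ev_idx <- which(es == 1)
  u <- numeric(nrow(x))
  info <- numeric(nrow(x))
  for (i in ev_idx) {
    k <- first_tied[i]
    nr <- n - k + 1L
    m <- s1[, k] / nr
    u <- u + (xs[, i] - m)
    info <- info + (s2[, k] / nr - m^2)
  }
  info <- pmax(info, 0)
  const <- apply(x, 1L, function(r) all(r == r[1L]))
  warn_constant(const, rownames(x))
  score <- ifelse(info > 1e-12 & !const, u / sqrt(info), 0)
  list(score = score, numerator = ifelse(const, 0, u),
       information = info)
}

score_continuous_matrix <- function(x, y) {
  n <- ncol(x)
  if (n < 3L) stop_superpca("continuous scoring needs at least 3 samples")
  if (stats::var(y) == 0) stop_superpca("constant outcome: no variance to associate with")
  xc <- x - rowMeans(x)
  yc <- y - mean(y)
  ssx <- rowSums(xc^2)
  const <- ssx == 0
  warn_constant(const, rownames(x))
  r <- as.numeric(xc %*% yc) / sqrt(pmax(ssx, .Machine$double.eps)) / sqrt(sum(yc^2))
  r <- pmin(pmax(r, -1), 1)
  exact <- !const & (1 - r^2) < .Machine$double.eps * n
  if (any(exact)) {
    warning("feature(s) perfectly collinear with the outcome mapped to the ",
            "maximum representable score: ",
            paste(utils::head(rownames(x)[exact], 5L), collapse = ", "), call. = FALSE)
  }
  t_stat <- ifelse(const, 0,
                   ifelse(exact, sign(r) * .Machine$double.xmax,
                          r * sqrt(n - 2) / sqrt(1 - r^2)))
  list(score = t_stat, numerator = rep(NA_real_, nrow(x)),
       information = rep(NA_real_, nrow(x)))
}

score_binary_matrix <- function(x, y) {
  check_binary_classes(y)
  ybar <- mean(y)
  xc <- x - rowMeans(x)
  u <- as.numeric(x %*% (y - ybar))
  info <- ybar * (1 - ybar) * rowSums(xc^2)
  const <- rowSums(xc^2) == 0
  warn_constant(const, rownames(x))
  score <- ifelse(info > 1e-12 & !const, u / sqrt(info), 0)
  list(score = score, numerator = ifelse(const, 0, u), information = info)
}

# Wald z from a per-feature logistic fit; the iterative alternative to the
# closed-form score test.
score_binary_wald_matrix <- function(x, y) {
  check_binary_classes(y)
  const <- apply(x, 1L, function(r) all(r == r[1L]))
  warn_constant(const, rownames(x))
  z <- vapply(seq_len(nrow(x)), function(j) {
    if (const[j]) return(0)
    fit <- suppressWarnings(stats::glm(y ~ x[j, ], family = stats::binomial()))
    s <- summary(fit)$coefficients
    if (nrow(s) < 2L || !is.finite(s[2L, 3L])) 0 else s[2L, 3L]
  }, numeric(1L))
  list(score = z, numerator = rep(NA_real_, nrow(x)),
       information = rep(NA_real_, nrow(x)))
}

check_binary_classes <- function(y) {
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  if (n0 == 0L || n1 == 0L) stop_superpca("binary outcome must contain both classes")
  if (n0 < 2L || n1 < 2L) stop_superpca("each binary class needs at least 2 samples")
  invisible(TRUE)
}

#' Write a score table
#'
#' @param scores Score tibble from [score_features()].
#' @param path Output path (`feature_id`, `score`, `abs_score` in input
#'   feature order).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  write_table_auto(scores[, c("feature_id", "score", "abs_score")], path)
}
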