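# Fixture builders shared across test files. Everything is generated in code;
# files are written to tempdirs at test time.

expr_tbl <- function(m, feature_ids = NULL, sample_ids = NULL) {
  if (is.null(feature_ids)) feature_ids <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(feature_ids, sample_ids)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  tibble::add_column(out, feature_id = feature_ids, .before = 1L)
}

tiny_expression <- function() {
  expr_tbl(matrix(c(1, 2, 3, 4,
                    2, 1, 0, -1,
                    0.5, 0.5, 1.5, 2.5), nrow = 3, byrow = TRUE),
           feature_ids = c("G1", "G2", "G3"),
           sample_ids = c("A", "B", "C", "D"))
}

surv_outcome <- function(time, event, ids = sprintf("s%d", seq_along(time))) {
  tibble::tibble(sample_id = ids, time = time, event = event)
}

cont_outcome <- function(value, ids = sprintf("s%d", seq_along(value))) {
  tibble::tibble(sample_id = ids, value = value)
}

bin_outcome <- function(label, ids = sprintf("s%d", seq_along(label))) {
  tibble::tibble(sample_id = ids, label = label)
}

# A random expression + outcome instance for oracle comparisons.
random_instance <- function(outcome_type, n = 30, p = 20, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), nrow = p)
    expr <- expr_tbl(x)
    outcome <- switch(outcome_type,
      survival = surv_outcome(time = rexp(n, rate = exp(0.3 * x[1, ])),
                              event = rbinom(n, 1, 0.7)),
      continuous = cont_outcome(rnorm(n) + 0.5 * x[1, ]),
      binary = bin_outcome(rbinom(n, 1, plogis(0.5 * x[1, ]))))
    if (outcome_type == "survival" && sum(outcome$event) == 0) outcome$event[1] <- 1L
    if (outcome_type == "binary" && length(unique(outcome$label)) < 2) {
      outcome$label[1:2] <- c(0L, 1L)
    }
    list(expression = expr, outcome = outcome)
  })
}

# Independent per-feature oracles built on fitted models --------------------

oracle_survival_scores <- function(expression, outcome) {
  x <- expression_matrix(expression)
  vapply(seq_len(nrow(x)), function(j) {
    fit <- survival::coxph(survival::Surv(outcome$time, outcome$event) ~ x[j, ],
                           ties = "breslow")
    unname(sign(coef(fit)) * sqrt(summary(fit)$sctest["test"]))
  }, numeric(1))
}

oracle_continuous_scores <- function(expression, outcome) {
  x <- expression_matrix(expression)
  vapply(seq_len(nrow(x)), function(j) {
    summary(lm(outcome$value ~ x[j, ]))$coefficients[2, 3]
  }, numeric(1))
}

# Numerical derivatives of the per-feature logistic log-likelihood at slope 0
# with the intercept fixed at logit(ybar): z = l'(0) / sqrt(-l''(0)), using
# five-point central-difference stencils (truncation O(h^4)).
oracle_binary_scores <- function(expression, outcome) {
  x <- expression_matrix(expression)
  y <- outcome$label
  a <- qlogis(mean(y))
  vapply(seq_len(nrow(x)), function(j) {
    # centering makes the slope orthogonal to the intercept, so the fixed-
    # intercept curvature is the efficient (profile) information; the
    # statistic itself is location-invariant
    xj <- x[j, ] - mean(x[j, ])
    ll <- function(b) sum(y * (a + b * xj) - log1p(exp(a + b * xj)))
    h <- 0.01 / max(sd(xj), 1e-8)
    u <- (-ll(2 * h) + 8 * ll(h) - 8 * ll(-h) + ll(-2 * h)) / (12 * h)
    i2 <- -(-ll(2 * h) + 16 * ll(h) - 30 * ll(0) + 16 * ll(-h) - ll(-2 * h)) / (12 * h^2)
    u / sqrt(i2)
  }, numeric(1))
}
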