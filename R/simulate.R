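# Seeded synthetic datasets with known single-factor signal structure:
# a latent factor u drives a block of signal genes and the clinical outcome,
# so screening, threshold selection and prediction can all be checked against
# ground truth without any external data.

#' Simulate an expression matrix with a latent-factor-driven outcome
#'
#' Generates `n_samples` draws of a standard-normal latent factor `u`. Each of
#' the first `n_signal` genes loads on it, `x_j = b_j u + noise` with
#' `b_j ~ Uniform(0.5, 1.5)` and standard-normal noise; the remaining genes
#' are independent standard normal. The outcome depends on `u` with strength
#' `effect`:
#'
#' * survival: event times are exponential with hazard `exp(effect * u)`,
#'   censored by an independent `Uniform(0, m)` time whose upper bound `m` is
#'   calibrated so the expected censoring fraction equals `censor_rate`;
#' * continuous: `y = effect * u + N(0, 1)`;
#' * binary: `y ~ Bernoulli(plogis(effect * u))`.
#'
#' With `effect = 0` the outcome is independent of the expression matrix,
#' giving an exact null for calibration checks. Everything is reproducible
#' from `seed`.
#'
#' @param outcome_type `"survival"`, `"continuous"` or `"binary"`.
#' @param n_samples Number of samples (>= 2).
#' @param n_genes Total number of genes.
#' @param n_signal Number of signal genes (<= `n_genes`).
#' @param effect Outcome effect size `gamma` >= 0 of the latent factor.
#' @param censor_rate Target censoring fraction in \[0, 1) (survival only).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @return A `superpc_sim` list: `expression` tibble, `outcome` tibble, and
#'   `truth` (list with `signal_feature_ids`, `latent` tibble of `u`,
#'   `effect`, `loadings` tibble of `b_j`).
#' @examples
#' sim <- simulate_dataset("survival", n_samples = 50, n_genes = 100,
#'                         n_signal = 10, effect = 1.5, censor_rate = 0.3,
#'                         seed = 42)
#' mean(sim$outcome$event == 0)  # realized censoring fraction
#' @export
simulate_dataset <- function(outcome_type = c("survival", "continuous", "binary"),
                             n_samples, n_genes, n_signal, effect = 1,
                             censor_rate = 0.3, seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (n_samples < 2L) stop_superpca("n_samples must be at least 2")
  if (n_signal > n_genes || n_signal < 0L) stop_superpca("need 0 <= n_signal <= n_genes")
  assert_scalar_number(effect, "effect", lower = 0)
  if (outcome_type == "survival") {
    if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1) {
      stop_superpca("censor_rate must lie in [0, 1)")
    }
  }
  with_seed_or_not(seed, {
    u <- stats::rnorm(n_samples)
    b <- stats::runif(n_signal, 0.5, 1.5)
    x <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes)
    if (n_signal > 0L) {
      x[seq_len(n_signal), ] <- x[seq_len(n_signal), , drop = FALSE] + outer(b, u)
    }
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
    dimnames(x) <- list(gene_ids, sample_ids)
    outcome <- switch(outcome_type,
      survival = {
        hazard <- exp(effect * u)
        t_event <- stats::rexp(n_samples, rate = hazard)
        if (censor_rate > 0) {
          m <- censor_bound(hazard, censor_rate)
          c_time <- stats::runif(n_samples, 0, m)
          tibble::tibble(sample_id = sample_ids,
                         time = pmin(t_event, c_time),
                         event = as.integer(t_event <= c_time))
        } else {
          tibble::tibble(sample_id = sample_ids, time = t_event,
                         event = rep(1L, n_samples))
        }
      },
      continuous = tibble::tibble(sample_id = sample_ids,
                                  value = effect * u + stats::rnorm(n_samples)),
      binary = tibble::tibble(sample_id = sample_ids,
                              label = stats::rbinom(n_samples, 1L,
                                                    stats::plogis(effect * u))))
    structure(list(expression = expression_from_matrix(x),
                   outcome = outcome,
                   truth = list(signal_feature_ids = gene_ids[seq_len(n_signal)],
                                latent = tibble::tibble(sample_id = sample_ids, u = u),
                                effect = effect,
                                loadings = tibble::tibble(
                                  feature_id = gene_ids[seq_len(n_signal)], b = b))),
              class = "superpc_sim")
  })
}

# Upper bound m of the Uniform(0, m) censoring time such that the expected
# censoring fraction, averaged over the realized hazards, equals the target:
# P(censored | hazard L) = (1 - exp(-L m)) / (L m) for C ~ U(0, m).
censor_bound <- function(hazard, censor_rate) {
  f <- function(m) mean((1 - exp(-hazard * m)) / (hazard * m)) - censor_rate
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Write a simulated dataset to disk
#'
#' @param sim A `superpc_sim` from [simulate_dataset()].
#' @param out_dir Output directory; writes `expression.tsv`, `clinical.tsv`
#'   and `truth.json`.
#' @param outcome_type The outcome type the dataset was generated with.
#' @return `out_dir`, invisibly.
#' @export
write_simulated <- function(sim, out_dir, outcome_type) {
  stopifnot(inherits(sim, "superpc_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expression, file.path(out_dir, "expression.tsv"))
  write_outcome(sim$outcome, outcome_type, file.path(out_dir, "clinical.tsv"))
  jsonlite::write_json(list(signal_feature_ids = sim$truth$signal_feature_ids,
                            effect = sim$truth$effect,
                            latent = sim$truth$latent,
                            loadings = sim$truth$loadings),
                       file.path(out_dir, "truth.json"), dataframe = "columns",
                       digits = NA)
  invisible(out_dir)
}
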