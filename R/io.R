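# Tabular IO with strict validation: expression matrices, clinical outcome
# tables, fold assignments and forest-plot input tables. All readers accept
# tab- or comma-delimited text chosen by file extension (.csv -> comma,
# anything else -> tab), with one header row and the ID in the first column.

#' Read a gene-expression matrix
#'
#' Reads a delimited text file into the canonical features-by-samples layout:
#' a tibble whose first column is `feature_id` and whose remaining columns are
#' one numeric column per sample. Files written samples-in-rows are transposed
#' on load.
#'
#' Validation is strict: duplicate feature or sample IDs, non-numeric cells and
#' missing values are all errors that name the offending ID or coordinate.
#' No imputation is performed.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file with one
#'   header row; the first column holds IDs.
#' @param orientation `"features_in_rows"` (default; header = sample IDs) or
#'   `"samples_in_rows"` (header = feature IDs, transposed on load).
#' @return A tibble with columns `feature_id` and one numeric column per sample.
#' @examples
#' sim <- simulate_dataset("continuous", n_samples = 4, n_genes = 3,
#'                         n_signal = 1, effect = 1, seed = 1)
#' tf <- tempfile(fileext = ".tsv")
#' write_expression(sim$expression, tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, orientation = c("features_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  raw <- read_table_auto(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2L) stop_superpca("expression file needs an ID column plus at least one data column")
  ids <- as.character(raw[[1L]])
  mat_chr <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat_chr) <- ids
  if (orientation == "samples_in_rows") mat_chr <- t(mat_chr)
  parsed <- suppressWarnings(matrix(as.numeric(mat_chr), nrow = nrow(mat_chr),
                                    dimnames = dimnames(mat_chr)))
  bad <- which(is.na(parsed), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    cell <- mat_chr[i, j]
    what <- if (is.na(cell) || cell == "") "missing value" else paste0("non-numeric cell '", cell, "'")
    stop_superpca(what, " at feature '", rownames(parsed)[i], "', sample '",
                  colnames(parsed)[j], "' (row ", i, ", column ", j, ")")
  }
  expression_from_matrix(parsed)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()] for the canonical features-in-rows layout.
#'
#' @param expression Expression tibble (`feature_id` + one column per sample).
#' @param path Output path; extension picks the delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  expression <- validate_expression(expression)
  write_table_auto(expression, path)
}

#' @rdname read_expression
#' @param x For `validate_expression()`, an expression tibble (or data frame)
#'   to check: unique IDs, all-finite numeric values, at least one feature and
#'   two samples.
#' @export
validate_expression <- function(x) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 3L) stop_superpca("expression needs a feature_id column and at least 2 samples")
  if (names(x)[1L] != "feature_id") names(x)[1L] <- "feature_id"
  x$feature_id <- as.character(x$feature_id)
  dup_f <- unique(x$feature_id[duplicated(x$feature_id)])
  if (length(dup_f) > 0L) {
    stop_superpca("duplicate feature IDs: ", paste(dup_f, collapse = ", "))
  }
  samples <- names(x)[-1L]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0L) {
    stop_superpca("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  }
  if (nrow(x) < 1L) stop_superpca("expression must contain at least one feature")
  vals <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop_superpca("expression values must be numeric")
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stop_superpca("non-finite value at feature '", x$feature_id[bad[1L]],
                  "', sample '", samples[bad[2L]], "'")
  }
  x
}

# tibble <-> matrix conversions (matrix: rownames = features, colnames = samples)
expression_from_matrix <- function(m) {
  stopifnot(is.matrix(m))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, feature_id = rownames(m), .before = 1L)
  validate_expression(out)
}

#' Convert an expression tibble to a numeric matrix
#'
#' @param expression Expression tibble as returned by [read_expression()].
#' @return Numeric matrix, rows = features (rownames), columns = samples.
#' @export
expression_matrix <- function(expression) {
  expression <- validate_expression(expression)
  m <- as.matrix(expression[, -1L, drop = FALSE])
  rownames(m) <- expression$feature_id
  m
}

#' Sample IDs of an expression tibble
#' @inheritParams expression_matrix
#' @return Character vector of sample IDs in column order.
#' @export
expression_samples <- function(expression) {
  names(validate_expression(expression))[-1L]
}

#' Read a clinical outcome table
#'
#' The file must contain a `sample_id` column plus, depending on
#' `outcome_type`: `time` and `event` (survival), `value` (continuous), or
#' `label` (binary). Survival times must be strictly positive; `event` and
#' `label` must lie in \{0, 1\}.
#'
#' @param path Delimited text file (see [read_expression()] for the dialect).
#' @param outcome_type One of `"survival"`, `"continuous"`, `"binary"`.
#' @param sample_ids Optional character vector; when given, the outcome must
#'   cover exactly these samples and is reordered to match (alignment is by ID,
#'   never by file position).
#' @return A validated outcome tibble in canonical column order.
#' @export
read_outcome <- function(path, outcome_type, sample_ids = NULL) {
  outcome_type <- match_outcome_type(outcome_type)
  out <- read_table_auto(path)
  out <- validate_outcome(out, outcome_type)
  if (!is.null(sample_ids)) {
    missing_ids <- setdiff(sample_ids, out$sample_id)
    extra_ids <- setdiff(out$sample_id, sample_ids)
    if (length(missing_ids) > 0L || length(extra_ids) > 0L) {
      stop_superpca("outcome samples do not match expression samples; ",
                    if (length(missing_ids) > 0L)
                      paste0("missing from outcome: ", paste(missing_ids, collapse = ", "), "; ") else "",
                    if (length(extra_ids) > 0L)
                      paste0("not in expression: ", paste(extra_ids, collapse = ", ")) else "")
    }
    out <- out[match(sample_ids, out$sample_id), , drop = FALSE]
  }
  out
}

#' @rdname read_outcome
#' @param outcome For `validate_outcome()`, an outcome data frame to check.
#' @export
validate_outcome <- function(outcome, outcome_type) {
  outcome_type <- match_outcome_type(outcome_type)
  outcome <- tibble::as_tibble(outcome)
  if (!"sample_id" %in% names(outcome)) stop_superpca("outcome table needs a 'sample_id' column")
  outcome$sample_id <- as.character(outcome$sample_id)
  dup <- unique(outcome$sample_id[duplicated(outcome$sample_id)])
  if (length(dup) > 0L) stop_superpca("duplicate sample IDs in outcome: ", paste(dup, collapse = ", "))
  need <- switch(outcome_type,
                 survival = c("time", "event"),
                 continuous = "value",
                 binary = "label")
  miss <- setdiff(need, names(outcome))
  if (length(miss) > 0L) {
    stop_superpca(outcome_type, " outcome needs column(s): ", paste(miss, collapse = ", "))
  }
  for (col in need) {
    v <- outcome[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- outcome$sample_id[!is.finite(suppressWarnings(as.numeric(v)))][1L]
      stop_superpca("column '", col, "' must be finite numeric (offending sample: ", bad, ")")
    }
  }
  if (outcome_type == "survival") {
    bad <- outcome$sample_id[outcome$time <= 0]
    if (length(bad) > 0L) {
      stop_superpca("survival times must be strictly positive; offending sample(s): ",
                    paste(bad, collapse = ", "))
    }
    bad <- outcome$sample_id[!outcome$event %in% c(0, 1)]
    if (length(bad) > 0L) {
      stop_superpca("event indicator must be 0 or 1; offending sample(s): ",
                    paste(bad, collapse = ", "))
    }
  }
  if (outcome_type == "binary") {
    bad <- outcome$sample_id[!outcome$label %in% c(0, 1)]
    if (length(bad) > 0L) {
      stop_superpca("binary label must be 0 or 1; offending sample(s): '",
                    paste(outcome$label[match(bad, outcome$sample_id)], collapse = "', '"),
                    "' for sample(s) ", paste(bad, collapse = ", "))
    }
  }
  outcome[, c("sample_id", need), drop = FALSE]
}

#' Write a clinical outcome table
#' @inheritParams validate_outcome
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcome <- function(outcome, outcome_type, path) {
  write_table_auto(validate_outcome(outcome, outcome_type), path)
}

#' Align expression and outcome sample sets
#'
#' By default the two tables must cover exactly the same samples; with
#' `allow_intersection = TRUE` the intersection is kept, the outcome is
#' reordered to the expression's sample order, and dropped IDs are reported
#' via a message.
#'
#' @inheritParams read_outcome
#' @param expression Expression tibble.
#' @param outcome Outcome tibble.
#' @param allow_intersection Keep the common samples instead of failing on a
#'   mismatch.
#' @return List with elements `expression`, `outcome` (aligned) and `dropped`
#'   (character vector of discarded sample IDs).
#' @export
align_samples <- function(expression, outcome, outcome_type, allow_intersection = FALSE) {
  expression <- validate_expression(expression)
  outcome <- validate_outcome(outcome, outcome_type)
  es <- expression_samples(expression)
  os <- outcome$sample_id
  only_e <- setdiff(es, os)
  only_o <- setdiff(os, es)
  dropped <- c(only_e, only_o)
  if (length(dropped) > 0L && !allow_intersection) {
    stop_superpca("expression and outcome sample sets differ; ",
                  if (length(only_e) > 0L)
                    paste0("expression-only: ", paste(only_e, collapse = ", "), "; ") else "",
                  if (length(only_o) > 0L)
                    paste0("outcome-only: ", paste(only_o, collapse = ", ")) else "",
                  " (set allow_intersection = TRUE to keep the intersection)")
  }
  keep <- intersect(es, os)
  if (length(keep) < 2L) stop_superpca("fewer than 2 samples shared between expression and outcome")
  if (length(dropped) > 0L) {
    message("dropping ", length(dropped), " unmatched sample(s): ", paste(dropped, collapse = ", "))
    expression <- expression[, c("feature_id", keep), drop = FALSE]
  }
  outcome <- outcome[match(keep, outcome$sample_id), , drop = FALSE]
  list(expression = expression, outcome = outcome, dropped = dropped)
}

#' Read a cross-validation fold assignment
#'
#' The file must have columns `sample_id` and `fold`, cover exactly the given
#' training samples, and use a contiguous 1..K fold numbering with every fold
#' non-empty. Such files allow an analysis to be replicated exactly.
#'
#' @param path Two-column delimited file (`sample_id`, `fold`).
#' @param training_sample_ids Character vector the assignment must cover
#'   exactly; `NULL` accepts the file's own sample set.
#' @return Tibble (`sample_id`, `fold`) with attribute `K`.
#' @export
read_fold_ids <- function(path, training_sample_ids = NULL) {
  f <- read_table_auto(path)
  if (!all(c("sample_id", "fold") %in% names(f))) {
    stop_superpca("fold file needs columns 'sample_id' and 'fold'")
  }
  f$sample_id <- as.character(f$sample_id)
  f$fold <- as.integer(f$fold)
  validate_folds(f[, c("sample_id", "fold")], training_sample_ids)
}

validate_folds <- function(folds, training_sample_ids = NULL) {
  folds <- tibble::as_tibble(folds)
  dup <- unique(folds$sample_id[duplicated(folds$sample_id)])
  if (length(dup) > 0L) stop_superpca("sample assigned to multiple folds: ", paste(dup, collapse = ", "))
  if (any(!is.finite(folds$fold)) || any(folds$fold < 1L)) {
    stop_superpca("fold indices must be positive integers")
  }
  k <- max(folds$fold)
  if (k < 2L) stop_superpca("at least 2 folds are required")
  present <- sort(unique(folds$fold))
  if (!identical(present, seq_len(k))) {
    stop_superpca("non-contiguous fold indices: expected 1..", k,
                  ", missing ", paste(setdiff(seq_len(k), present), collapse = ", "))
  }
  if (!is.null(training_sample_ids)) {
    miss <- setdiff(training_sample_ids, folds$sample_id)
    extra <- setdiff(folds$sample_id, training_sample_ids)
    if (length(miss) > 0L) stop_superpca("fold file omits training sample(s): ", paste(miss, collapse = ", "))
    if (length(extra) > 0L) stop_superpca("fold file contains non-training sample(s): ", paste(extra, collapse = ", "))
    folds <- folds[match(training_sample_ids, folds$sample_id), , drop = FALSE]
  }
  attr(folds, "K") <- as.integer(k)
  folds
}

#' Read a forest-plot input table
#'
#' Expects columns `label`, `estimate`, `lower`, `upper` holding ratio-scale
#' summaries (hazard or odds ratios with confidence bounds). Rows are kept in
#' file order; `lower <= estimate <= upper` and strict positivity are enforced.
#'
#' @param path Delimited text file.
#' @return Tibble of validated rows in file order.
#' @export
read_forest_table <- function(path) {
  f <- read_table_auto(path)
  validate_forest_rows(f)
}

#' @rdname read_forest_table
#' @param rows Data frame with columns `label`, `estimate`, `lower`, `upper`.
#' @export
validate_forest_rows <- function(rows) {
  rows <- tibble::as_tibble(rows)
  need <- c("label", "estimate", "lower", "upper")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0L) stop_superpca("forest table needs column(s): ", paste(miss, collapse = ", "))
  rows <- rows[, need, drop = FALSE]
  if (nrow(rows) < 1L) stop_superpca("forest table is empty")
  rows$label <- as.character(rows$label)
  for (col in c("estimate", "lower", "upper")) {
    v <- rows[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) stop_superpca("column '", col, "' must be finite numeric")
    if (any(v <= 0)) {
      stop_superpca("ratio-scale values must be positive; offending row(s): ",
                    paste(rows$label[v <= 0], collapse = ", "))
    }
  }
  bad <- rows$lower > rows$estimate | rows$estimate > rows$upper
  if (any(bad)) {
    stop_superpca("need lower <= estimate <= upper; offending row(s): ",
                  paste(rows$label[bad], collapse = ", "))
  }
  rows
}
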