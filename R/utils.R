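# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_superpca <- function(..., call. = FALSE) {
  stop(paste0(...), call. = call.)
}

# Delimiter by file extension: .csv -> comma, everything else (.tsv, .txt) -> tab.
delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_auto <- function(path, col_types = NULL) {
  if (!file.exists(path)) stop_superpca("file not found: ", path)
  readr::read_delim(path, delim = delim_for(path), col_types = col_types,
                    show_col_types = FALSE, progress = FALSE)
}

write_table_auto <- function(x, path) {
  readr::write_delim(x, path, delim = delim_for(path))
  invisible(path)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; with seed = NULL the current stream is used (and advanced).
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_superpca(name, " must be a single finite number in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

outcome_types <- c("survival", "continuous", "binary")

match_outcome_type <- function(outcome_type) {
  match.arg(outcome_type, outcome_types)
}
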