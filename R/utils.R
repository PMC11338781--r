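# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `code`,
#' and restores the previous state so library internals (e.g. the weighted
#' median bootstrap) never perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-operation substream; keeps derived seeds < 2^31.
seed_for <- function(cfg, k) {
  (as.double(cfg$seed) * 1009 + k) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DNA complement for strand-flip handling during harmonisation.
dna_complement <- function(x) chartr("ACGT", "TGCA", toupper(x))

is_palindromic <- function(a1, a2) dna_complement(a1) == toupper(a2)

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
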