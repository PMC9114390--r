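#' Run an expression with a local RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the stream so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a 31-bit seed,
#' so one `--seed` reproducibly drives every stage of a study (design,
#' cohorts, choices, cross-validation folds, ...). The derivation is
#' `(master * 48271 + sum of the label's UTF-8 bytes * 9349) mod (2^31 - 1)`.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"design"` or `"choices:KR-like"`.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "design")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, keeps the result a valid 32-bit R integer
  bytes <- as.integer(charToRaw(paste(stage, collapse = ":")))
  h <- ((abs(master) %% m) * 48271) %% m
  h <- (h + sum(bytes * seq_along(bytes)) * 9349) %% m
  as.integer(h %% (m - 2L) + 1L)
}
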