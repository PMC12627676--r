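# Internal validation and seeding helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  if (integer && x != round(x))
    stopf("'%s' must be an integer, got %s", name, x)
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, 0, 1)

#' Derive a stage-specific seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed; each stage
#' draws from its own substream so that adding a stage never perturbs the
#' draws of another. The derived seed is kept below `2^31 - 1`.
#'
#' @param seed Integer root seed.
#' @param stage Character stage name.
#' @return An integer seed for the stage.
#' @export
stage_seed <- function(seed, stage) {
  check_number(seed, "seed", integer = TRUE)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97) %%
               (.Machine$integer.max - 2)) + 1L
}

# coerce dense or sparse input to a general CsparseMatrix
to_sparse <- function(m) {
  if (!methods::is(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
}

# Rank-based AUC (Mann-Whitney): probability a random positive scores
# above a random negative, ties counted half.
auc_rank <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
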