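# Signature ("module") scores with expression-matched control genes, and
# per-condition Pearson correlation between two scores with the t-test
# for a correlation coefficient.

#' Log-normalize raw counts
#'
#' Per cell: `ln(1 + count / library_size * scale)` (counts per 10k by
#' default). Zero-library cells cannot be normalized and raise an error
#' naming them.
#'
#' @param expr Gene x cell count matrix (sparse or dense).
#' @param scale Library-size target (default 1e4).
#' @return A sparse gene x cell matrix of normalized values.
#' @export
lognormalize <- function(expr, scale = 1e4) {
  check_number(scale, "scale", 1e-12)
  expr <- to_sparse(expr)
  lib <- Matrix::colSums(expr)
  if (any(lib <= 0))
    stopf("cell(s) with zero library size: %s",
          paste(head(colnames(expr)[lib <= 0], 5), collapse = ", "))
  out <- expr %*% Matrix::Diagonal(x = scale / lib)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(expr)
  out
}

#' Control-gene-binned signature score
#'
#' Canonical module score: all genes are ranked by mean normalized
#' expression across cells and split into `n_bins` equal-frequency bins
#' (ties broken by stable gene order). For each signature gene, `n_ctrl`
#' control genes are drawn with replacement (seeded) from its bin. The
#' per-cell score is the mean normalized expression of the signature
#' genes minus the mean over the pooled control draws, so a signature
#' with no coherent program centers on zero.
#'
#' @param norm Gene x cell normalized matrix (see [lognormalize()]).
#' @param signature Character vector of signature genes; genes absent
#'   from the matrix are dropped with a warning.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes drawn per signature gene (default 100).
#' @param seed Integer seed for the control draws.
#' @return A list of class `score_result`: `score` (named per-cell),
#'   `signature_genes` (those used), `control_genes` (pooled draws, with
#'   multiplicity), `params`.
#' @export
module_score <- function(norm, signature, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  check_number(n_bins, "n_bins", 1, integer = TRUE)
  check_number(n_ctrl, "n_ctrl", 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (!length(signature) || anyDuplicated(signature))
    stopf("signature must be a non-empty set of unique genes")
  norm <- as.matrix(norm)
  genes <- rownames(norm)
  missing <- setdiff(signature, genes)
  if (length(missing))
    warning(sprintf("%d signature gene(s) absent from the matrix: %s",
                    length(missing),
                    paste(head(missing, 5), collapse = ", ")),
            call. = FALSE)
  sig <- intersect(signature, genes)
  if (!length(sig)) stopf("no signature gene present in the matrix")
  if (nrow(norm) < n_bins)
    stopf("need at least n_bins = %d genes, have %d", n_bins, nrow(norm))

  avg <- rowMeans(norm)
  # equal-frequency bins; ties broken by gene name so scores are
  # invariant to the ordering of genes and cells in the input
  ord <- order(avg, genes)
  r <- integer(length(avg))
  r[ord] <- seq_along(ord)
  bin <- ceiling(r / (length(r) / n_bins))
  names(bin) <- genes

  ctrl <- withr::with_seed(stage_seed(seed, "module_score_controls"), {
    unlist(lapply(sig, function(gn) {
      pool <- sort(genes[bin == bin[[gn]]])
      sample(pool, n_ctrl, replace = TRUE)
    }), use.names = FALSE)
  })

  score <- colMeans(norm[sig, , drop = FALSE]) -
    colMeans(norm[ctrl, , drop = FALSE])
  structure(list(
    score = score, signature_genes = sig, control_genes = ctrl,
    params = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  ), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("Signature score over %d cells (%d signature genes, %d bins, %d controls/gene)\n",
              length(x$score), length(x$signature_genes),
              x$params$n_bins, x$params$n_ctrl))
  print(summary(unname(x$score)))
  invisible(x)
}

#' Per-condition Pearson correlation between two scores
#'
#' For each condition, the Pearson correlation coefficient between the
#' two per-cell scores and its two-sided Student's t-test
#' (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`, `n - 2` degrees of freedom).
#' A zero-variance score vector makes `r` undefined; it is reported as
#' `NA` rather than an error.
#'
#' @param score_a,score_b Numeric per-cell scores (aligned, same cells),
#'   or `score_result` objects.
#' @param condition Condition label per cell.
#' @return Data frame: `condition`, `r`, `n`, `t`, `p`.
#' @export
pcc_by_condition <- function(score_a, score_b, condition) {
  if (inherits(score_a, "score_result")) score_a <- score_a$score
  if (inherits(score_b, "score_result")) score_b <- score_b$score
  stopifnot(length(score_a) == length(score_b),
            length(condition) == length(score_a))
  out <- lapply(unique(condition), function(cond) {
    i <- condition == cond
    n <- sum(i)
    if (n < 3L) stopf("condition '%s' has fewer than 3 cells", cond)
    a <- score_a[i]; b <- score_b[i]
    if (sd(a) < 1e-300 || sd(b) < 1e-300) {
      return(data.frame(condition = cond, r = NA_real_, n = n,
                        t = NA_real_, p = NA_real_))
    }
    r <- cor(a, b)
    t <- r * sqrt(n - 2) / sqrt(max(1 - r^2, 1e-300))
    data.frame(condition = cond, r = r, n = n, t = t,
               p = 2 * pt(-abs(t), df = n - 2))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
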