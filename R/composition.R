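# Cell-type composition across conditions: contingency counts, a probit
# transform for display of proportions, and a one-vs-rest Fisher exact
# enrichment of each cell type in a condition versus Control with
# Benjamini-Hochberg correction across the cell types of the population.

#' Condition x cell-type composition counts
#'
#' Tallies cells per condition and cell type within one general
#' population (e.g. stroma, T cells or HSPCs), optionally split by donor.
#'
#' @param meta Cell metadata with `condition`, `cell_type` and (if
#'   `by_donor`) `donor` columns.
#' @param cell_types Optional subset of cell types defining the
#'   population; unknown names raise an error.
#' @param by_donor Also split counts by donor.
#' @return A contingency table (condition x cell type, optionally x
#'   donor) of class `table`.
#' @export
composition_counts <- function(meta, cell_types = NULL, by_donor = FALSE) {
  stopifnot(all(c("condition", "cell_type") %in% names(meta)))
  if (!is.null(cell_types)) {
    unknown <- setdiff(cell_types, unique(meta$cell_type))
    if (length(unknown))
      stopf("unknown cell type(s): %s", paste(unknown, collapse = ", "))
    meta <- meta[meta$cell_type %in% cell_types, , drop = FALSE]
  }
  if (by_donor)
    table(condition = meta$condition, cell_type = meta$cell_type,
          donor = meta$donor)
  else
    table(condition = meta$condition, cell_type = meta$cell_type)
}

#' Probit transform of proportions
#'
#' The standard-normal quantile of a proportion, with boundary values
#' clamped to `[eps, 1 - eps]` so 0 and 1 stay finite. The default
#' continuity adjustment is `eps = 1 / (2 * n)` with `n` the group size.
#'
#' @param p Proportions in `[0, 1]`.
#' @param n Group size(s) used for the default clamp; required when `eps`
#'   is not given and any `p` touches 0 or 1.
#' @param eps Explicit clamp; overrides `n`.
#' @return `qnorm(clamp(p, eps, 1 - eps))`.
#' @export
probit_transform <- function(p, n = NULL, eps = NULL) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("proportions must lie in [0, 1]")
  if (is.null(eps)) {
    if (is.null(n)) {
      if (any(p <= 0 | p >= 1))
        stopf("boundary proportions need 'n' (or 'eps') for the clamp")
      eps <- 0
    } else {
      eps <- 1 / (2 * n)
    }
  }
  qnorm(pmin(pmax(p, eps), 1 - eps))
}

#' One-vs-rest Fisher enrichment of cell types versus Control
#'
#' For each cell type, a 2 x 2 table (this type vs all other types of the
#' population) x (condition vs reference) is tested two-sided with
#' Fisher's exact test. The reported odds ratio is the sample odds ratio
#' `(a * d) / (b * c)` (infinite by convention on zero margins). P values
#' are Benjamini-Hochberg adjusted across the cell types; `padj < 0.05`
#' is the conventional enrichment call.
#'
#' @param tab A condition x cell-type contingency table
#'   ([composition_counts()]).
#' @param condition Condition tested for enrichment.
#' @param reference Reference condition (default `"Control"`).
#' @return Data frame: `cell_type`, `condition`, `odds_ratio`, `p`,
#'   `padj`, `direction` (`up`/`down` vs the reference proportion).
#' @export
one_vs_rest_fisher <- function(tab, condition, reference = "Control") {
  if (!condition %in% rownames(tab)) stopf("condition '%s' absent", condition)
  if (!reference %in% rownames(tab)) stopf("reference '%s' absent", reference)
  if (sum(tab[condition, ]) == 0 || sum(tab[reference, ]) == 0)
    stopf("both conditions must contain cells")
  types <- colnames(tab)
  res <- lapply(types, function(ct) {
    a <- tab[condition, ct]; b <- sum(tab[condition, ]) - a
    c_ <- tab[reference, ct]; d <- sum(tab[reference, ]) - c_
    m <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
    p <- fisher.test(m, alternative = "two.sided")$p.value
    or <- (a * d) / (b * c_)     # sample OR; Inf on zero margins
    prop_cond <- a / (a + b); prop_ref <- c_ / (c_ + d)
    data.frame(cell_type = ct, condition = condition, odds_ratio = or,
               p = p,
               direction = if (prop_cond >= prop_ref) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$p, method = "BH")
  out[c("cell_type", "condition", "odds_ratio", "p", "padj", "direction")]
}
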