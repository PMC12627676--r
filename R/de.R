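# Pseudobulk differential expression between predicted clones: raw counts
# are summed per donor x genotype group, genes are filtered on fragments
# per million, and each gene is tested with a negative-binomial GLM (log
# link, size-factor offset, donor as a fixed-effect covariate) via a Wald
# test on the genotype coefficient. No effect-size shrinkage is applied.

#' Aggregate single-cell counts into pseudobulk groups
#'
#' Sums raw counts per gene over every combination of the grouping keys
#' (default donor x genotype). Groups with zero cells do not appear;
#' total counts are conserved.
#'
#' @param expr Gene x cell count matrix (sparse or dense).
#' @param meta Cell metadata data frame with a `cell_id` column and the
#'   grouping key columns.
#' @param cells Optional subset of cell ids (e.g. one cell type).
#' @param group_keys Metadata columns defining the groups.
#' @return A list of class `pseudobulk`: `counts` (gene x group integer
#'   matrix), `groups` (data frame with the keys, `n_cells` and
#'   `lib_size` per group).
#' @export
pseudobulk <- function(expr, meta, cells = NULL,
                       group_keys = c("donor", "genotype")) {
  if (!all(group_keys %in% names(meta)))
    stopf("meta lacks grouping column(s): %s",
          paste(setdiff(group_keys, names(meta)), collapse = ", "))
  if (is.null(cells)) cells <- meta$cell_id
  cells <- intersect(cells, intersect(meta$cell_id, colnames(expr)))
  if (!length(cells)) stopf("no cells selected for pseudobulk aggregation")
  m <- meta[match(cells, meta$cell_id), , drop = FALSE]
  for (k in group_keys) if (anyNA(m[[k]]))
    stopf("grouping key '%s' has missing values for selected cells", k)
  grp <- interaction(m[group_keys], sep = ":", drop = TRUE)
  ind <- Matrix::fac2sparse(grp)            # levels x cells
  counts <- as.matrix(expr[, cells, drop = FALSE] %*% Matrix::t(ind))
  storage.mode(counts) <- "double"
  key_df <- unique(cbind(m[group_keys], group = as.character(grp)))
  key_df <- key_df[match(colnames(counts), key_df$group), , drop = FALSE]
  rownames(key_df) <- NULL
  key_df$n_cells <- as.integer(table(grp)[colnames(counts)])
  key_df$lib_size <- colSums(counts)
  structure(list(counts = counts, groups = key_df), class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("Pseudobulk: %d genes x %d groups (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(setdiff(names(x$groups),
                            c("group", "n_cells", "lib_size")),
                    collapse = " x ")))
  invisible(x)
}

#' Fragments-per-million gene filter
#'
#' Keeps a gene if, in at least one of the two testing conditions, its
#' expression reaches `min_fpm` fragments per million (count / group
#' library size x 1e6) in at least `ceiling(min_donor_frac * n)` of the
#' condition's `n` groups.
#'
#' @param pb A [pseudobulk()] result.
#' @param condition_key Grouping column that defines the two testing
#'   conditions (default `"genotype"`).
#' @param min_fpm Minimum fragments per million (default 2).
#' @param min_donor_frac Minimum fraction of a condition's donors
#'   (default 0.5; ceiling is used for odd counts).
#' @return Character vector of retained gene ids.
#' @export
filter_fpm <- function(pb, condition_key = "genotype", min_fpm = 2,
                       min_donor_frac = 0.5) {
  stopifnot(inherits(pb, "pseudobulk"))
  check_number(min_fpm, "min_fpm", 0)
  check_number(min_donor_frac, "min_donor_frac", 0, 1)
  if (any(pb$groups$lib_size <= 0))
    stopf("all group library sizes must be positive")
  cond <- pb$groups[[condition_key]]
  if (is.null(cond)) stopf("unknown condition key '%s'", condition_key)
  fpm <- sweep(pb$counts, 2, pb$groups$lib_size, "/") * 1e6
  keep <- rep(FALSE, nrow(fpm))
  for (lv in unique(cond)) {
    idx <- cond == lv
    if (!any(idx)) stopf("condition '%s' has zero groups", lv)
    need <- ceiling(min_donor_frac * sum(idx))
    keep <- keep | rowSums(fpm[, idx, drop = FALSE] >= min_fpm) >= need
  }
  rownames(fpm)[keep]
}

#' Median-of-ratios size factors
#'
#' DESeq-style size factors: per group, the median ratio of counts to the
#' geometric-mean pseudo-reference over genes expressed in every group.
#' Falls back to library-size factors when fewer than 10 genes are usable.
#'
#' @param counts Gene x group count matrix.
#' @return Numeric size factors, geometric mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_ref <- rowMeans(log(counts))
  usable <- is.finite(log_ref)
  if (sum(usable) < 10L) {
    sf <- colSums(counts)
    if (any(sf <= 0)) stopf("library-size fallback requires positive totals")
    return(sf / exp(mean(log(sf))))
  }
  sf <- apply(counts[usable, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - log_ref[usable])))
  sf / exp(mean(log(sf)))
}

# Method-of-moments dispersion by Pearson matching: the alpha for which
# the Pearson chi-square sum((y - mu)^2 / (mu * (1 + alpha * mu))) equals
# the residual degrees of freedom. The naive estimator that ignores the
# fitted parameters is badly downward-biased with ~11 groups and an
# 8-column design. Floored at 1e-8.
mom_dispersion <- function(y, mu, df_resid, upper = 100) {
  if (df_resid < 1) return(1e-8)
  pearson_excess <- function(a) sum((y - mu)^2 / (mu * (1 + a * mu))) -
    df_resid
  if (pearson_excess(1e-8) <= 0) return(1e-8)
  if (pearson_excess(upper) >= 0) return(upper)
  stats::uniroot(pearson_excess, c(1e-8, upper), tol = 1e-10)$root
}

#' Negative-binomial Wald test between genotypes with donor covariate
#'
#' Per gene: a Poisson GLM provides fitted means for a method-of-moments
#' dispersion estimate (Pearson chi-square matched to the residual
#' degrees of freedom, floored at 1e-8), then a negative-binomial GLM
#' (log link, `log(size factor)` offset, design `~ genotype + donor`) is
#' fitted and the genotype coefficient Wald-tested. P values are
#' Benjamini-Hochberg adjusted over the tested genes. Fold changes are
#' reported in log2.
#'
#' @param pb A [pseudobulk()] result with `genotype` and `donor` keys.
#' @param genes Genes to test (default: all genes in `pb`; typically the
#'   [filter_fpm()] output).
#' @param contrast Length-2 character: the genotype level tested against
#'   the reference, default `c("MUT", "WT")` (positive log2FC = higher in
#'   MUT).
#' @return A data frame of class `de_result`: `gene`, `lfc` (log2), `se`,
#'   `stat`, `p`, `padj`, ordered by `p`.
#' @export
nb_de_test <- function(pb, genes = NULL, contrast = c("MUT", "WT")) {
  stopifnot(inherits(pb, "pseudobulk"))
  g <- pb$groups
  if (is.null(g$genotype) || is.null(g$donor))
    stopf("pseudobulk groups must carry 'genotype' and 'donor' keys")
  if (!all(contrast %in% g$genotype))
    stopf("both contrast levels must be present; have: %s",
          paste(unique(g$genotype), collapse = ", "))
  if (length(unique(g$genotype)) < 2L)
    stopf("need >= 2 genotype levels")
  for (lv in contrast)
    if (sum(g$genotype == lv) < 1L)
      stopf("genotype level '%s' has no groups", lv)

  genotype <- factor(g$genotype, levels = c(contrast[2L], contrast[1L]))
  donor <- factor(g$donor)
  if (nlevels(donor) > 1L) {
    design <- model.matrix(~ genotype + donor)
  } else {
    design <- model.matrix(~ genotype)
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(aliased, collapse = ", "))
  }
  coef_name <- paste0("genotype", contrast[1L])

  counts <- pb$counts
  if (is.null(genes)) genes <- rownames(counts)
  if (length(miss <- setdiff(genes, rownames(counts))))
    stopf("unknown gene(s): %s", paste(head(miss, 5), collapse = ", "))
  sf <- size_factors(counts)
  off <- log(sf)

  df_resid <- nrow(design) - ncol(design)
  res <- lapply(genes, function(gn) {
    y <- counts[gn, ]
    fit_p <- suppressWarnings(
      glm(y ~ 0 + design + offset(off), family = poisson()))
    mu <- pmax(fitted(fit_p), 1e-8)
    alpha <- mom_dispersion(y, mu, df_resid)
    fit <- suppressWarnings(
      glm(y ~ 0 + design + offset(off),
          family = MASS::negative.binomial(theta = 1 / alpha)))
    # dispersion fixed at 1: the NB variance is already in the family,
    # giving a Wald statistic (finite even for saturated designs)
    sm <- summary(fit, dispersion = 1)$coefficients
    row <- sm[paste0("design", coef_name), , drop = TRUE]
    b <- row[["Estimate"]]; se <- row[["Std. Error"]]
    stat <- if (is.finite(se) && se > 0) b / se
            else if (abs(b) < 1e-12) 0 else NA_real_
    data.frame(gene = gn, lfc = b / log(2), se = se / log(2), stat = stat,
               p = 2 * pnorm(-abs(stat)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Differential expression: %d genes tested, %d at padj < 0.05\n",
              nrow(x), sum(x$padj < 0.05, na.rm = TRUE)))
  print.data.frame(head(as.data.frame(x), 10), digits = 3)
  invisible(x)
}
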