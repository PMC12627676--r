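# Readers and writers for the plain-text formats the pipeline touches:
# MatrixMarket matrices with TSV sidecars for cell and feature ids, TSV
# tables for metadata, signatures and ligand-receptor pairs, JSON for
# configuration and run reports. Identifiers are opaque strings; joins
# are by id, never by position.

#' Write a sparse matrix with cell/feature sidecars
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format, 1-based indices),
#' `features.tsv` (row ids) and `cells.tsv` (column ids) into `dir`.
#'
#' @param m Feature x cell matrix.
#' @param dir Output directory (created if needed).
#' @param prefix Optional filename prefix (e.g. `"canonical_"`).
#' @return The directory, invisibly.
#' @export
write_counts <- function(m, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- to_sparse(m)
  Matrix::writeMM(m, file.path(dir, paste0(prefix, "matrix.mtx")))
  writeLines(rownames(m), file.path(dir, paste0(prefix, "features.tsv")))
  writeLines(colnames(m), file.path(dir, paste0(prefix, "cells.tsv")))
  invisible(dir)
}

#' Read a sparse matrix written by [write_counts()]
#'
#' Validates that the MatrixMarket dimensions match the sidecars and that
#' ids are unique; each failure is a named error.
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`, `cells.tsv`.
#' @param prefix Optional filename prefix.
#' @return A sparse feature x cell matrix with dimnames.
#' @export
read_counts <- function(dir, prefix = "") {
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "features.tsv",
                                           "cells.tsv")))
  for (p in paths) if (!file.exists(p)) stopf("missing file: %s", p)
  m <- tryCatch(Matrix::readMM(paths[1L]),
                error = function(e) stopf("malformed MatrixMarket file %s: %s",
                                          paths[1L], conditionMessage(e)))
  features <- readLines(paths[2L])
  cells <- readLines(paths[3L])
  if (anyDuplicated(features)) stopf("duplicate feature ids in %s", paths[2L])
  if (anyDuplicated(cells)) stopf("duplicate cell ids in %s", paths[3L])
  if (nrow(m) != length(features) || ncol(m) != length(cells))
    stopf("dimension mismatch: matrix is %d x %d but sidecars give %d x %d",
          nrow(m), ncol(m), length(features), length(cells))
  dimnames(m) <- list(features, cells)
  to_sparse(m)
}

#' Write a simulated cohort to disk
#'
#' Emits the junction layers (`canonical_`/`cryptic_` MTX + sidecars),
#' the expression matrix, the event/cell/donor tables, the ground truth
#' and a JSON echo of the configuration.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(cohort$junctions$canonical, dir, "canonical_")
  write_counts(cohort$junctions$cryptic, dir, "cryptic_")
  write_counts(cohort$expression, dir, "expression_")
  write_tsv <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  write_tsv(cohort$events, "events.tsv")
  write_tsv(cohort$cells, "cells.tsv")
  write_tsv(cohort$donors, "donors.tsv")
  write_tsv(data.frame(event_id = names(cohort$truth$psi0_by_event),
                       psi0 = cohort$truth$psi0_by_event,
                       psi1 = cohort$truth$psi1_by_event),
            "truth_events.tsv")
  write_tsv(data.frame(gene = names(cohort$truth$log2fc_by_gene),
                       log2fc = cohort$truth$log2fc_by_gene,
                       signature = names(cohort$truth$log2fc_by_gene) %in%
                         cohort$truth$signature_genes),
            "truth_genes.tsv")
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a two-column signature table
#'
#' @param path TSV with columns `signature` and `gene`.
#' @return Named list of gene vectors, one per signature.
#' @export
read_signatures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("signature", "gene") %in% names(df)))
    stopf("signature table must have 'signature' and 'gene' columns")
  split(df$gene, df$signature)
}

#' Read a ligand-receptor pair table
#'
#' @param path TSV with columns `ligand`, `receptor` and optionally
#'   `source`.
#' @return Data frame with unique ligand-receptor rows.
#' @export
read_lr_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df)))
    stopf("LR table must have 'ligand' and 'receptor' columns")
  df[!duplicated(df[c("ligand", "receptor")]), , drop = FALSE]
}
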