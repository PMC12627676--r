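# Cryptic splice-site usage: the per-cell, per-event feature of the clone
# classifier. Usage u = cryptic / (cryptic + canonical) is a bounded,
# PSI-like fraction; it is undefined (not zero) where the event has no
# reads in the cell.

#' Per-cell cryptic splice-site usage
#'
#' Computes, for every mis-splicing event in every cell, the cryptic-usage
#' fraction `u = cryptic / (cryptic + canonical)`. Entries with zero total
#' coverage are missing (`NA`), not zero: absence of reads carries no
#' information about splice-site choice.
#'
#' @param canonical,cryptic Event x cell matrices of non-negative integer
#'   junction read counts (dense or sparse, same dimensions), or a
#'   `sim_cohort` passed as `canonical` with `cryptic` missing.
#' @return A list of class `usage_matrix`: `usage` (event x cell, `NA`
#'   where uncovered), `covered` (logical mask), `covered_events`
#'   (per-cell count of covered events).
#' @export
splice_usage <- function(canonical, cryptic) {
  if (inherits(canonical, "sim_cohort") && missing(cryptic)) {
    cryptic <- canonical$junctions$cryptic
    canonical <- canonical$junctions$canonical
  }
  canonical <- as.matrix(canonical)
  cryptic <- as.matrix(cryptic)
  if (!identical(dim(canonical), dim(cryptic)))
    stopf("canonical and cryptic layers must have identical dimensions")
  if (any(canonical < 0) || any(cryptic < 0))
    stopf("junction counts must be non-negative")
  total <- canonical + cryptic
  covered <- total > 0
  u <- matrix(NA_real_, nrow(total), ncol(total), dimnames = dimnames(total))
  u[covered] <- cryptic[covered] / total[covered]
  structure(list(
    usage = u,
    covered = covered,
    covered_events = setNames(colSums(covered), colnames(total))
  ), class = "usage_matrix")
}

#' @export
print.usage_matrix <- function(x, ...) {
  cat(sprintf("Usage matrix: %d events x %d cells; %.1f%% covered; median covered events/cell: %s\n",
              nrow(x$usage), ncol(x$usage), 100 * mean(x$covered),
              stats::median(x$covered_events)))
  invisible(x)
}

#' Cells with enough covered events to classify
#'
#' A cell is considered for genotype classification only if at least
#' `min_events` mis-splicing events have read coverage (default 2).
#'
#' @param um A [splice_usage()] result.
#' @param min_events Minimum covered events (>= 1).
#' @return Character vector of cell ids, input order preserved.
#' @export
classifiable_cells <- function(um, min_events = 2) {
  stopifnot(inherits(um, "usage_matrix"))
  check_number(min_events, "min_events", 1, integer = TRUE)
  names(um$covered_events)[um$covered_events >= min_events]
}

#' Mean-impute missing usage values
#'
#' Replaces each missing usage entry by the mean usage of that event over
#' the cells where it is covered. Events covered in no cell carry no
#' information and are dropped with a warning.
#'
#' @param um A [splice_usage()] result.
#' @return A complete numeric event x cell matrix with attributes
#'   `event_means` (the per-event imputation values) and `dropped_events`.
#' @export
impute_usage <- function(um) {
  stopifnot(inherits(um, "usage_matrix"))
  if (ncol(um$usage) == 0L || nrow(um$usage) == 0L)
    stopf("cannot impute an empty usage matrix")
  event_means <- rowMeans(um$usage, na.rm = TRUE)
  dropped <- rownames(um$usage)[!is.finite(event_means)]
  if (length(dropped)) {
    warning(sprintf("dropping %d event(s) with zero coverage in all cells: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  keep <- is.finite(event_means)
  out <- um$usage[keep, , drop = FALSE]
  means <- event_means[keep]
  miss <- which(is.na(out), arr.ind = TRUE)
  if (nrow(miss)) out[miss] <- means[miss[, 1L]]
  attr(out, "event_means") <- means
  attr(out, "dropped_events") <- dropped
  out
}
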