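#' Default condition-specific cell-type proportions
#'
#' A stated world for the synthetic bone-marrow cohort: erythroid
#' progenitors and HSC/MPPs dominate in all conditions; inflammatory MSCs
#' (iMSC) expand and Pre-B cells and adipogenic CAR cells shrink from
#' Control through CHIP to MDS, mirroring the qualitative composition
#' shifts the analysis is designed to detect.
#'
#' @return Named list of per-condition probability vectors over cell types.
#' @export
default_cell_type_proportions <- function() {
  list(
    Control = c(HSC_MPP = 0.25, EryPr = 0.30, PreB = 0.20,
                AdipoCAR = 0.20, iMSC = 0.05),
    CHIP    = c(HSC_MPP = 0.28, EryPr = 0.30, PreB = 0.12,
                AdipoCAR = 0.18, iMSC = 0.12),
    MDS     = c(HSC_MPP = 0.20, EryPr = 0.30, PreB = 0.08,
                AdipoCAR = 0.12, iMSC = 0.30)
  )
}

#' Configuration for the synthetic bone-marrow cohort
#'
#' Validates and assembles the parameters of [simulate_cohort()]. Defaults
#' describe the cohort shape the splice-classifier analysis assumes: 3
#' wild-type-labeled and 4 mutant-labeled donors, 400 cells per donor, 50
#' mis-splicing events with baseline cryptic usage 0.02 versus 0.35 in
#' mutant cells, a mutant clone fraction of 0.6, and Poisson(0.6) read
#' coverage per event per cell.
#'
#' @param n_wt_donors,n_mut_donors Number of donors labeled wild-type /
#'   mutant at the sample level.
#' @param cells_per_donor Cells simulated per donor.
#' @param n_events Number of mis-splicing events in the catalog.
#' @param clone_fraction Probability that a cell of a mutant-labeled donor
#'   truly carries the mutation; scalar or one value per mutant donor.
#' @param psi0,psi1 Cryptic-usage probability in truly wild-type / mutant
#'   cells; must satisfy `0 <= psi0 < psi1 <= 1` unless equal (null
#'   simulations with `psi1 = psi0` are allowed).
#' @param event_coverage_rate Poisson mean of total reads per event per
#'   cell; controls sparsity.
#' @param psi_concentration Optional Beta concentration; when set, each
#'   event's (psi0, psi1) pair is jittered around the global values with
#'   `Beta(psi * k, (1 - psi) * k)`. Default `NULL` (off).
#' @param n_genes,n_de_genes Number of genes, and how many of them are
#'   genotype-responsive (differentially expressed in mutant cells).
#' @param de_log2fc True log2 fold change of the DE genes in mutant cells.
#' @param nb_dispersion Negative-binomial dispersion `alpha`
#'   (variance `mu + alpha * mu^2`).
#' @param n_signature_genes Number of genes carrying the cell-type
#'   signature effect (disjoint from the DE genes).
#' @param signature_effect Log2 fold applied to signature genes in
#'   `signature_cell_types`.
#' @param signature_cell_types Cell types carrying the signature effect.
#' @param cell_type_proportions Named list of per-condition simplex
#'   vectors over cell types; see [default_cell_type_proportions()].
#' @param conditions Condition per donor (`Control`, `CHIP` or `MDS`);
#'   default: wild-type donors are Control, mutant donors MDS. Pass
#'   `c(rep("Control", 3), rep("CHIP", 3), rep("MDS", 4))` with
#'   `n_wt_donors = 6, n_mut_donors = 4` for the full cohort shape.
#' @param seed Integer root seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_wt_donors = 3, n_mut_donors = 4,
                       cells_per_donor = 400, n_events = 50,
                       clone_fraction = 0.6, psi0 = 0.02, psi1 = 0.35,
                       event_coverage_rate = 0.6, psi_concentration = NULL,
                       n_genes = 1000, n_de_genes = 100, de_log2fc = 1.0,
                       nb_dispersion = 0.1, n_signature_genes = 25,
                       signature_effect = 1.0,
                       signature_cell_types = "iMSC",
                       cell_type_proportions = default_cell_type_proportions(),
                       conditions = NULL, seed = 1L) {
  check_number(n_wt_donors, "n_wt_donors", 1, integer = TRUE)
  check_number(n_mut_donors, "n_mut_donors", 1, integer = TRUE)
  check_number(cells_per_donor, "cells_per_donor", 1, integer = TRUE)
  check_number(n_events, "n_events", 1, integer = TRUE)
  check_probability(psi0, "psi0")
  check_probability(psi1, "psi1")
  if (psi0 > psi1)
    stopf("psi0 (%s) must be <= psi1 (%s)", psi0, psi1)
  check_number(event_coverage_rate, "event_coverage_rate", 0)
  if (!is.null(psi_concentration))
    check_number(psi_concentration, "psi_concentration", 1e-6)
  check_number(n_genes, "n_genes", 1, integer = TRUE)
  check_number(n_de_genes, "n_de_genes", 0, n_genes, integer = TRUE)
  check_number(de_log2fc, "de_log2fc")
  check_number(nb_dispersion, "nb_dispersion", 1e-12)
  check_number(n_signature_genes, "n_signature_genes", 0,
               n_genes - n_de_genes, integer = TRUE)
  check_number(signature_effect, "signature_effect")
  check_number(seed, "seed", integer = TRUE)

  if (length(clone_fraction) == 1L)
    clone_fraction <- rep(clone_fraction, n_mut_donors)
  if (length(clone_fraction) != n_mut_donors)
    stopf("clone_fraction must have length 1 or n_mut_donors (%d)",
          n_mut_donors)
  for (f in clone_fraction) check_probability(f, "clone_fraction")

  n_donors <- n_wt_donors + n_mut_donors
  if (is.null(conditions))
    conditions <- rep(c("Control", "MDS"), c(n_wt_donors, n_mut_donors))
  if (length(conditions) != n_donors)
    stopf("conditions must have one entry per donor (%d)", n_donors)
  bad <- setdiff(unique(conditions), names(cell_type_proportions))
  if (length(bad))
    stopf("no cell-type proportions configured for condition(s): %s",
          paste(bad, collapse = ", "))
  types <- names(cell_type_proportions[[1]])
  for (cond in names(cell_type_proportions)) {
    p <- cell_type_proportions[[cond]]
    if (!identical(names(p), types))
      stopf("cell-type proportion vectors must share names and order")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stopf("proportions for '%s' must be non-negative and sum to 1", cond)
  }
  if (length(st <- setdiff(signature_cell_types, types)))
    stopf("unknown signature_cell_types: %s", paste(st, collapse = ", "))

  structure(list(
    n_wt_donors = as.integer(n_wt_donors),
    n_mut_donors = as.integer(n_mut_donors),
    cells_per_donor = as.integer(cells_per_donor),
    n_events = as.integer(n_events),
    clone_fraction = clone_fraction, psi0 = psi0, psi1 = psi1,
    event_coverage_rate = event_coverage_rate,
    psi_concentration = psi_concentration,
    n_genes = as.integer(n_genes), n_de_genes = as.integer(n_de_genes),
    de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
    n_signature_genes = as.integer(n_signature_genes),
    signature_effect = signature_effect,
    signature_cell_types = signature_cell_types,
    cell_type_proportions = cell_type_proportions,
    conditions = conditions, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  donors: %d WT-labeled + %d MUT-labeled (%s)\n",
              x$n_wt_donors, x$n_mut_donors,
              paste(rle(x$conditions)$values, collapse = "/")))
  cat(sprintf("  cells/donor: %d; events: %d; psi0/psi1: %.3g/%.3g; clone fraction: %s\n",
              x$cells_per_donor, x$n_events, x$psi0, x$psi1,
              paste(unique(x$clone_fraction), collapse = ",")))
  cat(sprintf("  genes: %d (%d DE at log2FC %.2f, dispersion %.3g); seed %d\n",
              x$n_genes, x$n_de_genes, x$de_log2fc, x$nb_dispersion, x$seed))
  invisible(x)
}

#' Build a mis-splicing event annotation table
#'
#' Each event pairs a canonical with a cryptic splice junction in a gene
#' and is either an alternative 3' splice site (A3SS) or a skipped exon
#' (SE) event.
#'
#' @param n_events Number of events.
#' @return A data frame with columns `event_id`, `gene`, `event_class`,
#'   `canonical_junction`, `cryptic_junction`.
#' @export
splice_event_table <- function(n_events) {
  check_number(n_events, "n_events", 1, integer = TRUE)
  id <- sprintf("ev%03d", seq_len(n_events))
  data.frame(
    event_id = id,
    gene = sprintf("SPL%03d", seq_len(n_events)),
    event_class = rep_len(c("A3SS", "SE"), n_events),
    canonical_junction = paste0(id, ":canon"),
    cryptic_junction = paste0(id, ":cryptic"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a synthetic bone-marrow cohort with ground truth
#'
#' Generates, under a single root seed, (i) per-cell true genotype
#' (`Bernoulli(clone fraction)` in mutant-labeled donors, wild-type
#' otherwise), (ii) a sparse junction-count matrix per mis-splicing event
#' with total reads `Poisson(event_coverage_rate)` and cryptic reads
#' `Binomial(total, psi1 or psi0)` by true genotype, (iii) a sparse
#' negative-binomial gene-expression matrix in which DE genes have their
#' mean scaled by `2^de_log2fc` in mutant cells and signature genes by
#' `2^signature_effect` in the designated cell types, and (iv) cell types
#' drawn from the condition's proportion vector. Two calls with the same
#' config are byte-identical; the caller's RNG state is untouched.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `junctions` (list of
#'   `canonical` and `cryptic` sparse event x cell matrices), `events`
#'   (annotation table), `expression` (sparse gene x cell counts), `cells`
#'   (metadata: `cell_id`, `donor`, `condition`, `cell_type`, `genotype`),
#'   `donors` (donor table with labels and clone fractions), `truth`
#'   (per-event psi values, DE/signature gene truth, true proportions) and
#'   the `config` echo.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config"))
    stopf("'config' must be built by sim_config()")
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_donors <- cfg$n_wt_donors + cfg$n_mut_donors
  donor_id <- sprintf("D%02d", seq_len(n_donors))
  mut_label <- rep(c("WT", "MUT"), c(cfg$n_wt_donors, cfg$n_mut_donors))
  clone_frac <- c(rep(0, cfg$n_wt_donors), cfg$clone_fraction)
  donors <- data.frame(
    donor = donor_id, mut_status = mut_label, condition = cfg$conditions,
    clone_fraction = clone_frac, stringsAsFactors = FALSE
  )

  n_cells <- n_donors * cfg$cells_per_donor
  cell_donor <- rep(donor_id, each = cfg$cells_per_donor)
  cell_id <- sprintf("%s_c%04d", cell_donor,
                     rep(seq_len(cfg$cells_per_donor), n_donors))
  cell_cond <- rep(cfg$conditions, each = cfg$cells_per_donor)

  genotype <- ifelse(
    rbinom(n_cells, 1L, rep(clone_frac, each = cfg$cells_per_donor)) == 1L,
    "MUT", "WT")

  types <- names(cfg$cell_type_proportions[[1]])
  cell_type <- character(n_cells)
  for (cond in unique(cell_cond)) {
    idx <- which(cell_cond == cond)
    cell_type[idx] <- sample(types, length(idx), replace = TRUE,
                             prob = cfg$cell_type_proportions[[cond]])
  }

  # per-event cryptic-usage probabilities (optionally jittered)
  if (is.null(cfg$psi_concentration)) {
    psi0_e <- rep(cfg$psi0, cfg$n_events)
    psi1_e <- rep(cfg$psi1, cfg$n_events)
  } else {
    k <- cfg$psi_concentration
    jitter_beta <- function(p) {
      if (p <= 0 || p >= 1) rep(p, cfg$n_events)
      else stats::rbeta(cfg$n_events, p * k, (1 - p) * k)
    }
    psi0_e <- jitter_beta(cfg$psi0)
    psi1_e <- jitter_beta(cfg$psi1)
  }

  events <- splice_event_table(cfg$n_events)
  total <- matrix(rpois(cfg$n_events * n_cells, cfg$event_coverage_rate),
                  nrow = cfg$n_events)
  psi_cell <- matrix(psi0_e, nrow = cfg$n_events, ncol = n_cells)
  mut_cells <- genotype == "MUT"
  if (any(mut_cells)) psi_cell[, mut_cells] <- psi1_e
  cryptic <- matrix(rbinom(length(total), as.vector(total),
                           as.vector(psi_cell)),
                    nrow = cfg$n_events)
  canonical <- total - cryptic
  dimnames(canonical) <- dimnames(cryptic) <-
    list(events$event_id, cell_id)

  # gene expression: lognormal base means, per-cell depth factor,
  # genotype fold on DE genes, cell-type fold on signature genes
  gene_id <- sprintf("G%04d", seq_len(cfg$n_genes))
  de_genes <- gene_id[seq_len(cfg$n_de_genes)]
  sig_genes <- gene_id[cfg$n_de_genes + seq_len(cfg$n_signature_genes)]
  base_mu <- exp(rnorm(cfg$n_genes, log(2), 1))
  depth <- rlnorm(n_cells, 0, 0.25)

  log2fc_gene <- setNames(numeric(cfg$n_genes), gene_id)
  log2fc_gene[de_genes] <- cfg$de_log2fc
  mu <- outer(base_mu, depth)
  if (cfg$n_de_genes > 0 && any(mut_cells))
    mu[gene_id %in% de_genes, mut_cells] <-
      mu[gene_id %in% de_genes, mut_cells] * 2^cfg$de_log2fc
  sig_cells <- cell_type %in% cfg$signature_cell_types
  if (cfg$n_signature_genes > 0 && any(sig_cells))
    mu[gene_id %in% sig_genes, sig_cells] <-
      mu[gene_id %in% sig_genes, sig_cells] * 2^cfg$signature_effect
  expr <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                         size = 1 / cfg$nb_dispersion),
                 nrow = cfg$n_genes, dimnames = list(gene_id, cell_id))

  cells <- data.frame(
    cell_id = cell_id, donor = cell_donor, condition = cell_cond,
    cell_type = cell_type, genotype = genotype, stringsAsFactors = FALSE
  )

  structure(list(
    junctions = list(
      canonical = to_sparse(canonical),
      cryptic = to_sparse(cryptic)
    ),
    events = events,
    expression = to_sparse(expr),
    cells = cells,
    donors = donors,
    truth = list(
      psi0_by_event = setNames(psi0_e, events$event_id),
      psi1_by_event = setNames(psi1_e, events$event_id),
      log2fc_by_gene = log2fc_gene,
      de_genes = de_genes,
      signature_genes = sig_genes,
      cell_type_proportions = cfg$cell_type_proportions
    ),
    config = cfg
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cells, %d donors, %d events, %d genes\n",
              nrow(x$cells), nrow(x$donors), nrow(x$events),
              nrow(x$expression)))
  cat(sprintf("  true mutant cells: %d (%.1f%%)\n",
              sum(x$cells$genotype == "MUT"),
              100 * mean(x$cells$genotype == "MUT")))
  invisible(x)
}

#' Simulate coupled or anti-coupled signature programs in stromal cells
#'
#' Adds a shared latent per-cell factor to two disjoint gene programs on a
#' log-normalized matrix: with `coupling = +1` both programs move together
#' (MDS-like, positively correlated scores); with `coupling = -1` they move
#' in opposition (CHIP-like, anti-correlated scores). Used to test sign
#' recovery of the per-condition Pearson correlation between the
#' inflammation and HSPC-support scores.
#'
#' @param norm Gene x cell log-normalized matrix.
#' @param genes_a,genes_b Disjoint gene sets (e.g. inflammation and
#'   HSPC-support programs).
#' @param cells Cell ids to perturb.
#' @param coupling `+1` (coupled) or `-1` (anti-coupled).
#' @param sd Standard deviation of the latent factor.
#' @param seed Integer seed.
#' @return The perturbed matrix.
#' @export
simulate_signature_coupling <- function(norm, genes_a, genes_b, cells,
                                        coupling = 1, sd = 0.5, seed = 1L) {
  stopifnot(coupling %in% c(-1, 1))
  if (length(intersect(genes_a, genes_b)))
    stopf("gene programs must be disjoint")
  norm <- as.matrix(norm)
  withr::with_seed(seed, {
    z <- rnorm(length(cells), 0, sd)
    norm[genes_a, cells] <- sweep(norm[genes_a, cells, drop = FALSE], 2,
                                  z, "+")
    norm[genes_b, cells] <- sweep(norm[genes_b, cells, drop = FALSE], 2,
                                  coupling * z, "+")
  })
  pmax(norm, 0)
}
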