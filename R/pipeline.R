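# End-to-end driver: simulate -> usage -> classify -> pseudobulk DE ->
# signature scores -> composition -> interactions, with a JSON run
# report. Every stage draws its randomness from a named substream of the
# root seed; no stage mutates the outputs of another.

#' Run the full clone-aware analysis on a synthetic cohort
#'
#' Executes every stage of the pipeline on a freshly simulated cohort and
#' returns (optionally writes) a run report with per-stage record counts.
#' Two runs with the same configuration produce identical results.
#'
#' @param config A [sim_config()]; its seed is the pipeline's root seed.
#' @param out_dir Optional directory: the cohort, stage outputs and the
#'   JSON report are written there.
#' @param de_cell_type Cell type whose cells enter the clone DE stage
#'   (default `"EryPr"`, erythroid progenitors).
#' @param alpha Target false-positive rate of the clone classifier.
#' @param min_events Coverage filter for classification.
#' @param min_fpm,min_donor_frac Gene-filter parameters for the DE stage.
#' @param min_interactions Pair filter for the interaction stage.
#' @param n_bins,n_ctrl Module-score parameters.
#' @return A list of class `pipeline_result`: `cohort`, `model`, `calls`,
#'   `metrics`, `de`, `scores`, `pcc`, `composition`, `enrichment`,
#'   `interactions`, `report`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         de_cell_type = "EryPr", alpha = 0.10,
                         min_events = 2, min_fpm = 2, min_donor_frac = 0.5,
                         min_interactions = 5, n_bins = 24, n_ctrl = 100) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  report <- list(package = "spliceclone",
                 version = as.character(utils::packageVersion("spliceclone")),
                 seed = seed,
                 parameters = list(alpha = alpha, min_events = min_events,
                                   min_fpm = min_fpm,
                                   min_donor_frac = min_donor_frac,
                                   min_interactions = min_interactions,
                                   n_bins = n_bins, n_ctrl = n_ctrl),
                 stages = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  cohort <- run_stage("simulate", simulate_cohort(config))
  report$stages$simulate <- list(
    n_cells = nrow(cohort$cells), n_events = nrow(cohort$events),
    n_genes = nrow(cohort$expression))

  um <- run_stage("usage", splice_usage(cohort))
  report$stages$usage <- list(
    n_classifiable = length(classifiable_cells(um, min_events)))

  donor_labels <- setNames(cohort$donors$mut_status, cohort$donors$donor)
  cell_donor <- setNames(cohort$cells$donor, cohort$cells$cell_id)
  model <- run_stage("classify",
                     clone_fit(um, donor_labels, cell_donor, alpha = alpha,
                               min_events = min_events,
                               seed = stage_seed(seed, "classify")))
  calls <- run_stage("classify", predict(model, um))
  metrics <- evaluate_calls(calls, cohort)
  report$stages$classify <- list(
    n_called = sum(calls$call != "unclassified"),
    n_mut_calls = sum(calls$call == "MUT"),
    tau = model$tau, empirical_fpr = metrics$fpr, auc = metrics$auc)

  de <- run_stage("de", {
    meta <- cohort$cells
    meta$genotype_call <- calls$call[match(meta$cell_id, calls$cell_id)]
    sel <- meta$cell_id[meta$cell_type == de_cell_type &
                          meta$genotype_call %in% c("MUT", "WT")]
    meta$genotype <- meta$genotype_call
    pb <- pseudobulk(cohort$expression, meta, cells = sel)
    genes <- filter_fpm(pb, min_fpm = min_fpm,
                        min_donor_frac = min_donor_frac)
    list(pb = pb, genes = genes, result = nb_de_test(pb, genes))
  })
  report$stages$de <- list(n_groups = ncol(de$pb$counts),
                           n_genes_tested = length(de$genes),
                           n_sig = sum(de$result$padj < 0.05, na.rm = TRUE))

  scores <- run_stage("score", {
    norm <- lognormalize(cohort$expression)
    sig <- cohort$truth$signature_genes
    bg <- setdiff(rownames(norm), c(sig, cohort$truth$de_genes))
    ctrl_sig <- withr::with_seed(stage_seed(seed, "control_signature"),
                                 sample(bg, length(sig)))
    list(norm = norm,
         signature = module_score(norm, sig, n_bins, n_ctrl,
                                  seed = stage_seed(seed, "score_sig")),
         control = module_score(norm, ctrl_sig, n_bins, n_ctrl,
                                seed = stage_seed(seed, "score_ctrl")))
  })
  pcc <- pcc_by_condition(scores$signature, scores$control,
                          cohort$cells$condition)
  report$stages$score <- list(n_cells_scored = length(scores$signature$score))

  comp <- run_stage("composition", {
    tab <- composition_counts(cohort$cells)
    enr <- do.call(rbind, lapply(
      setdiff(rownames(tab), "Control"),
      function(cond) one_vs_rest_fisher(tab, cond)))
    list(table = tab, enrichment = enr)
  })
  report$stages$composition <- list(
    n_conditions = nrow(comp$table), n_cell_types = ncol(comp$table),
    n_enriched = sum(comp$enrichment$padj < 0.05))

  interactions <- run_stage("interactions", {
    senders <- cohort$cells$cell_id[cohort$cells$cell_type %in%
                                      c("iMSC", "AdipoCAR")]
    receivers <- cohort$cells$cell_id[cohort$cells$cell_type %in%
                                        c("HSC_MPP", "EryPr")]
    lr <- synthetic_lr_table(rownames(scores$norm),
                             seed = stage_seed(seed, "lr_table"))
    px <- lr_scores(scores$norm, lr, cohort$cells, senders, receivers,
                    seed = stage_seed(seed, "lr_pairs"))
    kept <- filter_min_interactions(px, min_interactions)
    list(summary = summarize_interactions(kept, cohort$cells, senders,
                                          receivers),
         n_pairs = nrow(px$pairs), n_retained = nrow(kept$pairs))
  })
  report$stages$interactions <- list(
    n_pairs_scored = interactions$n_pairs,
    n_pairs_retained = interactions$n_retained)

  out <- structure(list(
    cohort = cohort, model = model, calls = calls, metrics = metrics,
    de = de$result, scores = scores[c("signature", "control")], pcc = pcc,
    composition = comp$table, enrichment = comp$enrichment,
    interactions = interactions$summary, report = report
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(de$result), file.path(out_dir, "de.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(comp$enrichment, file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(interactions$summary$by_condition,
                file.path(out_dir, "interactions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report$stages
  cat("Clone-aware pipeline run\n")
  cat(sprintf("  simulate: %d cells, %d events, %d genes\n",
              r$simulate$n_cells, r$simulate$n_events, r$simulate$n_genes))
  cat(sprintf("  classify: %d called, %d MUT calls, held-out FPR %.3f, AUC %.3f\n",
              r$classify$n_called, r$classify$n_mut_calls,
              r$classify$empirical_fpr, r$classify$auc))
  cat(sprintf("  DE: %d genes tested, %d at padj < 0.05\n",
              r$de$n_genes_tested, r$de$n_sig))
  cat(sprintf("  composition: %d enriched cell types; interactions: %d/%d pairs retained\n",
              r$composition$n_enriched, r$interactions$n_pairs_retained,
              r$interactions$n_pairs_scored))
  invisible(x)
}

#' Synthetic ligand-receptor pair table
#'
#' Draws ligand and receptor genes (disjoint, seeded) from the supplied
#' gene universe. A stand-in for a curated ligand-receptor database when
#' running on synthetic cohorts; any TSV with `ligand` and `receptor`
#' columns can be used instead on real data.
#'
#' @param genes Gene universe.
#' @param n_pairs Number of LR pairs (default 30).
#' @param seed Integer seed.
#' @return Data frame with `ligand`, `receptor`, `source` columns.
#' @export
synthetic_lr_table <- function(genes, n_pairs = 30, seed = 1L) {
  check_number(n_pairs, "n_pairs", 1, integer = TRUE)
  if (length(genes) < 2 * n_pairs)
    stopf("need at least %d genes for %d disjoint LR pairs", 2 * n_pairs,
          n_pairs)
  withr::with_seed(stage_seed(seed, "synthetic_lr"), {
    pick <- sample(genes, 2 * n_pairs)
    data.frame(ligand = pick[seq_len(n_pairs)],
               receptor = pick[n_pairs + seq_len(n_pairs)],
               source = "synthetic", stringsAsFactors = FALSE)
  })
}
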