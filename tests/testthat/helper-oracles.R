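# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (loops, enumeration) and never call the
# code paths they check.

# Benjamini-Hochberg by the step-up definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration:
# sum of probabilities of tables (same margins) no more likely than the
# observed one, with the same relative tolerance R's fisher.test uses.
fisher_oracle <- function(m) {
  stopifnot(all(dim(m) == c(2L, 2L)))
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  d <- dhyper(support, c1, n - c1, r1)
  d0 <- dhyper(m[1, 1], c1, n - c1, r1)
  min(sum(d[d <= d0 * (1 + 1e-7)]), 1)
}

# small cohort configuration used where the full default is overkill
small_config <- function(...) {
  args <- list(...)
  defaults <- list(cells_per_donor = 120, n_genes = 200, n_de_genes = 20,
                   n_signature_genes = 10, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# complete usage matrix with named dims for direct clone_fit() input
random_usage <- function(n_events, n_cells, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_events * n_cells), n_events,
                dimnames = list(sprintf("ev%02d", seq_len(n_events)),
                                sprintf("c%03d", seq_len(n_cells))))
    m
  })
}

# donor label fixtures for a two-donor design
two_donor_labels <- function(n_wt, n_mut) {
  cells <- c(sprintf("w%03d", seq_len(n_wt)), sprintf("m%03d", seq_len(n_mut)))
  list(cells = cells,
       cell_donor = setNames(rep(c("DW", "DM"), c(n_wt, n_mut)), cells),
       donor_labels = c(DW = "WT", DM = "MUT"))
}
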