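test_that("log-normalization matches the formula entrywise", {
  withr::with_seed(19, {
    expr <- matrix(rpois(200, 2), 20,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  })
  expr[, 1] <- c(5, rep(0, 19))     # keep libraries positive
  norm <- as.matrix(lognormalize(expr))
  lib <- colSums(expr)
  for (j in seq_len(ncol(expr)))
    expect_equal(norm[, j], log1p(expr[, j] / lib[j] * 1e4),
                 tolerance = 1e-12)
  expect_equal(norm[expr == 0], rep(0, sum(expr == 0)))

  # a uniform cell normalizes to a single value
  u <- matrix(3, 5, 1, dimnames = list(paste0("g", 1:5), "c1"))
  expect_equal(length(unique(as.matrix(lognormalize(u)))), 1L)

  bad <- expr; bad[, 2] <- 0
  expect_error(lognormalize(bad), "zero library")
})

test_that("module scores center on zero for background signatures", {
  withr::with_seed(29, {
    expr <- matrix(rnbinom(500 * 80, mu = exp(rnorm(500, 1, 1)), size = 5),
                   500, dimnames = list(sprintf("g%03d", 1:500),
                                        sprintf("c%03d", 1:80)))
  })
  norm <- lognormalize(expr)
  sig <- withr::with_seed(1, sample(rownames(expr), 15))
  sc <- module_score(norm, sig, seed = 5)
  se <- sd(sc$score) / sqrt(length(sc$score))
  expect_lt(abs(mean(sc$score)), 3 * se)

  # reproducibility and seed stability
  sc2 <- module_score(norm, sig, seed = 5)
  expect_identical(sc$score, sc2$score)
  sc3 <- module_score(norm, sig, seed = 99)
  expect_false(identical(sc$score, sc3$score))
  expect_gt(cor(sc$score, sc3$score), 0.9)

  # invariance to gene and cell reordering
  perm <- withr::with_seed(2, list(g = sample(nrow(norm)),
                                   c = sample(ncol(norm))))
  scp <- module_score(as.matrix(norm)[perm$g, perm$c], sig, seed = 5)
  expect_equal(scp$score[names(sc$score)], sc$score)

  expect_warning(module_score(norm, c(sig, "NOT_A_GENE"), seed = 5),
                 "absent")
  expect_error(suppressWarnings(module_score(norm, c("NOPE1", "NOPE2"),
                                             seed = 5)),
               "no signature gene")
})

test_that("an additive shift on signature genes moves the score by delta", {
  # heterogeneous per-gene baselines: the expression bins must span a
  # range wide relative to the shift, as in real data, or every shifted
  # gene migrates into the same top bin and contaminates its own controls
  withr::with_seed(37, {
    base <- runif(400, 0.2, 3)
    norm <- matrix(rep(base, 100) + abs(rnorm(400 * 100, 0, 0.3)), 400,
                   dimnames = list(sprintf("g%03d", 1:400),
                                   sprintf("c%03d", 1:100)))
    sig <- rownames(norm)[sample(400, 12)]
  })
  subset <- colnames(norm)[1:50]
  delta <- 1
  shifted <- norm
  shifted[sig, subset] <- shifted[sig, subset] + delta
  sc <- module_score(shifted, sig, seed = 3)
  diff <- mean(sc$score[subset]) - mean(sc$score[setdiff(colnames(norm),
                                                         subset)])
  # ~6% of control draws are a shifted gene drawn from its own bin, so
  # recovery is slightly attenuated; 0.15*delta covers that plus noise
  expect_lt(abs(diff - delta), 0.15 * delta)
})

test_that("module scores equal a loop recomputation with the drawn controls", {
  withr::with_seed(41, {
    norm <- matrix(abs(rnorm(60 * 12)), 60,
                   dimnames = list(paste0("g", 1:60), paste0("c", 1:12)))
  })
  sc <- module_score(norm, c("g5", "g17", "g33"), n_bins = 6, n_ctrl = 20,
                     seed = 11)
  for (j in colnames(norm)) {
    manual <- mean(norm[sc$signature_genes, j]) -
      mean(norm[sc$control_genes, j])
    expect_equal(unname(sc$score[j]), manual, tolerance = 1e-12)
  }
  # controls come from the same expression bin as their signature gene
  avg <- rowMeans(norm)
  r <- rank(avg, ties.method = "first")
  bin <- ceiling(r / (length(r) / 6))
  names(bin) <- rownames(norm)
  ctrl_bins <- bin[sc$control_genes]
  expect_true(all(ctrl_bins %in% bin[sc$signature_genes]))
})

test_that("per-condition correlation matches the analytic t transform", {
  withr::with_seed(43, {
    a <- rnorm(1000)
    b_indep <- rnorm(1000)
    cond <- rep(c("Control", "MDS"), each = 500)
  })
  # perfect correlation
  res <- pcc_by_condition(a, a, cond)
  expect_equal(res$r, c(1, 1))
  # independence: r within 3/sqrt(n)
  res0 <- pcc_by_condition(a, b_indep, cond)
  expect_true(all(abs(res0$r) < 3 / sqrt(res0$n)))
  # formula oracle: covariance-based r and the t transform
  for (k in seq_len(nrow(res0))) {
    i <- cond == res0$condition[k]
    x <- a[i]; y <- b_indep[i]; n <- sum(i)
    r_manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res0$r[k], r_manual, tolerance = 1e-12)
    t_manual <- r_manual * sqrt(n - 2) / sqrt(1 - r_manual^2)
    expect_equal(res0$t[k], t_manual, tolerance = 1e-12)
    expect_equal(res0$p[k], 2 * pt(-abs(t_manual), n - 2),
                 tolerance = 1e-12)
    # cross-check against stats::cor.test
    ct <- cor.test(x, y)
    expect_equal(res0$p[k], ct$p.value, tolerance = 1e-9)
  }
  # zero variance is reported as NA, not an error
  resz <- pcc_by_condition(rep(1, 1000), b_indep, cond)
  expect_true(all(is.na(resz$r)))
  expect_error(pcc_by_condition(a[1:2], a[1:2], cond[1:2]), "fewer than 3")
})

test_that("coupled and anti-coupled programs give opposite-sign correlations", {
  co <- simulate_cohort(small_config(cells_per_donor = 150,
                                     conditions = rep(c("CHIP", "MDS"),
                                                      c(3, 4))))
  norm <- as.matrix(lognormalize(co$expression))
  stroma <- co$cells[co$cells$cell_type %in% c("iMSC", "AdipoCAR"), ]
  genes <- rownames(norm)
  inflam <- genes[1:15]; support <- genes[16:30]
  chip_cells <- stroma$cell_id[stroma$condition == "CHIP"]
  mds_cells <- stroma$cell_id[stroma$condition == "MDS"]
  norm <- simulate_signature_coupling(norm, inflam, support, chip_cells,
                                      coupling = -1, seed = 1)
  norm <- simulate_signature_coupling(norm, inflam, support, mds_cells,
                                      coupling = 1, seed = 2)
  s_inf <- module_score(norm[, stroma$cell_id], inflam, seed = 3)
  s_sup <- module_score(norm[, stroma$cell_id], support, seed = 4)
  res <- pcc_by_condition(s_inf, s_sup, stroma$condition)
  expect_lt(res$r[res$condition == "CHIP"], 0)
  expect_gt(res$r[res$condition == "MDS"], 0)
})
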