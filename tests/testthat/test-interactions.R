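toy_world <- function() {
  genes <- c("L1", "L2", "R1", "R2", "X")
  cells <- c("s1", "s2", "r1", "r2", "r3")
  norm <- matrix(0, 5, 5, dimnames = list(genes, cells))
  norm["L1", c("s1", "s2")] <- c(2, 0)
  norm["L2", c("s1", "s2")] <- c(3, 1)
  norm["R1", c("r1", "r2", "r3")] <- c(4, 1, 0)
  norm["R2", c("r1", "r2", "r3")] <- c(5, 0, 2)
  meta <- data.frame(cell_id = cells, donor = "D1",
                     condition = "Control",
                     cell_type = c("MSC", "MSC", "T", "T", "T"))
  lr <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  list(norm = norm, meta = meta, lr = lr)
}

test_that("pair scores are ligand x receptor products", {
  w <- toy_world()
  px <- lr_scores(w$norm, w$lr, w$meta, senders = c("s1", "s2"),
                  receivers = c("r1", "r2", "r3"))
  expect_equal(nrow(px$pairs), 6)
  s1r1 <- px$scores[px$pairs$sender == "s1" & px$pairs$receiver == "r1", ]
  expect_equal(unname(s1r1), c(2 * 4, 3 * 5))   # hand values (2,3)x(4,5)
  # zero ligand in the sender zeroes that entry
  s2 <- px$scores[px$pairs$sender == "s2", , drop = FALSE]
  expect_true(all(s2[, "L1_R1"] == 0))
  # nested-loop oracle over every pair and LR entry
  for (k in seq_len(nrow(px$pairs))) {
    for (e in seq_len(nrow(px$lr))) {
      manual <- w$norm[px$lr$ligand[e], px$pairs$sender[k]] *
        w$norm[px$lr$receptor[e], px$pairs$receiver[k]]
      expect_equal(px$scores[k, e], manual, tolerance = 1e-12)
    }
  }
  # homogeneity: scaling ligand expression scales the scores linearly
  norm2 <- w$norm; norm2[c("L1", "L2"), ] <- norm2[c("L1", "L2"), ] * 3
  px3 <- lr_scores(norm2, w$lr, w$meta, senders = c("s1", "s2"),
                   receivers = c("r1", "r2", "r3"))
  expect_equal(px3$scores, px$scores * 3, tolerance = 1e-12)

  expect_warning(
    lr_scores(w$norm, rbind(w$lr, data.frame(ligand = "NOPE",
                                             receptor = "R1")),
              w$meta, c("s1", "s2"), c("r1", "r2")), "absent")
  expect_error(
    suppressWarnings(lr_scores(w$norm,
                               data.frame(ligand = "NO", receptor = "PE"),
                               w$meta, "s1", "r1")),
    "no ligand-receptor pair")
})

test_that("cells are paired within donors and never with themselves", {
  w <- toy_world()
  w$meta$donor <- c("D1", "D2", "D1", "D2", "D2")
  px <- lr_scores(w$norm, w$lr, w$meta, senders = c("s1", "s2"),
                  receivers = c("r1", "r2", "r3"))
  expect_true(all(w$meta$donor[match(px$pairs$sender, w$meta$cell_id)] ==
                    w$meta$donor[match(px$pairs$receiver, w$meta$cell_id)]))
  expect_equal(nrow(px$pairs), 1 + 2)  # D1: s1x{r1}; D2: s2x{r2,r3}
  # overlapping sets: self-pairs excluded
  px2 <- lr_scores(w$norm, w$lr, w$meta, senders = c("s1", "r1"),
                   receivers = c("s1", "r1"))
  expect_true(all(px2$pairs$sender != px2$pairs$receiver))

  # the pair cap subsamples deterministically
  w$meta$donor <- "D1"
  pc <- lr_scores(w$norm, w$lr, w$meta, senders = c("s1", "s2"),
                  receivers = c("r1", "r2", "r3"), max_pairs = 4, seed = 9)
  pc2 <- lr_scores(w$norm, w$lr, w$meta, senders = c("s1", "s2"),
                   receivers = c("r1", "r2", "r3"), max_pairs = 4, seed = 9)
  expect_equal(nrow(pc$pairs), 4)
  expect_identical(pc$pairs, pc2$pairs)
})

test_that("the minimum-interaction filter keeps pairs at the boundary", {
  px <- structure(list(
    pairs = data.frame(sender = paste0("s", 1:4), receiver = "r",
                       donor = "D1", n_nonzero = c(3L, 4L, 5L, 6L)),
    scores = matrix(0, 4, 6), lr = data.frame(ligand = 1:6, receptor = 1:6)),
    class = "pair_interactions")
  kept <- filter_min_interactions(px)
  expect_equal(kept$pairs$n_nonzero, c(5L, 6L))
  expect_equal(min(kept$pairs$n_nonzero), 5L)
  expect_equal(nrow(filter_min_interactions(px, 0)$pairs), 4)

  # retained set equals a direct count over score vectors
  w <- toy_world()
  pw <- lr_scores(w$norm, w$lr, w$meta, senders = c("s1", "s2"),
                  receivers = c("r1", "r2", "r3"))
  manual_nz <- apply(pw$scores, 1, function(v) sum(v > 0))
  expect_equal(pw$pairs$n_nonzero, unname(as.integer(manual_nz)))
  k1 <- filter_min_interactions(pw, 2)
  expect_equal(nrow(k1$pairs), sum(manual_nz >= 2))
})

test_that("summaries normalize by possible pairs per donor", {
  w <- toy_world()
  px <- lr_scores(w$norm, w$lr, w$meta, senders = c("s1", "s2"),
                  receivers = c("r1", "r2", "r3"))
  # keep everything: exhaustive pairing means normalized value = 1
  s_all <- summarize_interactions(filter_min_interactions(px, 0), w$meta,
                                  c("s1", "s2"), c("r1", "r2", "r3"))
  expect_equal(s_all$by_donor$retained, 6)
  expect_equal(s_all$by_donor$possible, 6)
  expect_equal(s_all$by_donor$normalized, 1)

  # hand tally with the >=1 filter: s2-r2 (0 nonzero) drops
  s1 <- summarize_interactions(filter_min_interactions(px, 1), w$meta,
                               c("s1", "s2"), c("r1", "r2", "r3"))
  expect_equal(s1$by_donor$retained, 5)
  expect_equal(s1$by_donor$normalized, 5 / 6)

  # brute-force grouping oracle on random assignments
  withr::with_seed(61, {
    genes <- paste0("g", 1:6)
    cells <- paste0("c", 1:30)
    norm <- matrix(rexp(180) * rbinom(180, 1, 0.5), 6,
                   dimnames = list(genes, cells))
    meta <- data.frame(cell_id = cells,
                       donor = sample(c("D1", "D2"), 30, replace = TRUE),
                       condition = "MDS",
                       cell_type = sample(c("MSC", "T"), 30, replace = TRUE))
  })
  lr <- data.frame(ligand = c("g1", "g2", "g3"),
                   receptor = c("g4", "g5", "g6"))
  senders <- cells[1:15]; receivers <- cells[16:30]
  px2 <- lr_scores(norm, lr, meta, senders, receivers)
  kept <- filter_min_interactions(px2, 2)
  sm <- summarize_interactions(kept, meta, senders, receivers)
  for (k in seq_len(nrow(sm$by_donor))) {
    row <- sm$by_donor[k, ]
    manual_ret <- sum(
      meta$cell_type[match(kept$pairs$sender, meta$cell_id)] == row$sender_type &
      meta$cell_type[match(kept$pairs$receiver, meta$cell_id)] == row$receiver_type &
      kept$pairs$donor == row$donor)
    s_set <- intersect(senders,
                       meta$cell_id[meta$donor == row$donor &
                                      meta$cell_type == row$sender_type])
    r_set <- intersect(receivers,
                       meta$cell_id[meta$donor == row$donor &
                                      meta$cell_type == row$receiver_type])
    manual_pos <- length(s_set) * length(r_set) -
      length(intersect(s_set, r_set))
    expect_equal(row$retained, manual_ret)
    expect_equal(row$possible, manual_pos)
    if (manual_pos > 0)
      expect_equal(row$normalized, manual_ret / manual_pos)
    else
      expect_true(is.na(row$normalized))
  }
  # condition aggregation is a ratio of sums over donors
  agg <- sm$by_condition
  for (k in seq_len(nrow(agg))) {
    sub <- sm$by_donor[sm$by_donor$sender_type == agg$sender_type[k] &
                         sm$by_donor$receiver_type == agg$receiver_type[k], ]
    expect_equal(agg$retained[k], sum(sub$retained))
    expect_equal(agg$possible[k], sum(sub$possible))
  }
})

test_that("the shift test reduces to Fisher on retained/possible counts", {
  bc <- data.frame(
    condition = c("MDS", "CHIP"), sender_type = "iMSC",
    receiver_type = "HSPC", retained = c(12, 4), possible = c(20, 20))
  sm <- structure(list(by_condition = bc, by_donor = bc),
                  class = "interaction_summary")
  res <- interaction_shift_test(sm, "iMSC", "HSPC", "MDS", "CHIP")
  m <- matrix(c(12, 8, 4, 16), 2, byrow = TRUE)
  expect_equal(res$p, fisher_oracle(m), tolerance = 1e-12)
  expect_equal(res$odds_ratio, (12 * 16) / (8 * 4))

  # equal retained fractions give OR = 1
  bc2 <- transform(bc, retained = c(5, 5))
  sm2 <- structure(list(by_condition = bc2, by_donor = bc2),
                   class = "interaction_summary")
  expect_equal(interaction_shift_test(sm2, "iMSC", "HSPC", "MDS",
                                      "CHIP")$odds_ratio, 1)
  expect_error(interaction_shift_test(sm, "iMSC", "HSPC", "MDS", "Control"),
               "no summary row")
})

test_that("doubled ligand detection rates shift the odds ratio upward", {
  hits <- sapply(1:10, function(s) {
    withr::with_seed(70 + s, {
      genes <- c(paste0("L", 1:8), paste0("R", 1:8), paste0("X", 1:4))
      donors <- paste0("D", 1:6)
      cond_of <- setNames(rep(c("Control", "MDS"), each = 3), donors)
      cells <- character(0); meta_rows <- list()
      counts <- NULL
      for (d in donors) {
        ids <- sprintf("%s_c%02d", d, 1:80)
        ct <- rep(c("MSC", "T"), each = 40)
        lam_l <- if (cond_of[[d]] == "MDS") 1.0 else 0.5
        m <- rbind(
          matrix(rpois(8 * 80, lam_l), 8),   # ligands (senders only matter)
          matrix(rpois(8 * 80, 2), 8),       # receptors
          matrix(rpois(4 * 80, 5), 4))       # fillers keep libraries sane
        dimnames(m) <- list(genes, ids)
        counts <- cbind(counts, m)
        meta_rows[[d]] <- data.frame(cell_id = ids, donor = d,
                                     condition = cond_of[[d]],
                                     cell_type = ct)
      }
      meta <- do.call(rbind, meta_rows)
      norm <- lognormalize(counts)
      senders <- meta$cell_id[meta$cell_type == "MSC"]
      receivers <- meta$cell_id[meta$cell_type == "T"]
      lr <- data.frame(ligand = paste0("L", 1:8),
                       receptor = paste0("R", 1:8))
      px <- lr_scores(norm, lr, meta, senders, receivers)
      sm <- summarize_interactions(filter_min_interactions(px, 5), meta,
                                   senders, receivers)
      res <- interaction_shift_test(sm, "MSC", "T", "MDS", "Control")
      res$odds_ratio > 1 && res$p < 0.05
    })
  })
  expect_gte(mean(hits), 0.9)
})
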