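# Ligand-receptor interaction counting between sender and receiver cell
# types. The core score of a sender-receiver cell pair for one
# ligand-receptor entry is the product of ligand expression in the sender
# and receptor expression in the receiver (normalized values). Cell pairs
# are formed within donors; pairs with fewer than 5 nonzero entries are
# discarded; retained-pair counts are normalized by the number of
# possible sender x receiver cell pairs per donor.

#' Ligand x receptor scores for sender-receiver cell pairs
#'
#' Forms sender-receiver cell pairs within each donor (exhaustively, or a
#' seeded uniform subsample when the number of pairs exceeds `max_pairs`)
#' and scores every ligand-receptor entry as
#' `norm[ligand, sender] * norm[receptor, receiver]`. A cell present in
#' both sets is never paired with itself. Ligand-receptor entries whose
#' genes are absent from the matrix are dropped with a warning.
#'
#' @param norm Gene x cell normalized expression matrix.
#' @param lr_table Data frame with `ligand` and `receptor` columns.
#' @param meta Cell metadata with `cell_id`, `donor` and `cell_type`.
#' @param senders,receivers Cell ids of the sender and receiver sets.
#' @param max_pairs Cap on cell pairs per donor (default `Inf`).
#' @param seed Seed for the subsample when the cap binds.
#' @return A list of class `pair_interactions`: `pairs` (data frame:
#'   `sender`, `receiver`, `donor`, `n_nonzero`), `scores` (pairs x LR
#'   matrix), `lr` (the retained LR table).
#' @export
lr_scores <- function(norm, lr_table, meta, senders, receivers,
                      max_pairs = Inf, seed = 1L) {
  stopifnot(all(c("ligand", "receptor") %in% names(lr_table)))
  norm <- as.matrix(norm)
  present <- lr_table$ligand %in% rownames(norm) &
    lr_table$receptor %in% rownames(norm)
  if (any(!present))
    warning(sprintf("dropping %d LR pair(s) with gene(s) absent from the matrix",
                    sum(!present)), call. = FALSE)
  lr <- lr_table[present, , drop = FALSE]
  if (!nrow(lr)) stopf("no ligand-receptor pair overlaps the matrix")
  donor_of <- setNames(meta$donor, meta$cell_id)
  if (anyNA(donor_of[c(senders, receivers)]))
    stopf("sender/receiver cells missing from metadata")

  pair_list <- list()
  for (d in unique(donor_of[senders])) {
    s <- senders[donor_of[senders] == d]
    r <- receivers[donor_of[receivers] == d]
    if (!length(s) || !length(r)) next
    pairs <- expand.grid(sender = s, receiver = r,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$sender != pairs$receiver, , drop = FALSE]
    if (nrow(pairs) > max_pairs) {
      idx <- withr::with_seed(stage_seed(seed, paste0("lr_pairs_", d)),
                              sample.int(nrow(pairs), max_pairs))
      pairs <- pairs[sort(idx), , drop = FALSE]
    }
    if (nrow(pairs)) {
      pairs$donor <- d
      pair_list[[d]] <- pairs
    }
  }
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs) || !nrow(pairs))
    stopf("no sender-receiver cell pair could be formed within donors")
  rownames(pairs) <- NULL

  scores <- norm[lr$ligand, pairs$sender, drop = FALSE] *
    norm[lr$receptor, pairs$receiver, drop = FALSE]
  scores <- t(scores)
  colnames(scores) <- paste(lr$ligand, lr$receptor, sep = "_")
  pairs$n_nonzero <- as.integer(rowSums(scores > 0))
  structure(list(pairs = pairs, scores = scores, lr = lr),
            class = "pair_interactions")
}

#' @export
print.pair_interactions <- function(x, ...) {
  cat(sprintf("Cell-pair interactions: %d pairs x %d LR entries; median nonzero/pair: %s\n",
              nrow(x$pairs), nrow(x$lr), stats::median(x$pairs$n_nonzero)))
  invisible(x)
}

#' Discard cell pairs with too few inferred interactions
#'
#' Keeps pairs whose count of strictly positive ligand-receptor scores is
#' at least `min_n` (default 5).
#'
#' @param pi A [lr_scores()] result.
#' @param min_n Minimum nonzero LR entries per pair.
#' @return A filtered `pair_interactions` object.
#' @export
filter_min_interactions <- function(pi, min_n = 5) {
  stopifnot(inherits(pi, "pair_interactions"))
  check_number(min_n, "min_n", 0, integer = TRUE)
  keep <- pi$pairs$n_nonzero >= min_n
  structure(list(pairs = pi$pairs[keep, , drop = FALSE],
                 scores = pi$scores[keep, , drop = FALSE],
                 lr = pi$lr),
            class = "pair_interactions")
}

#' Summarize retained interactions by cell types and condition
#'
#' Per donor and (sender type, receiver type): the number of retained
#' cell pairs and that count divided by the number of possible pairs —
#' the product of the donor's sender-type and receiver-type cell counts
#' (minus the self-pairs excluded at scoring). Condition-level values
#' pool donors as a ratio of sums. A zero possible-pair denominator
#' yields `NA`.
#'
#' @param pi Retained [lr_scores()] pairs (after
#'   [filter_min_interactions()]).
#' @param meta Cell metadata with `cell_id`, `donor`, `condition`,
#'   `cell_type`.
#' @param senders,receivers The full sender / receiver cell-id sets that
#'   were offered for pairing (they define the possible-pair
#'   denominators).
#' @return A list of class `interaction_summary`: `by_donor` and
#'   `by_condition` data frames with `retained`, `possible`,
#'   `normalized`.
#' @export
summarize_interactions <- function(pi, meta, senders, receivers) {
  stopifnot(inherits(pi, "pair_interactions"))
  info <- meta[match(c(senders, receivers), meta$cell_id), , drop = FALSE]
  if (anyNA(info$cell_id)) stopf("cells missing from metadata")
  type_of <- setNames(meta$cell_type, meta$cell_id)
  donor_of <- setNames(meta$donor, meta$cell_id)
  cond_of_donor <- unique(meta[c("donor", "condition")])

  s_meta <- data.frame(cell = senders, donor = donor_of[senders],
                       type = type_of[senders], stringsAsFactors = FALSE)
  r_meta <- data.frame(cell = receivers, donor = donor_of[receivers],
                       type = type_of[receivers], stringsAsFactors = FALSE)

  grid <- expand.grid(donor = unique(c(s_meta$donor, r_meta$donor)),
                      sender_type = unique(s_meta$type),
                      receiver_type = unique(r_meta$type),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- pi$pairs
  p$sender_type <- type_of[p$sender]
  p$receiver_type <- type_of[p$receiver]

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$donor[i]; st <- grid$sender_type[i]; rt <- grid$receiver_type[i]
    ns <- sum(s_meta$donor == d & s_meta$type == st)
    nr <- sum(r_meta$donor == d & r_meta$type == rt)
    s_cells <- s_meta$cell[s_meta$donor == d & s_meta$type == st]
    r_cells <- r_meta$cell[r_meta$donor == d & r_meta$type == rt]
    possible <- ns * nr - length(intersect(s_cells, r_cells))
    retained <- sum(p$donor == d & p$sender_type == st &
                      p$receiver_type == rt)
    data.frame(donor = d, sender_type = st, receiver_type = rt,
               retained = retained, possible = possible,
               normalized = if (possible > 0) retained / possible
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  by_donor <- do.call(rbind, rows)
  by_donor$condition <-
    cond_of_donor$condition[match(by_donor$donor, cond_of_donor$donor)]

  agg <- stats::aggregate(cbind(retained, possible) ~
                            condition + sender_type + receiver_type,
                          data = by_donor, FUN = sum)
  agg$normalized <- ifelse(agg$possible > 0, agg$retained / agg$possible,
                           NA_real_)
  structure(list(by_donor = by_donor, by_condition = agg),
            class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat("Interaction summary (condition level):\n")
  print.data.frame(x$by_condition, digits = 3)
  invisible(x)
}

#' Fisher test for a condition shift in sender-receiver interaction usage
#'
#' Tests whether a sender-receiver cell-type pair is used more frequently
#' in condition A than B: a two-sided Fisher exact test on the 2 x 2
#' table `[retained, possible - retained]` x `[A, B]` of pooled
#' condition-level counts. The reported odds ratio is the sample odds
#' ratio.
#'
#' @param summary An [summarize_interactions()] result.
#' @param sender_type,receiver_type The cell-type pair tested.
#' @param condition_a,condition_b The conditions compared (OR > 1 means
#'   more frequent in `condition_a`).
#' @return A one-row data frame: `sender_type`, `receiver_type`,
#'   `odds_ratio`, `p` plus the four margins.
#' @export
interaction_shift_test <- function(summary, sender_type, receiver_type,
                                   condition_a, condition_b) {
  stopifnot(inherits(summary, "interaction_summary"))
  bc <- summary$by_condition
  pick <- function(cond) {
    row <- bc[bc$condition == cond & bc$sender_type == sender_type &
                bc$receiver_type == receiver_type, , drop = FALSE]
    if (nrow(row) != 1L)
      stopf("no summary row for %s -> %s in condition '%s'",
            sender_type, receiver_type, cond)
    row
  }
  a <- pick(condition_a); b <- pick(condition_b)
  m <- matrix(c(a$retained, a$possible - a$retained,
                b$retained, b$possible - b$retained),
              nrow = 2, byrow = TRUE)
  if (any(m < 0) || any(rowSums(m) == 0))
    stopf("degenerate margins: retained/possible counts are inconsistent")
  p <- fisher.test(m, alternative = "two.sided")$p.value
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  data.frame(sender_type = sender_type, receiver_type = receiver_type,
             retained_a = m[1, 1], possible_a = a$possible,
             retained_b = m[2, 1], possible_b = b$possible,
             odds_ratio = or, p = p, stringsAsFactors = FALSE)
}
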