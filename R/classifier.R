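# Weakly supervised clone classifier. Each cell inherits its donor's
# SF3B1 mutation status as a (noisy) label: cells of mutant donors may
# truly be wild-type because the clone fraction is below 1. An
# L2-penalized logistic regression on per-event cryptic-usage fractions
# separates the clones anyway, and the decision threshold is calibrated
# on wild-type-donor cells so that the per-cell false-positive rate does
# not exceed a stated target (default 10%).

#' Fit the clone classifier on cryptic-usage features
#'
#' Fits an L2-penalized logistic regression (penalty `lambda/2 * ||w||^2`,
#' intercept unpenalized, exact Newton/IRLS solver) on mean-imputed
#' cryptic-usage fractions, using each cell's donor-level mutation status
#' as a weak label. Wild-type-donor classifiable cells are split in half
#' (seeded): one half joins the mutant-donor cells in the fit, the other
#' is reserved for threshold calibration and never enters the fit. The
#' threshold `tau` is the `(1 - alpha)` empirical quantile of calibration
#' scores, so at most a fraction `alpha` of calibration cells scores above
#' it.
#'
#' @param um A [splice_usage()] result (or a complete numeric matrix, in
#'   which case every cell counts as fully covered).
#' @param donor_labels Named character vector mapping donor to `"MUT"` or
#'   `"WT"` sample status.
#' @param cell_donor Named character vector mapping cell id to donor.
#' @param lambda Ridge penalty strength (>= 0, default 1).
#' @param alpha Target per-cell false-positive rate in (0, 1); default 0.10.
#' @param min_events Coverage filter: cells with fewer covered events are
#'   excluded from fitting/calibration and always called `unclassified`.
#' @param calibration_frac Fraction of wild-type-donor cells reserved for
#'   calibration (default 0.5).
#' @param standardize Standardize features to unit variance before
#'   fitting (default `FALSE`: raw fractions).
#' @param seed Integer seed for the calibration split.
#' @param max_iter,tol Newton iteration cap and convergence tolerance on
#'   the max absolute coefficient update.
#' @return An object of class `clone_model` with components `weights`
#'   (named per-event), `intercept`, `tau`, `alpha`, `lambda`,
#'   `min_events`, `event_means` (imputation values reused at prediction
#'   time), `converged`, `iterations`, `cal_cells`, `fit_cells`, and
#'   `heldout_wt_cells` (wild-type-donor cells not used for calibration).
#' @seealso [predict.clone_model()], [calibrate_threshold()],
#'   [evaluate_calls()]
#' @export
clone_fit <- function(um, donor_labels, cell_donor, lambda = 1,
                      alpha = 0.10, min_events = 2, calibration_frac = 0.5,
                      standardize = FALSE, seed = 1L, max_iter = 100,
                      tol = 1e-8) {
  check_number(lambda, "lambda", 0)
  check_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  check_number(min_events, "min_events", 1, integer = TRUE)
  check_number(calibration_frac, "calibration_frac", 0, 1)
  check_number(seed, "seed", integer = TRUE)

  if (inherits(um, "usage_matrix")) {
    x_all <- impute_usage(um)
    covered_events <- um$covered_events
  } else {
    x_all <- as.matrix(um)
    if (anyNA(x_all))
      stopf("usage matrix passed to clone_fit() must be complete; use splice_usage() + impute_usage() or pass the usage_matrix itself")
    covered_events <- setNames(rep(nrow(x_all), ncol(x_all)),
                               colnames(x_all))
    attr(x_all, "event_means") <- rowMeans(x_all)
  }
  event_means <- attr(x_all, "event_means")

  cells <- colnames(x_all)
  if (is.null(cells)) stopf("usage matrix must have cell column names")
  if (is.null(names(cell_donor))) stopf("cell_donor must be named by cell id")
  if (anyNA(cell_donor[cells]))
    stopf("cell_donor is missing entries for some cells")
  lab <- donor_labels[cell_donor[cells]]
  if (anyNA(lab)) stopf("donor_labels is missing entries for some donors")
  if (!all(lab %in% c("MUT", "WT")))
    stopf("donor labels must be 'MUT' or 'WT'")
  if (length(unique(lab)) < 2L)
    stopf("both donor label classes (MUT and WT) must be present")

  keep <- cells[covered_events[cells] >= min_events]
  if (!length(keep)) stopf("no cell passes the coverage filter")
  wt_cells <- keep[lab[match(keep, cells)] == "WT"]
  mut_cells <- setdiff(keep, wt_cells)
  n_cal <- floor(length(wt_cells) * calibration_frac)
  if (n_cal < 20L)
    stopf("calibration requires >= 20 wild-type-donor cells, got %d", n_cal)
  cal_cells <- withr::with_seed(stage_seed(seed, "calibration_split"),
                                sort(sample(wt_cells, n_cal)))
  fit_cells <- c(setdiff(wt_cells, cal_cells), mut_cells)

  x_fit <- t(x_all[, fit_cells, drop = FALSE])
  y_fit <- as.numeric(lab[match(fit_cells, cells)] == "MUT")
  if (length(unique(y_fit)) < 2L)
    stopf("both label classes must survive the coverage filter")

  centers <- rep(0, ncol(x_fit))
  scales <- rep(1, ncol(x_fit))
  if (standardize) {
    centers <- colMeans(x_fit)
    scales <- apply(x_fit, 2, sd)
    scales[scales < 1e-12] <- 1
    x_fit <- scale(x_fit, centers, scales)
  }

  fit <- ridge_logistic_irls(x_fit, y_fit, lambda, max_iter, tol)
  if (!fit$converged)
    warning(sprintf("IRLS did not converge in %d iterations (last step %.3g)",
                    max_iter, fit$last_step), call. = FALSE)

  model <- structure(list(
    weights = setNames(fit$beta[-1L], rownames(x_all)),
    intercept = fit$beta[1L],
    lambda = lambda, alpha = alpha, tau = NA_real_,
    min_events = min_events, standardize = standardize,
    centers = setNames(centers, rownames(x_all)),
    scales = setNames(scales, rownames(x_all)),
    event_means = event_means,
    converged = fit$converged, iterations = fit$iterations,
    deviance = fit$deviance,
    n_fit = length(fit_cells), n_events = nrow(x_all),
    fit_cells = fit_cells, cal_cells = cal_cells,
    heldout_wt_cells = setdiff(wt_cells, cal_cells),
    seed = as.integer(seed), call = match.call()
  ), class = "clone_model")

  cal_scores <- clone_scores(model, x_all[, cal_cells, drop = FALSE])
  model$tau <- calibrate_threshold(cal_scores, alpha)
  model
}

# Exact Newton/IRLS for the ridge-penalized logistic log-likelihood:
# minimize -loglik(beta) + lambda/2 * ||w||^2, intercept unpenalized.
ridge_logistic_irls <- function(x, y, lambda, max_iter = 100, tol = 1e-8) {
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  step <- Inf
  it <- 0L
  while (it < max_iter && step > tol) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + diag(pen, p)
    g <- drop(crossprod(X, y - mu)) - pen * beta
    delta <- solve(H, g)
    beta <- beta + delta
    step <- max(abs(delta))
  }
  eta <- drop(X %*% beta)
  dev <- -2 * sum(y * eta - log1p(exp(eta)))
  list(beta = beta, converged = step <= tol, iterations = it,
       last_step = step, deviance = dev)
}

# scores on an imputed (complete) event x cell matrix
clone_scores <- function(model, x) {
  ev <- names(model$weights)
  if (!all(ev %in% rownames(x)))
    stopf("usage matrix lacks events the model was trained on: %s",
          paste(setdiff(ev, rownames(x)), collapse = ", "))
  z <- (x[ev, , drop = FALSE] - model$centers[ev]) / model$scales[ev]
  plogis(drop(crossprod(z, model$weights)) + model$intercept)
}

#' Calibrate the decision threshold to a target false-positive rate
#'
#' Returns the `(1 - alpha)` empirical quantile of the calibration scores,
#' ties resolved upward: with the strict `score > tau` call rule, at most
#' a fraction `alpha` of the calibration cells is called mutant.
#'
#' @param scores Classifier scores of wild-type-donor calibration cells.
#' @param alpha Target false-positive rate in (0, 1).
#' @return The threshold `tau`.
#' @export
calibrate_threshold <- function(scores, alpha = 0.10) {
  check_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  if (n < 20L)
    stopf("calibration requires >= 20 scores, got %d", n)
  sort(scores)[ceiling((1 - alpha) * n)]
}

#' Per-cell genotype calls
#'
#' Scores every cell through the logistic link on mean-imputed usage
#' (missing entries filled with the event means stored at training time)
#' and calls `MUT` when the score strictly exceeds the calibrated
#' threshold. Cells failing the coverage filter are scored but always
#' reported `unclassified`.
#'
#' @param object A fitted `clone_model`.
#' @param um A [splice_usage()] result (or complete matrix) covering the
#'   model's events.
#' @param min_events Coverage filter; defaults to the model's setting.
#' @param ... Unused.
#' @return A data frame with one row per input cell: `cell_id`, `score`,
#'   `call` (`MUT`/`WT`/`unclassified`), `covered_events`.
#' @export
predict.clone_model <- function(object, um, min_events = object$min_events,
                                ...) {
  check_number(min_events, "min_events", 1, integer = TRUE)
  if (inherits(um, "usage_matrix")) {
    ev <- names(object$weights)
    if (!all(ev %in% rownames(um$usage)))
      stopf("usage matrix lacks events the model was trained on: %s",
            paste(setdiff(ev, rownames(um$usage)), collapse = ", "))
    x <- um$usage[ev, , drop = FALSE]
    covered_events <- um$covered_events
    miss <- which(is.na(x), arr.ind = TRUE)
    if (nrow(miss)) x[miss] <- object$event_means[ev][miss[, 1L]]
  } else {
    x <- as.matrix(um)
    if (anyNA(x)) stopf("plain matrices passed to predict() must be complete")
    covered_events <- setNames(rep(nrow(x), ncol(x)), colnames(x))
  }
  score <- clone_scores(object, x)
  call <- ifelse(covered_events[colnames(x)] < min_events, "unclassified",
                 ifelse(score > object$tau, "MUT", "WT"))
  data.frame(cell_id = colnames(x), score = unname(score),
             call = unname(call),
             covered_events = unname(covered_events[colnames(x)]),
             stringsAsFactors = FALSE)
}

#' @export
coef.clone_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$weights)
}

#' @export
print.clone_model <- function(x, ...) {
  cat("Clone classifier (weak-label ridge logistic regression)\n")
  cat(sprintf("  events: %d; fit cells: %d; lambda: %.3g%s\n",
              x$n_events, x$n_fit, x$lambda,
              if (x$standardize) " (standardized features)" else ""))
  cat(sprintf("  threshold tau = %.4f at target FPR alpha = %.2f (%d calibration cells)\n",
              x$tau, x$alpha, length(x$cal_cells)))
  if (!x$converged) cat("  WARNING: solver did not converge\n")
  invisible(x)
}

#' @export
summary.clone_model <- function(object, ...) {
  w <- sort(object$weights, decreasing = TRUE)
  out <- list(model = object,
              top_events = head(w, 5L),
              bottom_events = head(sort(object$weights), 5L))
  class(out) <- "summary.clone_model"
  out
}

#' @export
print.summary.clone_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  converged in %d iterations (deviance %.2f)\n",
              x$model$iterations, x$model$deviance))
  cat("  largest positive event weights:\n")
  print(round(x$top_events, 4))
  cat("  largest negative event weights:\n")
  print(round(x$bottom_events, 4))
  invisible(x)
}

#' Score-distribution plot for a fitted clone model
#'
#' Histogram of classifier scores with the calibrated threshold marked.
#'
#' @param x A fitted `clone_model`.
#' @param um Usage matrix to score (defaults must be supplied).
#' @param ... Passed to [graphics::hist()].
#' @export
plot.clone_model <- function(x, um, ...) {
  calls <- predict(x, um)
  graphics::hist(calls$score, breaks = 30, main = "Clone classifier scores",
                 xlab = "score", ...)
  graphics::abline(v = x$tau, col = "red", lty = 2)
  invisible(calls)
}

#' Evaluate genotype calls against simulated truth
#'
#' Confusion-derived metrics over classified cells; unclassified cells are
#' counted separately and excluded from the rates. The AUC uses all cells
#' with a score and a truth label (rank/Mann-Whitney form).
#'
#' @param calls A [predict.clone_model()] data frame.
#' @param truth Named character vector (or `sim_cohort`) giving the true
#'   genotype (`MUT`/`WT`) per cell.
#' @return A list: `confusion` (2 x 2 table, truth x call), `sensitivity`,
#'   `specificity`, `fpr`, `auc`, `n_unclassified`.
#' @export
evaluate_calls <- function(calls, truth) {
  if (inherits(truth, "sim_cohort"))
    truth <- setNames(truth$cells$genotype, truth$cells$cell_id)
  tv <- truth[calls$cell_id]
  if (anyNA(tv)) stopf("truth is missing labels for some called cells")
  classified <- calls$call != "unclassified"
  conf <- table(truth = factor(tv[classified], c("MUT", "WT")),
                call = factor(calls$call[classified], c("MUT", "WT")))
  tp <- conf["MUT", "MUT"]; fn <- conf["MUT", "WT"]
  fp <- conf["WT", "MUT"]; tn <- conf["WT", "WT"]
  list(
    confusion = conf,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    auc = auc_rank(calls$score, tv == "MUT"),
    n_unclassified = sum(!classified)
  )
}
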