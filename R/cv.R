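# k-fold cross-validated prediction error of a learned network for one
# target variable (default: the guarding score).

.LEARNERS <- c("hill_climb", "grow_shrink", "iamb", "empty")

learn_structure <- function(learner, data, alpha = 0.05, n_restarts = 0,
                            seed = NULL) {
  switch(learner,
         hill_climb = hill_climb(data, seed = seed,
                                 n_restarts = n_restarts)$dag,
         grow_shrink = grow_shrink(data, alpha = alpha),
         iamb = iamb(data, alpha = alpha),
         empty = dag(colnames(data)),
         stop("unknown learner: ", learner))
}

#' Cross-validated mean squared error of network prediction
#'
#' Randomly partitions the records into k folds (optionally keeping all of a
#' patient's instances in one fold), learns the structure and parameters on
#' each training split, predicts the target on the held-out split, and
#' reports per-fold and overall mean squared error. The `"empty"` learner is
#' the mean-predictor baseline.
#'
#' @param data complete numeric matrix/data.frame of the analysis variables.
#' @param learner one of `"hill_climb"`, `"grow_shrink"`, `"iamb"`, `"empty"`.
#' @param target node to predict (default `"guarding"`).
#' @param k number of folds.
#' @param seed integer seed for the fold assignment (and restarts).
#' @param mode prediction mode, see [predict_conditional_mean()].
#' @param alpha CI-test level for the constraint-based learners.
#' @param n_restarts hill-climb restarts within each fold.
#' @param group_by optional factor (e.g. patient id) assigned to folds as
#'   whole groups, for patient-level cross-validation.
#' @return list of class `"cv_report"` with `learner`, `target`, `k`, `seed`,
#'   `mode`, `fold_assignment`, `fold_mse`, `fold_n`, `mean_mse` (the
#'   fold-size-weighted mean, i.e. the overall mean squared error), and
#'   `failed_folds`.
#' @export
cross_validated_mse <- function(data, learner = "hill_climb",
                                target = "guarding", k = 5, seed = 1,
                                mode = c("full", "parents"), alpha = 0.05,
                                n_restarts = 0, group_by = NULL) {
  mode <- match.arg(mode)
  learner <- match.arg(learner, .LEARNERS)
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < k) stop("need at least k records")
  if (!(target %in% colnames(data))) stop("unknown target: ", target)
  set.seed(seed)
  if (is.null(group_by)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    stopifnot(length(group_by) == n)
    groups <- unique(group_by)
    gf <- sample(rep_len(seq_len(k), length(groups)))
    fold <- gf[match(group_by, groups)]
  }
  fold_mse <- rep(NA_real_, k)
  fold_n <- tabulate(fold, k)
  failed <- integer(0)
  for (f in seq_len(k)) {
    tr <- data[fold != f, , drop = FALSE]
    te <- data[fold == f, , drop = FALSE]
    if (nrow(te) == 0) next
    res <- tryCatch({
      g <- learn_structure(learner, tr, alpha = alpha,
                           n_restarts = n_restarts, seed = seed + f)
      fit <- bic_score(tr, g)
      pred <- predict_conditional_mean(fit, as.data.frame(te), target,
                                       mode = mode)
      mean((te[, target] - pred)^2)
    }, error = function(e) NA_real_)
    if (is.na(res)) failed <- c(failed, f) else fold_mse[f] <- res
  }
  if (length(failed))
    warning("learner failed in fold(s) ", paste(failed, collapse = ", "),
            "; mean computed over the remaining folds")
  ok <- !is.na(fold_mse)
  mean_mse <- sum(fold_mse[ok] * fold_n[ok]) / sum(fold_n[ok])
  structure(list(learner = learner, target = target, k = k, seed = seed,
                 mode = mode, fold_assignment = fold, fold_mse = fold_mse,
                 fold_n = fold_n, mean_mse = mean_mse,
                 failed_folds = failed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV, learner = %s, target = %s, mode = %s\n",
              x$k, x$learner, x$target, x$mode))
  cat("  fold MSE:", paste(sprintf("%.3f", x$fold_mse), collapse = " "), "\n")
  cat(sprintf("  mean MSE: %.4f\n", x$mean_mse))
  invisible(x)
}
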