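# Random-Forest Gini-importance feature ranking with pair-aware five-fold
# cross-validation, plus RF classification evaluation on feature subsets.
# The forest itself comes from the randomForest package (the reference R
# implementation); this module owns the protocol: pair-aware folding,
# importance averaging, ranking, and subset evaluation.

#' Gini impurity of a class-frequency vector
#'
#' `I = 1 - sum(p_k^2)`: zero when all cases belong to one class, maximal
#' (`1 - 1/m`) when cases are spread equally over the m classes.
#'
#' @param p Non-negative class frequencies summing to 1.
#' @return The impurity.
#' @export
gini_impurity <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("gini_impurity(): frequencies must be non-negative and sum to 1")
  }
  1 - sum(p^2)
}

#' Pair-aware cross-validation folds
#'
#' Splits ortholog pairs (not individual sequences) into folds of
#' approximately equal size, so both members of a pair always share a fold.
#'
#' @param pair_ids Vector assigning each row of the feature matrix to its
#'   ortholog pair.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed for the random split.
#' @return Integer fold label per row.
#' @export
make_pair_folds <- function(pair_ids, n_folds = 5L, seed = 1L) {
  if (n_folds < 2L) stop("make_pair_folds(): n_folds must be >= 2")
  pairs <- unique(pair_ids)
  if (length(pairs) < n_folds) {
    stop("make_pair_folds(): fewer pairs than folds")
  }
  set.seed(as.integer(seed))
  fold_of_pair <- sample(rep_len(seq_len(n_folds), length(pairs)))
  names(fold_of_pair) <- as.character(pairs)
  unname(fold_of_pair[as.character(pair_ids)])
}

.rf_fit <- function(X, y, n_trees) {
  randomForest::randomForest(x = X, y = factor(y, levels = c("NP", "AP")),
                             ntree = n_trees)
}

#' Rank features by cross-validated Gini importance
#'
#' For each fold, a Random Forest is fitted on the training portion (both
#' members of every pair stay on the same side of the split) and the mean
#' decrease in Gini impurity is recorded per feature. Features are ranked by
#' the mean importance across folds.
#'
#' @param X Numeric feature matrix, one labeled row per protein.
#' @param labels `"AP"`/`"NP"` label per row.
#' @param pair_ids Ortholog pair id per row (see [make_pair_folds()]).
#' @param n_trees Trees per forest (default 5000).
#' @param n_folds Folds (default 5).
#' @param seed Integer seed (fold split and forests).
#' @return Data frame of class `rf_ranking` with columns `feature`,
#'   `mean_gini`, `sd_gini`, `rank` (1 = most important), ordered by rank.
#' @export
rank_features <- function(X, labels, pair_ids, n_trees = 5000L,
                          n_folds = 5L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(labels),
            nrow(X) == length(pair_ids))
  folds <- make_pair_folds(pair_ids, n_folds = n_folds, seed = seed)
  imp <- matrix(NA_real_, ncol(X), n_folds,
                dimnames = list(colnames(X), NULL))
  for (f in seq_len(n_folds)) {
    train <- folds != f
    set.seed(as.integer(seed) + f)
    fit <- .rf_fit(X[train, , drop = FALSE], labels[train], n_trees)
    imp[, f] <- fit$importance[colnames(X), "MeanDecreaseGini"]
  }
  out <- data.frame(
    feature = colnames(X),
    mean_gini = rowMeans(imp),
    sd_gini = apply(imp, 1L, stats::sd),
    stringsAsFactors = FALSE)
  out$rank <- rank(-out$mean_gini, ties.method = "first")
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rf_ranking", "data.frame")
  attr(out, "fold_importance") <- imp
  out
}

#' Cross-validated Random-Forest classification
#'
#' Pools out-of-fold predicted AP probabilities over a pair-aware split and
#' reports accuracy (0.5 probability threshold) and the rank-sum AUC.
#'
#' @param X,labels,pair_ids,n_trees,n_folds,seed As in [rank_features()].
#' @param feature_subset Optional character vector of feature names to use;
#'   unknown names are an error.
#' @return An `evaluation_result` (AP = positive class) with an extra
#'   `probabilities` attribute holding the pooled out-of-fold scores.
#' @export
evaluate_rf <- function(X, labels, pair_ids, feature_subset = NULL,
                        n_trees = 500L, n_folds = 5L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  if (!is.null(feature_subset)) {
    unknown <- setdiff(feature_subset, colnames(X))
    if (length(unknown) > 0L) {
      stop("evaluate_rf(): unknown feature name(s): ",
           paste(unknown, collapse = ", "))
    }
    X <- X[, feature_subset, drop = FALSE]
  }
  folds <- make_pair_folds(pair_ids, n_folds = n_folds, seed = seed)
  prob <- rep(NA_real_, nrow(X))
  for (f in seq_len(n_folds)) {
    train <- folds != f
    set.seed(as.integer(seed) + f)
    fit <- .rf_fit(X[train, , drop = FALSE], labels[train], n_trees)
    prob[!train] <- stats::predict(fit, X[!train, , drop = FALSE],
                                   type = "prob")[, "AP"]
  }
  pred_ap <- prob > 0.5
  is_ap <- labels == "AP"
  tp <- sum(pred_ap & is_ap)
  tn <- sum(!pred_ap & !is_ap)
  fp <- sum(pred_ap & !is_ap)
  fn <- sum(!pred_ap & is_ap)
  res <- new_evaluation_result(tp, tn, fp, fn,
                               auc = roc_auc(prob[is_ap], prob[!is_ap]))
  attr(res, "probabilities") <- prob
  res
}

#' Simple backward elimination on RF importance
#'
#' A documented simple variant of variable selection (not the varSelRF
#' algorithm): each round drops the lowest-importance 20% of the remaining
#' features (importance from a forest on the full data) and records the
#' pair-aware out-of-fold AUC of the remaining subset; the subset with the
#' best AUC is returned.
#'
#' @param X,labels,pair_ids,n_trees,n_folds,seed As in [rank_features()].
#' @param drop_frac Fraction of features dropped per round.
#' @param min_features Stop when at most this many features remain.
#' @return List with `best_subset`, `best_auc`, and the per-round `history`
#'   data frame.
#' @export
rf_backward_elimination <- function(X, labels, pair_ids, n_trees = 500L,
                                    n_folds = 5L, seed = 1L,
                                    drop_frac = 0.2, min_features = 2L) {
  features <- colnames(X)
  history <- list()
  best_auc <- -Inf
  best_subset <- features
  round <- 0L
  while (length(features) >= min_features) {
    round <- round + 1L
    res <- evaluate_rf(X, labels, pair_ids, feature_subset = features,
                       n_trees = n_trees, n_folds = n_folds, seed = seed)
    history[[round]] <- data.frame(round = round,
                                   n_features = length(features),
                                   auc = res$auc, accuracy = res$accuracy)
    if (res$auc > best_auc) {
      best_auc <- res$auc
      best_subset <- features
    }
    if (length(features) <= min_features) break
    set.seed(as.integer(seed) + 1000L + round)
    fit <- .rf_fit(X[, features, drop = FALSE], labels, n_trees)
    imp <- fit$importance[features, "MeanDecreaseGini"]
    n_drop <- max(1L, floor(drop_frac * length(features)))
    features <- names(sort(imp, decreasing = TRUE))[
      seq_len(length(features) - n_drop)]
  }
  list(best_subset = best_subset, best_auc = best_auc,
       history = do.call(rbind, history))
}

#' Write a feature ranking as TSV
#' @param ranking An `rf_ranking` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
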