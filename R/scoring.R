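# The linear relative-difference scoring function for relative
# acidostability: a pair is scored as the weighted sum of bounded relative
# feature differences over the ten most discriminative features, with
# positive scores predicting that the first sequence is the AP (more
# acid-stable) member. Weights are fitted by hill climbing on the count of
# correctly scored oriented pairs.

#' The ten scoring features
#' @return Character vector of feature names, in weight-table order.
#' @export
scoring_features <- function() {
  c("x_K", "x_small", "x_T", "x_tiny", "x_aliphatic", "x_aromatic",
    "x_I", "x_LQ", "x_Q", "x_Y")
}

#' Published scoring weights
#'
#' The fitted weights of the ten scoring features.
#' @return Named numeric vector over [scoring_features()].
#' @export
published_weights <- function() {
  stats::setNames(
    c(0.68, 0.75, 0.90, 0.58, -0.97, -0.74, -0.96, -0.04, -0.01, -0.53),
    scoring_features())
}

#' Relative feature difference between two feature vectors
#'
#' Default symmetric mode: `delta_i = (x1_i - x2_i) / (x1_i + x2_i)`, with 0
#' when both values are 0 -- bounded in \[-1, 1\] for non-negative features
#' and antisymmetric under swapping the sequences. Alternative modes:
#' `"plain"` (`x1 - x2`) and `"relative_to_second"` (`(x1 - x2) / x2`).
#'
#' @param f1,f2 Named feature vectors (see [compute_features()]).
#' @param features Names of the features to contrast (default the ten
#'   scoring features). Missing features are an error.
#' @param mode Difference mode.
#' @return Named numeric vector of deltas with attribute `mode`.
#' @export
relative_difference <- function(f1, f2, features = scoring_features(),
                                mode = c("symmetric", "plain",
                                         "relative_to_second")) {
  mode <- match.arg(mode)
  missing1 <- setdiff(features, names(f1))
  missing2 <- setdiff(features, names(f2))
  if (length(missing1) > 0L || length(missing2) > 0L) {
    stop("relative_difference(): missing feature(s): ",
         paste(unique(c(missing1, missing2)), collapse = ", "))
  }
  x1 <- f1[features]
  x2 <- f2[features]
  d <- switch(mode,
    symmetric = ifelse(x1 == 0 & x2 == 0, 0, (x1 - x2) / (x1 + x2)),
    plain = x1 - x2,
    relative_to_second = ifelse(x1 == x2, 0, (x1 - x2) / x2))
  d <- stats::setNames(as.numeric(d), features)
  attr(d, "mode") <- mode
  d
}

#' Score a pair from its delta vector
#'
#' `score = sum_i w_i * delta_i`. A positive score predicts that the first
#' sequence of the pair is the AP member.
#'
#' @param delta Named delta vector (or matrix with one row per pair).
#' @param weights Named weight vector (default [published_weights()]).
#' @return Signed numeric score(s).
#' @export
score_pair <- function(delta, weights = published_weights()) {
  if (is.matrix(delta)) {
    return(as.numeric(delta[, names(weights), drop = FALSE] %*% weights))
  }
  sum(weights * delta[names(weights)])
}

#' Delta matrix for a set of oriented ortholog pairs
#'
#' @param ap_features,np_features Feature matrices with matching rows (one
#'   per pair).
#' @param features,mode Passed to [relative_difference()].
#' @return Numeric matrix, one row per pair.
#' @export
pair_deltas <- function(ap_features, np_features,
                        features = scoring_features(), mode = "symmetric") {
  stopifnot(nrow(ap_features) == nrow(np_features))
  out <- vapply(seq_len(nrow(ap_features)), function(i) {
    relative_difference(ap_features[i, ], np_features[i, ],
                        features = features, mode = mode)
  }, numeric(length(features)))
  m <- t(matrix(out, nrow = length(features),
                dimnames = list(features, NULL)))
  m
}

#' Fit scoring weights by hill climbing
#'
#' Starts from random weights in \[-1, 1\]. At each iteration every weight
#' is perturbed by an independent uniform step in \[-`step`, `step`\] and
#' clamped to \[-1, 1\]; the move is kept only if the number of pairs with
#' strictly positive score increases, otherwise it is rolled back. (A
#' single-coordinate proposal is selectable via `coordinate = TRUE` but
#' locks into coarse local optima on weakly separable data, because with a
#' strict-increase rule only twenty move directions exist.) The search is
#' restarted `restarts` times from fresh random weights and the
#' element-wise average of the per-restart optima is returned.
#'
#' @param deltas Matrix of oriented (AP-first) delta vectors, one row per
#'   pair, columns named by feature.
#' @param iterations Iterations per restart (>= 1).
#' @param seed Integer seed; the entire fit is deterministic given it.
#' @param restarts Number of random restarts (default 5).
#' @param step Half-width of the uniform proposal step (default 0.1).
#' @param coordinate Perturb one random weight per move instead of all.
#' @return Object of class `weight_fit`: `weights` (the averaged vector),
#'   `restart_weights`, `restart_objective` (correct pairs at each restart's
#'   optimum), `trace` (list of accepted-objective traces) and `n_pairs`.
#' @export
hill_climb <- function(deltas, iterations = 1e5L, seed = 1L, restarts = 5L,
                       step = 0.1, coordinate = FALSE) {
  if (!is.matrix(deltas) || nrow(deltas) == 0L) {
    stop("hill_climb(): deltas must be a non-empty matrix")
  }
  if (iterations < 1L) stop("hill_climb(): iterations must be >= 1")
  features <- colnames(deltas)
  nf <- length(features)
  set.seed(as.integer(seed))
  restart_w <- matrix(NA_real_, restarts, nf,
                      dimnames = list(NULL, features))
  restart_obj <- integer(restarts)
  traces <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    w <- stats::runif(nf, -1, 1)
    obj <- sum(deltas %*% w > 0)
    trace <- obj
    for (it in seq_len(iterations)) {
      if (coordinate) {
        k <- sample.int(nf, 1L)
        w_new <- w
        w_new[k] <- min(1, max(-1, w_new[k] + stats::runif(1, -step, step)))
      } else {
        w_new <- pmin(1, pmax(-1, w + stats::runif(nf, -step, step)))
      }
      obj_new <- sum(deltas %*% w_new > 0)
      if (obj_new > obj) {
        w <- w_new
        obj <- obj_new
        trace <- c(trace, obj)
        if (obj == nrow(deltas)) break
      }
    }
    restart_w[r, ] <- w
    restart_obj[r] <- obj
    traces[[r]] <- trace
  }
  structure(list(
    weights = stats::setNames(colMeans(restart_w), features),
    restart_weights = restart_w,
    restart_objective = restart_obj,
    trace = traces,
    n_pairs = nrow(deltas)
  ), class = "weight_fit")
}

#' @export
print.weight_fit <- function(x, ...) {
  cat("Hill-climb weight fit over", x$n_pairs, "pairs;",
      "best restart objective", max(x$restart_objective), "\n")
  print(round(x$weights, 3))
  invisible(x)
}

new_evaluation_result <- function(tp, tn, fp, fn, auc = NA_real_) {
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / (tp + tn + fp + fn), auc = auc),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("tp %d tn %d fp %d fn %d; accuracy %.4f; AUC %s\n",
              x$tp, x$tn, x$fp, x$fn, x$accuracy,
              ifelse(is.na(x$auc), "-", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Evaluate the scoring function on oriented ortholog pairs
#'
#' A pair is correct iff its (AP-first) score is strictly positive; a score
#' of exactly 0 counts as incorrect. Each oriented pair contributes one
#' positive case and its reversal one negative case, so tp = tn and
#' fp = fn by score antisymmetry. AUC uses the oriented scores as positives
#' and the reversed scores as negatives.
#'
#' @param deltas Oriented delta matrix (see [pair_deltas()]).
#' @param weights Weight vector.
#' @return An `evaluation_result`.
#' @export
evaluate_ortholog_pairs <- function(deltas, weights = published_weights()) {
  s <- score_pair(deltas, weights)
  tp <- sum(s > 0)
  fn <- sum(s <= 0)
  auc <- roc_auc(s, -s)
  new_evaluation_result(tp = tp, tn = tp, fp = fn, fn = fn, auc = auc)
}

#' Evaluate the scoring function on all AP x NP cross pairs
#'
#' Scores every (AP_i, NP_j) combination AP-first; a combination is correct
#' iff its score is strictly positive.
#'
#' @param ap_features,np_features Feature matrices (rows need not match).
#' @param weights Weight vector.
#' @param features,mode Passed to [relative_difference()].
#' @return An `evaluation_result` over the n x m grid.
#' @export
evaluate_cross_pairs <- function(ap_features, np_features,
                                 weights = published_weights(),
                                 features = names(weights),
                                 mode = "symmetric") {
  if (nrow(ap_features) == 0L || nrow(np_features) == 0L) {
    stop("evaluate_cross_pairs(): both feature matrices must be non-empty")
  }
  scores <- matrix(NA_real_, nrow(ap_features), nrow(np_features))
  for (i in seq_len(nrow(ap_features))) {
    for (j in seq_len(nrow(np_features))) {
      d <- relative_difference(ap_features[i, ], np_features[j, ],
                               features = features, mode = mode)
      scores[i, j] <- score_pair(d, weights)
    }
  }
  tp <- sum(scores > 0)
  fn <- sum(scores <= 0)
  auc <- roc_auc(as.numeric(scores), -as.numeric(scores))
  new_evaluation_result(tp = tp, tn = tp, fp = fn, fn = fn, auc = auc)
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation: the probability that a random
#' positive score exceeds a random negative score, ties counted 0.5.
#'
#' @param scores_pos,scores_neg Non-empty numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("roc_auc(): both score vectors must be non-empty")
  }
  np <- length(scores_pos)
  nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Empirical ROC curve points
#'
#' @param scores_pos,scores_neg Score vectors.
#' @return Data frame with `threshold`, `tpr`, `fpr`, ordered from the
#'   highest threshold down (suitable for plotting or TSV export).
#' @export
roc_points <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("roc_points(): both score vectors must be non-empty")
  }
  thr <- sort(unique(c(scores_pos, scores_neg, Inf)), decreasing = TRUE)
  data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores_pos >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores_neg >= t), numeric(1)))
}

#' Write scoring weights as JSON
#' @param weights Named weight vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  jsonlite::write_json(as.list(weights), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read scoring weights from JSON
#' @param path JSON file path.
#' @return Named numeric vector.
#' @export
read_weights <- function(path) {
  w <- jsonlite::read_json(path)
  stats::setNames(vapply(w, as.numeric, numeric(1)), names(w))
}
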