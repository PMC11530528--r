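# Evaluation metrics: threshold-swept micro-F1 ("Best-F1"), rank-based AUROC,
# step-interpolated AUPRC, top-k contact precision/recall, inter-chain contact
# labeling, and the utilization-rate diagnostic for multi-scale imbalance.

#' Best (threshold-swept) micro-F1
#'
#' Micro-averaged F1 of binarized predictions, maximized over a global
#' decision threshold swept on the fixed grid `0.01, 0.02, ..., 0.99`. Used
#' for imbalanced multilabel interaction typing, where a tuned global
#' threshold is standard practice.
#'
#' @param scores Numeric matrix (or vector) of per-link per-class
#'   probabilities.
#' @param labels 0/1 matrix (or vector) of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
best_f1 <- function(scores, labels) {
  s <- as.numeric(scores); y <- as.numeric(labels)
  if (length(s) == 0L) stop("best_f1: empty input")
  if (length(s) != length(y)) stop("best_f1: shape mismatch")
  best <- 0
  for (th in seq(0.01, 0.99, by = 0.01)) {
    pred <- s >= th
    tp <- sum(pred & y == 1)
    fp <- sum(pred & y == 0)
    fn <- sum(!pred & y == 1)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best) best <- f1
  }
  best
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling; exactly the
#' normalized U statistic.
#'
#' @param scores Numeric score vector (or matrix, flattened).
#' @param labels 0/1 vector of the same length.
#' @return Scalar in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  s <- as.numeric(scores); y <- as.numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("auroc: both classes must be present")
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation: walking the ranking from the highest score,
#' AUPRC = sum over distinct score thresholds of
#' `precision * delta(recall)`. Tied scores are processed as one block, so
#' the value does not depend on input ordering.
#'
#' @param scores Numeric score vector (or matrix, flattened).
#' @param labels 0/1 vector of the same length.
#' @return Scalar in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  s <- as.numeric(scores); y <- as.numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("auprc: both classes must be present")
  thr <- sort(unique(s), decreasing = TRUE)
  tp <- 0; fp <- 0; prev_rec <- 0; area <- 0
  for (th in thr) {
    sel <- s == th
    tp <- tp + sum(y[sel] == 1)
    fp <- fp + sum(y[sel] == 0)
    rec <- tp / n1
    prec <- tp / (tp + fp)
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

#' Precision and recall over the top-k scored pairs
#'
#' Ranks candidate pairs by score (ties broken by position for determinism)
#' and reports precision and recall of the `k` best. The conventional
#' contact-prediction choices are `k = 10`, `ceiling(L/10)`, `ceiling(L/5)`
#' with `L` the ligand-chain length.
#'
#' @param scores Numeric vector/matrix of pair scores.
#' @param labels 0/1 vector/matrix of the same shape.
#' @param k Number of top pairs, `1 <= k <= length(scores)`.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall_at_k <- function(scores, labels, k) {
  s <- as.numeric(scores); y <- as.numeric(labels)
  if (k < 1L) stop("precision_recall_at_k: k must be >= 1")
  if (k > length(s)) stop("precision_recall_at_k: k exceeds the number of pairs")
  top <- order(-s, seq_along(s))[seq_len(k)]
  tp <- sum(y[top] == 1)
  c(precision = tp / k,
    recall = if (sum(y == 1) == 0) 0 else tp / sum(y == 1))
}

#' Label inter-chain residue contacts
#'
#' Binary contact matrix between two chains: entry `(i, j)` is 1 iff the
#' C-alpha distance is strictly below `cutoff` (default 6 Angstroms, the
#' standard interface-contact threshold).
#'
#' @param coords_a,coords_b Numeric `La x 3` and `Lb x 3` coordinate
#'   matrices.
#' @param cutoff Distance threshold in Angstroms.
#' @return Integer 0/1 matrix `La x Lb`.
#' @export
label_interchain_contacts <- function(coords_a, coords_b, cutoff = 6) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) == 0L || nrow(coords_b) == 0L) {
    stop("label_interchain_contacts: chains must be nonempty")
  }
  d2 <- outer(rowSums(coords_a^2), rowSums(coords_b^2), "+") -
    2 * coords_a %*% t(coords_b)
  (sqrt(pmax(d2, 0)) < cutoff) * 1L
}

#' Utilization rate of a scale
#'
#' Relative accuracy change when a scale is added to the single-scale model:
#' `(f_multi - f_single) / f_single`, where `f_single` is the multi-scale
#' model with the scale of interest ablated (its inputs replaced by their
#' feature mean) evaluated on the same test split.
#'
#' @param f_multi Accuracy of the full multi-scale model.
#' @param f_single Accuracy of the ablated single-scale model (> 0).
#' @return Scalar (unclipped; can exceed 1 when `f_multi > 2 * f_single`).
#' @export
utilization_rate <- function(f_multi, f_single) {
  if (f_single == 0) stop("utilization_rate: f_single must be nonzero")
  (f_multi - f_single) / f_single
}

#' Ratio of network-scale to structure-scale utilization
#'
#' Reported truncated (not rounded) to two decimals, the convention that
#' consistently reproduces the printed diagnostic ratios.
#'
#' @param u_network Utilization rate of the molecular network scale.
#' @param u_structure Utilization rate of the atomic structure scale
#'   (nonzero).
#' @return Scalar, truncated to two decimals.
#' @export
utilization_ratio <- function(u_network, u_structure) {
  if (u_structure == 0) stop("utilization_ratio: zero denominator")
  r <- u_network / u_structure
  trunc(r * 100) / 100
}

#' Assemble a metrics report
#'
#' @param scores Probability matrix on evaluated links.
#' @param labels 0/1 matrix of the same shape.
#' @param k_values Integer vector of `k` for precision/recall at `k`
#'   (entries exceeding the number of score entries are dropped).
#' @return A `metrics_report` list: `best_f1`, `auroc`, `auprc`,
#'   `precision_at_k`, `recall_at_k`.
#' @export
metrics_report <- function(scores, labels, k_values = integer(0)) {
  k_values <- k_values[k_values <= length(as.numeric(scores))]
  pk <- lapply(k_values, function(k) precision_recall_at_k(scores, labels, k))
  structure(list(
    best_f1 = best_f1(scores, labels),
    auroc = auroc(scores, labels),
    auprc = auprc(scores, labels),
    precision_at_k = stats::setNames(vapply(pk, `[[`, numeric(1), "precision"),
                                     k_values),
    recall_at_k = stats::setNames(vapply(pk, `[[`, numeric(1), "recall"),
                                  k_values)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Best-F1: %.4f  AUROC: %.4f  AUPRC: %.4f\n",
              x$best_f1, x$auroc, x$auprc))
  if (length(x$precision_at_k)) {
    cat("P@k:", paste(sprintf("%s=%.3f", names(x$precision_at_k),
                              x$precision_at_k), collapse = "  "), "\n")
    cat("R@k:", paste(sprintf("%s=%.3f", names(x$recall_at_k),
                              x$recall_at_k), collapse = "  "), "\n")
  }
  invisible(x)
}
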