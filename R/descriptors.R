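#' @include AllClasses.R
NULL

#' Optimal leaf weight of the second-order boosting objective
#'
#' For a fixed tree structure, the weight minimizing the second-order
#' approximation of the regularized loss on one leaf is -G / (H + lambda),
#' where G and H are the sums of first and second loss derivatives of the
#' samples on the leaf.
#'
#' @param G Sum of gradients on the leaf.
#' @param H Sum of hessians on the leaf.
#' @param lambdaReg L2 regularization (>= 0).
#' @return The optimal leaf weight.
#' @export
leafWeight <- function(G, H, lambdaReg = 1) {
  if (lambdaReg < 0) stop("lambdaReg must be >= 0")
  if (H + lambdaReg <= 0)
    stop("numeric-domain error: H + lambdaReg must be positive")
  -G / (H + lambdaReg)
}

#' Structure score of a fixed boosted tree
#'
#' obj = -(1/2) * sum_j G_j^2 / (H_j + lambda) + gamma * T, with T the number
#' of leaves; lower is better, and the reduction of this score under a split
#' is the split gain used for descriptor importance.
#'
#' @param leafStats List of `c(G, H)` pairs (or a 2-column matrix), one per
#'   leaf.
#' @param lambdaReg L2 regularization.
#' @param gamma Per-leaf complexity penalty.
#' @return The objective value.
#' @export
structureScore <- function(leafStats, lambdaReg = 1, gamma = 0) {
  if (is.matrix(leafStats))
    leafStats <- split(leafStats, row(leafStats))
  G <- vapply(leafStats, `[`, 0, 1)
  H <- vapply(leafStats, `[`, 0, 2)
  if (any(H + lambdaReg <= 0))
    stop("numeric-domain error: every H_j + lambdaReg must be positive")
  -0.5 * sum(G^2 / (H + lambdaReg)) + gamma * length(G)
}

#' Rank molecular descriptors with gradient-boosted trees
#'
#' Trains a gradient-boosted tree ensemble (xgboost engine) under the
#' second-order objective and ranks descriptors by total gain. A binary 0/1
#' target is fitted with logistic loss, a continuous one with squared error.
#' Descriptors never used in a split score 0; ties break by name. A constant
#' target cannot be boosted: the ranking falls back to column variance with
#' a warning and the `fallback` flag set.
#'
#' @param values Numeric matrix, compounds x descriptors, with column names.
#' @param target Numeric label vector, aligned with rows.
#' @param k Selection size (default 50).
#' @param nrounds Boosting rounds (default 200).
#' @param maxDepth Tree depth (default 4).
#' @param eta Learning rate (default 0.1).
#' @param lambdaReg L2 regularization (default 1).
#' @param gamma Split penalty (default 0).
#' @return A [DescriptorRanking-class].
#' @export
rankDescriptors <- function(values, target, k = 50L, nrounds = 200L,
                            maxDepth = 4L, eta = 0.1, lambdaReg = 1,
                            gamma = 0) {
  stopifnot(is.matrix(values), nrow(values) == length(target))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("D%03d", seq_len(ncol(values)))
  if (k > ncol(values)) stop("k cannot exceed the number of descriptors")
  if (stats::var(target) == 0) {
    warning("degenerate fit: constant target; ranking by column variance")
    v <- apply(values, 2, stats::var)
    ord <- order(-v, colnames(values))
    return(new("DescriptorRanking", rankedNames = colnames(values)[ord],
               scores = as.numeric(v[ord]), k = as.integer(k),
               fallback = TRUE))
  }
  objective <- if (all(target %in% c(0, 1))) "binary:logistic"
               else "reg:squarederror"
  dtrain <- xgboost::xgb.DMatrix(values, label = target, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = objective, max_depth = maxDepth, eta = eta,
                  lambda = lambdaReg, gamma = gamma, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = booster)
  scores <- stats::setNames(rep(0, ncol(values)), colnames(values))
  scores[imp$Feature] <- imp$Gain
  ord <- order(-scores, names(scores))
  new("DescriptorRanking", rankedNames = names(scores)[ord],
      scores = as.numeric(scores[ord]), k = as.integer(k), fallback = FALSE)
}

#' Merge per-task rankings by mean normalized gain
#'
#' @param rankings List of [DescriptorRanking-class] objects over the same
#'   descriptor set.
#' @param k Selection size of the merged ranking.
#' @return A [DescriptorRanking-class].
#' @export
mergeRankings <- function(rankings, k = 50L) {
  stopifnot(length(rankings) >= 1L)
  nms <- sort(rankings[[1]]@rankedNames)
  acc <- stats::setNames(rep(0, length(nms)), nms)
  for (r in rankings) {
    s <- stats::setNames(r@scores, r@rankedNames)[nms]
    tot <- sum(s)
    if (tot > 0) acc <- acc + s / tot
  }
  acc <- acc / length(rankings)
  ord <- order(-acc, names(acc))
  new("DescriptorRanking", rankedNames = names(acc)[ord],
      scores = as.numeric(acc[ord]), k = as.integer(k), fallback = FALSE)
}

#' Selected descriptor names of a ranking
#' @param ranking A [DescriptorRanking-class].
#' @return Character vector of the top-k descriptor names.
#' @export
selectedDescriptors <- function(ranking) {
  utils::head(ranking@rankedNames, ranking@k)
}

#' Write / read a descriptor ranking as a two-column TSV
#'
#' @param ranking A [DescriptorRanking-class].
#' @param path File path.
#' @return `path` invisibly; `readRanking` returns the ranking.
#' @export
writeRanking <- function(ranking, path) {
  utils::write.table(
    data.frame(name = ranking@rankedNames, score = ranking@scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRanking
#' @param k Selection size to restore (default: all but read from usage).
#' @export
readRanking <- function(path, k = 50L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("DescriptorRanking", rankedNames = tab$name,
      scores = as.numeric(tab$score), k = as.integer(min(k, nrow(tab))),
      fallback = FALSE)
}

#' Train-split standardization of selected descriptors
#'
#' Missing values are imputed with the train-split median (logged), then
#' columns are z-scored with train-split mean and standard deviation;
#' constant columns get unit scale.
#'
#' @param values Numeric matrix, compounds x descriptors.
#' @param stats Optional list with `center`, `scale`, `medians` from a
#'   previous call (apply train statistics to held-out data).
#' @return List with `values` (standardized matrix) and the statistics.
#' @export
standardizeDescriptors <- function(values, stats = NULL) {
  if (is.null(stats)) {
    medians <- apply(values, 2, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(values)))
      values[is.na(values[, j]), j] <- medians[j]
    center <- colMeans(values)
    scale <- apply(values, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    stats <- list(center = center, scale = scale, medians = medians)
  } else {
    for (j in seq_len(ncol(values)))
      values[is.na(values[, j]), j] <- stats$medians[j]
  }
  out <- sweep(sweep(values, 2, stats$center), 2, stats$scale, `/`)
  list(values = out, stats = stats)
}

#' Attention-weighted descriptor readout
#'
#' Applies the per-position attention (each scalar descriptor value is
#' embedded by its own tanh unit, scored against a shared context vector and
#' softmax-normalized) to reweight the k-vector, then projects it to the
#' hiddenDim-vector h_m with an affine layer.
#'
#' @param m Length-k numeric vector of standardized selected descriptors.
#' @param params A [GgnnParameters-class].
#' @param returnWeights If TRUE, return `list(hm, weights)`.
#' @return Length-hiddenDim vector (or a list when `returnWeights`).
#' @export
descriptorReadout <- function(m, params, returnWeights = FALSE) {
  stopifnot(is(params, "GgnnParameters"), all(is.finite(m)))
  w <- params@weights
  if (length(m) != ncol(w$P))
    stop("descriptor vector length ", length(m),
         " does not match descriptorK ", ncol(w$P))
  Y <- tanh(sweep(w$P, 2, m, `*`) + w$Q)
  e <- as.numeric(crossprod(w$cm, Y))
  wts <- softmaxStable(e)
  hm <- as.numeric(w$Wp %*% (wts * m) + w$bp)
  if (returnWeights) list(hm = hm, weights = wts) else hm
}
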