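#' @include AllClasses.R
NULL

#' Chi-square statistic of two adjacent intervals
#'
#' Pearson chi-square of a 2 x 2 table (intervals x classes) with
#' expectations E_ij = row_i * col_j / total. A zero marginal makes the
#' statistic undefined; the function returns 0 with the `degenerate`
#' attribute set, which forces the pair to merge in [chimergeBins()].
#'
#' @param A 2 x 2 numeric count matrix (rows: intervals, columns: classes).
#' @return The chi-square value, with attribute `degenerate`.
#' @export
chi2Pair <- function(A) {
  stopifnot(all(dim(A) == c(2, 2)), all(A >= 0))
  rs <- rowSums(A); cs <- colSums(A); tot <- sum(A)
  if (any(rs == 0) || any(cs == 0))
    return(structure(0, degenerate = TRUE))
  E <- outer(rs, cs) / tot
  structure(sum((A - E)^2 / E), degenerate = FALSE)
}

#' Bottom-up chi-merge discretization of one feature
#'
#' Starts from one interval per unique value (capped at `maxBins` quantile
#' bins), then repeatedly merges the adjacent pair with the smallest
#' chi-square statistic until every adjacent pair reaches the threshold
#' (qchisq(1 - alpha, df = 1)) or only `minBins` bins remain. Ties merge the
#' lowest-index pair first, so the procedure is deterministic; pairs with a
#' zero marginal count as chi-square 0 and merge first.
#'
#' @param values Numeric feature values.
#' @param labels Binary 0/1 labels, aligned with values.
#' @param alpha Significance level for the merge threshold (default 0.05).
#' @param maxBins Cap on the number of initial bins (default 20).
#' @param minBins Minimum number of final bins (default 2).
#' @param featureName Label stored in the result.
#' @return A [BinningResult-class].
#' @export
chimergeBins <- function(values, labels, alpha = 0.05, maxBins = 20L,
                         minBins = 2L, featureName = "feature") {
  stopifnot(length(values) == length(labels), all(labels %in% c(0, 1)))
  threshold <- stats::qchisq(1 - alpha, df = 1)
  ux <- sort(unique(values))
  if (length(ux) == 1L) {
    warning("constant feature '", featureName, "': single bin")
    counts <- matrix(c(sum(labels == 0), sum(labels == 1)), 1, 2,
                     dimnames = list(NULL, c("neg", "pos")))
    return(new("BinningResult", featureName = featureName,
               binEdges = c(-Inf, Inf), counts = counts,
               woe = .woeFromCounts(counts), degenerate = FALSE))
  }
  cuts <- if (length(ux) > maxBins) {
    q <- unique(stats::quantile(values, probs = seq_len(maxBins - 1) / maxBins,
                                type = 7))
    sort(unique(q))
  } else {
    (ux[-1] + ux[-length(ux)]) / 2
  }
  edges <- c(-Inf, cuts, Inf)
  bin <- findInterval(values, edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  nb <- length(edges) - 1L
  counts <- matrix(0L, nb, 2, dimnames = list(NULL, c("neg", "pos")))
  for (b in seq_len(nb)) {
    counts[b, 1] <- sum(bin == b & labels == 0)
    counts[b, 2] <- sum(bin == b & labels == 1)
  }
  # drop empty initial bins (possible with skewed quantiles)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  edges <- c(edges[1], edges[-1][keep])
  degenerate <- FALSE
  while (nrow(counts) > minBins) {
    chis <- vapply(seq_len(nrow(counts) - 1L), function(b) {
      x <- chi2Pair(counts[b:(b + 1L), , drop = FALSE])
      as.numeric(x)
    }, 0)
    b <- which.min(chis)  # lowest index wins ties
    if (chis[b] >= threshold) break
    if (any(colSums(counts[b:(b + 1L), , drop = FALSE]) == 0) ||
        any(rowSums(counts[b:(b + 1L), , drop = FALSE]) == 0))
      degenerate <- TRUE
    counts[b, ] <- counts[b, ] + counts[b + 1L, ]
    counts <- counts[-(b + 1L), , drop = FALSE]
    edges <- edges[-(b + 1L)]
  }
  new("BinningResult", featureName = featureName, binEdges = edges,
      counts = counts, woe = .woeFromCounts(counts), degenerate = degenerate)
}

.woeFromCounts <- function(counts) {
  sm <- counts
  empty <- rowSums(sm == 0) > 0
  sm[empty, ] <- sm[empty, ] + 0.5
  py <- sm[, 2] / sum(sm[, 2])
  pn <- sm[, 1] / sum(sm[, 1])
  log(py / pn)
}

#' Weight-of-evidence values of a binning
#'
#' woe_i = ln(py_i / pn_i), where py_i (pn_i) is bin i's share of all
#' positives (negatives). Bins with an empty cell receive 0.5-count
#' smoothing on both classes before the shares are formed, keeping every
#' value finite.
#'
#' @param binning A [BinningResult-class].
#' @return Numeric vector, one weight of evidence per bin.
#' @export
woeValues <- function(binning) {
  stopifnot(is(binning, "BinningResult"))
  .woeFromCounts(binning@counts)
}

# Map raw feature values to bin indices of a BinningResult.
.assignBins <- function(values, binning) {
  pmin(pmax(findInterval(values, binning@binEdges), 1L),
       nrow(binning@counts))
}

#' Fit a scorecard over WOE-encoded features
#'
#' Bins every feature with [chimergeBins()] against the binary target,
#' encodes each compound by its bins' weight of evidence, fits a logistic
#' regression to obtain coefficients beta_i and intercept a, and assembles
#' the per-bin points (woe_i * beta_i + a/n) * factor + offset/n. A
#' separable fit falls back to a ridge-penalized refit with a warning.
#'
#' @param features data.frame or matrix of raw feature values (columns are
#'   features).
#' @param target Binary 0/1 outcome defining a "good" candidate.
#' @param factor Scale factor (default 20/ln 2: twenty points double the
#'   odds).
#' @param offset Global score offset (default 600).
#' @param alpha Chi-merge significance level.
#' @param maxBins,minBins Chi-merge bin limits.
#' @return A [Scorecard-class].
#' @export
fitScorecard <- function(features, target, factor = 20 / log(2),
                         offset = 600, alpha = 0.05, maxBins = 20L,
                         minBins = 2L) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(target), all(target %in% c(0, 1)))
  binnings <- lapply(names(features), function(nm)
    chimergeBins(features[[nm]], target, alpha = alpha, maxBins = maxBins,
                 minBins = minBins, featureName = nm))
  names(binnings) <- names(features)
  W <- vapply(names(features), function(nm) {
    b <- binnings[[nm]]
    b@woe[.assignBins(features[[nm]], b)]
  }, numeric(nrow(features)))
  df <- as.data.frame(W)
  fit <- suppressWarnings(stats::glm(target ~ ., data = cbind(target = target,
                                                              df),
                                     family = stats::binomial()))
  beta <- stats::coef(fit)
  if (!fit$converged || any(!is.finite(beta)) || any(abs(beta) > 15)) {
    warning("separable logistic fit; refitting with ridge penalty")
    X <- as.matrix(df)
    lam <- 1e-2
    b <- rep(0, ncol(X) + 1L)
    for (it in 1:100) {  # penalized IRLS, intercept unpenalized
      eta <- as.numeric(b[1] + X %*% b[-1])
      p <- 1 / (1 + exp(-eta))
      wts <- pmax(p * (1 - p), 1e-6)
      z <- eta + (target - p) / wts
      Xa <- cbind(1, X)
      Pen <- diag(c(0, rep(lam * nrow(X), ncol(X))))
      bNew <- solve(crossprod(Xa, wts * Xa) + Pen, crossprod(Xa, wts * z))
      if (max(abs(bNew - b)) < 1e-10) { b <- bNew; break }
      b <- bNew
    }
    beta <- stats::setNames(as.numeric(b), c("(Intercept)", colnames(X)))
  }
  a <- unname(beta["(Intercept)"])
  coefs <- beta[-1]
  n <- length(binnings)
  pts <- do.call(rbind, lapply(names(binnings), function(nm) {
    b <- binnings[[nm]]
    data.frame(feature = nm, bin = seq_along(b@woe),
               lower = b@binEdges[-length(b@binEdges)],
               upper = b@binEdges[-1], woe = b@woe,
               points = (b@woe * coefs[nm] + a / n) * factor + offset / n)
  }))
  new("Scorecard", binnings = binnings,
      coefficients = stats::setNames(as.numeric(coefs), names(binnings)),
      intercept = a, factor = factor, offset = offset, pointsTable = pts)
}

#' Score compounds with a fitted scorecard
#'
#' score = sum_i ((woe_i * beta_i + a/n) * factor + offset/n) over the n
#' features, each woe_i looked up from the compound's bin. Orientation
#' follows the logistic fit: higher scores mean higher odds of the "good
#' candidate" outcome.
#'
#' @param scorecard A [Scorecard-class].
#' @param features data.frame of raw feature values with the scorecard's
#'   feature columns.
#' @return Numeric score per row.
#' @export
scoreCompounds <- function(scorecard, features) {
  features <- as.data.frame(features)
  n <- length(scorecard@binnings)
  miss <- setdiff(names(scorecard@binnings), names(features))
  if (length(miss))
    stop("missing scorecard features: ", paste(miss, collapse = ", "))
  total <- rep(0, nrow(features))
  for (nm in names(scorecard@binnings)) {
    b <- scorecard@binnings[[nm]]
    woe <- b@woe[.assignBins(features[[nm]], b)]
    total <- total +
      (woe * scorecard@coefficients[nm] + scorecard@intercept / n) *
      scorecard@factor + scorecard@offset / n
  }
  unname(total)
}

#' Rank candidate compounds by scorecard score
#'
#' @param scorecard A [Scorecard-class].
#' @param predictions data.frame with a `compound_id` column and the
#'   scorecard's feature columns (typically predicted pIC50 and the five
#'   binary ADMET calls).
#' @return data.frame (compound_id, score, rank), scores nonincreasing, ties
#'   broken by compound_id.
#' @export
rankCandidates <- function(scorecard, predictions) {
  stopifnot("compound_id" %in% names(predictions))
  sc <- scoreCompounds(scorecard,
                       predictions[setdiff(names(predictions),
                                           "compound_id")])
  ord <- order(-sc, as.character(predictions$compound_id))
  out <- data.frame(compound_id = predictions$compound_id[ord],
                    score = sc[ord], rank = seq_along(sc))
  rownames(out) <- NULL
  out
}

#' Serialize a scorecard to a human-readable TSV
#'
#' @param scorecard A [Scorecard-class].
#' @param path File path.
#' @return `path` invisibly.
#' @export
writeScorecard <- function(scorecard, path) {
  hdr <- sprintf("# scorecard intercept=%.10g factor=%.10g offset=%.10g",
                 scorecard@intercept, scorecard@factor, scorecard@offset)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(scorecard@pointsTable, digits = 10), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
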