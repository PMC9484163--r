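#' @include ggnn.R
NULL

# ---------------------------------------------------------------------------
# Losses and fusion (user-facing primitives)
# ---------------------------------------------------------------------------

#' Convex fusion of the two branch representations
#'
#' h_final = lambda * h + (1 - lambda) * h_m, the elementwise convex
#' combination of the topological readout and the descriptor readout.
#' lambda = 1 uses the graph branch only, lambda = 0 the descriptor branch
#' only; the default trade-off is 0.6.
#'
#' @param h Length-d topological vector.
#' @param hm Length-d descriptor vector.
#' @param lambdaFuse Mixing weight in [0, 1].
#' @return Length-d fused vector.
#' @export
fuseRepresentations <- function(h, hm, lambdaFuse = 0.6) {
  if (!is.numeric(lambdaFuse) || length(lambdaFuse) != 1L ||
      lambdaFuse < 0 || lambdaFuse > 1)
    stop("configuration error: lambdaFuse must lie in [0, 1]")
  if (length(h) != length(hm))
    stop("branch representations must have equal length")
  lambdaFuse * h + (1 - lambdaFuse) * hm
}

#' Mean squared error training loss
#'
#' @param pred Numeric predictions.
#' @param truth Numeric ground truth, same length.
#' @return Mean of squared errors over the batch.
#' @export
lossRegression <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  mean((truth - pred)^2)
}

#' Cross-entropy training loss
#'
#' @param probs Numeric class probabilities (vector for one sample or matrix
#'   with one row per sample), rows summing to 1.
#' @param onehot One-hot labels, same shape.
#' @return Mean cross-entropy over samples.
#' @export
lossClassification <- function(probs, onehot) {
  if (is.null(dim(probs))) { probs <- rbind(probs); onehot <- rbind(onehot) }
  stopifnot(all(dim(probs) == dim(onehot)))
  mean(-rowSums(onehot * log(pmax(probs, 1e-300))))
}

# ---------------------------------------------------------------------------
# Full-compound forward / backward
# ---------------------------------------------------------------------------

# A prepared compound is list(graph, subs = list of induced MolecularGraph,
# m = length-k descriptor vector, y = label).
.forwardCompound <- function(cmp, params, lambdaFuse, pooling,
                             dropoutMask = NULL) {
  w <- params@weights
  steps <- params@interactionSteps
  prefix <- if (!is.null(w$s_W_o)) "s_" else ""
  pc <- .propagateCache(atomFeatures(cmp$graph), adjacency(cmp$graph), w,
                        steps)
  rc <- .readoutCache(pc$H, w, pooling)
  subCaches <- lapply(cmp$subs, function(sg) {
    spc <- .propagateCache(atomFeatures(sg), adjacency(sg), w, steps, prefix)
    src <- .readoutCache(spc$H, w, pooling, prefix)
    list(pc = spc, rc = src)
  })
  fc <- .fuseCache(c(list(rc$hG), lapply(subCaches, function(s) s$rc$hG)), w)

  # descriptor branch: per-position attention then affine projection
  m <- cmp$m
  Y <- tanh(sweep(w$P, 2, m, `*`) + w$Q)      # attnDim x k
  e <- as.numeric(crossprod(w$cm, Y))
  wd <- softmaxStable(e)
  mt <- wd * m
  hm <- as.numeric(w$Wp %*% mt + w$bp)

  hFinal <- lambdaFuse * fc$h + (1 - lambdaFuse) * hm
  hDrop <- if (is.null(dropoutMask)) hFinal else hFinal * dropoutMask

  if (params@task == "regression") {
    yhat <- sum(w$v * hDrop) + w$v0
    out <- list(pred = yhat)
  } else {
    logits <- as.numeric(w$V %*% hDrop + w$V0)
    probs <- softmaxStable(logits)
    out <- list(pred = probs)
  }
  c(out, list(pc = pc, rc = rc, subCaches = subCaches, fc = fc,
              desc = list(m = m, Y = Y, wd = wd, mt = mt, hm = hm),
              hFinal = hFinal, hDrop = hDrop, dropoutMask = dropoutMask,
              lambdaFuse = lambdaFuse, prefix = prefix))
}

.zeroGrads <- function(w) lapply(w, function(x) x * 0)

.addTo <- function(grads, name, value) {
  grads[[name]] <- grads[[name]] + value
  grads
}

.readoutBackward <- function(rc, dhG, w, grads) {
  p <- rc$prefix
  pn <- if (nzchar(p) && !is.null(w[[paste0(p, "A1")]]))
    function(nm) paste0(p, nm) else function(nm) nm
  n <- nrow(rc$H); d <- ncol(rc$H)
  dG <- matrix(0, n, d)
  if (rc$pooling %in% c("fused", "mean"))
    dG <- dG + matrix(dhG / (n + 1), n, d, byrow = TRUE)
  if (rc$pooling %in% c("fused", "max"))
    dG[cbind(rc$argmax, seq_len(d))] <-
      dG[cbind(rc$argmax, seq_len(d))] + dhG
  dS <- dG * rc$Tt
  dTt <- dG * rc$S
  dF1 <- dS * rc$S * (1 - rc$S)
  dF2 <- dTt * (1 - rc$Tt^2)
  k <- pn("A2"); grads[[k]] <- grads[[k]] + crossprod(rc$T1, dF1)
  k <- pn("a2"); grads[[k]] <- grads[[k]] + colSums(dF1)
  dT1pre <- tcrossprod(dF1, .wt(w, "A2", p)) * (1 - rc$T1^2)
  k <- pn("A1"); grads[[k]] <- grads[[k]] + crossprod(rc$H, dT1pre)
  k <- pn("a1"); grads[[k]] <- grads[[k]] + colSums(dT1pre)
  dH <- tcrossprod(dT1pre, .wt(w, "A1", p))
  k <- pn("B2"); grads[[k]] <- grads[[k]] + crossprod(rc$T2, dF2)
  k <- pn("b2"); grads[[k]] <- grads[[k]] + colSums(dF2)
  dT2pre <- tcrossprod(dF2, .wt(w, "B2", p)) * (1 - rc$T2^2)
  k <- pn("B1"); grads[[k]] <- grads[[k]] + crossprod(rc$H, dT2pre)
  k <- pn("b1"); grads[[k]] <- grads[[k]] + colSums(dT2pre)
  dH <- dH + tcrossprod(dT2pre, .wt(w, "B1", p))
  list(grads = grads, dH = dH)
}

.propagateBackward <- function(pc, dH, w, grads) {
  p <- pc$prefix
  pn <- if (nzchar(p) && !is.null(w[[paste0(p, "W_o")]]))
    function(nm) paste0(p, nm) else function(nm) nm
  A <- pc$A
  W_h <- .wt(w, "W_h", p); U_h <- .wt(w, "U_h", p)
  W_r <- .wt(w, "W_r", p); U_r <- .wt(w, "U_r", p)
  W_z <- .wt(w, "W_z", p); U_z <- .wt(w, "U_z", p)
  W_o <- .wt(w, "W_o", p)
  kWh <- pn("W_h"); kUh <- pn("U_h"); kbh <- pn("b_h")
  kWr <- pn("W_r"); kUr <- pn("U_r"); kbr <- pn("b_r")
  kWz <- pn("W_z"); kUz <- pn("U_z"); kbz <- pn("b_z")
  kWo <- pn("W_o"); kbo <- pn("b_o")
  for (t in rev(seq_len(pc$steps))) {
    s <- pc[[paste0("s", t)]]
    dC <- dH * s$Z
    dZ <- dH * (s$C - s$Hprev)
    dHprev <- dH * (1 - s$Z)
    dCpre <- dC * (1 - s$C^2)
    grads[[kWh]] <- grads[[kWh]] + crossprod(s$O, dCpre)
    grads[[kUh]] <- grads[[kUh]] + crossprod(s$RH, dCpre)
    grads[[kbh]] <- grads[[kbh]] + colSums(dCpre)
    dO <- tcrossprod(dCpre, W_h)
    dRH <- tcrossprod(dCpre, U_h)
    dR <- dRH * s$Hprev
    dHprev <- dHprev + dRH * s$R
    dRpre <- dR * s$R * (1 - s$R)
    grads[[kWr]] <- grads[[kWr]] + crossprod(s$O, dRpre)
    grads[[kUr]] <- grads[[kUr]] + crossprod(s$Hprev, dRpre)
    grads[[kbr]] <- grads[[kbr]] + colSums(dRpre)
    dO <- dO + tcrossprod(dRpre, W_r)
    dHprev <- dHprev + tcrossprod(dRpre, U_r)
    dZpre <- dZ * s$Z * (1 - s$Z)
    grads[[kWz]] <- grads[[kWz]] + crossprod(s$O, dZpre)
    grads[[kUz]] <- grads[[kUz]] + crossprod(s$Hprev, dZpre)
    grads[[kbz]] <- grads[[kbz]] + colSums(dZpre)
    dO <- dO + tcrossprod(dZpre, W_z)
    dHprev <- dHprev + tcrossprod(dZpre, U_z)
    grads[[kWo]] <- grads[[kWo]] + crossprod(s$AH, dO)
    grads[[kbo]] <- grads[[kbo]] + colSums(dO)
    dHprev <- dHprev + crossprod(A, tcrossprod(dO, W_o))
    dH <- dHprev
  }
  grads
}

# Backward pass for one compound; `dLdPred` is dLoss/dPrediction (scalar for
# regression, length-2 dLoss/dLogits for classification).
.backwardCompound <- function(fw, params, grads, dLdPred) {
  w <- params@weights
  if (params@task == "regression") {
    dHdrop <- dLdPred * w$v
    grads <- .addTo(grads, "v", dLdPred * fw$hDrop)
    grads <- .addTo(grads, "v0", dLdPred)
  } else {
    grads <- .addTo(grads, "V", dLdPred %o% fw$hDrop)
    grads <- .addTo(grads, "V0", dLdPred)
    dHdrop <- as.numeric(crossprod(w$V, dLdPred))
  }
  dHfinal <- if (is.null(fw$dropoutMask)) dHdrop else dHdrop * fw$dropoutMask
  dh <- fw$lambdaFuse * dHfinal
  dhm <- (1 - fw$lambdaFuse) * dHfinal

  # descriptor branch backward
  d <- fw$desc
  grads <- .addTo(grads, "Wp", dhm %o% d$mt)
  grads <- .addTo(grads, "bp", dhm)
  dmt <- as.numeric(crossprod(w$Wp, dhm))
  dwd <- dmt * d$m
  de <- d$wd * (dwd - sum(d$wd * dwd))
  grads <- .addTo(grads, "cm", as.numeric(d$Y %*% de))
  dYpre <- (w$cm %o% de) * (1 - d$Y^2)
  grads <- .addTo(grads, "P", sweep(dYpre, 2, d$m, `*`))
  grads <- .addTo(grads, "Q", dYpre)

  # fusion backward
  fc <- fw$fc
  K <- length(fc$vectors)
  dwts <- vapply(seq_len(K), function(j) sum(dh * fc$vectors[[j]]), 0)
  deF <- fc$weights * (dwts - sum(fc$weights * dwts))
  dVecs <- lapply(seq_len(K), function(j) fc$weights[j] * dh)
  for (j in seq_len(K)) {
    q <- fc$Qs[[j]]
    dqpre <- (deF[j] * w$cf) * (1 - q^2)
    grads <- .addTo(grads, "Wf", dqpre %o% fc$vectors[[j]])
    grads <- .addTo(grads, "bf", dqpre)
    grads <- .addTo(grads, "cf", deF[j] * q)
    dVecs[[j]] <- dVecs[[j]] + as.numeric(crossprod(w$Wf, dqpre))
  }

  # parent graph backward
  rb <- .readoutBackward(fw$rc, dVecs[[1]], w, grads)
  grads <- .propagateBackward(fw$pc, rb$dH, w, rb$grads)
  # substructure backward (shared or prefixed arrays)
  for (j in seq_along(fw$subCaches)) {
    sc <- fw$subCaches[[j]]
    rb <- .readoutBackward(sc$rc, dVecs[[j + 1L]], w, grads)
    grads <- .propagateBackward(sc$pc, rb$dH, w, rb$grads)
  }
  grads
}

# ---------------------------------------------------------------------------
# Training
# ---------------------------------------------------------------------------

.adamInit <- function(w) list(m = .zeroGrads(w), v = .zeroGrads(w), t = 0L)

.adamStep <- function(w, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(w)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

.batchLossGrad <- function(batch, params, lambdaFuse, pooling, dropout) {
  w <- params@weights
  grads <- .zeroGrads(w)
  loss <- 0
  B <- length(batch)
  for (cmp in batch) {
    mask <- if (dropout > 0)
      stats::rbinom(params@hiddenDim, 1L, 1 - dropout) / (1 - dropout)
    else NULL
    fw <- .forwardCompound(cmp, params, lambdaFuse, pooling, mask)
    if (params@task == "regression") {
      err <- fw$pred - cmp$y
      loss <- loss + err^2 / B
      grads <- .backwardCompound(fw, params, grads, 2 * err / B)
    } else {
      cls <- cmp$y + 1L
      loss <- loss - log(max(fw$pred[cls], 1e-300)) / B
      onehot <- c(0, 0); onehot[cls] <- 1
      grads <- .backwardCompound(fw, params, grads,
                                 (fw$pred - onehot) / B)
    }
  }
  list(loss = loss, grads = grads)
}

.datasetLoss <- function(data, params, lambdaFuse, pooling) {
  loss <- 0
  for (cmp in data) {
    fw <- .forwardCompound(cmp, params, lambdaFuse, pooling)
    loss <- loss + if (params@task == "regression") (fw$pred - cmp$y)^2
                   else -log(max(fw$pred[cmp$y + 1L], 1e-300))
  }
  loss / length(data)
}

#' Train the dual-branch model
#'
#' Minimizes the task loss (mean squared error for regression, softmax
#' cross-entropy for binary classification) with Adam over hand-written
#' reverse-mode gradients of the whole model: GGNN propagation, gated
#' readout, subgraph fusion, descriptor attention/projection, convex fusion
#' and the task head. Inverted dropout is applied to the fused representation
#' during training. Training is deterministic for a fixed seed on one thread.
#'
#' @param train List of prepared compounds, each
#'   `list(graph, subs, m, y)` as built by [prepareModelData()].
#' @param val Optional validation list for early stopping.
#' @param params A [GgnnParameters-class] (initial weights).
#' @param epochs Maximum epochs (default 200).
#' @param lr Adam learning rate (default 0.01).
#' @param batchSize Minibatch size (default 32).
#' @param dropout Dropout rate on the fused vector (default 0.5).
#' @param lambdaFuse Branch mixing weight (default 0.6).
#' @param pooling Readout pooling mode.
#' @param patience Early-stopping patience in epochs (Inf disables).
#' @param seed Integer seed governing shuffling and dropout.
#' @param verbose Print one structured line per epoch.
#' @return List with elements `params` (trained [GgnnParameters-class], best
#'   validation weights when early stopping is active), `history`
#'   (data.frame epoch/trainLoss/valLoss) and the training settings.
#' @export
trainModel <- function(train, val = NULL, params, epochs = 200L, lr = 0.01,
                       batchSize = 32L, dropout = 0.5, lambdaFuse = 0.6,
                       pooling = "fused", patience = 20L, seed = 1L,
                       verbose = FALSE) {
  if (!length(train)) stop("configuration error: empty training split")
  stopifnot(is(params, "GgnnParameters"))
  set.seed(as.integer(seed))
  w <- params@weights
  state <- .adamInit(w)
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric())
  bestVal <- Inf; bestW <- w; wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(length(train))
    epochLoss <- 0; nb <- 0L
    for (start in seq(1L, length(train), by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, length(train))]
      params@weights <- w
      bg <- .batchLossGrad(train[idx], params, lambdaFuse, pooling, dropout)
      upd <- .adamStep(w, bg$grads, state, lr)
      w <- upd$w; state <- upd$state
      epochLoss <- epochLoss + bg$loss; nb <- nb + 1L
    }
    params@weights <- w
    valLoss <- if (is.null(val)) NA_real_
               else .datasetLoss(val, params, lambdaFuse, pooling)
    history <- rbind(history, data.frame(epoch = ep,
                                         trainLoss = epochLoss / nb,
                                         valLoss = valLoss))
    if (verbose)
      message(sprintf("epoch %d trainLoss %.5f valLoss %.5f", ep,
                      epochLoss / nb, valLoss))
    if (!is.null(val)) {
      if (valLoss < bestVal - 1e-9) {
        bestVal <- valLoss; bestW <- w; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  params@weights <- if (is.null(val)) w else bestW
  list(params = params, history = history,
       settings = list(lr = lr, batchSize = batchSize, dropout = dropout,
                       lambdaFuse = lambdaFuse, pooling = pooling,
                       seed = seed))
}

#' Predict properties for prepared compounds
#'
#' @param fit Result of [trainModel()] (or a list with `params` and
#'   `settings`).
#' @param data List of prepared compounds.
#' @return For regression, numeric predictions; for classification, a matrix
#'   with columns `p0`, `p1`, `call` (threshold 0.5).
#' @export
predictModel <- function(fit, data) {
  params <- fit$params
  lambdaFuse <- fit$settings$lambdaFuse %||% 0.6
  pooling <- fit$settings$pooling %||% "fused"
  if (params@task == "regression") {
    vapply(data, function(cmp)
      .forwardCompound(cmp, params, lambdaFuse, pooling)$pred, 0)
  } else {
    probs <- t(vapply(data, function(cmp)
      .forwardCompound(cmp, params, lambdaFuse, pooling)$pred, numeric(2)))
    cbind(p0 = probs[, 1], p1 = probs[, 2],
          call = as.numeric(probs[, 2] >= 0.5))
  }
}

# ---------------------------------------------------------------------------
# Metrics
# ---------------------------------------------------------------------------

#' Evaluation metrics for regression and classification
#'
#' Regression: MSE and R-squared. Classification: precision, recall and F1 of
#' the positive class at threshold 0.5, the area under the ROC curve
#' (Mann-Whitney rank formulation, ties counted half) and the area under the
#' precision-recall curve (step interpolation / average precision).
#'
#' @param pred Numeric predictions: values for regression, positive-class
#'   probabilities (or scores) for classification.
#' @param truth Numeric labels (continuous, or 0/1).
#' @param task "regression" or "classification".
#' @return Named numeric vector of metrics.
#' @export
evaluateMetrics <- function(pred, truth, task = c("regression",
                                                  "classification")) {
  task <- match.arg(task)
  stopifnot(length(pred) == length(truth))
  if (task == "regression") {
    mse <- mean((truth - pred)^2)
    r2 <- 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
    return(c(MSE = mse, R2 = r2))
  }
  calls <- as.numeric(pred >= 0.5)
  tp <- sum(calls == 1 & truth == 1)
  fp <- sum(calls == 1 & truth == 0)
  fn <- sum(calls == 0 & truth == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  pos <- pred[truth == 1]; neg <- pred[truth == 0]
  auc <- if (length(pos) && length(neg)) {
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  } else NA_real_
  aupr <- if (length(pos)) {
    ord <- order(-pred, truth)
    y <- truth[ord]
    cumTp <- cumsum(y == 1)
    prec <- cumTp / seq_along(y)
    sum(prec[y == 1]) / length(pos)   # average precision
  } else NA_real_
  c(precision = precision, recall = recall, F1 = f1, AUC = auc, AUPR = aupr)
}
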