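# Fusion, losses, gradients, training determinism, metrics.

makeCompound <- function(smi, k = 4L, y = 1, seed = 1L) {
  set.seed(seed)
  g <- molFromSmiles(smi)
  subs <- if (atomCount(g) >= 3) list(inducedSubgraph(g, 1:2),
                                      inducedSubgraph(g, 2:3))
          else list(inducedSubgraph(g, 1:2))
  list(graph = g, subs = subs, m = rnorm(k), y = y)
}

test_that("branch fusion is the exact convex combination", {
  h <- rep(1, 39); hm <- rep(0, 39)
  expect_equal(fuseRepresentations(h, hm, 1), h)
  expect_equal(fuseRepresentations(h, hm, 0), hm)
  expect_equal(fuseRepresentations(h, hm, 0.6), rep(0.6, 39))
  expect_error(fuseRepresentations(h, hm, 1.2), "configuration error")
})

test_that("training losses match their definitions", {
  expect_equal(lossRegression(c(1, 2), c(1, 2)), 0)
  expect_equal(lossRegression(c(1, 2), c(3, 2)), 2)
  e1 <- lossRegression(c(0, 0), c(1, 2))
  expect_equal(lossRegression(c(0, 0), 3 * c(1, 2)), 9 * e1)

  expect_equal(lossClassification(c(1, 0), c(1, 0)), 0)
  expect_equal(lossClassification(c(0.5, 0.5), c(0, 1)), log(2))
  expect_equal(lossClassification(c(0.8, 0.2), c(1, 0)), -log(0.8))
})

test_that("analytic gradients match central finite differences", {
  for (task in c("regression", "classification")) {
    p <- tinyParams(task = task, steps = 2L, k = 4L, seed = 17L)
    batch <- list(makeCompound("CCOC", y = if (task == "regression") 1.7 else 1,
                               seed = 2L),
                  makeCompound("c1ccccc1C", y = if (task == "regression") -0.4
                               else 0, seed = 3L))
    lossAt <- function(w) {
      p2 <- p; p2@weights <- w
      MolRank:::.batchLossGrad(batch, p2, lambdaFuse = 0.6,
                               pooling = "fused", dropout = 0)$loss
    }
    bg <- MolRank:::.batchLossGrad(batch, p, 0.6, "fused", 0)
    set.seed(99)
    eps <- 1e-6
    for (nm in c("W_o", "U_h", "b_z", "A1", "a2", "B2", "Wf", "cf", "P",
                 "Wp", "bp", if (task == "regression") "v" else "V")) {
      arr <- p@weights[[nm]]
      for (probe in seq_len(min(3, length(arr)))) {
        i <- sample(length(arr), 1)
        wPlus <- p@weights; wPlus[[nm]][i] <- wPlus[[nm]][i] + eps
        wMinus <- p@weights; wMinus[[nm]][i] <- wMinus[[nm]][i] - eps
        num <- (lossAt(wPlus) - lossAt(wMinus)) / (2 * eps)
        ana <- bg$grads[[nm]][i]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = sprintf("%s grad of %s[%d]", task, nm, i))
      }
    }
  }
})

test_that("max-only and mean-only pooling gradients are also exact", {
  p <- tinyParams(task = "regression", steps = 1L, k = 4L, seed = 23L)
  batch <- list(makeCompound("CCO", y = 0.5, seed = 5L))
  for (mode in c("mean", "max")) {
    bg <- MolRank:::.batchLossGrad(batch, p, 0.6, mode, 0)
    lossAt <- function(w) {
      p2 <- p; p2@weights <- w
      MolRank:::.batchLossGrad(batch, p2, 0.6, mode, 0)$loss
    }
    set.seed(7)
    for (nm in c("A2", "B1", "W_h")) {
      i <- sample(length(p@weights[[nm]]), 1)
      eps <- 1e-6
      wPlus <- p@weights; wPlus[[nm]][i] <- wPlus[[nm]][i] + eps
      wMinus <- p@weights; wMinus[[nm]][i] <- wMinus[[nm]][i] - eps
      num <- (lossAt(wPlus) - lossAt(wMinus)) / (2 * eps)
      expect_equal(bg$grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("%s grad of %s[%d]", mode, nm, i))
    }
  }
})

test_that("training is seed-reproducible and its loss history is sane", {
  data <- list(makeCompound("CCO", y = 1.2, seed = 1L),
               makeCompound("CCN", y = 0.3, seed = 2L),
               makeCompound("c1ccccc1", y = -0.5, seed = 3L),
               makeCompound("CCOC", y = 0.9, seed = 4L))
  p <- tinyParams(task = "regression", k = 4L, seed = 2L)
  f1 <- trainModel(data, val = NULL, p, epochs = 15, batchSize = 2,
                   dropout = 0.5, seed = 42L)
  f2 <- trainModel(data, val = NULL, p, epochs = 15, batchSize = 2,
                   dropout = 0.5, seed = 42L)
  expect_identical(f1$params@weights, f2$params@weights)
  expect_true(all(is.finite(f1$history$trainLoss)))
  runMin <- cummin(f1$history$trainLoss)
  expect_true(all(diff(runMin) <= 0))
  expect_error(trainModel(list(), val = NULL, p), "empty training split")
})

test_that("early stopping returns the best validation weights", {
  data <- lapply(1:6, function(i)
    makeCompound(c("CCO", "CCN", "CCOC", "c1ccccc1", "CC", "CCC")[i],
                 y = i / 3, seed = i))
  p <- tinyParams(task = "regression", k = 4L, seed = 3L)
  fit <- trainModel(data[1:4], val = data[5:6], p, epochs = 40,
                    batchSize = 2, dropout = 0, patience = 5, seed = 9L)
  best <- min(fit$history$valLoss, na.rm = TRUE)
  p2 <- fit$params
  got <- MolRank:::.datasetLoss(data[5:6], p2, 0.6, "fused")
  expect_equal(got, best, tolerance = 1e-10)
})

test_that("evaluation metrics agree with definitions and a rank oracle", {
  m <- evaluateMetrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                       "classification")
  expect_equal(unname(m[c("precision", "recall", "F1", "AUC")]),
               c(1, 1, 1, 1))

  y <- c(2, 4, 6, 8)
  m2 <- evaluateMetrics(rep(mean(y), 4), y, "regression")
  expect_equal(unname(m2["R2"]), 0)
  expect_equal(unname(m2["MSE"]), mean((y - mean(y))^2))

  # 8 scored samples: AUC must equal the fraction of correctly ordered
  # positive/negative pairs (ties count half)
  set.seed(12)
  score <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  truth <- c(1, 0, 1, 1, 0, 0, 1, 0)
  pairsOk <- 0; pairsAll <- 0
  for (i in which(truth == 1)) for (j in which(truth == 0)) {
    pairsAll <- pairsAll + 1
    pairsOk <- pairsOk + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  }
  m3 <- evaluateMetrics(score, truth, "classification")
  expect_equal(unname(m3["AUC"]), pairsOk / pairsAll)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE)))
    expect_equal(unname(m3["AUC"]), ref, tolerance = 1e-12)
  }
  expect_true(m3["AUPR"] >= 0 && m3["AUPR"] <= 1)
})

test_that("dropout is applied only during training", {
  p <- tinyParams(task = "regression", k = 4L, seed = 4L)
  cmp <- makeCompound("CCO", y = 1, seed = 8L)
  fit <- list(params = p, settings = list(lambdaFuse = 0.6,
                                          pooling = "fused"))
  a <- predictModel(fit, list(cmp))
  b <- predictModel(fit, list(cmp))
  expect_identical(a, b)
})
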