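#' @include model.R descriptors.R ranker.R io.R subgraph.R
NULL

#' Stratified train/validation/test split
#'
#' Splits indices 8:1:1 by default; for a binary label the split is
#' stratified so each part keeps the class balance.
#'
#' @param labels Numeric labels (binary labels are stratified; anything else
#'   is split at random).
#' @param ratios Length-3 positive weights (default `c(8, 1, 1)`).
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
splitDataset <- function(labels, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  n <- length(labels)
  if (n < 3) stop("configuration error: need at least 3 samples to split")
  set.seed(as.integer(seed))
  ratios <- ratios / sum(ratios)
  splitIdx <- function(idx) {
    idx <- sample(idx)
    nTr <- max(1L, round(length(idx) * ratios[1]))
    nVa <- max(1L, round(length(idx) * ratios[2]))
    nTr <- min(nTr, length(idx) - 2L)
    list(train = idx[seq_len(nTr)],
         val = idx[nTr + seq_len(min(nVa, length(idx) - nTr - 1L))],
         test = idx[(nTr + min(nVa, length(idx) - nTr - 1L) + 1L):length(idx)])
  }
  if (all(labels %in% c(0, 1))) {
    s0 <- splitIdx(which(labels == 0))
    s1 <- splitIdx(which(labels == 1))
    list(train = sort(c(s0$train, s1$train)),
         val = sort(c(s0$val, s1$val)),
         test = sort(c(s0$test, s1$test)))
  } else {
    splitIdx(seq_len(n))
  }
}

#' Prepare compounds for the model
#'
#' Parses each SMILES into a [MolecularGraph-class], extracts its
#' substructure members with the learned vocabulary and precomputes their
#' induced subgraphs, and standardizes the selected descriptor columns
#' (train-split statistics; pass `descStats` to apply them to held-out
#' rows).
#'
#' @param table Compound data.frame.
#' @param selected Character vector of selected descriptor names.
#' @param vocab A [SpeVocabulary-class].
#' @param config A [pipelineConfig()].
#' @param descStats Optional standardization statistics from a previous
#'   call.
#' @param labelColumn Optional column name; fills each compound's `y`.
#' @return List with `compounds` (list of prepared compounds) and
#'   `descStats`.
#' @export
prepareModelData <- function(table, selected, vocab,
                             config = pipelineConfig(), descStats = NULL,
                             labelColumn = NULL) {
  smis <- table[[config$smilesColumn]]
  vals <- as.matrix(table[, selected, drop = FALSE])
  std <- standardizeDescriptors(vals, descStats)
  y <- if (!is.null(labelColumn)) table[[labelColumn]] else rep(NA_real_,
                                                                nrow(table))
  compounds <- vector("list", nrow(table))
  graphCache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(table))) {
    smi <- smis[i]
    entry <- graphCache[[smi]]
    if (is.null(entry)) {
      g <- suppressWarnings(molFromSmiles(smi, atomVocab = config$atomVocab,
                                          massNorm = config$massNorm))
      ss <- extractSubstructures(g, vocab, config$nMaxSubstructures)
      subs <- lapply(ss@atomIndices, function(idx) inducedSubgraph(g, idx))
      entry <- list(graph = g, subs = subs)
      graphCache[[smi]] <- entry
    }
    compounds[[i]] <- list(graph = entry$graph, subs = entry$subs,
                           m = std$values[i, ], y = y[i])
  }
  list(compounds = compounds, descStats = std$stats)
}

#' Run the modelling pipeline for one prediction task
#'
#' End to end on one compound table: stratified 8:1:1 split, SMILES pair
#' encoding vocabulary learned on the training split only, boosted-tree
#' descriptor ranking on the training split (target given by
#' `selectionTarget`, default the activity column), preparation of all
#' splits, model training with early stopping on the validation loss, and
#' evaluation on the held-out test split.
#'
#' @param table Compound data.frame (see [readCompoundTable()] /
#'   [generateCompounds()]).
#' @param task Column to predict: the activity column (regression) or one of
#'   the ADMET columns (classification).
#' @param config A [pipelineConfig()]; seeds, architecture and training
#'   settings all come from here.
#' @param verbose Print per-epoch training lines.
#' @return List with `fit`, `metrics`, `predictions` (data.frame on the test
#'   split), `split`, `vocab`, `ranking`, `descStats` and `config`.
#' @export
runPipeline <- function(table, task, config = pipelineConfig(),
                        verbose = FALSE) {
  if (!task %in% names(table))
    stop("configuration error: task column '", task, "' not in table")
  isReg <- task == config$activityColumn
  split <- splitDataset(if (isReg) rep(NA_real_, nrow(table))
                        else table[[task]],
                        seed = stageSeed(config$seed, "split"))
  trainTab <- table[split$train, , drop = FALSE]

  vocab <- learnVocab(trainTab[[config$smilesColumn]],
                      maxVocab = config$maxVocab,
                      minFrequency = config$minFrequency)

  descNames <- setdiff(names(table),
                       c(config$smilesColumn, config$idColumn,
                         config$activityColumn, config$admetColumns))
  selTarget <- if (config$selectionTarget %in% names(table))
    config$selectionTarget else config$activityColumn
  ranking <- rankDescriptors(as.matrix(trainTab[, descNames, drop = FALSE]),
                             trainTab[[selTarget]], k = config$topK)
  selected <- selectedDescriptors(ranking)

  prepTr <- prepareModelData(trainTab, selected, vocab, config,
                             labelColumn = task)
  prepVa <- prepareModelData(table[split$val, , drop = FALSE], selected,
                             vocab, config, prepTr$descStats, task)
  prepTe <- prepareModelData(table[split$test, , drop = FALSE], selected,
                             vocab, config, prepTr$descStats, task)

  params <- ggnnParameters(
    hiddenDim = config$hiddenDim,
    interactionSteps = config$interactionSteps,
    descriptorK = config$topK,
    task = if (isReg) "regression" else "classification",
    seed = stageSeed(config$seed, "init"),
    shareSubgraphParams = config$shareSubgraphParams)

  fit <- trainModel(prepTr$compounds, prepVa$compounds, params,
                    epochs = config$epochs, lr = config$learningRate,
                    batchSize = config$batchSize, dropout = config$dropout,
                    lambdaFuse = config$lambdaFuse, pooling = config$pooling,
                    patience = config$patience,
                    seed = stageSeed(config$seed, "train"),
                    verbose = verbose)

  testTab <- table[split$test, , drop = FALSE]
  pred <- predictModel(fit, prepTe$compounds)
  if (isReg) {
    metrics <- evaluateMetrics(pred, testTab[[task]], "regression")
    predictions <- data.frame(compound_id = testTab[[config$idColumn]],
                              predicted = pred, truth = testTab[[task]])
  } else {
    metrics <- evaluateMetrics(pred[, "p1"], testTab[[task]],
                               "classification")
    predictions <- data.frame(compound_id = testTab[[config$idColumn]],
                              p1 = pred[, "p1"], call = pred[, "call"],
                              truth = testTab[[task]])
  }
  list(fit = fit, metrics = metrics, predictions = predictions,
       split = split, vocab = vocab, ranking = ranking,
       descStats = prepTr$descStats, config = config)
}

#' Default binary outcome behind the scorecard
#'
#' A compound is a "good candidate" when its (predicted) pIC50 exceeds the
#' set's `goodQuantile` quantile and at least `minFavorable` of the five
#' ADMET calls are favorable (favorable level 1 by convention of the
#' synthetic labels). Both thresholds are configurable and a user-supplied
#' target column can replace this construction entirely.
#'
#' @param predictions data.frame with a pIC50 column (name given by
#'   `activityColumn`) and the five ADMET call columns.
#' @param config A [pipelineConfig()].
#' @return Integer 0/1 vector.
#' @export
candidateTarget <- function(predictions, config = pipelineConfig()) {
  act <- predictions[[config$activityColumn]]
  adm <- as.matrix(predictions[, config$admetColumns, drop = FALSE])
  thr <- stats::quantile(act, config$goodQuantile, type = 7)
  as.integer(act > thr & rowSums(adm == 1) >= config$minFavorable)
}

#' Scorecard ranking from per-compound predictions
#'
#' Fits the chi-merge/WOE scorecard on the prediction table (predicted pIC50
#' as the continuous feature, ADMET calls as binary features) against the
#' good-candidate target, then scores and ranks every compound.
#'
#' @param predictions data.frame with compound_id, the activity column and
#'   the five ADMET columns (predicted values).
#' @param config A [pipelineConfig()].
#' @param target Optional user-supplied binary target; defaults to
#'   [candidateTarget()].
#' @return List with `scorecard` ([Scorecard-class]) and `ranking`
#'   (data.frame compound_id, score, rank).
#' @export
scorecardPipeline <- function(predictions, config = pipelineConfig(),
                              target = NULL) {
  if (is.null(target)) target <- candidateTarget(predictions, config)
  feats <- predictions[, c(config$activityColumn, config$admetColumns),
                       drop = FALSE]
  sc <- fitScorecard(feats, target, factor = config$scFactor,
                     offset = config$scOffset, alpha = config$scAlpha,
                     maxBins = config$scMaxBins, minBins = config$scMinBins)
  list(scorecard = sc, ranking = rankCandidates(sc, predictions))
}

#' Synthetic-data benchmark of one configuration
#'
#' Generates a synthetic compound table and runs [runPipeline()] on one
#' task; the workhorse behind the ablation experiments (branch mixing
#' weight, pooling strategy, interaction steps).
#'
#' @param seed Integer seed for both the generator and the pipeline.
#' @param task Task column (default "hERG").
#' @param nCompounds Compound count of the generated table.
#' @param spec Optional [syntheticSpec()] overriding the default conditions.
#' @param ... Config overrides passed to [pipelineConfig()].
#' @return Named numeric metric vector of the test split.
#' @export
syntheticBenchmark <- function(seed, task = "hERG", nCompounds = 120L,
                               spec = NULL, ...) {
  if (is.null(spec))
    spec <- syntheticSpec(nCompounds = nCompounds,
                          seed = stageSeed(seed, "data"))
  ds <- generateCompounds(spec)
  cfg <- pipelineConfig(seed = seed, ...)
  runPipeline(ds$table, task, cfg)$metrics
}

#' Ablation experiments on planted-signal synthetic data
#'
#' For each seed: generates one synthetic table, learns the vocabulary and
#' descriptor ranking on the training split, prepares the compounds once,
#' then trains the model under a family of configurations sharing that
#' preparation: the branch mixing weight lambda in \{0, 0.6, 1\} (0 =
#' descriptor branch only, 1 = graph branch only), mean-only / max-only /
#' fused readout pooling, and interaction steps T in \{0, 2, 6\}. Training
#' runs a fixed number of epochs (no early stopping) and every configuration
#' is evaluated on the pooled validation + test split, which keeps the
#' comparison across configurations paired and reduces small-sample metric
#' jitter.
#'
#' @param seeds Integer vector of seeds (one replicate each).
#' @param task ADMET column to predict (default "hERG").
#' @param nCompounds Compounds per replicate (default 160).
#' @param epochs Training epochs (default 25).
#' @param nMaxSubstructures Substructure cap per molecule (default 4).
#' @param batchSize Minibatch size.
#' @param verbose Print one line per trained configuration.
#' @return data.frame with columns seed, config, lambda, pooling, steps and
#'   the classification metrics.
#' @export
ablationStudy <- function(seeds = 1:5, task = "hERG", nCompounds = 160L,
                          epochs = 25L, nMaxSubstructures = 4L,
                          batchSize = 32L, verbose = FALSE) {
  # descriptorOnly/graphOnly are the lambda in {0, 1} endpoints; the
  # interaction-step sweep runs on the graph representation part alone
  # (lambda = 1, as the step ablation varies only that branch), so graphOnly
  # doubles as its T = 2 point.
  configs <- data.frame(
    config = c("fused", "descriptorOnly", "graphOnly", "meanPool", "maxPool",
               "steps0", "steps6"),
    lambda = c(0.6, 0, 1, 0.6, 0.6, 1, 1),
    pooling = c("fused", "fused", "fused", "mean", "max", "fused", "fused"),
    steps = c(2L, 2L, 2L, 2L, 2L, 0L, 6L),
    stringsAsFactors = FALSE)
  out <- list()
  for (seed in seeds) {
    cfg <- pipelineConfig(seed = seed, epochs = epochs,
                          nMaxSubstructures = nMaxSubstructures,
                          batchSize = batchSize)
    ds <- generateCompounds(syntheticSpec(nCompounds = nCompounds,
                                          seed = stageSeed(seed, "data")))
    tab <- ds$table
    split <- splitDataset(tab[[task]], seed = stageSeed(seed, "split"))
    trainTab <- tab[split$train, , drop = FALSE]
    vocab <- learnVocab(trainTab[[cfg$smilesColumn]], cfg$maxVocab,
                        cfg$minFrequency)
    descNames <- grep("^D\\d+$", names(tab), value = TRUE)
    ranking <- rankDescriptors(as.matrix(trainTab[, descNames]),
                               trainTab[[cfg$activityColumn]], k = cfg$topK)
    sel <- selectedDescriptors(ranking)
    prepTr <- prepareModelData(trainTab, sel, vocab, cfg, labelColumn = task)
    evalIdx <- sort(c(split$val, split$test))
    prepEv <- prepareModelData(tab[evalIdx, , drop = FALSE], sel, vocab,
                               cfg, prepTr$descStats, task)
    for (r in seq_len(nrow(configs))) {
      params <- ggnnParameters(
        hiddenDim = cfg$hiddenDim, interactionSteps = configs$steps[r],
        descriptorK = cfg$topK, task = "classification",
        seed = stageSeed(seed, "init"))
      fit <- trainModel(prepTr$compounds, val = NULL, params,
                        epochs = epochs, lr = cfg$learningRate,
                        batchSize = batchSize, dropout = cfg$dropout,
                        lambdaFuse = configs$lambda[r],
                        pooling = configs$pooling[r],
                        seed = stageSeed(seed, "train"))
      pred <- predictModel(fit, prepEv$compounds)
      m <- evaluateMetrics(pred[, "p1"], tab[[task]][evalIdx],
                           "classification")
      if (verbose)
        message(sprintf("seed %d %-14s F1 %.3f AUC %.3f", seed,
                        configs$config[r], m["F1"], m["AUC"]))
      out[[length(out) + 1L]] <- cbind(
        data.frame(seed = seed, configs[r, ], row.names = NULL),
        as.data.frame(as.list(m)))
    }
  }
  do.call(rbind, out)
}

#' Overfit sanity check on a tiny compound set
#'
#' Trains the regression model on a small synthetic set for a fixed number
#' of epochs with early stopping and dropout disabled; with enough capacity
#' the training MSE must collapse. Returns the final training MSE.
#'
#' @param nCompounds Training-set size (default 30).
#' @param epochs Epochs (default 500).
#' @param seed Integer seed.
#' @return Final training mean squared error.
#' @export
overfitCheck <- function(nCompounds = 30L, epochs = 500L, seed = 1L) {
  cfg <- pipelineConfig(seed = seed, nMaxSubstructures = 4L)
  ds <- generateCompounds(syntheticSpec(nCompounds = nCompounds,
                                        seed = stageSeed(seed, "data")))
  tab <- ds$table
  vocab <- learnVocab(tab$SMILES, cfg$maxVocab, minFrequency = 2L)
  descNames <- grep("^D\\d+$", names(tab), value = TRUE)
  ranking <- rankDescriptors(as.matrix(tab[, descNames]), tab$pIC50,
                             k = cfg$topK, nrounds = 50)
  prep <- prepareModelData(tab, selectedDescriptors(ranking), vocab, cfg,
                           labelColumn = "pIC50")
  params <- ggnnParameters(task = "regression", descriptorK = cfg$topK,
                           seed = stageSeed(seed, "init"))
  fit <- trainModel(prep$compounds, val = NULL, params, epochs = epochs,
                    lr = cfg$learningRate, batchSize = cfg$batchSize,
                    dropout = 0, lambdaFuse = cfg$lambdaFuse,
                    seed = stageSeed(seed, "train"))
  pred <- predictModel(fit, prep$compounds)
  mean((pred - tab$pIC50)^2)
}

#' Planted-descriptor recovery experiment
#'
#' For each replicate, generates a synthetic table with planted informative
#' descriptors among the noise columns, ranks all descriptors with the
#' boosted-tree selector against the activity label, and counts how many of
#' the planted descriptors land inside the top-k selection.
#'
#' @param replicates Number of seeded replicates (default 10).
#' @param nCompounds Compounds per replicate (default 1000).
#' @param k Selection size (default 50).
#' @param seed Base seed; replicate r uses `stageSeed(seed + r, "recovery")`.
#' @return data.frame with columns replicate, recovered, planted.
#' @export
descriptorRecovery <- function(replicates = 10L, nCompounds = 1000L,
                               k = 50L, seed = 0L) {
  out <- data.frame(replicate = seq_len(replicates), recovered = 0L,
                    planted = 0L)
  for (r in seq_len(replicates)) {
    ds <- generateCompounds(syntheticSpec(
      nCompounds = nCompounds, seed = stageSeed(seed + r, "recovery")))
    descNames <- grep("^D\\d+$", names(ds$table), value = TRUE)
    ranking <- rankDescriptors(as.matrix(ds$table[, descNames]),
                               ds$table$pIC50, k = k)
    sel <- selectedDescriptors(ranking)
    out$recovered[r] <- sum(ds$truth$informative %in% sel)
    out$planted[r] <- length(ds$truth$informative)
  }
  out
}
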