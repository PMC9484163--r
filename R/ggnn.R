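#' @include AllClasses.R molgraph.R
NULL

# All dense layers use the row-state convention: node states are rows of an
# n x d matrix and weights right-multiply (H %*% W + 1 b^T). The scalar-loop
# oracles in the test suite spell out the same formulas per node.

.initMatrix <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

.ggnnWeightSet <- function(d, k, attnDim, task, scale) {
  w <- list(
    W_o = .initMatrix(d, d, scale), b_o = numeric(d),
    W_z = .initMatrix(d, d, scale), U_z = .initMatrix(d, d, scale),
    b_z = numeric(d),
    W_r = .initMatrix(d, d, scale), U_r = .initMatrix(d, d, scale),
    b_r = numeric(d),
    W_h = .initMatrix(d, d, scale), U_h = .initMatrix(d, d, scale),
    b_h = numeric(d),
    # readout perceptrons f1 (gate) and f2 (transform), one hidden layer
    A1 = .initMatrix(d, d, scale), a1 = numeric(d),
    A2 = .initMatrix(d, d, scale), a2 = numeric(d),
    B1 = .initMatrix(d, d, scale), b1 = numeric(d),
    B2 = .initMatrix(d, d, scale), b2 = numeric(d),
    # subgraph fusion attention
    Wf = .initMatrix(d, d, scale), bf = numeric(d), cf = .initMatrix(d, 1, scale)[, 1],
    # descriptor per-position attention and projection
    P = .initMatrix(attnDim, k, scale), Q = .initMatrix(attnDim, k, scale),
    cm = .initMatrix(attnDim, 1, scale)[, 1],
    Wp = .initMatrix(d, k, scale), bp = numeric(d)
  )
  if (task == "regression") {
    w$v <- .initMatrix(d, 1, scale)[, 1]; w$v0 <- 0
  } else {
    w$V <- .initMatrix(2, d, scale); w$V0 <- numeric(2)
  }
  w
}

#' Initialize model parameters
#'
#' Creates every trainable array of the dual-branch model: GGNN propagation
#' and GRU gate weights, the two readout perceptrons, subgraph fusion
#' attention, descriptor attention/projection, and the task head. Weights are
#' uniform in +/- 1/sqrt(d); all randomness comes from `seed`.
#'
#' @param hiddenDim State width d; default 39 so raw atom features are the
#'   initial node states and both branch readouts share one size.
#' @param interactionSteps Number of propagation steps T (default 2).
#' @param descriptorK Number of selected descriptors k (default 50).
#' @param task "regression" or "classification".
#' @param attnDim Embedding width of the descriptor per-position attention.
#' @param seed Integer seed.
#' @param shareSubgraphParams If FALSE, subgraphs get their own GGNN/readout
#'   arrays (prefix "s_") instead of sharing the parent's.
#' @return A [GgnnParameters-class].
#' @export
ggnnParameters <- function(hiddenDim = 39L, interactionSteps = 2L,
                           descriptorK = 50L, task = c("regression",
                                                       "classification"),
                           attnDim = 8L, seed = 1L,
                           shareSubgraphParams = TRUE) {
  task <- match.arg(task)
  d <- as.integer(hiddenDim)
  set.seed(as.integer(seed))
  scale <- 1 / sqrt(d)
  w <- .ggnnWeightSet(d, as.integer(descriptorK), as.integer(attnDim),
                      task, scale)
  if (!shareSubgraphParams) {
    sub <- .ggnnWeightSet(d, as.integer(descriptorK), as.integer(attnDim),
                          task, scale)
    keep <- c("W_o", "b_o", "W_z", "U_z", "b_z", "W_r", "U_r", "b_r",
              "W_h", "U_h", "b_h", "A1", "a1", "A2", "a2",
              "B1", "b1", "B2", "b2")
    for (nm in keep) w[[paste0("s_", nm)]] <- sub[[nm]]
  }
  new("GgnnParameters", weights = w, hiddenDim = d,
      interactionSteps = as.integer(interactionSteps),
      descriptorK = as.integer(descriptorK), task = task)
}

# Fetch a weight, honouring the subgraph prefix when unshared params exist.
.wt <- function(w, name, prefix = "") {
  if (prefix == "") return(w[[name]])
  full <- paste0(prefix, name)
  if (!is.null(w[[full]])) w[[full]] else w[[name]]
}

# --- propagation -----------------------------------------------------------

# Forward pass with cached intermediates for backprop.
.propagateCache <- function(X, A, w, steps, prefix = "") {
  H <- X
  cache <- list(H0 = X, steps = steps, A = A, prefix = prefix)
  n <- nrow(X); d <- ncol(X)
  W_o <- .wt(w, "W_o", prefix); B_o <- matrix(.wt(w, "b_o", prefix), n, d,
                                              byrow = TRUE)
  W_z <- .wt(w, "W_z", prefix); U_z <- .wt(w, "U_z", prefix)
  B_z <- matrix(.wt(w, "b_z", prefix), n, d, byrow = TRUE)
  W_r <- .wt(w, "W_r", prefix); U_r <- .wt(w, "U_r", prefix)
  B_r <- matrix(.wt(w, "b_r", prefix), n, d, byrow = TRUE)
  W_h <- .wt(w, "W_h", prefix); U_h <- .wt(w, "U_h", prefix)
  B_h <- matrix(.wt(w, "b_h", prefix), n, d, byrow = TRUE)
  for (t in seq_len(steps)) {
    AH <- A %*% H
    O <- AH %*% W_o + B_o
    Z <- sigmoid(O %*% W_z + H %*% U_z + B_z)
    R <- sigmoid(O %*% W_r + H %*% U_r + B_r)
    RH <- R * H
    C <- tanh(O %*% W_h + RH %*% U_h + B_h)
    Hnew <- C * Z + H * (1 - Z)
    cache[[paste0("s", t)]] <- list(Hprev = H, AH = AH, O = O, Z = Z, R = R,
                                    RH = RH, C = C)
    H <- Hnew
  }
  cache$H <- H
  cache
}

#' Gated graph propagation over a molecular graph
#'
#' Runs T steps of GRU-style message passing: each node aggregates its
#' neighbours' states weighted by numeric bond order (aromatic = 1.5), then
#' updates its state through update and reset gates and a tanh candidate,
#' keeping a convex combination of candidate and previous state. With T = 0
#' the raw atom features are returned unchanged.
#'
#' @param graph A [MolecularGraph-class].
#' @param params A [GgnnParameters-class]; the graph's feature width must
#'   equal `hiddenDim`.
#' @param steps Number of interaction steps; defaults to the value stored in
#'   `params`.
#' @return Numeric matrix, atoms x hiddenDim, of final node states.
#' @export
propagate <- function(graph, params, steps = params@interactionSteps) {
  stopifnot(is(graph, "MolecularGraph"), is(params, "GgnnParameters"))
  X <- atomFeatures(graph)
  if (ncol(X) != params@hiddenDim)
    stop("configuration error: feature width ", ncol(X),
         " does not match hiddenDim ", params@hiddenDim)
  .propagateCache(X, adjacency(graph), params@weights, steps)$H
}

# --- readout ---------------------------------------------------------------

.readoutCache <- function(H, w, pooling = "fused", prefix = "") {
  n <- nrow(H); d <- ncol(H)
  T1 <- tanh(H %*% .wt(w, "A1", prefix) +
               matrix(.wt(w, "a1", prefix), n, d, byrow = TRUE))
  F1 <- T1 %*% .wt(w, "A2", prefix) +
    matrix(.wt(w, "a2", prefix), n, d, byrow = TRUE)
  S <- sigmoid(F1)
  T2 <- tanh(H %*% .wt(w, "B1", prefix) +
               matrix(.wt(w, "b1", prefix), n, d, byrow = TRUE))
  F2 <- T2 %*% .wt(w, "B2", prefix) +
    matrix(.wt(w, "b2", prefix), n, d, byrow = TRUE)
  Tt <- tanh(F2)
  G <- S * Tt
  meanPart <- colSums(G) / (n + 1)
  argmax <- max.col(t(G), ties.method = "first")
  maxPart <- G[cbind(argmax, seq_len(ncol(G)))]
  hG <- switch(pooling,
               fused = meanPart + maxPart,
               mean = meanPart,
               max = maxPart,
               stop("unknown pooling '", pooling, "'"))
  list(H = H, T1 = T1, S = S, T2 = T2, Tt = Tt, G = G, argmax = argmax,
       pooling = pooling, prefix = prefix, hG = hG)
}

#' Gated attention readout of node states
#'
#' Per node, a sigmoid gate (perceptron f1) is multiplied elementwise with a
#' tanh-transformed feature (perceptron f2); the gated vectors are aggregated
#' as a shrunken mean (divisor n + 1) plus an elementwise max-pool. The
#' `pooling` argument selects mean-only, max-only, or their sum (default),
#' the ablation hook for the readout fusion strategy.
#'
#' @param nodeStates Numeric matrix, atoms x hiddenDim.
#' @param params A [GgnnParameters-class].
#' @param pooling "fused", "mean" or "max".
#' @return Numeric vector of length hiddenDim.
#' @export
readout <- function(nodeStates, params, pooling = "fused") {
  if (is.null(dim(nodeStates)) || nrow(nodeStates) < 1L)
    stop("invalid graph: readout needs at least one node state")
  .readoutCache(nodeStates, params@weights, pooling)$hG
}

# --- subgraph fusion -------------------------------------------------------

.fuseCache <- function(vectors, w) {
  # vectors: list of length-d candidates, parent graph first
  Qs <- lapply(vectors, function(h) tanh(w$Wf %*% h + w$bf)[, 1])
  e <- vapply(Qs, function(q) sum(w$cf * q), 0)
  wts <- softmaxStable(e)
  h <- Reduce(`+`, Map(`*`, vectors, as.list(wts)))
  list(vectors = vectors, Qs = Qs, e = e, weights = wts, h = h)
}

#' Attention fusion of a graph vector with its substructure vectors
#'
#' Scores the parent-graph vector and every substructure vector with a shared
#' additive attention (e_j = c' tanh(W h_j + b)), softmax-normalizes the
#' scores, and returns the attention-weighted sum. With no substructures the
#' parent vector is returned exactly (single-entry softmax).
#'
#' @param hG Length-d parent graph vector.
#' @param subgraphVectors List of length-d substructure vectors (may be
#'   empty).
#' @param params A [GgnnParameters-class].
#' @param returnWeights If TRUE, return `list(h, weights)`.
#' @return Length-d fused vector, or a list when `returnWeights`.
#' @export
fuseSubgraphs <- function(hG, subgraphVectors = list(), params,
                          returnWeights = FALSE) {
  stopifnot(is(params, "GgnnParameters"))
  fc <- .fuseCache(c(list(hG), subgraphVectors), params@weights)
  if (returnWeights) list(h = fc$h, weights = fc$weights) else fc$h
}

#' Topological representation of one molecule
#'
#' Convenience wrapper: propagate + readout on the parent graph, the same on
#' every substructure member (induced subgraphs, shared or dedicated
#' parameters), then attention fusion into a single vector.
#'
#' @param graph A [MolecularGraph-class].
#' @param substructures A [SubstructureSet-class] (or NULL for none).
#' @param params A [GgnnParameters-class].
#' @param pooling Readout pooling mode.
#' @return Length-hiddenDim numeric vector.
#' @export
graphRepresentation <- function(graph, substructures = NULL, params,
                                pooling = "fused") {
  hG <- readout(propagate(graph, params), params, pooling)
  subVecs <- list()
  if (!is.null(substructures) && length(substructures@tokens)) {
    prefix <- if (!is.null(params@weights$s_W_o)) "s_" else ""
    subVecs <- lapply(substructures@atomIndices, function(idx) {
      sg <- inducedSubgraph(graph, idx)
      cc <- .propagateCache(atomFeatures(sg), adjacency(sg), params@weights,
                            params@interactionSteps, prefix)
      .readoutCache(cc$H, params@weights, pooling, prefix)$hG
    })
  }
  fuseSubgraphs(hG, subVecs, params)
}

#' Save / load parameter checkpoints
#'
#' Serializes a [GgnnParameters-class] together with a hash of its
#' configuration; loading verifies the hash so a checkpoint cannot silently
#' be applied under a different architecture.
#'
#' @param params A [GgnnParameters-class].
#' @param path File path.
#' @return `path` invisibly; `loadCheckpoint` returns the parameters.
#' @export
saveCheckpoint <- function(params, path) {
  stopifnot(is(params, "GgnnParameters"))
  cfg <- c(params@hiddenDim, params@interactionSteps, params@descriptorK,
           match(params@task, c("regression", "classification")))
  saveRDS(list(weights = params@weights, config = cfg,
               hash = sum(cfg * seq_along(cfg))), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  if (x$hash != sum(x$config * seq_along(x$config)))
    stop("checkpoint config hash mismatch: ", path)
  new("GgnnParameters", weights = x$weights, hiddenDim = x$config[1],
      interactionSteps = x$config[2], descriptorK = x$config[3],
      task = c("regression", "classification")[x$config[4]])
}
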