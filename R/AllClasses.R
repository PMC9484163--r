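#' @import methods
NULL

#' Block sizes of the atom featurization, in concatenation order
#'
#' The row length of every atom feature matrix is their sum (39).
#' @export
ATOM_FEATURE_BLOCKS <- c(
  atom_type = 12L, n_bonds = 6L, formal_charge = 5L, chirality = 4L,
  n_hydrogens = 5L, hybridization = 5L, aromaticity = 1L, mass = 1L
)

#' Default 12-element atom-type vocabulary
#'
#' Frozen ordering of the atom-type one-hot block; feature column j always
#' means the same category. Unlisted elements encode as all-zero with a
#' warning.
#' @export
DEFAULT_ATOM_VOCAB <- c("C", "N", "O", "S", "F", "Cl", "Br", "I",
                        "P", "B", "Si", "Se")
CHARGE_LEVELS <- c(-2L, -1L, 0L, 1L, 2L)
CHIRALITY_LEVELS <- c("CW", "CCW", "unspecified", "other")
HYBRIDIZATION_LEVELS <- c("sp", "sp2", "sp3", "sp3d", "sp3d2")
VALID_BOND_ORDERS <- c(0, 1, 1.5, 2, 3)

#' MolecularGraph: atom-level graph of one compound
#'
#' Holds the heavy-atom graph parsed from a SMILES string: a 39-column atom
#' feature matrix (one-hot blocks for atom type, degree, formal charge,
#' chirality, bound hydrogens, hybridization, aromaticity, plus a normalized
#' mass) and a symmetric adjacency matrix whose entries encode bond order
#' (1 single, 2 double, 3 triple, 1.5 aromatic, 0 no bond). Atom order is the
#' order of first appearance in the SMILES string and is shared by all
#' downstream operations.
#'
#' @slot smiles Character SMILES string the graph was parsed from.
#' @slot atomFeatures Numeric matrix, atoms x 39.
#' @slot adjacency Numeric symmetric matrix, atoms x atoms.
#' @slot atomInfo data.frame of per-atom perception (symbol, degree, charge,
#'   chirality, nH, hybridization, aromatic flag, mass) kept for inspection.
#' @export
setClass("MolecularGraph",
  representation(smiles = "character",
                 atomFeatures = "matrix",
                 adjacency = "matrix",
                 atomInfo = "data.frame"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@atomFeatures)
    A <- object@adjacency
    if (ncol(object@atomFeatures) != sum(ATOM_FEATURE_BLOCKS))
      msg <- c(msg, sprintf("atomFeatures must have %d columns",
                            sum(ATOM_FEATURE_BLOCKS)))
    if (!all(dim(A) == c(n, n)))
      msg <- c(msg, "adjacency dimensions must match atom count")
    if (n > 0) {
      if (max(abs(A - t(A))) > 0)
        msg <- c(msg, "adjacency must be symmetric")
      if (any(diag(A) != 0))
        msg <- c(msg, "adjacency diagonal must be zero")
      if (!all(A %in% VALID_BOND_ORDERS))
        msg <- c(msg, "adjacency entries must be in {0, 1, 1.5, 2, 3}")
      m <- object@atomFeatures[, sum(ATOM_FEATURE_BLOCKS), drop = TRUE]
      if (any(m < 0 | m > 1))
        msg <- c(msg, "mass feature must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  }
)

#' SpeVocabulary: SMILES pair encoding merge table
#'
#' An ordered list of token-pair merge rules learned over a SMILES corpus by
#' byte-pair-encoding style counting, together with the multi-character tokens
#' the merges produce and their corpus frequencies. Applying the merges in
#' order to any atomwise-tokenized SMILES is deterministic.
#'
#' @slot merges data.frame with columns first, second, frequency (one merge
#'   rule per row, in learning order).
#' @slot tokens data.frame with columns token, frequency for every retained
#'   multi-atom token.
#' @slot minFrequency Integer; merges below this corpus frequency were not
#'   learned.
#' @slot maxVocab Integer cap on the number of merges.
#' @export
setClass("SpeVocabulary",
  representation(merges = "data.frame", tokens = "data.frame",
                 minFrequency = "integer", maxVocab = "integer"),
  validity = function(object) {
    msg <- character()
    if (!all(c("first", "second", "frequency") %in% colnames(object@merges)))
      msg <- c(msg, "merges needs columns first, second, frequency")
    if (nrow(object@merges) && any(object@merges$frequency < object@minFrequency))
      msg <- c(msg, "all merges must reach minFrequency")
    if (length(msg)) msg else TRUE
  }
)

#' SubstructureSet: substructure tokens of one molecule
#'
#' Multi-atom tokens found in a molecule's SPE tokenization, each mapped to
#' the heavy-atom indices it spans in the parent MolecularGraph. Members are
#' ordered by descending corpus frequency, ties broken lexicographically.
#'
#' @slot parentSmiles SMILES of the parent molecule.
#' @slot tokens Character vector of substructure token strings.
#' @slot atomIndices List of integer vectors (1-based indices into the parent
#'   graph), parallel to tokens; every set has at least two atoms.
#' @slot frequencies Numeric corpus frequencies, parallel to tokens.
#' @export
setClass("SubstructureSet",
  representation(parentSmiles = "character", tokens = "character",
                 atomIndices = "list", frequencies = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@tokens) != length(object@atomIndices) ||
        length(object@tokens) != length(object@frequencies))
      msg <- c(msg, "tokens, atomIndices and frequencies must be parallel")
    if (any(vapply(object@atomIndices, length, 1L) < 2L))
      msg <- c(msg, "every member must span at least 2 atoms")
    if (length(msg)) msg else TRUE
  }
)

#' GgnnParameters: weights of the gated graph network and heads
#'
#' Container for every trainable array of the dual-branch model: GGNN
#' propagation and gate weights, the two readout perceptrons, subgraph fusion
#' attention, descriptor attention/projection, and the task head. Created by
#' [ggnnParameters()]; the weights slot is a named list of numeric arrays.
#'
#' @slot weights Named list of numeric matrices/vectors.
#' @slot hiddenDim Integer state width d (39 so atom features need no input
#'   projection and both branch readouts share one size).
#' @slot interactionSteps Integer number of propagation steps T.
#' @slot descriptorK Integer number of selected descriptors feeding the
#'   descriptor branch.
#' @slot task Character, "regression" or "classification".
#' @export
setClass("GgnnParameters",
  representation(weights = "list", hiddenDim = "integer",
                 interactionSteps = "integer", descriptorK = "integer",
                 task = "character"),
  validity = function(object) {
    d <- object@hiddenDim
    w <- object@weights
    need <- c("W_o", "b_o", "W_z", "U_z", "b_z", "W_r", "U_r", "b_r",
              "W_h", "U_h", "b_h")
    if (!all(need %in% names(w)))
      return("missing GGNN weight arrays")
    if (!all(dim(w$W_o) == c(d, d)))
      return("W_o must be hiddenDim x hiddenDim")
    if (object@interactionSteps < 0L)
      return("interactionSteps must be >= 0")
    TRUE
  }
)

#' BinningResult: chi-merge bins of one feature
#'
#' @slot featureName Character feature label.
#' @slot binEdges Numeric cut points (length bins + 1, -Inf/Inf at the ends).
#' @slot counts Integer matrix bins x 2 (negative, positive class counts).
#' @slot woe Numeric weight-of-evidence value per bin.
#' @slot degenerate Logical; TRUE when a zero marginal forced merging.
#' @export
setClass("BinningResult",
  representation(featureName = "character", binEdges = "numeric",
                 counts = "matrix", woe = "numeric", degenerate = "logical"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@counts) != length(object@woe))
      msg <- c(msg, "one woe value per bin required")
    if (length(object@binEdges) != nrow(object@counts) + 1L)
      msg <- c(msg, "binEdges must have bins + 1 entries")
    if (is.unsorted(object@binEdges, strictly = TRUE))
      msg <- c(msg, "binEdges must be strictly increasing")
    if (any(!is.finite(object@woe)))
      msg <- c(msg, "woe must be finite after smoothing")
    if (length(msg)) msg else TRUE
  }
)

#' Scorecard: additive points model over binned, WOE-encoded features
#'
#' Maps a compound's predicted properties to a single score: each feature is
#' binned, the bin's weight of evidence is multiplied by the logistic
#' regression coefficient, shifted by the shared intercept a/n, scaled by
#' `factor` and offset by `offset`/n; the score is the sum over features.
#'
#' @slot binnings List of [BinningResult-class] objects, one per feature.
#' @slot coefficients Named numeric logistic coefficients (per feature).
#' @slot intercept Numeric intercept a.
#' @slot factor Numeric scale factor.
#' @slot offset Numeric global offset.
#' @slot pointsTable data.frame with feature, bin, woe, points for reporting.
#' @export
setClass("Scorecard",
  representation(binnings = "list", coefficients = "numeric",
                 intercept = "numeric", factor = "numeric", offset = "numeric",
                 pointsTable = "data.frame"),
  validity = function(object) {
    if (length(object@binnings) != length(object@coefficients))
      return("one coefficient per binned feature required")
    TRUE
  }
)

#' DescriptorRanking: boosted-tree importance ranking of descriptors
#'
#' @slot rankedNames Character descriptor names, most important first.
#' @slot scores Numeric importance (total gain), nonincreasing.
#' @slot k Integer selection size.
#' @slot fallback Logical; TRUE when a degenerate target forced the variance
#'   fallback ranking.
#' @export
setClass("DescriptorRanking",
  representation(rankedNames = "character", scores = "numeric",
                 k = "integer", fallback = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@rankedNames) != length(object@scores))
      msg <- c(msg, "rankedNames and scores must be parallel")
    if (length(object@scores) > 1 && any(diff(object@scores) > 1e-12))
      msg <- c(msg, "scores must be nonincreasing")
    if (object@k > length(object@rankedNames))
      msg <- c(msg, "k cannot exceed the number of descriptors")
    if (length(msg)) msg else TRUE
  }
)
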