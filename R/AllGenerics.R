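#' @include AllClasses.R
NULL

#' Number of heavy atoms in a molecular graph
#' @param x A [MolecularGraph-class].
#' @return Integer atom count.
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' Atom feature matrix accessor
#' @param x A [MolecularGraph-class].
#' @return Numeric matrix, atoms x 39.
#' @export
setGeneric("atomFeatures", function(x) standardGeneric("atomFeatures"))

#' Bond-order adjacency matrix accessor
#' @param x A [MolecularGraph-class].
#' @return Numeric symmetric matrix with entries in \{0, 1, 1.5, 2, 3\}.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' SMILES string accessor
#' @param x A [MolecularGraph-class] or [SubstructureSet-class].
#' @return Character SMILES.
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' @rdname atomCount
#' @export
setMethod("atomCount", "MolecularGraph", function(x) nrow(x@atomFeatures))

#' @rdname atomFeatures
#' @export
setMethod("atomFeatures", "MolecularGraph", function(x) x@atomFeatures)

#' @rdname adjacency
#' @export
setMethod("adjacency", "MolecularGraph", function(x) x@adjacency)

#' @rdname smiles
#' @export
setMethod("smiles", "MolecularGraph", function(x) x@smiles)

#' @rdname smiles
#' @export
setMethod("smiles", "SubstructureSet", function(x) x@parentSmiles)

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %s\n  %d heavy atoms, %d bonds\n",
              object@smiles, atomCount(object),
              sum(object@adjacency > 0) / 2))
})

setMethod("show", "SpeVocabulary", function(object) {
  cat(sprintf("SpeVocabulary: %d merges (maxVocab %d, minFrequency %d)\n",
              nrow(object@merges), object@maxVocab, object@minFrequency))
  if (nrow(object@tokens)) {
    top <- utils::head(object@tokens[order(-object@tokens$frequency), ], 5)
    cat("  top tokens:", paste(top$token, collapse = " "), "\n")
  }
})

setMethod("show", "SubstructureSet", function(object) {
  cat(sprintf("SubstructureSet of %s: %d members\n",
              object@parentSmiles, length(object@tokens)))
  if (length(object@tokens))
    cat(" ", paste(sprintf("%s{%s}", object@tokens,
                           vapply(object@atomIndices,
                                  function(i) paste(i, collapse = ","), "")),
                   collapse = "  "), "\n")
})

setMethod("show", "GgnnParameters", function(object) {
  cat(sprintf(
    "GgnnParameters: d=%d, T=%d, k=%d, task=%s (%d arrays, %d values)\n",
    object@hiddenDim, object@interactionSteps, object@descriptorK,
    object@task, length(object@weights),
    sum(vapply(object@weights, length, 1L))))
})

setMethod("show", "BinningResult", function(object) {
  cat(sprintf("BinningResult for '%s': %d bins%s\n", object@featureName,
              nrow(object@counts),
              if (object@degenerate) " (degenerate marginal)" else ""))
})

setMethod("show", "Scorecard", function(object) {
  cat(sprintf("Scorecard: %d features, factor %.4f, offset %.1f\n",
              length(object@binnings), object@factor, object@offset))
})

setMethod("show", "DescriptorRanking", function(object) {
  cat(sprintf("DescriptorRanking: %d descriptors ranked, top %d selected%s\n",
              length(object@rankedNames), object@k,
              if (object@fallback) " (variance fallback)" else ""))
  cat("  head:", paste(utils::head(object@rankedNames, 5), collapse = ", "),
      "\n")
})
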