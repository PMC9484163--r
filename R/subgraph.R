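#' @include AllClasses.R molgraph.R
NULL

# Count atoms inside a (possibly merged) token string.
.tokenAtomCount <- function(token) {
  tryCatch(sum(tokenizeSmiles(token)$isAtom), error = function(e) 0L)
}

# Apply one merge rule to a token sequence, left to right, non-overlapping.
# `extra` is an optional parallel list (atom-index vectors) merged alongside.
.applyMerge <- function(tokens, first, second, extra = NULL) {
  i <- 1L
  while (i < length(tokens)) {
    if (tokens[i] == first && tokens[i + 1L] == second) {
      tokens[i] <- paste0(first, second)
      tokens <- tokens[-(i + 1L)]
      if (!is.null(extra)) {
        extra[[i]] <- c(extra[[i]], extra[[i + 1L]])
        extra[[i + 1L]] <- NULL
      }
    }
    i <- i + 1L
  }
  list(tokens = tokens, extra = extra)
}

#' Learn a SMILES pair encoding vocabulary
#'
#' Byte-pair-encoding style merge learning over atomwise SMILES tokens: the
#' corpus is tokenized with [tokenizeSmiles()], then the most frequent
#' adjacent token pair is repeatedly merged into a new token, until
#' `maxVocab` merges have been learned or no pair reaches `minFrequency`.
#' Ties between equally frequent pairs break lexicographically so learning
#' is deterministic.
#'
#' @param corpus Character vector of SMILES strings (typically the training
#'   split only, to avoid leakage into held-out evaluation).
#' @param maxVocab Maximum number of merges (default 300).
#' @param minFrequency Minimum corpus frequency for a merge (default 5).
#' @return A [SpeVocabulary-class].
#' @examples
#' v <- learnVocab(rep("CCO", 10), maxVocab = 2, minFrequency = 2)
#' @export
learnVocab <- function(corpus, maxVocab = 300L, minFrequency = 5L) {
  if (!length(corpus) || !is.character(corpus))
    stop("configuration error: corpus must be a non-empty character vector")
  if (maxVocab < 1L)
    stop("configuration error: maxVocab must be >= 1")
  seqs <- lapply(corpus, function(s) tokenizeSmiles(s)$token)
  merges <- data.frame(first = character(), second = character(),
                       frequency = integer(), stringsAsFactors = FALSE)
  for (step in seq_len(maxVocab)) {
    pairFirst <- character(); pairSecond <- character()
    for (s in seqs) {
      if (length(s) < 2L) next
      pairFirst <- c(pairFirst, s[-length(s)])
      pairSecond <- c(pairSecond, s[-1L])
    }
    if (!length(pairFirst)) break
    key <- paste(pairFirst, pairSecond, sep = "\r")
    tab <- table(key)
    best <- sort(names(tab)[tab == max(tab)])[1L]  # lexicographic tie-break
    freq <- as.integer(max(tab))
    if (freq < minFrequency) break
    parts <- strsplit(best, "\r", fixed = TRUE)[[1]]
    merges <- rbind(merges, data.frame(first = parts[1], second = parts[2],
                                       frequency = freq,
                                       stringsAsFactors = FALSE))
    seqs <- lapply(seqs, function(s)
      .applyMerge(s, parts[1], parts[2])$tokens)
  }
  final <- unlist(seqs)
  multi <- vapply(unique(final), .tokenAtomCount, 0L) >= 2L
  tab <- table(final)[unique(final)[multi]]
  tokens <- data.frame(token = names(tab), frequency = as.integer(tab),
                       stringsAsFactors = FALSE)
  tokens <- tokens[tokens$frequency >= minFrequency, , drop = FALSE]
  tokens <- tokens[order(-tokens$frequency, tokens$token), , drop = FALSE]
  rownames(tokens) <- NULL
  new("SpeVocabulary", merges = merges, tokens = tokens,
      minFrequency = as.integer(minFrequency), maxVocab = as.integer(maxVocab))
}

#' Tokenize a SMILES string with a learned vocabulary
#'
#' Replays the vocabulary's merge rules, in learning order, over the atomwise
#' tokenization. Concatenating the returned tokens reproduces the input
#' string exactly.
#'
#' @param smi SMILES string.
#' @param vocab A [SpeVocabulary-class].
#' @return data.frame with columns `token` and `atomIndices` (list column of
#'   1-based heavy-atom indices covered by each token).
#' @export
applyVocab <- function(smi, vocab) {
  base <- tokenizeSmiles(smi)
  tokens <- base$token
  idx <- lapply(seq_len(nrow(base)), function(r)
    if (base$isAtom[r]) base$atomIndex[r] else integer())
  for (m in seq_len(nrow(vocab@merges))) {
    res <- .applyMerge(tokens, vocab@merges$first[m], vocab@merges$second[m],
                       extra = idx)
    tokens <- res$tokens
    idx <- res$extra
  }
  out <- data.frame(token = tokens, stringsAsFactors = FALSE)
  out$atomIndices <- idx
  out
}

#' Extract substructure subgraph members of one molecule
#'
#' Tokenizes the molecule's SMILES with the learned vocabulary and maps each
#' multi-atom token to the heavy-atom indices it spans. Members are ordered
#' by descending corpus frequency (ties lexicographic) and capped at `nMax`.
#' Tokens covering fewer than two atoms (ring-closure digits, brackets,
#' punctuation runs) are discarded; a molecule with no multi-atom token
#' yields an empty set.
#'
#' @param graph A [MolecularGraph-class].
#' @param vocab A [SpeVocabulary-class].
#' @param nMax Maximum number of members retained (default 8).
#' @return A [SubstructureSet-class].
#' @export
extractSubstructures <- function(graph, vocab, nMax = 8L) {
  stopifnot(is(graph, "MolecularGraph"), is(vocab, "SpeVocabulary"),
            nMax >= 0L)
  tk <- applyVocab(smiles(graph), vocab)
  nAtoms <- vapply(tk$atomIndices, length, 1L)
  keep <- which(nAtoms >= 2L)
  tokens <- tk$token[keep]
  idx <- tk$atomIndices[keep]
  freq <- vocab@tokens$frequency[match(tokens, vocab@tokens$token)]
  freq[is.na(freq)] <- 0
  ord <- order(-freq, tokens)
  take <- utils::head(ord, nMax)
  new("SubstructureSet", parentSmiles = smiles(graph),
      tokens = tokens[take], atomIndices = idx[take],
      frequencies = as.numeric(freq[take]))
}

#' Vertex-induced subgraph of a molecular graph
#'
#' Restricts a [MolecularGraph-class] to a set of atoms: feature rows are the
#' parent rows; adjacency is the parent submatrix, so ring-closure bonds
#' internal to the atom set are kept even when not contiguous in the SMILES
#' string.
#'
#' @param graph A [MolecularGraph-class].
#' @param atomIdx Integer vector of 1-based atom indices, length >= 2.
#' @return A [MolecularGraph-class] over the selected atoms.
#' @export
inducedSubgraph <- function(graph, atomIdx) {
  stopifnot(is(graph, "MolecularGraph"))
  atomIdx <- sort(unique(as.integer(atomIdx)))
  if (length(atomIdx) < 2L)
    stop("an induced subgraph needs at least 2 atoms")
  if (any(atomIdx < 1L | atomIdx > atomCount(graph)))
    stop("atom index out of range [1, ", atomCount(graph), "]")
  new("MolecularGraph",
      smiles = graph@smiles,
      atomFeatures = graph@atomFeatures[atomIdx, , drop = FALSE],
      adjacency = graph@adjacency[atomIdx, atomIdx, drop = FALSE],
      atomInfo = graph@atomInfo[atomIdx, , drop = FALSE])
}

#' Write / read a vocabulary as a plain-text merge table
#'
#' One merge per line (`first<TAB>second<TAB>frequency`), followed by the
#' retained multi-atom tokens with their frequencies, so a run can be
#' reproduced bit-exactly from the file alone.
#'
#' @param vocab A [SpeVocabulary-class].
#' @param path File path.
#' @return `path` invisibly; `readVocabulary` returns the
#'   [SpeVocabulary-class].
#' @export
writeVocabulary <- function(vocab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spe-vocabulary maxVocab=%d minFrequency=%d",
                     vocab@maxVocab, vocab@minFrequency), con)
  writeLines("[merges]", con)
  if (nrow(vocab@merges))
    writeLines(sprintf("%s\t%s\t%d", vocab@merges$first, vocab@merges$second,
                       vocab@merges$frequency), con)
  writeLines("[tokens]", con)
  if (nrow(vocab@tokens))
    writeLines(sprintf("%s\t%d", vocab@tokens$token, vocab@tokens$frequency),
               con)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  lines <- readLines(path)
  hd <- regmatches(lines[1],
                   regexec("maxVocab=(\\d+) minFrequency=(\\d+)", lines[1]))[[1]]
  if (length(hd) != 3) stop("not a vocabulary file: ", path)
  mStart <- which(lines == "[merges]")
  tStart <- which(lines == "[tokens]")
  parse3 <- function(ls) {
    if (!length(ls)) return(data.frame(first = character(),
                                       second = character(),
                                       frequency = integer()))
    parts <- strsplit(ls, "\t", fixed = TRUE)
    data.frame(first = vapply(parts, `[`, "", 1),
               second = vapply(parts, `[`, "", 2),
               frequency = as.integer(vapply(parts, `[`, "", 3)),
               stringsAsFactors = FALSE)
  }
  mergeLines <- lines[seq.int(mStart + 1L, length.out = tStart - mStart - 1L)]
  tokLines <- if (tStart < length(lines)) lines[(tStart + 1L):length(lines)]
              else character()
  toks <- if (length(tokLines)) {
    parts <- strsplit(tokLines, "\t", fixed = TRUE)
    data.frame(token = vapply(parts, `[`, "", 1),
               frequency = as.integer(vapply(parts, `[`, "", 2)),
               stringsAsFactors = FALSE)
  } else data.frame(token = character(), frequency = integer())
  new("SpeVocabulary", merges = parse3(mergeLines), tokens = toks,
      minFrequency = as.integer(hd[3]), maxVocab = as.integer(hd[2]))
}
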