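#' @include AllClasses.R
NULL

# Standard atomic masses for the elements the featurizer expects to meet.
ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.086, P = 30.974, S = 32.06,
                 Cl = 35.453, Se = 78.971, Br = 79.904, I = 126.904)

# Smallest-first allowed valences used to derive implicit hydrogen counts for
# organic-subset atoms (standard SMILES valence model).
DEFAULT_VALENCE <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                        S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

.SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]*\\]",      # bracket atom
  "|Br|Cl",             # two-letter organic-subset elements
  "|[BCNOPSFI]",        # one-letter organic-subset elements
  "|[bcnops]",          # aromatic organic-subset elements
  "|%[0-9]{2}|[0-9]",   # ring-bond labels
  "|[-=#:/\\\\().]"     # bonds, branches, dot
)

#' Tokenize a SMILES string atomwise
#'
#' Splits a SMILES string into its lexical tokens: bracket atoms and
#' two-letter elements are single tokens; ring-closure digits, bond symbols
#' and parentheses are their own tokens. Each atom token carries the 1-based
#' index of the heavy atom it introduces, which is how substructure tokens
#' are later mapped back onto graph vertices.
#'
#' @param smi Character SMILES string.
#' @return data.frame with columns `token`, `isAtom`, `atomIndex` (NA for
#'   non-atom tokens).
#' @examples
#' tokenizeSmiles("c1ccccc1Cl")
#' @export
tokenizeSmiles <- function(smi) {
  stopifnot(is.character(smi), length(smi) == 1L, !is.na(smi))
  m <- gregexpr(.SMILES_TOKEN_RE, smi, perl = TRUE)
  toks <- regmatches(smi, m)[[1]]
  if (sum(nchar(toks)) != nchar(smi))
    stop("unrecognized characters in SMILES: '", smi, "'")
  isAtom <- grepl("^\\[|^Br$|^Cl$|^[BCNOPSFIbcnops]$", toks)
  atomIndex <- rep(NA_integer_, length(toks))
  atomIndex[isAtom] <- seq_len(sum(isAtom))
  data.frame(token = toks, isAtom = isAtom, atomIndex = atomIndex,
             stringsAsFactors = FALSE)
}

# Parse the content of a bracket atom token "[...]". Returns symbol,
# aromatic flag, charge, explicit H count and the 4-way chirality tag.
.parseBracketAtom <- function(tok, smi) {
  body <- substr(tok, 2L, nchar(tok) - 1L)
  re <- "^([0-9]*)([A-Za-z][a-z]?|\\*)(@@|@)?(H[0-9]?)?([+-][0-9]?|\\+{2,3}|-{2,3})?(:[0-9]+)?$"
  m <- regmatches(body, regexec(re, body))[[1]]
  if (length(m) == 0L)
    stop("cannot parse bracket atom '", tok, "' in SMILES '", smi, "'")
  sym <- m[3]
  aromatic <- sym == tolower(sym) && sym != "*"
  symbol <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  chir <- switch(m[4], "@" = "CCW", "@@" = "CW", "unspecified")
  hTok <- m[5]
  nH <- if (!nzchar(hTok)) 0L
        else if (hTok == "H") 1L
        else as.integer(substring(hTok, 2))
  cTok <- m[6]
  charge <- if (!nzchar(cTok)) 0L
            else if (cTok %in% c("+", "-")) ifelse(cTok == "+", 1L, -1L)
            else if (grepl("^[+-][0-9]$", cTok))
              as.integer(substr(cTok, 2, 2)) * ifelse(substr(cTok, 1, 1) == "+", 1L, -1L)
            else nchar(cTok) * ifelse(substr(cTok, 1, 1) == "+", 1L, -1L)
  list(symbol = symbol, aromatic = aromatic, charge = charge,
       nH = nH, chirality = chir, bracket = TRUE)
}

# Full SMILES parser: atoms, bonds (with order resolution), ring closures.
# Returns list(atoms = data.frame, bonds = data.frame(i, j, order)).
.parseSmiles <- function(smi) {
  toks <- tokenizeSmiles(smi)
  if (any(toks$token == "."))
    stop("disconnected SMILES (dot) not supported: '", smi, "'")
  atoms <- list()
  bonds <- list()      # each: list(i, j, spec)
  stack <- integer()   # branch return points
  prev <- NA_integer_
  pending <- "default"
  rings <- list()      # label -> list(atom, spec)
  bondSpec <- c("-" = "single", "=" = "double", "#" = "triple",
                ":" = "aromatic", "/" = "single", "\\" = "single")

  for (r in seq_len(nrow(toks))) {
    tk <- toks$token[r]
    if (toks$isAtom[r]) {
      a <- if (startsWith(tk, "[")) .parseBracketAtom(tk, smi)
           else list(symbol = paste0(toupper(substr(tk, 1, 1)), substring(tk, 2)),
                     aromatic = tk == tolower(tk),
                     charge = 0L, nH = NA_integer_,
                     chirality = "unspecified", bracket = FALSE)
      atoms[[length(atoms) + 1L]] <- a
      idx <- length(atoms)
      if (!is.na(prev))
        bonds[[length(bonds) + 1L]] <- list(i = prev, j = idx, spec = pending)
      prev <- idx
      pending <- "default"
    } else if (tk %in% names(bondSpec)) {
      pending <- bondSpec[[tk]]
    } else if (tk == "(") {
      if (is.na(prev)) stop("branch before any atom in SMILES '", smi, "'")
      stack <- c(stack, prev)
    } else if (tk == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES '", smi, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("^%?[0-9]", tk)) {
      lab <- sub("^%", "", tk)
      if (is.na(prev)) stop("ring bond before any atom in SMILES '", smi, "'")
      if (is.null(rings[[lab]])) {
        rings[[lab]] <- list(atom = prev, spec = pending)
      } else {
        op <- rings[[lab]]
        spec <- if (pending != "default") pending
                else if (op$spec != "default") op$spec
                else "default"
        if (pending != "default" && op$spec != "default" && pending != op$spec)
          stop("conflicting ring-bond orders for label ", lab,
               " in SMILES '", smi, "'")
        bonds[[length(bonds) + 1L]] <- list(i = op$atom, j = prev, spec = spec)
        rings[[lab]] <- NULL
      }
      pending <- "default"
    } else {
      stop("unexpected token '", tk, "' in SMILES '", smi, "'")
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES '", smi, "'")
  if (length(rings)) stop("unclosed ring bond(s) ",
                          paste(names(rings), collapse = ", "),
                          " in SMILES '", smi, "'")
  if (!length(atoms)) stop("no atoms parsed from SMILES '", smi, "'")

  at <- data.frame(
    symbol = vapply(atoms, `[[`, "", "symbol"),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    nH = vapply(atoms, `[[`, NA_integer_, "nH"),
    chirality = vapply(atoms, `[[`, "", "chirality"),
    bracket = vapply(atoms, `[[`, TRUE, "bracket"),
    stringsAsFactors = FALSE)

  bd <- if (length(bonds))
    data.frame(i = vapply(bonds, `[[`, 0L, "i"),
               j = vapply(bonds, `[[`, 0L, "j"),
               spec = vapply(bonds, `[[`, "", "spec"),
               stringsAsFactors = FALSE)
  else data.frame(i = integer(), j = integer(), spec = character())

  # Default bonds between two aromatic atoms are aromatic only when the edge
  # lies in a ring (an edge is in a ring iff it is not a bridge).
  inRing <- rep(FALSE, nrow(bd))
  if (nrow(bd)) {
    g <- igraph::graph_from_edgelist(cbind(bd$i, bd$j), directed = FALSE)
    br <- igraph::bridges(g)
    inRing <- !(seq_len(nrow(bd)) %in% as.integer(br))
  }
  order <- numeric(nrow(bd))
  for (b in seq_len(nrow(bd))) {
    order[b] <- switch(bd$spec[b],
      single = 1, double = 2, triple = 3, aromatic = 1.5,
      default = if (at$aromatic[bd$i[b]] && at$aromatic[bd$j[b]] && inRing[b])
        1.5 else 1)
  }
  bd$order <- order
  list(atoms = at, bonds = bd)
}

# Derive degree, implicit hydrogens and hybridization from the parsed graph.
.perceiveAtoms <- function(parsed, smi) {
  at <- parsed$atoms
  bd <- parsed$bonds
  n <- nrow(at)
  degree <- integer(n); bondSum <- numeric(n)
  nDouble <- integer(n); nTriple <- integer(n); nArom <- integer(n)
  for (b in seq_len(nrow(bd))) {
    for (v in c(bd$i[b], bd$j[b])) {
      degree[v] <- degree[v] + 1L
      bondSum[v] <- bondSum[v] + bd$order[b]
      if (bd$order[b] == 2) nDouble[v] <- nDouble[v] + 1L
      if (bd$order[b] == 3) nTriple[v] <- nTriple[v] + 1L
      if (bd$order[b] == 1.5) nArom[v] <- nArom[v] + 1L
    }
  }
  nH <- at$nH
  for (v in seq_len(n)) {
    if (!is.na(nH[v])) next  # bracket atom: explicit H only
    val <- DEFAULT_VALENCE[[at$symbol[v]]]
    if (is.null(val)) {
      nH[v] <- 0L
    } else {
      used <- ceiling(bondSum[v])
      fit <- val[val >= used]
      nH[v] <- if (length(fit)) as.integer(fit[1] - used) else 0L
    }
  }
  hyb <- character(n)
  for (v in seq_len(n)) {
    conn <- degree[v] + nH[v]
    hyb[v] <-
      if (nTriple[v] >= 1L || nDouble[v] >= 2L) "sp"
      else if (nDouble[v] >= 1L || at$aromatic[v]) "sp2"
      else if (conn == 5L) "sp3d"
      else if (conn >= 6L) "sp3d2"
      else "sp3"
  }
  data.frame(symbol = at$symbol, degree = degree, charge = at$charge,
             chirality = at$chirality, nH = nH, hybridization = hyb,
             aromatic = at$aromatic,
             mass = unname(ATOMIC_MASS[at$symbol]),
             stringsAsFactors = FALSE)
}

#' Encode one atom's descriptors as a 39-dimensional feature vector
#'
#' Concatenates, in this fixed order: atom type one-hot (12), number of bonds
#' one-hot for degrees 0-5 (6), formal charge one-hot for -2..+2 (5),
#' chirality one-hot CW/CCW/unspecified/other (4), bound hydrogen count
#' one-hot for 0-4 (5), hybridization one-hot sp/sp2/sp3/sp3d/sp3d2 (5),
#' aromaticity flag (1), and atomic mass divided by `massNorm` and clipped to
#' [0, 1] (1). Category orderings are frozen so feature positions are stable.
#' Out-of-vocabulary atom types encode as all-zero with a warning; degrees
#' above 5 and charges outside -2..+2 saturate/clamp with a warning.
#'
#' @param atomType Element symbol (e.g. "C").
#' @param nBonds Integer number of bonds the atom participates in.
#' @param formalCharge Integer formal charge.
#' @param chirality One of "CW", "CCW", "unspecified", "other".
#' @param nHydrogens Integer count of bound hydrogens.
#' @param hybridization One of "sp", "sp2", "sp3", "sp3d", "sp3d2".
#' @param aromatic Logical aromaticity flag.
#' @param mass Atomic mass (unified atomic mass units).
#' @param atomVocab Ordered character vector of recognized element symbols
#'   (default 12 types).
#' @param massNorm Mass normalization constant (default 200).
#' @param atomIndex Optional integer used in error messages.
#' @return Numeric vector of length 39.
#' @examples
#' length(featurizeAtom("C", 4, 0, "unspecified", 0, "sp3", FALSE, 12.011))
#' @export
featurizeAtom <- function(atomType, nBonds, formalCharge, chirality,
                          nHydrogens, hybridization, aromatic, mass,
                          atomVocab = DEFAULT_ATOM_VOCAB, massNorm = 200,
                          atomIndex = NA_integer_) {
  where <- if (is.na(atomIndex)) "" else sprintf(" (atom %d)", atomIndex)
  oneHot <- function(size, pos) { v <- numeric(size); if (!is.na(pos)) v[pos] <- 1; v }

  typePos <- match(atomType, atomVocab)
  if (is.na(typePos))
    warning("atom type '", atomType, "' not in vocabulary", where,
            "; encoding as all-zero")
  if (!is.numeric(nBonds) || is.na(nBonds) || nBonds < 0)
    stop("invalid bond count", where, " in block 'n_bonds'")
  if (nBonds > 5) {
    warning("degree ", nBonds, " saturates the bond-count block", where)
    nBonds <- 5
  }
  if (!formalCharge %in% CHARGE_LEVELS) {
    warning("formal charge ", formalCharge, " clamped to [-2, 2]", where)
    formalCharge <- max(min(formalCharge, 2L), -2L)
  }
  chirPos <- match(chirality, CHIRALITY_LEVELS)
  if (is.na(chirPos))
    stop("invalid chirality '", chirality, "'", where, " in block 'chirality'")
  if (!is.numeric(nHydrogens) || is.na(nHydrogens) || nHydrogens < 0)
    stop("invalid hydrogen count", where, " in block 'n_hydrogens'")
  if (nHydrogens > 4) {
    warning("hydrogen count ", nHydrogens, " saturates the block", where)
    nHydrogens <- 4
  }
  hybPos <- match(hybridization, HYBRIDIZATION_LEVELS)
  if (is.na(hybPos))
    stop("invalid hybridization '", hybridization, "'", where,
         " in block 'hybridization'")
  if (is.na(mass)) {
    warning("unknown atomic mass", where, "; encoding as 0")
    mass <- 0
  }
  c(oneHot(length(atomVocab), typePos),
    oneHot(6L, nBonds + 1L),
    oneHot(5L, match(as.integer(formalCharge), CHARGE_LEVELS)),
    oneHot(4L, chirPos),
    oneHot(5L, nHydrogens + 1L),
    oneHot(5L, hybPos),
    as.numeric(aromatic),
    min(max(mass / massNorm, 0), 1))
}

#' Parse a SMILES string into a MolecularGraph
#'
#' Builds the heavy-atom graph of a compound: atoms in order of appearance in
#' the SMILES string, a symmetric adjacency matrix carrying numeric bond
#' orders (aromatic = 1.5), and the 39-column atom feature matrix of
#' [featurizeAtom()]. Hydrogens are never vertices; explicit and implicit
#' hydrogens are folded into the hydrogen-count feature block. Parsing is
#' deterministic: the same string always yields a bit-identical graph.
#'
#' @param smi Character SMILES string.
#' @param atomVocab Ordered element vocabulary for the atom-type block.
#' @param massNorm Mass normalization constant.
#' @return A [MolecularGraph-class].
#' @examples
#' g <- molFromSmiles("c1ccccc1")
#' atomCount(g)
#' adjacency(g)[1, 2]
#' @export
molFromSmiles <- function(smi, atomVocab = DEFAULT_ATOM_VOCAB,
                          massNorm = 200) {
  parsed <- tryCatch(.parseSmiles(smi), error = function(e)
    stop("invalid SMILES '", smi, "': ", conditionMessage(e), call. = FALSE))
  info <- .perceiveAtoms(parsed, smi)
  n <- nrow(info)
  A <- matrix(0, n, n)
  bd <- parsed$bonds
  for (b in seq_len(nrow(bd))) {
    A[bd$i[b], bd$j[b]] <- bd$order[b]
    A[bd$j[b], bd$i[b]] <- bd$order[b]
  }
  X <- t(vapply(seq_len(n), function(v)
    featurizeAtom(info$symbol[v], info$degree[v], info$charge[v],
                  info$chirality[v], info$nH[v], info$hybridization[v],
                  info$aromatic[v], info$mass[v],
                  atomVocab = atomVocab, massNorm = massNorm,
                  atomIndex = v),
    numeric(sum(ATOM_FEATURE_BLOCKS))))
  new("MolecularGraph", smiles = smi, atomFeatures = X, adjacency = A,
      atomInfo = info)
}

#' Featurize a column of SMILES strings
#'
#' @param smilesVec Character vector of SMILES.
#' @param ... Passed to [molFromSmiles()].
#' @return List of [MolecularGraph-class] objects, named by SMILES.
#' @export
molsFromSmiles <- function(smilesVec, ...) {
  out <- lapply(smilesVec, molFromSmiles, ...)
  names(out) <- smilesVec
  out
}

#' Cache featurized graphs on disk
#'
#' Writes a list of graphs (and optionally their substructure sets) to an
#' RDS archive so repeated pipeline runs skip re-parsing; [loadGraphCache()]
#' restores them bit-identically.
#'
#' @param graphs List of [MolecularGraph-class] objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
saveGraphCache <- function(graphs, path) {
  stopifnot(all(vapply(graphs, is, TRUE, "MolecularGraph")))
  saveRDS(graphs, path, compress = "gzip")
  invisible(path)
}

#' @rdname saveGraphCache
#' @export
loadGraphCache <- function(path) readRDS(path)
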