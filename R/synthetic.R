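#' @include molgraph.R
NULL

#' Default fragment pool of the synthetic generator
#'
#' Drug-like SMILES fragments used to assemble synthetic compounds. Every
#' fragment starts and ends on an atom with spare valence, so plain string
#' concatenation of fragments is again valid SMILES; kept small so learned
#' vocabularies stay inspectable.
#' @export
DEFAULT_FRAGMENT_POOL <- c(
  "C", "CC", "CCC", "C(C)C", "CC(C)(C)C",
  "CO", "COC", "CCOC", "CCSC", "CNC", "CCNCC",
  "CC(=O)C", "CC(=O)NC", "CC(=O)OC",
  "C=CC", "CC#CC",
  "CC(F)C", "CC(Cl)C", "CC(Br)C",
  "C[C@H](N)C",
  "c1ccccc1", "c1ccc(C)cc1", "c1ccc(F)cc1", "c1ccncc1",
  "C1CCCCC1", "C1CCOC1", "C1CC1"
)

#' Specification of a synthetic compound table
#'
#' Collects and validates every knob of the generator: compound count,
#' fragment pool, the designated activity-raising substructure, descriptor
#' matrix shape and planted informative subset, effect sizes, noise, and the
#' per-task positive fraction of the five binary ADMET labels.
#'
#' @param nCompounds Number of compounds (default 400).
#' @param fragmentPool Character vector of concatenable SMILES fragments.
#' @param signalSubstructure Pool fragment whose presence raises activity
#'   and drives part of the ADMET latents (default piperidine "C1CCNCC1" --
#'   composed of the same elements as the rest of the pool, so topology and
#'   not atom composition carries the signal).
#' @param nDescriptors Number of descriptor columns p (default 729).
#' @param nInformative Number of planted informative descriptors (default
#'   10).
#' @param effectSize Linear coefficient magnitude of informative descriptors
#'   on activity (default 0.6; signs alternate).
#' @param substructureBonus Activity bonus when the signal substructure is
#'   present (default 1.5 pIC50 units).
#' @param noiseSd Gaussian noise on activity (default 0.5).
#' @param admetBalance Positive fraction per ADMET task (default 0.5 each).
#' @param admetSubstructureEffect Weight of the substructure indicator in
#'   the ADMET latents (default 1.8).
#' @param admetDescriptorEffect Weight of the informative descriptors in the
#'   ADMET latents (default 1.0).
#' @param admetNoiseSd Latent noise of the ADMET labels (default 0.8).
#' @param pSignal Probability a compound contains the signal fragment
#'   (default 0.5).
#' @param seed Integer seed; the emitted table is byte-identical for a fixed
#'   seed.
#' @return A validated list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nCompounds = 400L,
                          fragmentPool = DEFAULT_FRAGMENT_POOL,
                          signalSubstructure = "C1CCNCC1",
                          nDescriptors = 729L, nInformative = 10L,
                          effectSize = 0.6, substructureBonus = 1.5,
                          noiseSd = 0.5,
                          admetBalance = c(Caco2 = 0.5, CYP3A4 = 0.5,
                                           hERG = 0.5, HOB = 0.5, MN = 0.5),
                          admetSubstructureEffect = 1.8,
                          admetDescriptorEffect = 1.0,
                          admetNoiseSd = 0.8, pSignal = 0.5, seed = 1L) {
  stopifnot(nCompounds >= 1, length(fragmentPool) >= 2,
            nInformative <= nDescriptors, noiseSd >= 0,
            all(admetBalance > 0 & admetBalance < 1),
            pSignal > 0, pSignal < 1)
  if (length(admetBalance) != 5L)
    stop("admetBalance must give one positive fraction per ADMET task")
  structure(list(
    nCompounds = as.integer(nCompounds), fragmentPool = fragmentPool,
    signalSubstructure = signalSubstructure,
    nDescriptors = as.integer(nDescriptors),
    nInformative = as.integer(nInformative), effectSize = effectSize,
    substructureBonus = substructureBonus, noiseSd = noiseSd,
    admetBalance = admetBalance,
    admetSubstructureEffect = admetSubstructureEffect,
    admetDescriptorEffect = admetDescriptorEffect,
    admetNoiseSd = admetNoiseSd, pSignal = pSignal,
    seed = as.integer(seed)), class = "SyntheticSpec")
}

ADMET_TASKS <- c("Caco2", "CYP3A4", "hERG", "HOB", "MN")

#' Generate a synthetic compound table with known ground truth
#'
#' Builds molecules by concatenating random pool fragments (roughly half
#' include the designated signal substructure), a dense standard-normal
#' descriptor matrix with a small informative subset, a continuous pIC50
#' driven by the informative descriptors plus a bonus for the signal
#' substructure plus Gaussian noise, and five binary ADMET labels drawn from
#' logistic latents mixing the substructure indicator and informative
#' descriptors, centered so the positive fraction matches `admetBalance`.
#' Every emitted SMILES parses under [molFromSmiles()]; a fragment
#' combination that failed to parse would be skipped with a warning.
#'
#' @param spec A [syntheticSpec()] object.
#' @return List of class `SyntheticDataset` with elements `table` (the
#'   compound data.frame: compound_id, SMILES, descriptor columns, pIC50 and
#'   the five ADMET columns) and `truth` (informative descriptor names,
#'   per-compound signal indicator, coefficients, and the signal
#'   substructure).
#' @export
generateCompounds <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  n <- spec$nCompounds
  p <- spec$nDescriptors
  pool <- setdiff(spec$fragmentPool, spec$signalSubstructure)

  smiles <- character(n)
  hasSignal <- logical(n)
  for (i in seq_len(n)) {
    repeat {
      nFrag <- sample(2:4, 1)
      frags <- sample(pool, nFrag, replace = TRUE)
      withSignal <- stats::runif(1) < spec$pSignal
      if (withSignal) {
        pos <- sample(nFrag + 1L, 1)
        frags <- append(frags, spec$signalSubstructure, after = pos - 1L)
      }
      smi <- paste(frags, collapse = "")
      ok <- tryCatch({
        suppressWarnings(molFromSmiles(smi))
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      warning("skipping unparsable fragment combination: ", smi)
    }
    smiles[i] <- smi
    hasSignal[i] <- withSignal
  }

  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("D%03d", seq_len(p))))
  informative <- sort(sample(p, spec$nInformative))
  coefs <- spec$effectSize * rep_len(c(1, -1), spec$nInformative)
  pic50 <- 5 + as.numeric(X[, informative, drop = FALSE] %*% coefs) +
    spec$substructureBonus * hasSignal +
    stats::rnorm(n, sd = spec$noiseSd)

  sCent <- hasSignal - 0.5
  labels <- matrix(0L, n, 5, dimnames = list(NULL, ADMET_TASKS))
  for (t in seq_len(5)) {
    j1 <- informative[(2 * t - 1 - 1) %% spec$nInformative + 1]
    j2 <- informative[(2 * t - 1) %% spec$nInformative + 1]
    latent <- spec$admetSubstructureEffect * sCent * rep_len(c(1, -1), 5)[t] +
      spec$admetDescriptorEffect * (X[, j1] - X[, j2]) / sqrt(2) +
      stats::rnorm(n, sd = spec$admetNoiseSd)
    shift <- stats::quantile(latent, 1 - spec$admetBalance[t], type = 7)
    labels[, t] <- stats::rbinom(n, 1L, stats::plogis(2 * (latent - shift)))
  }

  tab <- data.frame(compound_id = sprintf("CPD%04d", seq_len(n)),
                    SMILES = smiles, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(X), pIC50 = pic50, as.data.frame(labels))
  structure(list(table = tab,
                 truth = list(informative = colnames(X)[informative],
                              coefficients = stats::setNames(
                                coefs, colnames(X)[informative]),
                              hasSignal = hasSignal,
                              signalSubstructure = spec$signalSubstructure,
                              spec = spec)),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d compounds, %d descriptors (%d informative)\n",
              nrow(x$table), length(grep("^D\\d+$", names(x$table))),
              length(x$truth$informative)))
  invisible(x)
}
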