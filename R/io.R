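#' @include molgraph.R synthetic.R
NULL

.CONFIG_DEFAULTS <- list(
  smilesColumn = "SMILES", idColumn = "compound_id",
  activityColumn = "pIC50", admetColumns = ADMET_TASKS,
  lambdaFuse = 0.6, interactionSteps = 2L, hiddenDim = 39L,
  learningRate = 0.01, dropout = 0.5, batchSize = 32L, epochs = 200L,
  patience = 20L, topK = 50L, maxVocab = 300L, minFrequency = 5L,
  nMaxSubstructures = 8L, massNorm = 200, atomVocab = DEFAULT_ATOM_VOCAB,
  selectionTarget = "pIC50", pooling = "fused",
  scAlpha = 0.05, scMinBins = 2L, scMaxBins = 20L,
  scFactor = 20 / log(2), scOffset = 600,
  goodQuantile = 0.7, minFavorable = 4L,
  shareSubgraphParams = TRUE, seed = 1L
)

#' Pipeline configuration with validated overrides
#'
#' Returns the full configuration list: every default of the modelling
#' pipeline (branch mixing weight 0.6, 2 interaction steps, learning rate
#' 0.01, dropout 0.5, top-50 descriptor selection, vocabulary limits,
#' scorecard settings, seeds and column names), with the supplied overrides
#' applied. Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("configuration error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
  if (cfg$lambdaFuse < 0 || cfg$lambdaFuse > 1)
    stop("configuration error: lambdaFuse must lie in [0, 1]")
  structure(cfg, class = "PipelineConfig")
}

#' Dump a resolved configuration next to an output
#'
#' @param config A `PipelineConfig`.
#' @param path File path (plain text, one `key: value` line each).
#' @return `path` invisibly.
#' @export
dumpConfig <- function(config, path) {
  lines <- vapply(names(config), function(nm)
    sprintf("%s: %s", nm, paste(format(config[[nm]]), collapse = " ")), "")
  writeLines(c(sprintf("# resolved pipeline config (hash %d)",
                       configHash(config)), lines), path)
  invisible(path)
}

#' @rdname dumpConfig
#' @export
configHash <- function(config) {
  s <- paste(names(config),
             vapply(config, function(x) paste(format(x), collapse = ","), ""),
             collapse = ";")
  as.integer(sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
               2147483647)
}

#' Read a compound table CSV
#'
#' Reads the comma-separated compound table (header row required; UTF-8):
#' one SMILES column, descriptor columns (everything that is not
#' SMILES/id/label), a continuous activity column and five binary ADMET
#' columns. Validates SMILES parseability, descriptor numeric-ness and label
#' domains, reporting row numbers for every failure; more than 5%
#' unparsable SMILES aborts with a summary.
#'
#' @param path CSV file path.
#' @param config A [pipelineConfig()] (column names).
#' @return List with `table` (validated data.frame), `descriptorNames`,
#'   and `smiles`.
#' @export
readCompoundTable <- function(path, config = pipelineConfig()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(config$smilesColumn, config$idColumn, config$activityColumn,
            config$admetColumns)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  for (cl in config$admetColumns) {
    bad <- which(!tab[[cl]] %in% c(0, 1))
    if (length(bad))
      stop("domain error: column '", cl, "' must be 0/1; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.numeric(tab[[config$activityColumn]]))
    stop("domain error: column '", config$activityColumn,
         "' must be numeric")
  descNames <- setdiff(names(tab), need)
  nonNum <- descNames[!vapply(tab[descNames], is.numeric, TRUE)]
  if (length(nonNum))
    stop("schema error: non-numeric descriptor column(s): ",
         paste(utils::head(nonNum, 5), collapse = ", "))
  parseFail <- integer()
  for (i in seq_len(nrow(tab))) {
    ok <- tryCatch({
      suppressWarnings(molFromSmiles(tab[[config$smilesColumn]][i]))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) parseFail <- c(parseFail, i)
  }
  if (length(parseFail) > 0.05 * nrow(tab))
    stop(sprintf("%d of %d SMILES failed to parse (rows %s ...)",
                 length(parseFail), nrow(tab),
                 paste(utils::head(parseFail, 5), collapse = ", ")))
  if (length(parseFail)) {
    warning("dropping ", length(parseFail), " unparsable SMILES row(s): ",
            paste(parseFail, collapse = ", "))
    tab <- tab[-parseFail, , drop = FALSE]
    rownames(tab) <- NULL
  }
  list(table = tab, descriptorNames = descNames,
       smiles = tab[[config$smilesColumn]])
}

#' Write a compound table CSV
#'
#' @param table Compound data.frame (as produced by [generateCompounds()]).
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
writeCompoundTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
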