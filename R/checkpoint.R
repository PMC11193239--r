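## Checkpoints: the weight list plus the configuration, the full vocabulary
## and its hash, written with saveRDS.  Loading rebuilds the S4 objects and
## verifies shape consistency and the vocabulary hash.

#' Save a model checkpoint
#'
#' @param model a \code{SmilesLM}.
#' @param path output file.
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(
    format = "smilesgen-checkpoint-1",
    params = model@params,
    config = sapply(slotNames(model@config), function(s)
      slot(model@config, s), simplify = FALSE),
    vocabTokens = model@vocab@tokens,
    vocabSpecials = model@vocab@specials,
    vocabHash = vocabHash(model@vocab),
    trace = model@trace)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the model and verifies that every weight array has the shape
#' the stored configuration implies and that the stored vocabulary hash
#' matches the stored token list.
#'
#' @param path file written by \code{\link{saveCheckpoint}}.
#' @return a \code{SmilesLM}.
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "smilesgen-checkpoint-1"))
    stop("not a smilesgen checkpoint: ", path)
  vocab <- new("Vocabulary", tokens = obj$vocabTokens,
               specials = obj$vocabSpecials)
  if (!identical(vocabHash(vocab), obj$vocabHash))
    stop("checkpoint vocabulary hash mismatch")
  cfg <- do.call(modelConfig, obj$config[c(
    "dVoc", "nHeads", "nBlocks", "dEmb", "dFfn", "dropoutP", "maxSmilesLen",
    "nNumericConditions", "maxTsLen", "ropeBase")])
  shapes <- .paramShapes(cfg)
  if (!identical(sort(names(shapes)), sort(names(obj$params))))
    stop("checkpoint parameter groups do not match the configuration")
  for (nm in names(shapes)) {
    want <- shapes[[nm]]
    have <- if (is.matrix(obj$params[[nm]])) dim(obj$params[[nm]]) else
      length(obj$params[[nm]])
    if (!identical(as.integer(want), as.integer(have)))
      stop("checkpoint shape mismatch for ", nm)
  }
  new("SmilesLM", params = obj$params, config = cfg, vocab = vocab,
      trace = obj$trace)
}
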