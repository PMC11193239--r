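## Autoregressive conditional generation with temperature control.  Pure
## multinomial sampling over the temperature-scaled softmax; no top-k or
## nucleus filtering.

#' Generation settings constructor
#'
#' @param temperature logit divisor (> 0); 0.8 (the full-scale evaluation
#'   value) by default.
#' @param maxNewTokens hard stop if no end-of-SMILES token appears.
#' @param nSamples number of molecules.
#' @param seed RNG seed; fixed seed and weights give identical samples.
#' @return a \code{\linkS4class{GenerationSettings}}.
#' @export
generationSettings <- function(temperature = 0.8, maxNewTokens = 256L,
                               nSamples = 1L, seed = 1L) {
  new("GenerationSettings", temperature = temperature,
      maxNewTokens = as.integer(maxNewTokens), nSamples = as.integer(nSamples),
      seed = as.integer(seed))
}

setMethod("show", "GenerationSettings", function(object) {
  cat("GenerationSettings: t =", object@temperature, ",", object@nSamples,
      "sample(s), cap", object@maxNewTokens, "tokens, seed", object@seed,
      "\n")
})

#' Temperature scaling of logits
#'
#' Divides the logits by the temperature: t = 1 leaves the distribution
#' unchanged, t < 1 sharpens it, t > 1 flattens it; the probability
#' ordering is preserved for every t > 0.
#'
#' @param logits numeric vector or matrix.
#' @param temperature positive scalar.
#' @return scaled logits.
#' @export
scaleLogits <- function(logits, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  logits / temperature
}

#' Generate molecules by autoregressive sampling
#'
#' Each sample starts from the context plus a \code{[CLS]} token; at every
#' step the final logits row is temperature-scaled, softmaxed and sampled.
#' Generation stops at \code{[SEP]} or after \code{maxNewTokens} tokens.
#' The pad token's logit is masked out during sampling ([PAD] is never a
#' legal continuation).  Returned strings are decoded without special
#' tokens; they are raw model output and may or may not be valid SMILES.
#'
#' @param model a \code{SmilesLM}.
#' @param bundle a \code{ContextBundle}; empty bundle = unconditional.
#' @param settings a \code{GenerationSettings}.
#' @return character vector of \code{nSamples} generated strings.
#' @export
generateSmiles <- function(model, bundle = contextBundle(),
                           settings = generationSettings()) {
  validObject(settings)
  vocab <- model@vocab
  params <- model@params
  config <- model@config
  sp <- specialIds(vocab)
  ctx <- embedContext(bundle, params, config)
  withr::with_seed(settings@seed, {
    vapply(seq_len(settings@nSamples), function(s) {
      ids <- sp[["cls"]]
      repeat {
        X <- rbind(ctx, params$tok_emb[ids + 1L, , drop = FALSE])
        logits <- .forwardPass(params, config, X)$logits
        z <- logits[nrow(logits), ]
        z[sp[["pad"]] + 1L] <- -Inf
        z <- scaleLogits(z, settings@temperature)
        z <- z - max(z)
        pr <- exp(z)
        pr <- pr / sum(pr)
        nxt <- sample.int(length(pr), 1L, prob = pr) - 1L
        ids <- c(ids, nxt)
        if (nxt == sp[["sep"]] ||
            length(ids) - 1L >= settings@maxNewTokens) break
      }
      decodeIds(ids, vocab)
    }, character(1))
  })
}

#' Build a condition bundle from user-facing units
#'
#' Convenience wrapper for generation: molecular weight is accepted in
#' Daltons and divided by 100 to the training scale, and a core-structure
#' SMILES is canonicalized before tokenization.
#'
#' @param vocab a \code{Vocabulary} (needed when \code{core} is supplied).
#' @param logp,sascore optional numeric conditions.
#' @param mwDa optional molecular weight in Daltons.
#' @param core optional core-structure SMILES.
#' @return a \code{\linkS4class{ContextBundle}}.
#' @export
conditionFromUnits <- function(vocab = NULL, logp = NA_real_,
                               sascore = NA_real_, mwDa = NA_real_,
                               core = NULL) {
  tsIds <- integer(0)
  if (!is.null(core)) {
    if (is.null(vocab)) stop("a vocabulary is required to tokenize a core")
    can <- canonicalizeSmiles(core)
    if (is.na(can)) stop("unparseable core SMILES: ", core)
    message("core canonicalized to ", can)
    tsIds <- encodeSmiles(can, vocab, frame = FALSE)
  }
  mw <- if (is.na(mwDa)) NA_real_ else {
    message("molecular weight ", mwDa, " Da scaled to ", mwDa / 100)
    mwDa / 100
  }
  contextBundle(logp = logp, sascore = sascore, mw = mw, tsIds = tsIds)
}
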