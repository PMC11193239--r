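#' @import methods
NULL

# Token ids are 0-based throughout the package ([PAD]=0, [CLS]=1, [SEP]=2),
# matching the convention that the pad id is 0; R-side lookups add 1.

#' Vocabulary: bijective token/id mapping with reserved special tokens
#'
#' An ordered token list defining a bijection token -> id over 0..size-1.
#' Ids 0, 1 and 2 are always the pad, start-of-SMILES and end-of-SMILES
#' markers \code{[PAD]}, \code{[CLS]}, \code{[SEP]}; chemistry tokens follow
#' in lexicographic order.
#'
#' @slot tokens character vector; \code{tokens[i]} is the token with id
#'   \code{i - 1}.
#' @slot specials named integer vector with entries \code{pad}, \code{cls},
#'   \code{sep} (always \code{c(pad = 0L, cls = 1L, sep = 2L)}).
#' @export
setClass("Vocabulary",
  representation(tokens = "character", specials = "integer"))

setValidity("Vocabulary", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@tokens))
    msgs <- c(msgs, "tokens must be distinct (token->id must be a bijection)")
  need <- c("pad", "cls", "sep")
  if (!all(need %in% names(object@specials)))
    msgs <- c(msgs, "specials must name pad, cls and sep")
  else {
    sp <- object@specials[need]
    if (anyDuplicated(sp)) msgs <- c(msgs, "special ids must be distinct")
    if (any(sp < 0L | sp >= length(object@tokens)))
      msgs <- c(msgs, "special ids out of range")
    lab <- c("[PAD]", "[CLS]", "[SEP]")
    if (!identical(object@tokens[sp + 1L], lab))
      msgs <- c(msgs, "special ids must point at [PAD], [CLS], [SEP]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Model hyperparameter configuration
#'
#' Defaults are the full-scale configuration of the reference model: 8 heads,
#' 8 decoder blocks, embedding dimension 384, feed-forward hidden dimension
#' 1024, dropout 0.1, SMILES length cap 256 tokens, 3 numeric condition
#' types, token-sequence condition cap 50.  \code{dVoc} always comes from the
#' vocabulary in use.
#'
#' @slot nHeads,nBlocks,dEmb,dFfn,dVoc,maxSmilesLen,nNumericConditions,maxTsLen
#'   integer dimensions.
#' @slot dropoutP dropout probability applied to attention and feed-forward
#'   outputs during training.
#' @slot ropeBase base of the rotary-embedding frequency ladder.
#' @export
setClass("ModelConfig",
  representation(nHeads = "integer", nBlocks = "integer", dEmb = "integer",
                 dFfn = "integer", dVoc = "integer", dropoutP = "numeric",
                 maxSmilesLen = "integer", nNumericConditions = "integer",
                 maxTsLen = "integer", ropeBase = "numeric"))

setValidity("ModelConfig", function(object) {
  msgs <- character(0)
  dims <- c(object@nHeads, object@nBlocks, object@dEmb, object@dFfn,
            object@dVoc, object@maxSmilesLen, object@nNumericConditions,
            object@maxTsLen)
  if (any(dims < 1L)) msgs <- c(msgs, "all dimensions must be positive")
  if (object@dEmb %% object@nHeads != 0L)
    msgs <- c(msgs, "dEmb must be divisible by nHeads")
  if ((object@dEmb %/% object@nHeads) %% 2L != 0L)
    msgs <- c(msgs, "head dimension must be even (rotary embedding pairs)")
  if (object@dropoutP < 0 || object@dropoutP >= 1)
    msgs <- c(msgs, "dropoutP must lie in [0, 1)")
  if (object@ropeBase <= 0) msgs <- c(msgs, "ropeBase must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Training configuration
#'
#' Defaults follow the full-scale optimization recipe: constant learning rate
#' 1e-4, AdamW with beta1 = 0.9 / beta2 = 0.95, batch size 256 with 4
#' gradient-accumulation steps, condition-deletion probability 0.15, all
#' three numeric condition types plus a token-sequence condition sampled for
#' every batch.  Desk-scale runs override \code{steps}, \code{batchSize},
#' \code{lr} and the condition selection.
#'
#' @slot pDel per-batch deletion probability for each condition row.
#' @slot lr,beta1,beta2,weightDecay AdamW settings.
#' @slot batchSize,gradAccumSteps,steps loop sizes; \code{steps} counts
#'   optimizer updates, each consuming \code{gradAccumSteps} micro-batches.
#' @slot maxTsLen cap on sampled token-sequence condition length.
#' @slot conditionTypes 0-based numeric condition type ids used in training
#'   (0 = logP, 1 = SAScore, 2 = scaled molecular weight).
#' @slot useTsCondition whether a token-sequence condition is sampled for
#'   each batch (before possible deletion).
#' @slot seed run-level RNG seed.
#' @export
setClass("TrainingConfig",
  representation(pDel = "numeric", lr = "numeric", beta1 = "numeric",
                 beta2 = "numeric", weightDecay = "numeric",
                 batchSize = "integer", gradAccumSteps = "integer",
                 steps = "integer", maxTsLen = "integer",
                 conditionTypes = "integer", useTsCondition = "logical",
                 seed = "integer"))

setValidity("TrainingConfig", function(object) {
  msgs <- character(0)
  if (object@pDel < 0 || object@pDel > 1)
    msgs <- c(msgs, "pDel must lie in [0, 1]")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@gradAccumSteps < 1L) msgs <- c(msgs, "gradAccumSteps must be >= 1")
  if (object@lr <= 0) msgs <- c(msgs, "lr must be positive")
  if (anyDuplicated(object@conditionTypes))
    msgs <- c(msgs, "conditionTypes must be distinct")
  if (length(msgs)) msgs else TRUE
})

#' Condition bundle for conditional generation
#'
#' Any subset of the numeric condition types plus an optional token-sequence
#' condition (a tokenized core-structure SMILES).  An empty bundle means
#' unconditional generation.
#'
#' @slot numericTypes 0-based type ids of the supplied numeric conditions
#'   (0 = logP, 1 = SAScore, 2 = molecular weight / 100), in context order.
#' @slot numericValues the corresponding values, on the training scale.
#' @slot tsIds 0-based token ids of the token-sequence condition (unframed);
#'   may be empty.
#' @export
setClass("ContextBundle",
  representation(numericTypes = "integer", numericValues = "numeric",
                 tsIds = "integer"))

setValidity("ContextBundle", function(object) {
  msgs <- character(0)
  if (length(object@numericTypes) != length(object@numericValues))
    msgs <- c(msgs, "numericTypes and numericValues must align")
  if (anyDuplicated(object@numericTypes))
    msgs <- c(msgs, "numeric condition types must be distinct")
  if (any(object@numericTypes < 0L))
    msgs <- c(msgs, "type ids are 0-based and non-negative")
  if (any(is.na(object@numericValues)))
    msgs <- c(msgs, "numeric condition values must not be NA")
  if (any(object@tsIds < 0L)) msgs <- c(msgs, "token ids must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Sampling settings for autoregressive generation
#'
#' @slot temperature positive divisor applied to logits before the softmax;
#'   the full-scale evaluation value 0.8 is the default.
#' @slot maxNewTokens generation stops after this many tokens if no
#'   end-of-SMILES token is produced.
#' @slot nSamples number of molecules to draw.
#' @slot seed RNG seed.
#' @export
setClass("GenerationSettings",
  representation(temperature = "numeric", maxNewTokens = "integer",
                 nSamples = "integer", seed = "integer"))

setValidity("GenerationSettings", function(object) {
  msgs <- character(0)
  if (object@temperature <= 0) msgs <- c(msgs, "temperature must be positive")
  if (object@maxNewTokens < 1L) msgs <- c(msgs, "maxNewTokens must be >= 1")
  if (object@nSamples < 1L) msgs <- c(msgs, "nSamples must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Train/test partition of an annotated corpus
#'
#' @slot train,test data.frames of molecule records (columns smiles, logp,
#'   sascore, mw_scaled), disjoint by SMILES string.
#' @slot seed the seed that produced the permutation.
#' @export
setClass("CorpusSplit",
  representation(train = "data.frame", test = "data.frame", seed = "integer"))

setValidity("CorpusSplit", function(object) {
  msgs <- character(0)
  if (length(intersect(object@train$smiles, object@test$smiles)))
    msgs <- c(msgs, "train and test must be disjoint by SMILES")
  if (length(msgs)) msgs else TRUE
})

#' A trained (or freshly initialized) SMILES language model
#'
#' Bundles the weight list with the configuration and the vocabulary it was
#' built against, so sampling and checkpoint loading can verify consistency.
#'
#' @slot params named list of weight arrays (see \code{\link{initParams}}).
#' @slot config a \code{ModelConfig}.
#' @slot vocab the \code{Vocabulary} the model indexes into.
#' @slot trace per-optimizer-step loss trace (may be empty for an untrained
#'   model).
#' @export
setClass("SmilesLM",
  representation(params = "list", config = "ModelConfig",
                 vocab = "Vocabulary", trace = "data.frame"))

setValidity("SmilesLM", function(object) {
  if (object@config@dVoc != vocabSize(object@vocab))
    return("config dVoc does not match the vocabulary size")
  TRUE
})

#' Evaluation report for a batch of generated molecules
#'
#' @slot validityPct,uniquenessPct,noveltyPct percentages in [0, 100];
#'   uniqueness/novelty may be NA when not computed.
#' @slot uniquenessAt the batch size uniqueness was computed at.
#' @slot madPerProperty named numeric vector (subset of logp, sascore,
#'   mw_scaled), mean absolute deviation between requested and recomputed
#'   values; empty for an unconditional run.
#' @slot smPct substructure-match percentage, NA when no core was requested.
#' @slot nGenerated,nValid counts.
#' @export
setClass("MetricsReport",
  representation(validityPct = "numeric", uniquenessPct = "numeric",
                 noveltyPct = "numeric", uniquenessAt = "integer",
                 madPerProperty = "numeric", smPct = "numeric",
                 nGenerated = "integer", nValid = "integer"))

setValidity("MetricsReport", function(object) {
  pct <- c(object@validityPct, object@uniquenessPct, object@noveltyPct,
           object@smPct)
  pct <- pct[!is.na(pct)]
  if (any(pct < 0 | pct > 100)) return("percentages must lie in [0, 100]")
  if (any(object@madPerProperty < 0, na.rm = TRUE))
    return("MAD must be non-negative")
  TRUE
})
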