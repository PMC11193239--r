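## Stochastic context learning: random contiguous token-sequence conditions,
## per-batch condition deletion, padding/collation, and the SMILES-only
## cross-entropy loss.  These functions consume the current R RNG stream;
## callers (the training loop, tests) seed it.

#' Training configuration constructor
#'
#' @param batchSize sequences per micro-batch.
#' @param steps number of optimizer updates.
#' @param seed run-level seed; all batch randomness derives from it.
#' @param pDel per-batch condition-deletion probability (default 0.15).
#' @param lr,beta1,beta2,weightDecay AdamW settings (defaults 1e-4, 0.9,
#'   0.95, 0.01; weight decay applies to matrix-shaped weights only).
#' @param gradAccumSteps micro-batches accumulated per update (default 4).
#' @param maxTsLen token-sequence condition cap (default 50).
#' @param conditionTypes 0-based numeric condition types used (default all
#'   three: logP, SAScore, scaled molecular weight).
#' @param useTsCondition sample a token-sequence condition for every batch
#'   (default TRUE; it may still be deleted with probability \code{pDel}).
#' @return a \code{\linkS4class{TrainingConfig}}.
#' @export
trainingConfig <- function(batchSize = 256L, steps = 100L, seed = 1L,
                           pDel = 0.15, lr = 1e-4, beta1 = 0.9, beta2 = 0.95,
                           weightDecay = 0.01, gradAccumSteps = 4L,
                           maxTsLen = 50L, conditionTypes = 0:2,
                           useTsCondition = TRUE) {
  new("TrainingConfig", pDel = pDel, lr = lr, beta1 = beta1, beta2 = beta2,
      weightDecay = weightDecay, batchSize = as.integer(batchSize),
      gradAccumSteps = as.integer(gradAccumSteps), steps = as.integer(steps),
      maxTsLen = as.integer(maxTsLen),
      conditionTypes = as.integer(conditionTypes),
      useTsCondition = useTsCondition, seed = as.integer(seed))
}

setMethod("show", "TrainingConfig", function(object) {
  cat("TrainingConfig:", object@steps, "steps x", object@gradAccumSteps,
      "micro-batches of", object@batchSize,
      "| lr", object@lr, "AdamW(", object@beta1, ",", object@beta2, ")",
      "| p_del", object@pDel, "\n")
})

#' Sample a contiguous token-sequence condition
#'
#' Picks a random start index, then a random end index at or after it, and
#' returns that slice of the tokenized SMILES, truncated to \code{maxLen}
#' tokens.  Uses the current RNG stream.
#'
#' @param ids unframed 0-based token ids (length >= 1).
#' @param maxLen slice cap (default 50).
#' @return contiguous integer slice, length in [1, maxLen].
#' @export
sampleTsCondition <- function(ids, maxLen = 50L) {
  L <- length(ids)
  stopifnot(L >= 1L)
  start <- sample.int(L, 1L)
  end <- start + sample.int(L - start + 1L, 1L) - 1L
  end <- min(end, start + maxLen - 1L)
  ids[start:end]
}

#' Batched stochastic context deletion
#'
#' One Bernoulli(\code{pDel}) draw per numeric-condition type and one for
#' the token sequence, applied identically to every bundle in the batch, so
#' all sequences of a batch share the surviving condition layout.  When a
#' numeric type is deleted its row disappears from every bundle; when the
#' token sequence is deleted the whole token-sequence block disappears.
#' With \code{pDel = 0} the contexts are returned unchanged; with
#' \code{pDel = 1} every context becomes empty (an unconditional batch).
#'
#' @param bundles list of \code{ContextBundle}s sharing the same numeric
#'   types.
#' @param pDel deletion probability.
#' @return list with \code{bundles} (reduced), \code{deletedTypes} (0-based
#'   ids), and \code{tsDeleted} (logical).
#' @export
sclDrop <- function(bundles, pDel) {
  stopifnot(pDel >= 0, pDel <= 1)
  types <- if (length(bundles)) bundles[[1L]]@numericTypes else integer(0)
  delNum <- if (length(types)) stats::runif(length(types)) < pDel else logical(0)
  anyTs <- any(vapply(bundles, function(b) length(b@tsIds) > 0L, logical(1)))
  delTs <- if (anyTs) stats::runif(1L) < pDel else FALSE
  out <- lapply(bundles, function(b) {
    keep <- !delNum[match(b@numericTypes, types)]
    new("ContextBundle",
        numericTypes = b@numericTypes[keep],
        numericValues = b@numericValues[keep],
        tsIds = if (delTs) integer(0) else b@tsIds)
  })
  list(bundles = out, deletedTypes = types[delNum], tsDeleted = delTs)
}

.typeColumn <- c("logp", "sascore", "mw_scaled")

#' Collate records into a padded training batch
#'
#' For every record the framed SMILES ids are built, a contiguous
#' token-sequence condition is sampled from the record's own tokens (when
#' enabled), numeric conditions are read off the record, and stochastic
#' context deletion is applied batch-wide.  Surviving token-sequence
#' conditions are padded to the longest in the batch, as are the framed
#' SMILES; the loss mask marks exactly the SMILES-region next-token targets
#' (from the position of [CLS] through the token before [SEP]), never
#' context rows or pads, so a framed SMILES of length m contributes m - 1
#' targets.
#'
#' @param records data.frame rows of the batch (smiles + property columns).
#' @param vocab a \code{Vocabulary}.
#' @param trainCfg a \code{TrainingConfig}.
#' @return list with per-sequence elements: \code{bundles} (post-deletion,
#'   ts padded), \code{inputIds} (padded framed SMILES ids), \code{targets}
#'   (0-based target id per SMILES-region position, NA where unscored),
#'   \code{lossMasks} (logical, full sequence length including context), and
#'   batch info \code{deletedTypes}, \code{tsDeleted}, \code{nTargets}.
#' @export
collateBatch <- function(records, vocab, trainCfg) {
  stopifnot(nrow(records) >= 1L)
  pad <- specialIds(vocab)[["pad"]]
  unframed <- lapply(records$smiles, encodeSmiles, vocab = vocab,
                     frame = FALSE)
  framed <- lapply(unframed, function(ids)
    c(specialIds(vocab)[["cls"]], ids, specialIds(vocab)[["sep"]]))
  types <- sort(trainCfg@conditionTypes)
  bundles <- lapply(seq_len(nrow(records)), function(i) {
    ts <- if (trainCfg@useTsCondition)
      sampleTsCondition(unframed[[i]], trainCfg@maxTsLen) else integer(0)
    vals <- vapply(types, function(t)
      records[[.typeColumn[t + 1L]]][i], numeric(1))
    new("ContextBundle", numericTypes = types, numericValues = vals,
        tsIds = ts)
  })
  drop <- sclDrop(bundles, trainCfg@pDel)
  bundles <- drop$bundles
  kMax <- max(vapply(bundles, function(b) length(b@tsIds), integer(1)))
  bundles <- lapply(bundles, function(b) {
    k <- length(b@tsIds)
    if (k < kMax) b@tsIds <- c(b@tsIds, rep(pad, kMax - k))
    b
  })
  sMax <- max(lengths(framed))
  inputIds <- lapply(framed, function(ids) c(ids, rep(pad, sMax - length(ids))))
  ctxLen <- contextLength(bundles[[1L]])
  targets <- lapply(seq_along(framed), function(i) {
    m <- length(framed[[i]])
    tg <- rep(NA_integer_, sMax)
    if (m >= 2L) tg[seq_len(m - 1L)] <- framed[[i]][2:m]
    tg
  })
  lossMasks <- lapply(targets, function(tg)
    c(rep(FALSE, ctxLen), !is.na(tg)))
  list(bundles = bundles, inputIds = inputIds, targets = targets,
       lossMasks = lossMasks, deletedTypes = drop$deletedTypes,
       tsDeleted = drop$tsDeleted,
       nTargets = sum(vapply(targets, function(t) sum(!is.na(t)), integer(1))))
}

#' SMILES-only cross-entropy loss
#'
#' Mean negative log-probability of the true next token over exactly the
#' masked target positions; context rows and pad positions contribute
#' nothing.  With uniform logits over a vocabulary of size V the loss is
#' ln(V).
#'
#' @param logits L x d_voc matrix of unnormalized scores (a monotone
#'   relabeling of log-probabilities; the softmax is taken internally).
#' @param targets length-L integer vector of 0-based target ids (values at
#'   unmasked positions are ignored).
#' @param lossMask length-L logical; TRUE at scored positions.
#' @return scalar mean loss in nats per token.
#' @export
sequenceLoss <- function(logits, targets, lossMask) {
  stopifnot(nrow(logits) == length(lossMask),
            length(targets) == length(lossMask))
  idx <- which(lossMask)
  if (length(idx) == 0L) stop("degenerate batch: no target positions")
  nll <- vapply(idx, function(t) {
    r <- logits[t, ]
    m <- max(r)
    (m + log(sum(exp(r - m)))) - r[targets[t] + 1L]
  }, numeric(1))
  mean(nll)
}
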