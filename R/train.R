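## Training loop: hand-written reverse-mode gradients for the decoder stack
## (no autodiff framework is used), AdamW, gradient accumulation, and the
## SCL batch pipeline from scl.R.  Sequences of a collated batch are
## processed one at a time; because pad tokens are part of each padded
## sequence exactly as in a tensorized batch, the loop computes the same
## quantities a batched implementation would.

# Backward of rmsNorm for matrix input x (rows independent).
.rmsNormBack <- function(x, gain, dy, eps = 1e-5) {
  r <- sqrt(rowMeans(x^2) + eps)
  xhat <- x / r
  dxhat <- sweep(dy, 2L, gain, `*`)
  s <- rowSums(dxhat * xhat) / ncol(x)
  dx <- (dxhat - xhat * s) / r
  list(dx = dx, dgain = colSums(dy * xhat))
}

.siluGrad <- function(u) {
  sg <- 1 / (1 + exp(-u))
  sg * (1 + u * (1 - sg))
}

# Forward + backward for one (context bundle, padded framed ids) sequence
# given the upstream gradient on the logits.  dLogits rows at unscored
# positions must be zero.  Used directly by the gradient-check tests.
.seqBackward <- function(params, config, bundle, inputIds, dLogits,
                         dropoutMasks = NULL) {
  ctx <- embedContext(bundle, params, config)
  X <- rbind(ctx, params$tok_emb[inputIds + 1L, , drop = FALSE])
  fw <- .forwardPass(params, config, X, cache = TRUE,
                     dropoutMasks = dropoutMasks)
  grads <- .seqBackwardFromForward(params, config, bundle, inputIds, fw,
                                   dLogits, dropoutMasks)
  list(grads = grads, logits = fw$logits, contextLength = nrow(ctx))
}

# Draw inverted dropout masks for one sequence (NULL when p == 0).
.drawDropoutMasks <- function(config, L) {
  p <- config@dropoutP
  if (p <= 0) return(NULL)
  lapply(seq_len(config@nBlocks), function(b) list(
    attn = matrix(stats::rbinom(L * config@dEmb, 1L, 1 - p), L) / (1 - p),
    ffn = matrix(stats::rbinom(L * config@dEmb, 1L, 1 - p), L) / (1 - p)))
}

# One micro-batch: returns summed gradients, total loss numerator and
# target count.
.microBatch <- function(params, config, batch) {
  gsum <- list()
  nllSum <- 0
  N <- batch$nTargets
  if (N == 0L) stop("degenerate batch: no target positions")
  for (i in seq_along(batch$inputIds)) {
    bundle <- batch$bundles[[i]]
    inputIds <- batch$inputIds[[i]]
    cLen <- contextLength(bundle)
    Ltot <- cLen + length(inputIds)
    masks <- .drawDropoutMasks(config, Ltot)
    # forward once inside .seqBackward; build dLogits from its logits
    # (two-pass would double cost, so compute loss grads from the cache)
    tg <- batch$targets[[i]]
    scored <- which(!is.na(tg))
    res <- .seqBackwardWithLoss(params, config, bundle, inputIds, tg,
                                scored, cLen, N, masks)
    nllSum <- nllSum + res$nllSum
    for (nm in names(res$grads)) {
      gsum[[nm]] <- if (is.null(gsum[[nm]])) res$grads[[nm]] else
        gsum[[nm]] + res$grads[[nm]]
    }
  }
  list(grads = gsum, loss = nllSum / N)
}

# Forward, cross-entropy over scored positions, then backward.  Target
# position t (1-based within the SMILES region) lives at sequence row
# cLen + t and predicts tg[t].
.seqBackwardWithLoss <- function(params, config, bundle, inputIds, tg,
                                 scored, cLen, N, masks) {
  ctx <- embedContext(bundle, params, config)
  X <- rbind(ctx, params$tok_emb[inputIds + 1L, , drop = FALSE])
  fw <- .forwardPass(params, config, X, cache = TRUE, dropoutMasks = masks)
  Ltot <- nrow(X)
  dLogits <- matrix(0, Ltot, config@dVoc)
  nllSum <- 0
  for (t in scored) {
    row <- fw$logits[cLen + t, ]
    m <- max(row)
    pr <- exp(row - m)
    pr <- pr / sum(pr)
    y1 <- tg[t] + 1L
    nllSum <- nllSum - log(pr[y1])
    pr[y1] <- pr[y1] - 1
    dLogits[cLen + t, ] <- pr / N
  }
  bk <- .seqBackwardFromForward(params, config, bundle, inputIds, fw,
                                dLogits, masks)
  list(grads = bk, nllSum = nllSum)
}

# Shared backward body given a cached forward pass (used by both the
# training path above and the gradient-check path in .seqBackward).
.seqBackwardFromForward <- function(params, config, bundle, inputIds, fw,
                                    dLogits, dropoutMasks = NULL) {
  g <- new.env(parent = emptyenv())
  addG <- function(nm, val) {
    cur <- g[[nm]]
    g[[nm]] <- if (is.null(cur)) val else cur + val
  }
  addG("Wout", crossprod(fw$y, dLogits))
  dy <- dLogits %*% t(params$Wout)
  rb <- .rmsNormBack(fw$xFinal, params$g_final, dy)
  addG("g_final", rb$dgain)
  dx <- rb$dx
  dk <- headDim(config)
  for (b in rev(seq_len(config@nBlocks))) {
    cb <- fw$caches[[b]]
    pn <- function(nm) paste0("b", b, ".", nm)
    p <- function(nm) params[[pn(nm)]]
    dffnOut <- if (is.null(dropoutMasks)) dx else dx * dropoutMasks[[b]]$ffn
    H <- cb$Su * cb$G
    addG(pn("W2"), crossprod(H, dffnOut))
    dH <- dffnOut %*% t(p("W2"))
    dSu <- dH * cb$G
    dGm <- dH * cb$Su
    dU <- dSu * .siluGrad(cb$U)
    addG(pn("W1"), crossprod(cb$f, dU))
    addG(pn("W3"), crossprod(cb$f, dGm))
    df <- dU %*% t(p("W1")) + dGm %*% t(p("W3"))
    rb <- .rmsNormBack(cb$x1, p("g_ffn"), df)
    addG(pn("g_ffn"), rb$dgain)
    dx1 <- dx + rb$dx
    dattnOut <- if (is.null(dropoutMasks)) dx1 else
      dx1 * dropoutMasks[[b]]$attn
    addG(pn("Wo"), crossprod(cb$headsMat, dattnOut))
    dHeads <- dattnOut %*% t(p("Wo"))
    L <- nrow(dx)
    dQ <- matrix(0, L, config@dEmb)
    dK <- matrix(0, L, config@dEmb)
    dV <- matrix(0, L, config@dEmb)
    for (h in seq_len(config@nHeads)) {
      idx <- ((h - 1L) * dk + 1L):(h * dk)
      hc <- cb$heads[[h]]
      dOh <- dHeads[, idx, drop = FALSE]
      Vh <- cb$V[, idx, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[, idx] <- crossprod(hc$A, dOh)
      dS <- hc$A * (dA - rowSums(dA * hc$A))
      dQrot <- (dS %*% hc$Kh) / sqrt(dk)
      dKrot <- (crossprod(dS, hc$Qh)) / sqrt(dk)
      dQ[, idx] <- .ropeApplyInv(dQrot, fw$ropeTb)
      dK[, idx] <- .ropeApplyInv(dKrot, fw$ropeTb)
    }
    addG(pn("Wq"), crossprod(cb$a, dQ))
    addG(pn("Wk"), crossprod(cb$a, dK))
    addG(pn("Wv"), crossprod(cb$a, dV))
    da <- dQ %*% t(p("Wq")) + dK %*% t(p("Wk")) + dV %*% t(p("Wv"))
    rb <- .rmsNormBack(cb$xin, p("g_attn"), da)
    addG(pn("g_attn"), rb$dgain)
    dx <- dx1 + rb$dx
  }
  nNum <- length(bundle@numericTypes)
  kTs <- length(bundle@tsIds)
  dTok <- matrix(0, config@dVoc, config@dEmb)
  if (nNum) {
    t1 <- bundle@numericTypes + 1L
    dNum <- dx[seq_len(nNum), , drop = FALSE]
    dW <- matrix(0, config@nNumericConditions, config@dEmb)
    dB <- matrix(0, config@nNumericConditions, config@dEmb)
    dW[t1, ] <- bundle@numericValues * dNum
    dB[t1, ] <- dNum
    addG("num_w", dW)
    addG("num_b", dB)
    addG("type_enc", dB)
  }
  if (kTs) {
    dTs <- matrix(0, config@dVoc, config@dEmb)
    rows <- dx[nNum + seq_len(kTs), , drop = FALSE]
    for (j in seq_len(kTs)) {
      v <- bundle@tsIds[j] + 1L
      dTok[v, ] <- dTok[v, ] + rows[j, ]
      dTs[v, ] <- dTs[v, ] + rows[j, ]
    }
    addG("ts_emb", dTs)
    addG("ts_label", colSums(rows))
  }
  cLen <- nNum + kTs
  sRows <- dx[(cLen + 1L):nrow(dx), , drop = FALSE]
  for (j in seq_along(inputIds)) {
    v <- inputIds[j] + 1L
    dTok[v, ] <- dTok[v, ] + sRows[j, ]
  }
  addG("tok_emb", dTok)
  as.list(g)
}

# AdamW update in place on the parameter list.  Weight decay is decoupled
# and applied to matrix-shaped weights only (not gains, biases, or the
# label vector).
.adamwStep <- function(params, grads, state, trainCfg, step) {
  b1 <- trainCfg@beta1
  b2 <- trainCfg@beta2
  lr <- trainCfg@lr
  eps <- 1e-8
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gr * 0
      state$v[[nm]] <- gr * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    mhat <- state$m[[nm]] / (1 - b1^step)
    vhat <- state$v[[nm]] / (1 - b2^step)
    upd <- mhat / (sqrt(vhat) + eps)
    if (is.matrix(params[[nm]]) && !nm %in% c("num_b"))
      upd <- upd + trainCfg@weightDecay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  params
}

#' Train a SMILES language model with stochastic context learning
#'
#' Runs the optimization loop: per optimizer step, \code{gradAccumSteps}
#' micro-batches are collated (conditions sampled and stochastically
#' deleted), gradients are computed sequence by sequence with the
#' hand-written backward pass, accumulated, averaged, and applied with
#' AdamW.  The run is deterministic given \code{trainCfg@seed}
#' (single-threaded; all randomness flows from one seeded stream).
#' Divergence (non-finite loss) aborts with a diagnostic.
#'
#' @param split a \code{CorpusSplit} of annotated records.
#' @param vocab the \code{Vocabulary} (must cover the corpus).
#' @param config a \code{ModelConfig} with \code{dVoc == vocabSize(vocab)}.
#' @param trainCfg a \code{TrainingConfig}.
#' @param init optional \code{SmilesLM} to continue from.
#' @param verbose print the loss every 50 steps.
#' @return a trained \code{\linkS4class{SmilesLM}} whose \code{trace} holds
#'   the per-step loss and number of deleted conditions.
#' @export
trainModel <- function(split, vocab, config, trainCfg, init = NULL,
                       verbose = FALSE) {
  records <- trainRecords(split)
  stopifnot(nrow(records) >= 1L)
  model <- if (is.null(init)) smilesLM(vocab, config, seed = trainCfg@seed)
  else init
  params <- model@params
  state <- new.env(parent = emptyenv())
  state$m <- list()
  state$v <- list()
  trace <- data.frame(step = integer(0), loss = numeric(0),
                      nConditionsDeleted = integer(0))
  withr::with_seed(trainCfg@seed, {
    queue <- sample.int(nrow(records))
    nextBatch <- function() {
      while (length(queue) < trainCfg@batchSize)
        queue <<- c(queue, sample.int(nrow(records)))
      idx <- queue[seq_len(trainCfg@batchSize)]
      queue <<- queue[-seq_len(trainCfg@batchSize)]
      idx
    }
    for (step in seq_len(trainCfg@steps)) {
      acc <- list()
      lossSum <- 0
      nDel <- 0L
      for (k in seq_len(trainCfg@gradAccumSteps)) {
        idx <- nextBatch()
        batch <- collateBatch(records[idx, , drop = FALSE], vocab, trainCfg)
        nDel <- nDel + length(batch$deletedTypes) + batch$tsDeleted
        mb <- .microBatch(params, config, batch)
        lossSum <- lossSum + mb$loss
        for (nm in names(mb$grads))
          acc[[nm]] <- if (is.null(acc[[nm]])) mb$grads[[nm]] else
            acc[[nm]] + mb$grads[[nm]]
      }
      acc <- lapply(acc, function(gm) gm / trainCfg@gradAccumSteps)
      loss <- lossSum / trainCfg@gradAccumSteps
      if (!is.finite(loss))
        stop("training diverged at step ", step, " (loss = ", loss, ")")
      params <- .adamwStep(params, acc, state, trainCfg, step)
      trace <- rbind(trace, data.frame(step = step, loss = loss,
                                       nConditionsDeleted = nDel))
      if (verbose && step %% 50L == 0L)
        message("step ", step, "  loss ", signif(loss, 4))
    }
  })
  new("SmilesLM", params = params, config = config, vocab = vocab,
      trace = trace)
}
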