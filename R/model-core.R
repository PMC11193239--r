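## Decoder-only transformer core: causal masked multi-head attention with
## rotary positional embeddings, RMSNorm pre-normalization, SwiGLU
## feed-forward blocks, and the context-ingestion scheme that prepends
## numeric-condition embeddings and a token-sequence condition to the SMILES
## embeddings: X = Concat(C, S).
##
## Weights live in a flat named list so the optimizer and the parameter
## count can treat them uniformly.  All token ids are 0-based.

#' Construct a model configuration
#'
#' Defaults are the full-scale hyperparameters (8 heads, 8 blocks,
#' d_emb 384, d_ffn 1024, dropout 0.1, SMILES cap 256, 3 numeric condition
#' types, token-sequence cap 50, rotary base 10000).
#'
#' @param dVoc vocabulary size (take it from the \code{Vocabulary} in use).
#' @param nHeads,nBlocks,dEmb,dFfn,dropoutP,maxSmilesLen,nNumericConditions,maxTsLen,ropeBase
#'   see \code{\linkS4class{ModelConfig}}.
#' @return a \code{ModelConfig}.
#' @export
modelConfig <- function(dVoc, nHeads = 8L, nBlocks = 8L, dEmb = 384L,
                        dFfn = 1024L, dropoutP = 0.1, maxSmilesLen = 256L,
                        nNumericConditions = 3L, maxTsLen = 50L,
                        ropeBase = 10000) {
  new("ModelConfig", nHeads = as.integer(nHeads), nBlocks = as.integer(nBlocks),
      dEmb = as.integer(dEmb), dFfn = as.integer(dFfn), dVoc = as.integer(dVoc),
      dropoutP = dropoutP, maxSmilesLen = as.integer(maxSmilesLen),
      nNumericConditions = as.integer(nNumericConditions),
      maxTsLen = as.integer(maxTsLen), ropeBase = ropeBase)
}

#' Per-head dimension of a configuration
#'
#' @param config a \code{ModelConfig}.
#' @return \code{dEmb / nHeads} (both key and value dimension).
#' @export
headDim <- function(config) config@dEmb %/% config@nHeads

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig:", object@nBlocks, "blocks,", object@nHeads,
      "heads (d_k = d_v =", paste0(headDim(object), "),"),
      "d_emb", object@dEmb, ", d_ffn", object@dFfn, ", d_voc", object@dVoc,
      "\n  dropout", object@dropoutP, ", max SMILES len",
      object@maxSmilesLen, ",", object@nNumericConditions,
      "numeric condition types, token-sequence cap", object@maxTsLen, "\n")
})

## ---- parameter inventory ------------------------------------------------

# Named list of array dims for every trainable weight group.  Per block:
# fused head projections Wq/Wk/Wv (dEmb x dEmb, heads side by side), output
# projection Wo, SwiGLU W1/W3 (dEmb x dFfn) and W2 (dFfn x dEmb), and the
# two pre-normalization gains.  The token-sequence condition reuses the
# token embedding table plus an additive table of the same shape and a
# single label vector.  Output projection is untied from the embedding.
.paramShapes <- function(config) {
  d <- config@dEmb
  shp <- list(
    tok_emb = c(config@dVoc, d),
    ts_emb = c(config@dVoc, d),
    ts_label = d,
    num_w = c(config@nNumericConditions, d),
    num_b = c(config@nNumericConditions, d),
    type_enc = c(config@nNumericConditions, d),
    g_final = d,
    Wout = c(d, config@dVoc))
  for (i in seq_len(config@nBlocks)) {
    blk <- list(c(d, d), c(d, d), c(d, d), c(d, d),
                c(d, config@dFfn), c(config@dFfn, d), c(d, config@dFfn),
                d, d)
    names(blk) <- paste0("b", i, ".",
                         c("Wq", "Wk", "Wv", "Wo", "W1", "W2", "W3",
                           "g_attn", "g_ffn"))
    shp <- c(shp, blk)
  }
  shp
}

#' Count trainable parameters
#'
#' Exact total over the enumerated shape inventory; a pure function of the
#' configuration.  The full-scale configuration with a 591-token vocabulary
#' comes to about 15 million parameters.
#'
#' @param config a \code{ModelConfig}.
#' @return integer-valued numeric scalar.
#' @export
countParameters <- function(config) {
  sum(vapply(.paramShapes(config), prod, numeric(1)))
}

#' Initialize model weights
#'
#' Matrices are drawn N(0, 0.02^2); normalization gains start at one and the
#' numeric-projection biases at zero.  Deterministic given the seed.
#'
#' @param config a \code{ModelConfig}.
#' @param seed integer seed.
#' @return flat named list of weight arrays.
#' @export
initParams <- function(config, seed = 1L) {
  shapes <- .paramShapes(config)
  withr::with_seed(as.integer(seed), {
    params <- lapply(names(shapes), function(nm) {
      dm <- shapes[[nm]]
      if (grepl("^g_|\\.g_", nm)) return(rep(1, dm))
      if (nm == "num_b") return(matrix(0, dm[1], dm[2]))
      if (length(dm) == 1L) return(stats::rnorm(dm, 0, 0.02))
      matrix(stats::rnorm(prod(dm), 0, 0.02), dm[1], dm[2])
    })
    names(params) <- names(shapes)
    params
  })
}

#' Create an untrained model
#'
#' @param vocab a \code{Vocabulary}; fixes \code{dVoc}.
#' @param config a \code{ModelConfig} built against the same vocabulary.
#' @param seed initialization seed.
#' @return a \code{\linkS4class{SmilesLM}}.
#' @export
smilesLM <- function(vocab, config, seed = 1L) {
  new("SmilesLM", params = initParams(config, seed), config = config,
      vocab = vocab,
      trace = data.frame(step = integer(0), loss = numeric(0)))
}

setMethod("show", "SmilesLM", function(object) {
  cat("SmilesLM with", format(countParameters(object@config), big.mark = ","),
      "parameters over a", vocabSize(object@vocab), "token vocabulary\n")
  if (nrow(object@trace))
    cat("  trained for", max(object@trace$step), "optimizer steps; final loss",
        signif(utils::tail(object@trace$loss, 1), 4), "\n")
  else cat("  untrained (random initialization)\n")
})

#' @describeIn smilesLM the weight list.
#' @param object a \code{SmilesLM}.
#' @export
modelParams <- function(object) object@params

#' @describeIn smilesLM the configuration.
#' @export
modelConfigOf <- function(object) object@config

#' @describeIn smilesLM the vocabulary.
#' @export
modelVocab <- function(object) object@vocab

#' @describeIn smilesLM the per-step loss trace.
#' @export
lossTrace <- function(object) object@trace

## ---- primitive operations ----------------------------------------------

#' Causal attention mask
#'
#' Square matrix with 0 on and below the diagonal and -Inf strictly above,
#' so position i can attend only to positions <= i.  (The -Inf entries are
#' neutralized by max-subtraction inside the softmax.)
#'
#' @param L sequence length (>= 1).
#' @return L x L numeric matrix.
#' @export
causalMask <- function(L) {
  if (L < 1L) stop("L must be >= 1")
  m <- matrix(0, L, L)
  m[upper.tri(m)] <- -Inf
  m
}

# Row-wise softmax with max subtraction; -Inf entries get weight 0.
.softmaxRows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Masked scaled dot-product attention
#'
#' \code{softmax(Q K^T / sqrt(d_k) + M) V}: each output row is a convex
#' combination of the value rows its position is allowed to see.
#'
#' @param Q,K L x d_k query/key matrices.
#' @param V L x d_v value matrix.
#' @param mask L x L additive mask (see \code{\link{causalMask}}).
#' @return L x d_v matrix.
#' @export
maskedAttention <- function(Q, K, V, mask) {
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V) || nrow(Q) != nrow(mask) ||
      nrow(K) != ncol(mask))
    stop("shape mismatch in maskedAttention")
  scores <- (Q %*% t(K)) / sqrt(ncol(Q)) + mask
  .softmaxRows(scores) %*% V
}

# cos/sin tables for rotary embeddings: rows = positions, cols = pairs.
.ropeTables <- function(positions, d, base) {
  j <- seq_len(d %/% 2L)
  theta <- base^(-(2 * (j - 1)) / d)
  ang <- outer(positions, theta)
  list(cos = cos(ang), sin = sin(ang))
}

#' Apply rotary positional embedding
#'
#' Rotates consecutive column pairs (1,2), (3,4), ... of each row by the
#' angle pos * theta_j with theta_j = base^(-2(j-1)/d).  Position 0 is the
#' identity and each pair's norm is preserved, so attention scores between
#' rotated queries and keys depend on relative offsets only.
#'
#' @param X L x d matrix (d even), one row per position.
#' @param positions 0-based position of each row.
#' @param base frequency-ladder base (default 10000).
#' @return the rotated matrix.
#' @export
applyRope <- function(X, positions, base = 10000) {
  d <- ncol(X)
  if (d %% 2L != 0L) stop("head dimension must be even for rotary embedding")
  stopifnot(length(positions) == nrow(X))
  tb <- .ropeTables(positions, d, base)
  odd <- seq(1L, d, by = 2L)
  even <- odd + 1L
  x1 <- X[, odd, drop = FALSE]
  x2 <- X[, even, drop = FALSE]
  out <- X
  out[, odd] <- x1 * tb$cos - x2 * tb$sin
  out[, even] <- x1 * tb$sin + x2 * tb$cos
  out
}

#' Root-mean-square normalization
#'
#' Each row (or the single vector) is scaled by 1/sqrt(mean(x^2) + eps) and
#' multiplied elementwise by the learned gain; a pre-normalization step in
#' every decoder block.
#'
#' @param x numeric vector or L x d matrix.
#' @param gain length-d gain vector.
#' @param eps stabilizer for all-zero input (default 1e-5).
#' @return same shape as \code{x}.
#' @export
rmsNorm <- function(x, gain, eps = 1e-5) {
  if (is.matrix(x)) {
    r <- sqrt(rowMeans(x^2) + eps)
    sweep(x / r, 2L, gain, `*`)
  } else {
    x / sqrt(mean(x^2) + eps) * gain
  }
}

.silu <- function(x) x / (1 + exp(-x))

#' SwiGLU feed-forward layer
#'
#' \code{(silu(X W1) * (X W3)) W2} with the elementwise product as the gate.
#'
#' @param X L x d_emb input.
#' @param W1,W3 d_emb x d_ffn weight matrices.
#' @param W2 d_ffn x d_emb weight matrix.
#' @return L x d_emb matrix.
#' @export
swigluFFN <- function(X, W1, W2, W3) {
  (.silu(X %*% W1) * (X %*% W3)) %*% W2
}

#' Multi-head causal self-attention with rotary embeddings
#'
#' Projects X to per-head queries, keys and values, rotates Q and K by
#' position, runs masked attention per head, concatenates the heads and
#' applies the output projection.
#'
#' @param X L x d_emb input (already normalized).
#' @param Wq,Wk,Wv,Wo d_emb x d_emb projection matrices (heads side by
#'   side).
#' @param positions 0-based positions for rotary embedding.
#' @param nHeads number of heads.
#' @param ropeBase rotary base.
#' @return L x d_emb matrix.
#' @export
multiHeadAttention <- function(X, Wq, Wk, Wv, Wo, positions, nHeads,
                               ropeBase = 10000) {
  L <- nrow(X)
  d <- ncol(X)
  dk <- d %/% nHeads
  Q <- X %*% Wq
  K <- X %*% Wk
  V <- X %*% Wv
  mask <- causalMask(L)
  out <- matrix(0, L, d)
  for (h in seq_len(nHeads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- applyRope(Q[, idx, drop = FALSE], positions, ropeBase)
    Kh <- applyRope(K[, idx, drop = FALSE], positions, ropeBase)
    out[, idx] <- maskedAttention(Qh, Kh, V[, idx, drop = FALSE], mask)
  }
  out %*% Wo
}

## ---- context ingestion and forward pass ---------------------------------

#' Build a condition bundle
#'
#' @param logp,sascore,mw optional numeric condition values (molecular
#'   weight on the /100 training scale); omit (NA) to leave a condition out.
#' @param tsIds optional 0-based token ids of a token-sequence condition.
#' @return a \code{\linkS4class{ContextBundle}}.
#' @export
contextBundle <- function(logp = NA_real_, sascore = NA_real_, mw = NA_real_,
                          tsIds = integer(0)) {
  vals <- c(logp, sascore, mw)
  keep <- !is.na(vals)
  new("ContextBundle", numericTypes = (0:2)[keep],
      numericValues = as.numeric(vals[keep]), tsIds = as.integer(tsIds))
}

#' @describeIn contextBundle number of context rows (numeric + token
#'   sequence).
#' @param bundle a \code{ContextBundle}.
#' @export
contextLength <- function(bundle) {
  length(bundle@numericTypes) + length(bundle@tsIds)
}

setMethod("show", "ContextBundle", function(object) {
  lab <- c("logP", "SAScore", "mw/100")
  if (length(object@numericTypes))
    cat("ContextBundle:",
        paste(lab[object@numericTypes + 1L], "=", object@numericValues,
              collapse = ", "),
        if (length(object@tsIds)) paste("+", length(object@tsIds),
                                        "token-sequence ids") else "", "\n")
  else if (length(object@tsIds))
    cat("ContextBundle:", length(object@tsIds), "token-sequence ids\n")
  else cat("ContextBundle: empty (unconditional)\n")
})

#' Embed a condition bundle into context rows
#'
#' Each numeric value is mapped to the embedding dimension by its own
#' per-type linear projection (value * w_t + b_t) and the learned type
#' encoding is added, so the model sees the value and its label.  The
#' token-sequence condition reuses the shared token embedding table, adds a
#' second table specific to the token-sequence role, and a single learned
#' label vector is added to every row.  An empty bundle yields a 0-row
#' matrix (unconditional sequence).
#'
#' @param bundle a \code{ContextBundle}.
#' @param params weight list (see \code{\link{initParams}}).
#' @param config a \code{ModelConfig}.
#' @return c x d_emb matrix, c = #numeric conditions + token-sequence length.
#' @export
embedContext <- function(bundle, params, config) {
  validObject(bundle)
  if (length(bundle@numericTypes) &&
      any(bundle@numericTypes >= config@nNumericConditions))
    stop("numeric condition type id out of range")
  if (length(bundle@tsIds) > config@maxTsLen)
    stop("token-sequence condition longer than maxTsLen")
  rows <- matrix(0, 0, config@dEmb)
  if (length(bundle@numericTypes)) {
    t1 <- bundle@numericTypes + 1L
    rows <- bundle@numericValues * params$num_w[t1, , drop = FALSE] +
      params$num_b[t1, , drop = FALSE] + params$type_enc[t1, , drop = FALSE]
  }
  if (length(bundle@tsIds)) {
    i1 <- bundle@tsIds + 1L
    ts <- params$tok_emb[i1, , drop = FALSE] +
      params$ts_emb[i1, , drop = FALSE]
    ts <- sweep(ts, 2L, params$ts_label, `+`)
    rows <- rbind(rows, ts)
  }
  rows
}

# Shared forward pass.  Returns raw logits and (optionally) every
# intermediate needed by the hand-written backward pass in train.R.
# dropoutMasks, when supplied, is a list of per-block {attn, ffn} inverted
# dropout masks (already scaled by 1/(1-p)).
.forwardPass <- function(params, config, X, cache = FALSE,
                         dropoutMasks = NULL) {
  L <- nrow(X)
  positions <- 0:(L - 1L)
  mask <- causalMask(L)
  dk <- headDim(config)
  tb <- .ropeTables(positions, dk, config@ropeBase)
  caches <- if (cache) vector("list", config@nBlocks)
  x <- X
  for (b in seq_len(config@nBlocks)) {
    p <- function(nm) params[[paste0("b", b, ".", nm)]]
    a <- rmsNorm(x, p("g_attn"))
    Q <- a %*% p("Wq"); K <- a %*% p("Wk"); V <- a %*% p("Wv")
    heads <- matrix(0, L, config@dEmb)
    hc <- if (cache) vector("list", config@nHeads)
    for (h in seq_len(config@nHeads)) {
      idx <- ((h - 1L) * dk + 1L):(h * dk)
      Qh <- .ropeApply(Q[, idx, drop = FALSE], tb)
      Kh <- .ropeApply(K[, idx, drop = FALSE], tb)
      S <- (Qh %*% t(Kh)) / sqrt(dk) + mask
      A <- .softmaxRows(S)
      heads[, idx] <- A %*% V[, idx, drop = FALSE]
      if (cache) hc[[h]] <- list(Qh = Qh, Kh = Kh, A = A)
    }
    attnOut <- heads %*% p("Wo")
    if (!is.null(dropoutMasks)) attnOut <- attnOut * dropoutMasks[[b]]$attn
    x1 <- x + attnOut
    f <- rmsNorm(x1, p("g_ffn"))
    U <- f %*% p("W1"); G <- f %*% p("W3")
    Su <- .silu(U)
    ffnOut <- (Su * G) %*% p("W2")
    if (!is.null(dropoutMasks)) ffnOut <- ffnOut * dropoutMasks[[b]]$ffn
    x2 <- x1 + ffnOut
    if (cache)
      caches[[b]] <- list(xin = x, a = a, Q = Q, K = K, V = V, heads = hc,
                          headsMat = heads, x1 = x1, f = f, U = U, G = G,
                          Su = Su)
    x <- x2
  }
  y <- rmsNorm(x, params$g_final)
  logits <- y %*% params$Wout
  list(logits = logits, xFinal = x, y = y, caches = caches, ropeTb = tb,
       mask = mask)
}

# Apply precomputed rope tables (columns already split into pairs).
.ropeApply <- function(Xh, tb) {
  d <- ncol(Xh)
  odd <- seq(1L, d, by = 2L)
  even <- odd + 1L
  x1 <- Xh[, odd, drop = FALSE]
  x2 <- Xh[, even, drop = FALSE]
  Xh[, odd] <- x1 * tb$cos - x2 * tb$sin
  Xh[, even] <- x1 * tb$sin + x2 * tb$cos
  Xh
}

# Inverse rotation (transpose of the rotation), for the backward pass.
.ropeApplyInv <- function(Xh, tb) {
  d <- ncol(Xh)
  odd <- seq(1L, d, by = 2L)
  even <- odd + 1L
  x1 <- Xh[, odd, drop = FALSE]
  x2 <- Xh[, even, drop = FALSE]
  Xh[, odd] <- x1 * tb$cos + x2 * tb$sin
  Xh[, even] <- -x1 * tb$sin + x2 * tb$cos
  Xh
}

#' Forward pass: next-token log-probabilities
#'
#' Embeds the context rows (numeric conditions first, then the
#' token-sequence condition) followed by the SMILES token embeddings,
#' applies rotary positions 0..L-1 over the whole concatenated sequence,
#' runs the decoder stack and returns the log-softmaxed output rows: row t
#' holds the log-probabilities of the token following position t.
#' Deterministic (dropout disabled); used for inference and diagnostics.
#'
#' @param model a \code{SmilesLM}.
#' @param bundle a \code{ContextBundle} (possibly empty).
#' @param smilesIds framed 0-based id vector (\code{[CLS] ... [SEP]}, or a
#'   prefix during generation).
#' @return L_total x d_voc matrix of log-probabilities, with the context
#'   length attached as attribute \code{"contextLength"}.
#' @export
modelForward <- function(model, bundle, smilesIds) {
  config <- model@config
  params <- model@params
  ctx <- embedContext(bundle, params, config)
  L <- nrow(ctx) + length(smilesIds)
  if (L > config@maxSmilesLen + config@nNumericConditions + config@maxTsLen +
      2L)
    stop("sequence too long for this configuration")
  X <- rbind(ctx, params$tok_emb[smilesIds + 1L, , drop = FALSE])
  logits <- .forwardPass(params, config, X)$logits
  lse <- apply(logits, 1L, function(r) {
    m <- max(r); m + log(sum(exp(r - m)))
  })
  structure(logits - lse, contextLength = nrow(ctx))
}
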