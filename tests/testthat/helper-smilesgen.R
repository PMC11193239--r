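# Shared fixtures, built in code and cached across test files (the chem
# bridge pays a python start-up cost per call, so batches are reused).

.testCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.testCache[[key]])) .testCache[[key]] <- force(expr)
  .testCache[[key]]
}

toyCorpus <- function(n = 400L, seed = 7L) {
  cached(paste0("corpus_", n, "_", seed), generateToyCorpus(n, seed = seed))
}

toyVocab <- function(n = 400L, seed = 7L) {
  cached(paste0("vocab_", n, "_", seed), buildVocab(toyCorpus(n, seed)$smiles))
}

tinyConfig <- function(vocab, dEmb = 16L, nHeads = 2L, nBlocks = 2L,
                       dFfn = 24L, dropoutP = 0) {
  modelConfig(dVoc = vocabSize(vocab), nHeads = nHeads, nBlocks = nBlocks,
              dEmb = dEmb, dFfn = dFfn, dropoutP = dropoutP)
}

tinyModel <- function(seed = 5L) {
  cached(paste0("tinymodel_", seed), {
    vocab <- toyVocab()
    smilesLM(vocab, tinyConfig(vocab), seed = seed)
  })
}

# Independent brute-force oracles (scalar loops, no reuse of package code).

bruteSoftmaxAttention <- function(Q, K, V, mask) {
  L <- nrow(Q)
  out <- matrix(0, L, ncol(V))
  for (i in seq_len(L)) {
    s <- numeric(L)
    for (j in seq_len(L)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(Q)) + mask[i, j]
    e <- exp(s - max(s))
    w <- e / sum(e)
    for (j in seq_len(L)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

bruteRmsNorm <- function(x, gain, eps = 1e-5) {
  r <- sqrt(sum(x^2) / length(x) + eps)
  sapply(seq_along(x), function(i) x[i] / r * gain[i])
}

bruteSwiglu <- function(X, W1, W2, W3) {
  L <- nrow(X)
  out <- matrix(0, L, ncol(W2))
  for (i in seq_len(L)) {
    u <- drop(X[i, ] %*% W1)
    v <- drop(X[i, ] %*% W3)
    silu <- u / (1 + exp(-u))
    out[i, ] <- drop((silu * v) %*% W2)
  }
  out
}

bruteSequenceLoss <- function(logits, targets, mask) {
  tot <- 0
  n <- 0L
  for (t in seq_along(mask)) {
    if (!mask[t]) next
    p <- exp(logits[t, ]) / sum(exp(logits[t, ]))
    tot <- tot - log(p[targets[t] + 1L])
    n <- n + 1L
  }
  tot / n
}
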