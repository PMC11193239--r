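test_that("causal mask zeros the lower triangle and -Inf above", {
  expect_identical(causalMask(1), matrix(0, 1, 1))
  expect_identical(causalMask(2), matrix(c(0, 0, -Inf, 0), 2, 2))
  m4 <- causalMask(4)
  expect_identical(sum(m4 == 0), 10L)          # L(L+1)/2
  expect_true(all(m4[upper.tri(m4)] == -Inf))
  expect_error(causalMask(0), ">= 1")
})

test_that("masked attention mixes only the allowed prefix", {
  set.seed(1)
  V <- matrix(rnorm(12), 4, 3)
  # single position: output is the single value row
  expect_equal(maskedAttention(matrix(1, 1, 2), matrix(1, 1, 2),
                               V[1, , drop = FALSE], causalMask(1)),
               V[1, , drop = FALSE])
  # zero logits: row i is the uniform average of value rows 1..i
  Z <- matrix(0, 4, 2)
  out <- maskedAttention(Z, Z, V, causalMask(4))
  for (i in 1:4)
    expect_equal(out[i, ], colMeans(V[1:i, , drop = FALSE]))
  # random instance against the scalar brute-force oracle
  Q <- matrix(rnorm(8), 4, 2); K <- matrix(rnorm(8), 4, 2)
  expect_equal(maskedAttention(Q, K, V, causalMask(4)),
               bruteSoftmaxAttention(Q, K, V, causalMask(4)),
               tolerance = 1e-12)
  expect_error(maskedAttention(Q, K[, 1, drop = FALSE], V, causalMask(4)),
               "shape")
})

test_that("attention weights are row-stochastic over the prefix", {
  set.seed(2)
  L <- 6
  Q <- matrix(rnorm(L * 4), L, 4)
  K <- matrix(rnorm(L * 4), L, 4)
  A <- maskedAttention(Q, K, diag(L), causalMask(L))  # V = I recovers A
  expect_equal(rowSums(A), rep(1, L))
  expect_true(all(A[upper.tri(A)] == 0))
  expect_true(all(A >= 0))
})

test_that("rotary embedding: identity at 0, isometry, relative positions", {
  set.seed(3)
  X <- matrix(rnorm(40), 5, 8)
  expect_equal(applyRope(X, rep(0, 5)), X)
  R <- applyRope(X, 0:4)
  for (j in seq(1, 7, by = 2))   # per-pair norms preserved
    expect_equal(R[, j]^2 + R[, j + 1]^2, X[, j]^2 + X[, j + 1]^2)
  # dot(rope(q,p1), rope(k,p2)) depends only on p1 - p2
  q <- matrix(rnorm(8), 1, 8); k <- matrix(rnorm(8), 1, 8)
  for (off in 0:8) {
    dots <- vapply(0:5, function(p)
      sum(applyRope(q, p + off) * applyRope(k, p)), numeric(1))
    expect_equal(max(dots) - min(dots), 0, tolerance = 1e-10)
  }
  expect_error(applyRope(matrix(1, 2, 3), 0:1), "even")
})

test_that("rmsNorm matches its formula and is scale invariant", {
  expect_equal(rmsNorm(rep(2, 8), rep(1, 8)), rep(1, 8), tolerance = 1e-5)
  set.seed(4)
  x <- rnorm(16); g <- runif(16)
  expect_equal(rmsNorm(x, g), bruteRmsNorm(x, g), tolerance = 1e-12)
  expect_equal(rmsNorm(7 * x, g), rmsNorm(x, g), tolerance = 1e-5)
  expect_true(all(is.finite(rmsNorm(rep(0, 8), rep(1, 8)))))
  # matrix form normalizes each row independently
  M <- matrix(rnorm(32), 4, 8)
  MM <- rmsNorm(M, g[1:8])
  expect_equal(MM[2, ], bruteRmsNorm(M[2, ], g[1:8]), tolerance = 1e-12)
})

test_that("SwiGLU gate matches elementwise recomputation", {
  set.seed(5)
  W1 <- matrix(rnorm(24), 4, 6); W3 <- matrix(rnorm(24), 4, 6)
  W2 <- matrix(rnorm(24), 6, 4)
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(swigluFFN(X, W1, W2, W3), bruteSwiglu(X, W1, W2, W3),
               tolerance = 1e-12)
  expect_equal(swigluFFN(matrix(0, 3, 4), W1, W2, W3), matrix(0, 3, 4))
  expect_equal(swigluFFN(X, W1, W2, 0 * W3), matrix(0, 3, 4))
})

test_that("one-head attention reduces to masked attention plus W_O", {
  set.seed(6)
  d <- 6; L <- 5
  Wq <- matrix(rnorm(d * d), d); Wk <- matrix(rnorm(d * d), d)
  Wv <- matrix(rnorm(d * d), d); Wo <- matrix(rnorm(d * d), d)
  X <- matrix(rnorm(L * d), L, d)
  pos <- 0:(L - 1)
  got <- multiHeadAttention(X, Wq, Wk, Wv, Wo, pos, nHeads = 1L)
  want <- maskedAttention(applyRope(X %*% Wq, pos), applyRope(X %*% Wk, pos),
                          X %*% Wv, causalMask(L)) %*% Wo
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("parameter count equals a hand-summed shape inventory", {
  cfg <- modelConfig(dVoc = 40L, nHeads = 4L, nBlocks = 2L, dEmb = 64L,
                     dFfn = 128L)
  perBlock <- 4 * 64 * 64 +            # Wq Wk Wv Wo
    2 * 64 * 128 + 128 * 64 +          # W1 W3, W2
    2 * 64                             # two norm gains
  want <- 40 * 64 +                    # token embedding
    40 * 64 + 64 +                     # ts table + label vector
    3 * (64 + 64 + 64) +               # per-type value proj w, b, type enc
    2 * perBlock +
    64 +                               # final norm gain
    64 * 40                            # output projection
  expect_identical(countParameters(cfg), want)
  # block additivity
  cfg4 <- modelConfig(dVoc = 40L, nHeads = 4L, nBlocks = 4L, dEmb = 64L,
                      dFfn = 128L)
  expect_identical(countParameters(cfg4) - countParameters(cfg),
                   2 * perBlock)
  # initParams realizes exactly the inventory
  p <- initParams(cfg, seed = 1)
  expect_identical(sum(vapply(p, length, integer(1))), as.integer(want))
})

test_that("full-scale configuration has d_k = d_v = 48", {
  cfg <- modelConfig(dVoc = 591L)
  expect_identical(headDim(cfg), 48L)
  expect_identical(cfg@dEmb %/% cfg@nHeads, 384L %/% 8L)
})

test_that("context embedding layout: numeric rows then token-sequence rows", {
  model <- tinyModel()
  cfg <- modelConfigOf(model)
  p <- modelParams(model)
  expect_identical(nrow(embedContext(contextBundle(), p, cfg)), 0L)
  b <- contextBundle(logp = 1, sascore = 2, mw = 3, tsIds = c(3L, 4L, 5L, 6L, 7L))
  expect_identical(nrow(embedContext(b, p, cfg)), 8L)
  # same value under different type ids embeds differently
  e1 <- embedContext(contextBundle(logp = 2), p, cfg)
  e2 <- embedContext(contextBundle(sascore = 2), p, cfg)
  expect_gt(max(abs(e1 - e2)), 0)
  expect_error(embedContext(new("ContextBundle", numericTypes = 7L,
                                numericValues = 1, tsIds = integer(0)),
                            p, cfg), "out of range")
})

test_that("forward rows are normalized distributions and causal", {
  model <- tinyModel()
  vocab <- modelVocab(model)
  ids <- encodeSmiles("CCOC", vocab)
  b <- contextBundle(mw = 1.0)
  lp <- modelForward(model, b, ids)
  expect_equal(rowSums(exp(lp)), rep(1, nrow(lp)), tolerance = 1e-9)
  expect_identical(attr(lp, "contextLength"), 1L)
  # perturbing a later token leaves earlier rows bit-identical
  ids2 <- ids
  ids2[4] <- ids2[4] + 1L
  lp2 <- modelForward(model, b, ids2)
  expect_identical(lp[1:(1 + 3), ], lp2[1:(1 + 3), ])
  expect_false(isTRUE(all.equal(lp[1 + 4, ], lp2[1 + 4, ])))
  # changing a condition value changes SMILES-region logits
  lp3 <- modelForward(model, contextBundle(mw = 2.0), ids)
  expect_gt(max(abs(lp3[3:nrow(lp3), ] - lp[3:nrow(lp), ])), 0)
  # deterministic in evaluation mode
  expect_identical(lp, modelForward(model, b, ids))
})
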