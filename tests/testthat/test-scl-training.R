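test_that("token-sequence conditions are contiguous bounded slices", {
  expect_identical(sampleTsCondition(42L), 42L)
  ids <- 100:119
  set.seed(1)
  for (i in 1:2000) {
    sl <- sampleTsCondition(ids)
    expect_true(length(sl) >= 1 && length(sl) <= 50)
    # contiguity: the slice appears verbatim in the source
    start <- match(sl[1], ids)
    expect_identical(ids[start:(start + length(sl) - 1L)], sl)
  }
  # a 200-token sequence is always capped at 50
  long <- 1:200
  set.seed(2)
  lens <- replicate(500, length(sampleTsCondition(long)))
  expect_true(all(lens <= 50))
  expect_true(any(lens == 50))   # the cap is actually reached
})

test_that("sclDrop applies one batch-wide pattern; 0 and 1 are exact", {
  mk <- function() new("ContextBundle", numericTypes = 0:2,
                       numericValues = c(1, 2, 3), tsIds = c(5L, 6L))
  bundles <- replicate(4, mk())
  set.seed(3)
  same <- sclDrop(bundles, 0)
  expect_identical(same$bundles[[2]]@numericTypes, 0:2)
  expect_identical(same$bundles[[3]]@tsIds, c(5L, 6L))
  gone <- sclDrop(bundles, 1)
  for (b in gone$bundles) expect_identical(contextLength(b), 0L)
  expect_identical(gone$deletedTypes, 0:2)
  # the surviving layout is identical across the batch
  set.seed(4)
  for (i in 1:50) {
    d <- sclDrop(bundles, 0.5)
    layouts <- unique(lapply(d$bundles, function(b)
      list(b@numericTypes, length(b@tsIds))))
    expect_length(layouts, 1L)
  }
})

test_that("per-type deletion frequency matches Binomial(3, p_del)", {
  mk <- function() new("ContextBundle", numericTypes = 0:2,
                       numericValues = c(1, 2, 3), tsIds = 4L)
  bundles <- list(mk())
  set.seed(5)
  nBatches <- 4000
  deleted <- matrix(FALSE, nBatches, 3)
  tsDel <- logical(nBatches)
  for (i in seq_len(nBatches)) {
    d <- sclDrop(bundles, 0.15)
    deleted[i, ] <- (0:2) %in% d$deletedTypes
    tsDel[i] <- d$tsDeleted
  }
  se <- sqrt(0.15 * 0.85 / nBatches)
  for (k in 1:3) expect_lt(abs(mean(deleted[, k]) - 0.15), 3 * se)
  expect_lt(abs(mean(tsDel) - 0.15), 3 * se)
  # expected deletions per batch = 3 * 0.15
  expect_lt(abs(mean(rowSums(deleted)) - 0.45), 3 * sqrt(3) * se)
})

test_that("collate pads to the batch maximum and masks only SMILES targets", {
  vocab <- toyVocab()
  rec <- toyCorpus()[1:6, ]
  tc <- trainingConfig(batchSize = 6L, pDel = 0, conditionTypes = 0:2,
                       useTsCondition = TRUE, seed = 1L)
  set.seed(6)
  batch <- collateBatch(rec, vocab, tc)
  lens <- lengths(batch$inputIds)
  expect_length(unique(lens), 1L)   # all padded to common length
  framedLens <- vapply(rec$smiles, function(s)
    length(encodeSmiles(s, vocab)), integer(1), USE.NAMES = FALSE)
  expect_identical(max(framedLens), unique(lens))
  ctxLen <- contextLength(batch$bundles[[1]])
  expect_true(ctxLen >= 3L)   # 3 numerics survive at pDel = 0, plus ts
  for (i in seq_len(6)) {
    m <- batch$lossMasks[[i]]
    # context rows are never scored
    expect_true(all(!m[seq_len(ctxLen)]))
    # a framed SMILES of length m yields m - 1 targets
    expect_identical(sum(m), framedLens[i] - 1L)
    # targets are the shifted input ids over the scored region
    tg <- batch$targets[[i]]
    scored <- which(!is.na(tg))
    expect_identical(tg[scored], batch$inputIds[[i]][scored + 1L])
  }
  expect_identical(batch$nTargets, sum(framedLens - 1L))
})

test_that("sequence loss: analytic values and brute-force agreement", {
  V <- 23L
  L <- 7L
  uniform <- matrix(0, L, V)
  tg <- c(NA, NA, 3L, 4L, 5L, NA, 2L)
  mask <- !is.na(tg)
  expect_equal(sequenceLoss(uniform, tg, mask), log(V), tolerance = 1e-12)
  # dominant logit at the true token drives the loss to zero
  sharp <- uniform
  for (t in which(mask)) sharp[t, tg[t] + 1L] <- 200
  expect_lt(sequenceLoss(sharp, tg, mask), 1e-8)
  # unscored rows (context, pads) cannot influence the loss
  noise <- uniform
  noise[!mask, ] <- rnorm(sum(!mask) * V, sd = 50)
  expect_identical(sequenceLoss(noise, tg, mask),
                   sequenceLoss(uniform, tg, mask))
  set.seed(7)
  lg <- matrix(rnorm(L * V), L, V)
  expect_equal(sequenceLoss(lg, tg, mask), bruteSequenceLoss(lg, tg, mask),
               tolerance = 1e-12)
  expect_error(sequenceLoss(lg, tg, rep(FALSE, L)), "degenerate")
})

test_that("short training runs reduce the loss deterministically", {
  rec <- toyCorpus(300L)
  vocab <- toyVocab()
  split <- splitCorpus(rec, seed = 2L)
  cfg <- tinyConfig(vocab, dEmb = 32L, dFfn = 48L)
  tc <- trainingConfig(batchSize = 16L, steps = 40L, seed = 9L, lr = 2e-3,
                       gradAccumSteps = 1L, conditionTypes = 2L,
                       useTsCondition = FALSE)
  m1 <- trainModel(split, vocab, cfg, tc)
  tr <- lossTrace(m1)
  expect_identical(nrow(tr), 40L)
  expect_lt(mean(tail(tr$loss, 5)), mean(head(tr$loss, 5)))
  # determinism: same seed, same trace
  m2 <- trainModel(split, vocab, cfg, tc)
  expect_identical(lossTrace(m2), tr)
  expect_identical(modelParams(m2)$Wout, modelParams(m1)$Wout)
})

test_that("a single repeated molecule is memorized to < 0.1 nats/token", {
  vocab <- toyVocab()
  one <- toyCorpus()[3, , drop = FALSE]
  other <- toyCorpus()[4, , drop = FALSE]
  split <- new("CorpusSplit", train = one, test = other, seed = 1L)
  cfg <- tinyConfig(vocab, dEmb = 32L, dFfn = 48L)
  tc <- trainingConfig(batchSize = 4L, steps = 60L, seed = 1L, lr = 5e-3,
                       gradAccumSteps = 1L, conditionTypes = integer(0),
                       useTsCondition = FALSE, pDel = 0)
  m <- trainModel(split, vocab, cfg, tc)
  expect_lt(tail(lossTrace(m)$loss, 1), 0.1)
})

test_that("gradient accumulation averages micro-batch gradients", {
  # accumulating k identical micro-batches must equal a single one
  vocab <- toyVocab()
  rec <- toyCorpus()[5:8, ]
  split <- new("CorpusSplit", train = rec, test = toyCorpus()[9:10, ],
               seed = 1L)
  cfg <- tinyConfig(vocab)
  tcA <- trainingConfig(batchSize = 4L, steps = 3L, seed = 2L,
                        gradAccumSteps = 2L, lr = 1e-3,
                        conditionTypes = 2L, useTsCondition = FALSE, pDel = 0)
  m <- trainModel(split, vocab, cfg, tcA)
  expect_identical(nrow(lossTrace(m)), 3L)
  expect_true(all(is.finite(lossTrace(m)$loss)))
})
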