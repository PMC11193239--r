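test_that("validity counts parseable strings and is permutation invariant", {
  batch <- c("CCO", "CCC", "C(", "c1ccccc1")
  v <- cached("validity_batch", validityMetric(batch))
  expect_equal(v$pct, 75.0)
  expect_identical(v$valid, c("CCO", "CCC", "c1ccccc1"))
  v2 <- cached("validity_batch_perm", validityMetric(rev(batch)))
  expect_equal(v2$pct, v$pct)
  expect_error(validityMetric(character(0)), "empty")
})

test_that("uniqueness is the distinct fraction at the declared size", {
  expect_equal(as.numeric(uniquenessMetric(c("CCO", "CCO", "CCC"))), 200 / 3,
               tolerance = 1e-9)
  expect_equal(as.numeric(uniquenessMetric(letters)), 100)
  x <- c("CCO", "CCC", "CCN")
  expect_equal(as.numeric(uniquenessMetric(rep(x, each = 2))), 50)
  # short batches are computed on what exists and flagged
  u <- uniquenessMetric(x, at = 1000L)
  expect_true(attr(u, "short"))
  expect_equal(as.numeric(u), 100)
  # string-level: synonymous SMILES for one molecule count as distinct
  expect_equal(as.numeric(uniquenessMetric(c("c1ccccc1", "C1=CC=CC=C1"))),
               100)
})

test_that("novelty compares canonical strings against the reference", {
  expect_equal(noveltyMetric(c("CCO", "CCCC"), "CCO"), 50)
  expect_equal(noveltyMetric(c("CCO", "CCC"), c("CCO", "CCC", "CCN")), 0)
  expect_equal(noveltyMetric(c("CCO", "CCC"), c("CCCCCC")), 100)
  expect_error(noveltyMetric("CCO", character(0)), "empty")
})

test_that("MAD is the mean absolute elementwise deviation", {
  expect_equal(madMetric(c(1, 2), c(1, 2)), 0)
  expect_equal(madMetric(c(1, 2), c(2, 4)), 1.5)
  expect_equal(madMetric(c(2, 4), c(1, 2)), 1.5)      # symmetry
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(madMetric(3 * x, 3 * y), 3 * madMetric(x, y))
  brute <- sum(vapply(seq_along(x), function(i) abs(x[i] - y[i]),
                      numeric(1))) / length(x)
  expect_equal(madMetric(x, y), brute, tolerance = 1e-12)
  expect_error(madMetric(1:3, 1:2), "length")
})

test_that("relaxed patterns keep topology but drop bond orders", {
  pat <- cached("pat_benzene", relaxedPattern("c1ccccc1"))
  expect_match(pat, "~")            # bonds rewritten to any-bond
  expect_false(grepl(":", gsub("\\[[^]]*\\]", "", pat)))
  m <- cached("match_benzene",
              matchesCore(c("Cc1ccccc1", "C1CCCCC1", "CCO"), "c1ccccc1"))
  expect_identical(as.logical(m), c(TRUE, TRUE, FALSE))
  m2 <- cached("match_ethanol", matchesCore(c("CCOC", "CC"), "CCO"))
  expect_identical(as.logical(m2), c(TRUE, FALSE))
  expect_error(relaxedPattern("C("), "unparseable")
})

test_that("substructure match rate counts duplicates individually", {
  fx <- generateCoreFixtures()$thiophene
  pos <- cached("sm_pos", substructureMatchRate(fx$positive, fx$core))
  neg <- cached("sm_neg", substructureMatchRate(fx$negative, fx$core))
  expect_equal(as.numeric(pos), 100)
  expect_equal(as.numeric(neg), 0)
  halfdup <- cached("sm_halfdup", substructureMatchRate(
    c(fx$positive[1], fx$positive[1], fx$negative[1], fx$negative[2]),
    fx$core))
  expect_equal(as.numeric(halfdup), 50)
})

test_that("evaluateRun assembles the report per conditioned property only", {
  gen <- c("CCO", "CCO", "C(", "CCC")
  rep1 <- cached("er_uncond", evaluateRun(gen))
  expect_s4_class(rep1, "MetricsReport")
  expect_equal(rep1@validityPct, 75.0)
  expect_length(rep1@madPerProperty, 0L)   # unconditional: no MAD
  expect_true(is.na(rep1@smPct))           # no core: no SM
  # conditioning on the exactly-met value gives MAD 0
  props <- cached("er_props", chemProperties("CCO"))
  rep2 <- cached("er_mw", evaluateRun(c("CCO", "CCO"),
                                      conditions = list(mw_scaled = props$mw / 100)))
  expect_equal(unname(rep2@madPerProperty["mw_scaled"]), 0, tolerance = 1e-9)
  expect_named(rep2@madPerProperty, "mw_scaled")
  # novelty against a reference and reproducibility
  rep3 <- cached("er_nov", evaluateRun(gen, reference = c("CCO")))
  expect_equal(rep3@noveltyPct, 50)        # CCC novel, CCO not
  rep3b <- evaluateRun(gen, reference = c("CCO"))
  expect_identical(rep3b@noveltyPct, rep3@noveltyPct)
  expect_identical(rep3b@validityPct, rep3@validityPct)
})

test_that("report JSON serialization carries all fields", {
  rep1 <- cached("er_uncond", evaluateRun(c("CCO", "CCO", "C(", "CCC")))
  f <- withr::local_tempfile(fileext = ".json")
  writeMetricsReport(rep1, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$validity_pct, 75.0)
  expect_equal(back$n_generated, 4L)
  expect_null(back$sm_pct)
})
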