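test_that("canonicalization matches the toolkit and is idempotent", {
  out <- canonicalizeSmiles(c("OCC", "C1=CC=CC=C1", "CCO"))
  expect_identical(out[1], "CCO")
  expect_identical(out[2], "c1ccccc1")
  expect_identical(canonicalizeSmiles(out), out)   # idempotence
  expect_true(is.na(canonicalizeSmiles("C(")))
})

test_that("filters reject salts, overlong and unparseable strings", {
  v <- passesFilters(c("CCO", "[Na+].[Cl-]", "xx(("),
                     parseable = c(TRUE, TRUE, FALSE))
  expect_identical(v$ok, c(TRUE, FALSE, FALSE))
  expect_identical(v$reason, c("", "salt", "parse"))
  long <- paste(rep("C", 257), collapse = "")
  expect_identical(passesFilters(long, parseable = TRUE)$reason, "length")
  expect_identical(passesFilters(paste(rep("C", 256), collapse = ""),
                                 parseable = TRUE)$reason, "")
  # charged single fragments are kept (salt = multi-fragment)
  expect_true(passesFilters("CC(=O)[O-]", parseable = TRUE)$ok)
})

test_that("annotation produces the toolkit descriptors on the /100 scale", {
  prep <- cached("prep_benzene", prepareCorpus(c("C1=CC=CC=C1", "OCC")))
  rec <- prep$records
  benz <- rec[rec$smiles == "c1ccccc1", ]
  expect_equal(benz$mw_scaled, 0.7811, tolerance = 1e-3)
  expect_true(all(rec$sascore >= 1 & rec$sascore <= 10))
  expect_true(all(rec$mw_scaled > 0))
  # deterministic: a second run agrees exactly
  prep2 <- prepareCorpus(c("C1=CC=CC=C1", "OCC"))
  expect_identical(prep$records, prep2$records)
})

test_that("pipeline drops salts/unparseable and reports statistics", {
  prep <- cached("prep_mixed",
                 suppressMessages(prepareCorpus(
                   c("CCO", "OCC", "[Na+].[Cl-]", "notasmiles", "CCC"))))
  expect_identical(prep$records$smiles, c("CCO", "CCC"))  # OCC == CCO
  expect_identical(unname(prep$stats["salt"]), 1L)
  expect_identical(unname(prep$stats["duplicate"]), 1L)
  expect_identical(unname(prep$stats["kept"]), 2L)
  expect_false(any(grepl(".", prep$records$smiles, fixed = TRUE)))
})

test_that("deduplication keeps first occurrences, is stable and idempotent", {
  r <- data.frame(smiles = c("CCO", "CCO", "CCC"), x = 1:3)
  d <- deduplicateRecords(r)
  expect_identical(d$smiles, c("CCO", "CCC"))
  expect_identical(d$x, c(1L, 3L))
  expect_identical(deduplicateRecords(d), d)
  expect_identical(nrow(deduplicateRecords(r[integer(0), ])), 0L)
  shuffled <- r[rep(1:3, 30), ]
  expect_identical(nrow(deduplicateRecords(shuffled)), 2L)
})

test_that("corpus split is 90/10, disjoint and seed-reproducible", {
  rec <- toyCorpus(100L)
  s1 <- splitCorpus(rec, seed = 3L)
  expect_identical(nrow(trainRecords(s1)), 90L)
  expect_identical(nrow(testRecords(s1)), 10L)
  expect_length(intersect(trainRecords(s1)$smiles, testRecords(s1)$smiles), 0L)
  s2 <- splitCorpus(rec, seed = 3L)
  expect_identical(trainRecords(s1), trainRecords(s2))
  # ten records, fraction 0.9 -> 9/1
  s10 <- splitCorpus(rec[1:10, ], seed = 1L)
  expect_identical(nrow(trainRecords(s10)), 9L)
  # different seeds give different permutations at least once
  diff <- vapply(1:20, function(s)
    !identical(trainRecords(splitCorpus(rec, seed = s))$smiles,
               trainRecords(s1)$smiles), logical(1))
  expect_true(any(diff))
  expect_error(splitCorpus(rec, fraction = 1.2), "fraction")
})

test_that("split manifests round-trip through train/test CSVs", {
  rec <- toyCorpus(50L)
  s <- splitCorpus(rec, seed = 4L)
  dir <- withr::local_tempdir()
  writeSplit(s, dir)
  expect_true(all(file.exists(file.path(dir, c("train.csv", "test.csv",
                                               "split.json")))))
  back <- readSplit(dir)
  expect_identical(trainRecords(back)$smiles, trainRecords(s)$smiles)
  expect_identical(back@seed, 4L)
})

test_that("corpus CSV and line formats round-trip", {
  rec <- toyCorpus(50L)
  f <- withr::local_tempfile(fileext = ".csv")
  writeCorpus(rec, f)
  back <- readCorpus(f)
  expect_identical(back$smiles, rec$smiles)
  expect_equal(back$mw_scaled, rec$mw_scaled, tolerance = 1e-6)
  fl <- withr::local_tempfile(fileext = ".smi")
  writeLines(c(rec$smiles[1:3], "", "  "), fl)
  expect_identical(readCorpus(fl), rec$smiles[1:3])
})
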