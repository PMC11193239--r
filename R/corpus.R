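## Corpus preparation: canonicalize -> filter -> deduplicate -> annotate,
## then a reproducible 90/10 split.  Records are plain data.frames with
## columns smiles, logp, sascore, mw_scaled (molecular weight / 100).

.RECORD_COLS <- c("smiles", "logp", "sascore", "mw_scaled")

#' Filter verdicts for canonicalized SMILES
#'
#' A molecule is rejected when it is unparseable (\code{"parse"}), contains
#' the \code{.} fragment separator, i.e. is an ionic/multi-fragment structure
#' (\code{"salt"}), or exceeds the token limit (\code{"length"}).
#' Single-fragment molecules carrying formal charges are kept: the salt
#' criterion is multi-fragmentedness.  Token counts are measured with
#' \code{\link{splitSmiles}} on the string as given, frame tokens excluded.
#'
#' @param smiles character vector (canonical SMILES).
#' @param parseable logical vector from the parser; defaults to checking via
#'   RDKit.  Pass it explicitly to avoid a second bridge call.
#' @param maxTokens token-count limit (default 256).
#' @return data.frame with columns \code{ok} and \code{reason}
#'   (\code{"parse"}, \code{"salt"}, \code{"length"} or \code{""}).
#' @export
passesFilters <- function(smiles, parseable = NULL, maxTokens = 256L) {
  if (is.null(parseable)) parseable <- isValidSmiles(smiles)
  nTok <- vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_integer_)
    tryCatch(length(splitSmiles(s)), error = function(e) NA_integer_)
  }, integer(1), USE.NAMES = FALSE)
  reason <- character(length(smiles))
  reason[!parseable | is.na(smiles)] <- "parse"
  isSalt <- !is.na(smiles) & grepl(".", smiles, fixed = TRUE)
  reason[reason == "" & isSalt] <- "salt"
  tooLong <- is.na(nTok) | nTok > maxTokens
  reason[reason == "" & tooLong] <- "length"
  data.frame(ok = reason == "", reason = reason, stringsAsFactors = FALSE)
}

#' Drop duplicate records by SMILES string
#'
#' String-based comparison on the (canonical) SMILES column; the first
#' occurrence is kept, so the operation is order-stable and idempotent.
#'
#' @param records data.frame with a \code{smiles} column.
#' @return the deduplicated data.frame.
#' @export
deduplicateRecords <- function(records) {
  records[!duplicated(records$smiles), , drop = FALSE]
}

#' Prepare an annotated molecule corpus
#'
#' Runs the full preprocessing pipeline: RDKit canonicalization with
#' stereochemistry kept, rejection of unparseable strings, salts
#' (multi-fragment SMILES) and molecules longer than \code{maxTokens}
#' tokens, string-level deduplication, and annotation with Crippen logP,
#' synthetic-accessibility score and molecular weight divided by 100.
#'
#' @param smiles character vector of raw SMILES.
#' @param maxTokens token limit (default 256).
#' @return list with \code{records} (data.frame smiles, logp, sascore,
#'   mw_scaled) and \code{stats} (named counts: input, parse, salt, length,
#'   duplicate, kept).
#' @export
prepareCorpus <- function(smiles, maxTokens = 256L) {
  smiles <- smiles[!is.na(smiles) & nzchar(smiles)]
  props <- chemProperties(smiles)
  verdict <- passesFilters(props$canonical, parseable = props$ok,
                           maxTokens = maxTokens)
  kept <- props[verdict$ok, , drop = FALSE]
  records <- data.frame(smiles = kept$canonical, logp = kept$logp,
                        sascore = kept$sascore, mw_scaled = kept$mw / 100,
                        stringsAsFactors = FALSE)
  nBefore <- nrow(records)
  records <- deduplicateRecords(records)
  rownames(records) <- NULL
  nDropped <- table(factor(verdict$reason[!verdict$ok],
                           levels = c("parse", "salt", "length")))
  if (sum(nDropped) > 0)
    message("prepareCorpus: dropped ", sum(nDropped), " molecule(s) (",
            paste(names(nDropped), nDropped, sep = "=", collapse = ", "), ")")
  list(records = records,
       stats = c(input = length(smiles),
                 parse = unname(nDropped["parse"]),
                 salt = unname(nDropped["salt"]),
                 length = unname(nDropped["length"]),
                 duplicate = nBefore - nrow(records),
                 kept = nrow(records)))
}

#' Split records into train and test sets
#'
#' Random permutation under the given seed, then the first
#' \code{round(fraction * n)} records form the training set.
#'
#' @param records annotated data.frame.
#' @param fraction training fraction in (0, 1); default 0.9.
#' @param seed integer seed; the split is reproducible given the seed.
#' @return a \code{\link{CorpusSplit}}.
#' @export
splitCorpus <- function(records, fraction = 0.9, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to split")
  perm <- withr::with_seed(seed, sample.int(n))
  nTrain <- max(1L, min(n - 1L, round(fraction * n)))
  train <- records[perm[seq_len(nTrain)], , drop = FALSE]
  test <- records[perm[(nTrain + 1L):n], , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  new("CorpusSplit", train = train, test = test, seed = as.integer(seed))
}

#' @describeIn splitCorpus training records.
#' @param x a \code{CorpusSplit}.
#' @export
trainRecords <- function(x) x@train

#' @describeIn splitCorpus held-out records.
#' @export
testRecords <- function(x) x@test

setMethod("show", "CorpusSplit", function(object) {
  cat("CorpusSplit:", nrow(object@train), "train /", nrow(object@test),
      "test records (seed", paste0(object@seed, ")"), "\n")
})

#' Write a corpus split as two CSVs plus a metadata file
#'
#' Writes \code{train.csv}, \code{test.csv} and \code{split.json} (seed and
#' record counts) into a directory.
#'
#' @param split a \code{CorpusSplit}.
#' @param dir output directory (created if missing).
#' @export
writeSplit <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCorpus(split@train, file.path(dir, "train.csv"))
  writeCorpus(split@test, file.path(dir, "test.csv"))
  jsonlite::write_json(list(seed = split@seed, nTrain = nrow(split@train),
                            nTest = nrow(split@test)),
                       file.path(dir, "split.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a corpus split written by \code{\link{writeSplit}}
#'
#' @param dir directory holding train.csv, test.csv and split.json.
#' @return a \code{CorpusSplit}.
#' @export
readSplit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "split.json"))
  new("CorpusSplit", train = readCorpus(file.path(dir, "train.csv")),
      test = readCorpus(file.path(dir, "test.csv")),
      seed = as.integer(meta$seed))
}

#' Read a SMILES corpus from disk
#'
#' Accepts either plain text (one SMILES per line, blank lines ignored) or a
#' CSV with a \code{smiles} column (additional columns such as precomputed
#' properties are carried along when all of logp, sascore, mw_scaled are
#' present).
#'
#' @param path input file.
#' @return character vector of SMILES, or a data.frame of records when the
#'   CSV already carries the annotation columns.
#' @export
readCorpus <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("CSV must have a 'smiles' column")
    if (all(.RECORD_COLS %in% names(df))) return(df[.RECORD_COLS])
    return(df$smiles)
  }
  lines <- readLines(path)
  lines[nzchar(trimws(lines))]
}

#' Write annotated records as CSV
#'
#' @param records data.frame with columns smiles, logp, sascore, mw_scaled.
#' @param path output path.
#' @export
writeCorpus <- function(records, path) {
  stopifnot(all(.RECORD_COLS %in% names(records)))
  utils::write.csv(records[.RECORD_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
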