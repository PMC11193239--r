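## SMILES tokenizer: character-level splitting except that bracket atoms
## ([nH], [C@@H], ...), the two-character elements Cl/Br and %nn ring-closure
## labels are single tokens.  Token ids are 0-based with [PAD]=0, [CLS]=1,
## [SEP]=2.

.SPECIAL_TOKENS <- c("[PAD]", "[CLS]", "[SEP]")
.SMILES_TOKEN_RE <- "\\[[^][]*\\]|Cl|Br|%[0-9]{2}|."

#' Split a SMILES string into tokens
#'
#' Splitting is at the character level except that square-bracket atom groups
#' are kept as single tokens, as are the two-character element symbols
#' \code{Cl} and \code{Br} and two-digit ring-closure labels \code{\%nn}.
#' The concatenation of the returned tokens always reproduces the input.
#'
#' @param smiles a single non-empty SMILES string.
#' @return character vector of tokens.
#' @examples
#' splitSmiles("CCO")        # "C" "C" "O"
#' splitSmiles("[nH]1cccc1") # "[nH]" "1" "c" "c" "c" "c" "1"
#' @export
splitSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(smiles)) stop("SMILES string is empty")
  nOpen <- lengths(regmatches(smiles, gregexpr("[", smiles, fixed = TRUE)))
  nClose <- lengths(regmatches(smiles, gregexpr("]", smiles, fixed = TRUE)))
  if (nOpen != nClose)
    stop("malformed SMILES (unbalanced square brackets): ", smiles)
  toks <- regmatches(smiles, gregexpr(.SMILES_TOKEN_RE, smiles))[[1L]]
  if (!identical(paste(toks, collapse = ""), smiles))
    stop("malformed SMILES (tokenization does not cover the string): ",
         smiles)
  toks
}

#' Build a vocabulary from a corpus
#'
#' The vocabulary holds the three special tokens at ids 0..2 followed by
#' every distinct chemistry token observed in the corpus, in lexicographic
#' order (C locale), so construction is deterministic.
#'
#' @param corpus character vector of SMILES strings (blank entries ignored).
#' @return a \code{\link{Vocabulary}}.
#' @export
buildVocab <- function(corpus) {
  corpus <- corpus[nzchar(corpus)]
  if (length(corpus) == 0L) stop("cannot build a vocabulary from an empty corpus")
  toks <- unique(unlist(lapply(corpus, splitSmiles), use.names = FALSE))
  toks <- withr::with_collate("C", sort(toks))
  new("Vocabulary", tokens = c(.SPECIAL_TOKENS, toks),
      specials = c(pad = 0L, cls = 1L, sep = 2L))
}

#' @describeIn buildVocab number of tokens (the model's vocabulary dimension).
#' @param vocab a \code{Vocabulary}.
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' Special-token ids of a vocabulary
#'
#' @param vocab a \code{Vocabulary}.
#' @return named integer vector with entries \code{pad}, \code{cls}, \code{sep}.
#' @export
specialIds <- function(vocab) vocab@specials

#' Look up token ids
#'
#' @param vocab a \code{Vocabulary}.
#' @param tokens character vector of tokens.
#' @return 0-based integer ids; an unknown token is a hard error (silent
#'   substitution would corrupt generation).
#' @export
tokenIds <- function(vocab, tokens) {
  ids <- match(tokens, vocab@tokens)
  if (anyNA(ids)) {
    bad <- unique(tokens[is.na(ids)])
    stop("token(s) not in vocabulary: ", paste(sQuote(bad), collapse = ", "))
  }
  ids - 1L
}

#' Encode a SMILES string as token ids
#'
#' @param smiles a single SMILES string.
#' @param vocab a \code{Vocabulary} containing every token of \code{smiles}.
#' @param frame if TRUE (default) the ids are framed as
#'   \code{[CLS] ... [SEP]}.
#' @return 0-based integer id vector.
#' @export
encodeSmiles <- function(smiles, vocab, frame = TRUE) {
  ids <- tokenIds(vocab, splitSmiles(smiles))
  if (frame) ids <- c(vocab@specials[["cls"]], ids, vocab@specials[["sep"]])
  ids
}

#' Decode token ids back to a SMILES string
#'
#' Special tokens ([PAD], [CLS], [SEP]) are stripped; the remaining tokens
#' are concatenated in order.  Stripping is idempotent and the empty id
#' vector decodes to the empty string.
#'
#' @param ids 0-based integer id vector.
#' @param vocab a \code{Vocabulary}.
#' @return a character scalar.
#' @export
decodeIds <- function(ids, vocab) {
  if (length(ids) == 0L) return("")
  if (any(ids < 0L | ids >= vocabSize(vocab))) stop("token id out of range")
  keep <- !(ids %in% vocab@specials)
  paste(vocab@tokens[ids[keep] + 1L], collapse = "")
}

#' Write a vocabulary to JSON
#'
#' Layout: \code{{"tokens": [...], "special": {"pad":0,"cls":1,"sep":2}}}.
#'
#' @param vocab a \code{Vocabulary}.
#' @param path output file path.
#' @export
writeVocab <- function(vocab, path) {
  jsonlite::write_json(
    list(tokens = vocab@tokens, special = as.list(vocab@specials)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a vocabulary from JSON
#'
#' @param path file written by \code{\link{writeVocab}}.
#' @return a \code{Vocabulary}.
#' @export
readVocab <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("Vocabulary", tokens = as.character(obj$tokens),
      specials = c(pad = as.integer(obj$special$pad),
                   cls = as.integer(obj$special$cls),
                   sep = as.integer(obj$special$sep)))
}

#' Stable content hash of a vocabulary (used to guard checkpoints)
#' @param vocab a \code{Vocabulary}.
#' @return character scalar.
#' @export
vocabHash <- function(vocab) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(vocab@tokens, f)
  unname(tools::md5sum(f))
}

setMethod("show", "Vocabulary", function(object) {
  cat("Vocabulary of", vocabSize(object), "tokens",
      "(specials: [PAD]=0, [CLS]=1, [SEP]=2)\n")
  chem <- setdiff(object@tokens, .SPECIAL_TOKENS)
  cat("  chemistry tokens:", paste(utils::head(chem, 12), collapse = " "),
      if (length(chem) > 12) "...\n" else "\n")
})
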