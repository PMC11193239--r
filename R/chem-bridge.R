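## Batched bridge to the system RDKit (python) for the standard
## cheminformatics primitives: canonicalization, parsing, Crippen logP,
## synthetic-accessibility score, molecular weight and relaxed substructure
## matching.  One python process per call; callers batch their molecules.

.bridgeScript <- function() {
  path <- system.file("python", "chem_bridge.py", package = "smilesgen")
  if (!nzchar(path) || !file.exists(path))
    stop("chem_bridge.py not found; is the package installed correctly?")
  path
}

.pythonBin <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) stop("no python interpreter found on PATH")
  bin
}

.chemBridge <- function(task, input = character(0), args = character(0)) {
  out <- suppressWarnings(system2(
    .pythonBin(), c(shQuote(.bridgeScript()), task, shQuote(args)),
    input = input, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("chemistry bridge failed (task '", task, "'): ",
         paste(out, collapse = "\n"))
  out
}

#' Compute RDKit properties for a batch of SMILES
#'
#' Parses each string with RDKit and returns the canonical SMILES
#' (stereochemistry preserved) together with the three conditioning
#' properties: Crippen logP, the synthetic-accessibility score (SA_Score
#' contrib, bounded to [1, 10]) and the molecular weight in Daltons.
#' Unparseable strings yield \code{ok = FALSE} and NA fields.
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns \code{smiles} (the input), \code{ok},
#'   \code{canonical}, \code{logp}, \code{sascore}, \code{mw}.
#' @export
chemProperties <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L)
    return(data.frame(smiles = character(0), ok = logical(0),
                      canonical = character(0), logp = numeric(0),
                      sascore = numeric(0), mw = numeric(0)))
  out <- .chemBridge("props", input = smiles)
  if (length(out) != length(smiles))
    stop("chemistry bridge returned ", length(out), " rows for ",
         length(smiles), " inputs")
  parts <- strsplit(out, "\t", fixed = TRUE)
  asNum <- function(i) suppressWarnings(as.numeric(
    vapply(parts, `[`, character(1), i)))
  data.frame(
    smiles = smiles,
    ok = vapply(parts, `[`, character(1), 1L) == "1",
    canonical = ifelse(vapply(parts, `[`, character(1), 2L) == "NA", NA,
                       vapply(parts, `[`, character(1), 2L)),
    logp = asNum(3L), sascore = asNum(4L), mw = asNum(5L),
    stringsAsFactors = FALSE)
}

#' Canonicalize SMILES strings
#'
#' RDKit canonical form, keeping stereochemistry descriptors.  Idempotent;
#' unparseable inputs map to NA.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES (NA where parsing failed).
#' @export
canonicalizeSmiles <- function(smiles) {
  chemProperties(smiles)$canonical
}

#' Which strings parse as molecules?
#'
#' @param smiles character vector.
#' @return logical vector: does RDKit parse the string?
#' @export
isValidSmiles <- function(smiles) {
  chemProperties(smiles)$ok
}

#' Bond-order-relaxed substructure pattern for a core SMILES
#'
#' Converts the core structure into a SMARTS pattern in which each atom
#' matches by element only (aromaticity-agnostic atomic-number queries) and
#' every bond matches any bond type, so only the connectivity of the core is
#' compared.  A benzene core therefore also matches cyclohexane: electronic
#' detail is deliberately ignored while the topology is retained.
#'
#' @param core a single SMILES string; canonicalized before conversion.
#' @return the SMARTS pattern as a character scalar, with the canonical core
#'   attached as attribute \code{"core"}.
#' @export
relaxedPattern <- function(core) {
  stopifnot(is.character(core), length(core) == 1L)
  can <- canonicalizeSmiles(core)
  if (is.na(can)) stop("unparseable core SMILES: ", core)
  smarts <- .chemBridge("smarts", args = can)
  structure(smarts[length(smarts)], core = can)
}

#' Match molecules against a relaxed core pattern
#'
#' @param smiles character vector of molecules.
#' @param core core-structure SMILES; relaxed to a connectivity-only SMARTS
#'   via \code{\link{relaxedPattern}} before matching.
#' @return logical vector (NA for unparseable molecules), with the SMARTS
#'   used attached as attribute \code{"smarts"}.
#' @export
matchesCore <- function(smiles, core) {
  stopifnot(is.character(smiles), is.character(core), length(core) == 1L)
  can <- canonicalizeSmiles(core)
  if (is.na(can)) stop("unparseable core SMILES: ", core)
  out <- .chemBridge("match", input = smiles, args = can)
  if (length(out) != length(smiles) + 1L)
    stop("chemistry bridge returned an unexpected number of rows")
  res <- out[-1L]
  structure(ifelse(res == "NA", NA, res == "1"), smarts = out[1L])
}
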