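## Evaluation metrics for generated molecules: validity, uniqueness at a
## declared batch size, novelty against a reference corpus, per-property
## mean absolute deviation, and the bond-order-relaxed substructure match.
## Uniqueness and novelty are string-level comparisons of canonical SMILES:
## synonymous SMILES for the same molecular graph deliberately count as
## distinct, so no graph-isomorphism deduplication is attempted.

#' Validity of generated strings
#'
#' Percentage of strings that parse as molecules, plus the valid molecules
#' in canonical form.
#'
#' @param generated non-empty character vector of generated strings.
#' @return list with \code{pct} (100 * valid / total) and \code{valid}
#'   (canonical SMILES of the parseable entries, in order).
#' @export
validityMetric <- function(generated) {
  if (length(generated) == 0L) stop("empty generation batch")
  can <- canonicalizeSmiles(generated)
  ok <- !is.na(can)
  list(pct = 100 * sum(ok) / length(generated), valid = can[ok])
}

#' Uniqueness within a batch
#'
#' Percentage of distinct strings among the first \code{at} entries
#' (string comparison of canonical forms).  If fewer entries exist the
#' computation runs on what is there and the result carries
#' \code{attr(, "short") = TRUE}.
#'
#' @param validSmiles character vector (canonical SMILES).
#' @param at declared batch size (default: the full batch).
#' @return percentage in [0, 100].
#' @export
uniquenessMetric <- function(validSmiles, at = length(validSmiles)) {
  if (length(validSmiles) == 0L) stop("empty batch")
  short <- length(validSmiles) < at
  x <- utils::head(validSmiles, at)
  structure(100 * length(unique(x)) / length(x), short = short)
}

#' Novelty against a reference corpus
#'
#' Percentage of distinct generated molecules not present in the reference,
#' by string comparison of canonical SMILES.
#'
#' @param validSmiles character vector (canonical SMILES of valid
#'   generations).
#' @param reference character vector of reference canonical SMILES.
#' @return percentage in [0, 100].
#' @export
noveltyMetric <- function(validSmiles, reference) {
  if (length(reference) == 0L) stop("empty reference corpus")
  gen <- unique(validSmiles)
  100 * sum(!gen %in% reference) / length(gen)
}

#' Mean absolute deviation between measured and requested values
#'
#' \code{mean(|x - y|)}: symmetric in its arguments and linear under a
#' common scaling.
#'
#' @param x measured (recomputed) property values.
#' @param y requested target values, same length.
#' @return non-negative scalar.
#' @export
madMetric <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch in madMetric")
  if (length(x) == 0L) stop("madMetric needs at least one pair")
  mean(abs(x - y))
}

#' Substructure-match rate under the relaxed pattern
#'
#' Percentage of (valid) generated molecules containing the core's
#' connectivity, bond orders ignored (see \code{\link{relaxedPattern}}).
#' Duplicates count individually: the denominator is all valid molecules.
#'
#' @param validSmiles character vector of valid SMILES.
#' @param core core-structure SMILES.
#' @return percentage, with the SMARTS used attached as attribute
#'   \code{"smarts"}.
#' @export
substructureMatchRate <- function(validSmiles, core) {
  if (length(validSmiles) == 0L) return(structure(NA_real_, smarts = NA))
  m <- matchesCore(validSmiles, core)
  structure(100 * sum(m, na.rm = TRUE) / length(m),
            smarts = attr(m, "smarts"))
}

#' Evaluate a generation run
#'
#' Recomputes the true properties of the valid molecules with RDKit and
#' assembles the full metric report.  MAD is computed per conditioned
#' property only (none for an unconditional run); the substructure-match
#' rate only when a core was requested.
#'
#' @param generated character vector of generated strings.
#' @param reference reference corpus: character vector of canonical SMILES
#'   or a records data.frame with a \code{smiles} column; NULL skips
#'   novelty.
#' @param conditions named list of requested values (any of \code{logp},
#'   \code{sascore}, \code{mw_scaled}) or NULL for unconditional.
#' @param core core-structure SMILES or NULL.
#' @param uniquenessAt batch size for the uniqueness metric (default: all
#'   generated).
#' @return a \code{\linkS4class{MetricsReport}}.
#' @export
evaluateRun <- function(generated, reference = NULL, conditions = NULL,
                        core = NULL, uniquenessAt = length(generated)) {
  if (length(generated) == 0L) stop("empty generation batch")
  props <- chemProperties(generated)
  ok <- props$ok
  valid <- props$canonical[ok]
  validityPct <- 100 * sum(ok) / length(generated)
  uniq <- if (length(valid)) as.numeric(
    uniquenessMetric(valid, uniquenessAt)) else NA_real_
  if (is.data.frame(reference)) reference <- reference$smiles
  nov <- if (!is.null(reference) && length(valid))
    noveltyMetric(valid, reference) else NA_real_
  mad <- numeric(0)
  if (!is.null(conditions) && length(conditions) && length(valid)) {
    measured <- data.frame(logp = props$logp[ok], sascore = props$sascore[ok],
                           mw_scaled = props$mw[ok] / 100)
    mad <- vapply(names(conditions), function(nm) {
      if (!nm %in% names(measured)) stop("unknown condition: ", nm)
      madMetric(measured[[nm]], rep(conditions[[nm]], nrow(measured)))
    }, numeric(1))
  }
  sm <- if (!is.null(core) && length(valid))
    as.numeric(substructureMatchRate(valid, core)) else NA_real_
  new("MetricsReport", validityPct = validityPct, uniquenessPct = uniq,
      noveltyPct = nov, uniquenessAt = as.integer(uniquenessAt),
      madPerProperty = mad, smPct = sm,
      nGenerated = length(generated), nValid = length(valid))
}

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", object@nGenerated, "generated /", object@nValid,
      "valid molecules\n")
  cat(sprintf("  validity   %6.2f %%\n", object@validityPct))
  if (!is.na(object@uniquenessPct))
    cat(sprintf("  uniqueness %6.2f %% (at %d)\n", object@uniquenessPct,
                object@uniquenessAt))
  if (!is.na(object@noveltyPct))
    cat(sprintf("  novelty    %6.2f %%\n", object@noveltyPct))
  for (nm in names(object@madPerProperty))
    cat(sprintf("  MAD(%s) = %.4g\n", nm, object@madPerProperty[[nm]]))
  if (!is.na(object@smPct))
    cat(sprintf("  substructure match %6.2f %%\n", object@smPct))
})

#' Serialize a metrics report to JSON
#'
#' @param report a \code{MetricsReport}.
#' @param path output path.
#' @export
writeMetricsReport <- function(report, path) {
  jsonlite::write_json(list(
    validity_pct = report@validityPct,
    uniqueness_pct = report@uniquenessPct,
    uniqueness_at = report@uniquenessAt,
    novelty_pct = report@noveltyPct,
    mad_per_property = as.list(report@madPerProperty),
    sm_pct = report@smPct,
    n_generated = report@nGenerated,
    n_valid = report@nValid), path, auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(path)
}
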