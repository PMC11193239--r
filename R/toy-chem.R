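## Deterministic toy chemical space: a stochastic grammar over small
## acyclic chains, 5-/6-membered rings (benzene, thiophene, pyrrole,
## cyclopentane, cyclohexane, tetrahydrofuran) and simple heteroatom
## substituents (alcohol, ether, amine, carbonyl, ester, acid).  The
## grammar emits only single-fragment, neutral molecules of at most
## maxHeavyAtoms heavy atoms, so every string passes the corpus filters;
## annotation goes through the same RDKit pipeline as real data, keeping
## train-time conditions and eval-time measurements definitionally
## consistent.

# Ring systems: plain form and forms with a branch slot "%s" on a ring atom
# (benzene and cyclohexane get two slot positions, so meta- and para-like
# substitution patterns are both reachable).
.TOY_RINGS <- c("c1ccccc1", "c1ccsc1", "c1cc[nH]c1", "C1CCCCC1", "C1CCCC1",
                "C1CCOC1")
.TOY_RING_SLOTS <- list(c("c1ccc(%s)cc1", "c1cccc(%s)c1"),
                        "c1cc(%s)sc1", "c1cc(%s)[nH]c1",
                        c("C1CCC(%s)CC1", "C1CCCC(%s)C1"),
                        "C1CC(%s)CC1", "C1CC(%s)OC1")
# Functional tails, written root-first so they attach to the preceding atom.
.TOY_TAILS <- c("", "O", "N", "OC", "OCC", "S", "SC", "F", "Cl", "C=O",
                "C#N", "C(=O)C", "C(=O)O", "C(=O)OC", "N(C)C", "COC")
.TOY_BRANCHES <- c("(C)", "(CC)", "(O)")

.heavyAtomCount <- function(smiles) {
  lengths(regmatches(smiles, gregexpr("Cl|[CcNnOoSsF]", smiles)))
}

# A small substituent: 0-3 alkyl carbons followed by an optional functional
# tail, root-first ("", the empty substituent, becomes a methyl).
.toySub <- function() {
  s <- paste0(strrep("C", sample(0:3, 1L, prob = c(0.4, 0.3, 0.2, 0.1))),
              sample(.TOY_TAILS, 1L))
  if (nzchar(s)) s else "C"
}

# One random SMILES from the grammar, using the current RNG stream.
.toyMolecule <- function(maxHeavy) {
  if (stats::runif(1) < 0.55) {
    # branched functionalized chain
    len <- sample.int(7L, 1L)
    chain <- strrep("C", len)
    nBranch <- if (len >= 3L) sample(0:2, 1L, prob = c(0.55, 0.35, 0.1)) else 0L
    if (nBranch > 0L) {
      pos <- sort(sample(2:(len - 1L), min(nBranch, len - 2L)),
                  decreasing = TRUE)
      for (p in pos)
        chain <- paste0(substr(chain, 1L, p), sample(.TOY_BRANCHES, 1L),
                        substr(chain, p + 1L, nchar(chain)))
    }
    if (len >= 4L && nBranch == 0L && stats::runif(1) < 0.25) {
      # an interior carbon becomes an ether oxygen
      p <- sample(2:(len - 1L), 1L)
      substr(chain, p, p) <- "O"
    }
    tail <- sample(.TOY_TAILS, 1L)
    smi <- if (tail == "C=O" && len == 1L) "CC=O" else paste0(chain, tail)
  } else {
    which <- sample.int(length(.TOY_RINGS), 1L)
    nSub <- sample(0:2, 1L, prob = c(0.25, 0.45, 0.3))
    smi <- if (nSub == 0L) .TOY_RINGS[which]
    else if (nSub == 1L) paste0(.TOY_RINGS[which], .toySub())
    else paste0(sprintf(sample(.TOY_RING_SLOTS[[which]], 1L), .toySub()),
                .toySub())
  }
  if (.heavyAtomCount(smi) > maxHeavy) NULL else smi
}

#' Generate the toy corpus
#'
#' Draws molecules from the grammar until \code{n} distinct canonical
#' SMILES survive the full preprocessing pipeline (canonicalize, filter,
#' deduplicate, annotate), or the attempt budget (20 n draws) is exhausted,
#' in which case fewer records are returned with a warning.  Bit-exactly
#' reproducible from the seed.  The emitted space spans well over 2 logP
#' units and over 1.0 in scaled molecular weight, so property conditioning
#' is learnable from it.
#'
#' @param n target number of molecules.
#' @param seed integer seed.
#' @param maxHeavyAtoms heavy-atom cap per molecule (default 12).
#' @return annotated records data.frame (smiles, logp, sascore, mw_scaled).
#' @export
generateToyCorpus <- function(n, seed = 7L, maxHeavyAtoms = 12L) {
  stopifnot(n >= 1L)
  raw <- withr::with_seed(as.integer(seed), {
    out <- vector("list", 15L * n)
    k <- 0L
    for (i in seq_len(15L * n)) {
      smi <- .toyMolecule(maxHeavyAtoms)
      if (!is.null(smi)) {
        k <- k + 1L
        out[[k]] <- smi
      }
    }
    unlist(out[seq_len(k)])
  })
  prep <- suppressMessages(prepareCorpus(unique(raw)))
  records <- prep$records
  if (nrow(records) < n)
    warning("toy grammar exhausted: ", nrow(records), " < ", n,
            " distinct molecules")
  utils::head(records, n)
}

#' Labelled substructure fixtures for the relaxed-match metric
#'
#' For each small core (benzene, thiophene, ethanol, acetaldehyde) returns
#' molecules constructed to contain it and molecules constructed to lack
#' its connectivity, for testing the bond-order-relaxed matcher.
#'
#' @return named list of lists with elements \code{core}, \code{positive},
#'   \code{negative}.
#' @export
generateCoreFixtures <- function() {
  list(
    benzene = list(core = "c1ccccc1",
                   positive = c("Cc1ccccc1", "OCc1ccccc1", "c1ccccc1",
                                "CC(=O)c1ccccc1"),
                   negative = c("CCO", "C1CCOC1", "c1ccsc1")),
    thiophene = list(core = "c1ccsc1",
                     positive = c("Cc1ccsc1", "c1ccsc1", "CCc1ccsc1"),
                     negative = c("c1ccccc1", "CCCC", "C1CCCC1")),
    ethanol = list(core = "CCO",
                   positive = c("CCO", "CCOC", "CCCO", "OCc1ccccc1"),
                   negative = c("CC", "c1ccsc1", "O")),
    acetaldehyde = list(core = "CC=O",
                        positive = c("CC=O", "CCC=O", "CC(=O)C", "CC(=O)O"),
                        negative = c("CCC", "OC", "c1ccccc1")))
}
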