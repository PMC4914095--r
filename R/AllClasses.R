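#' @import methods
NULL

## Nomenclature labels, ordered from the canonical (C) helix through the loop
## into the non-canonical (NC) helix.  b = bulged strand, n = non-bulged strand.
KT_LABELS <- c("-1b", "-1n", "L1", "L2", "L3",
               "1b", "1n", "2b", "2n", "3b", "3n", "4b", "4n")

## Minimum label set an annotation must provide for N3/N1 classification.
KT_REQUIRED_LABELS <- c("-1n", "1n", "2b", "2n", "3b", "3n")

## Named atoms the downstream geometry needs, per position.  Positions not
## listed contribute no required atoms (their C1' is still kept if present).
KT_REQUIRED_ATOMS <- list(
  "-1n" = "O2'",
  "L1"  = "O2'",
  "1n"  = "N1",
  "2b"  = c("N1", "N3", "N6", "C1'"),
  "2n"  = c("N1", "N3", "C1'"),
  "3b"  = "C1'",
  "3n"  = "C1'",
  "4b"  = "C1'",
  "4n"  = "C1'"
)

RNA_BASES <- c("A", "C", "G", "U")

#' KTurnInstance: named-atom coordinates for one k-turn copy
#'
#' Holds, for a single crystallographically independent copy of a k-turn, the
#' nucleotide identity at each annotated nomenclature position and the
#' coordinates of the named atoms the geometric analysis uses.  Instances are
#' normally produced by [extractInstance()], [enumerateInstances()] or the
#' generator [simulateKTurns()], not constructed directly.
#'
#' @slot instanceId single identifier string.
#' @slot residues named character vector mapping nomenclature labels
#'   (\code{-1b}, \code{-1n}, \code{L1}\dots\code{L3}, \code{1b}/\code{1n},
#'   \code{2b}/\code{2n}, \code{3b}/\code{3n}, \code{4b}/\code{4n}) to the
#'   one-letter base (A/C/G/U after modified-base normalization).
#' @slot rawResidues the residue names as found in the coordinate file,
#'   before normalization (same names as \code{residues}).
#' @slot atoms data.frame with columns \code{label}, \code{elety}, \code{x},
#'   \code{y}, \code{z}: one row per kept named atom, coordinates in Angstrom.
#' @slot source provenance string (file, model number, copy index).
#' @slot incomplete TRUE if any required atom is missing.
#' @slot missingAtoms character vector "label:atom" of missing required atoms.
#'
#' @seealso [classifyConformation()], [helixWidth()], [bpFamily()]
#' @export
setClass("KTurnInstance",
  representation(
    instanceId   = "character",
    residues     = "character",
    rawResidues  = "character",
    atoms        = "data.frame",
    source       = "character",
    incomplete   = "logical",
    missingAtoms = "character"
  ),
  prototype(
    instanceId = NA_character_, residues = character(),
    rawResidues = character(), atoms = data.frame(),
    source = "", incomplete = FALSE, missingAtoms = character()
  )
)

setValidity("KTurnInstance", function(object) {
  msg <- character()
  if (length(object@instanceId) != 1L)
    msg <- c(msg, "instanceId must be a single string")
  a <- object@atoms
  need <- c("label", "elety", "x", "y", "z")
  if (!all(need %in% names(a)))
    msg <- c(msg, sprintf("atoms must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
      msg <- c(msg, "all atom coordinates must be finite")
    if (anyDuplicated(paste(a$label, a$elety)))
      msg <- c(msg, "duplicated (label, atom) entries in atoms")
  }
  if (is.null(names(object@residues)) && length(object@residues))
    msg <- c(msg, "residues must be named by nomenclature label")
  if (length(msg)) msg else TRUE
})

#' RuleTable: 3b,3n sequence to conformation / foldability lookup
#'
#' A 4x4 array over the sixteen possible 3b,3n base combinations, each cell
#' carrying the associated conformational class (N3, N1 or unknown), the
#' ion-induced foldability (yes/no), supporting evidence counts and a
#' provenance string.  The packaged default is returned by
#' [defaultRuleTable()]; tables can also be rebuilt from classified structures
#' with [buildRuleTable()].
#'
#' @slot cells data.frame with 16 rows and columns \code{b}, \code{n},
#'   \code{conformation}, \code{folds}, \code{n_n3}, \code{n_n1},
#'   \code{provenance}, \code{notes}.
#' @export
setClass("RuleTable", representation(cells = "data.frame"))

setValidity("RuleTable", function(object) {
  msg <- character()
  cl <- object@cells
  need <- c("b", "n", "conformation", "folds", "n_n3", "n_n1",
            "provenance", "notes")
  if (!all(need %in% names(cl)))
    return(sprintf("cells must have columns %s", paste(need, collapse = ", ")))
  if (nrow(cl) != 16L) msg <- c(msg, "cells must have exactly 16 rows")
  if (anyDuplicated(paste(cl$b, cl$n))) msg <- c(msg, "duplicated 3b,3n pair")
  if (!all(cl$b %in% RNA_BASES) || !all(cl$n %in% RNA_BASES))
    msg <- c(msg, "bases must be A, C, G or U")
  if (!all(cl$conformation %in% c("N3", "N1", "unknown")))
    msg <- c(msg, "conformation must be N3, N1 or unknown")
  if (!all(cl$folds %in% c("yes", "no", "unknown")))
    msg <- c(msg, "folds must be yes, no or unknown")
  if (length(msg)) msg else TRUE
})

#' Freq4x4: counts of 3b,3n base combinations in a sequence population
#'
#' Counts of the sixteen 3b,3n combinations observed across an alignment,
#' with rows indexed by the 3b base and columns by the 3n base (both in
#' A, C, G, U order), plus a tally of excluded sequences (gap or ambiguity at
#' either column).  Produced by [profilePairs()] / [profileAlignment()] or
#' read from a 4x4 TSV with [readFreq()].
#'
#' @slot counts 4x4 numeric matrix, dimnames A,C,G,U by A,C,G,U.
#' @slot nExcluded number of sequences excluded from the denominator.
#' @slot excludedReasons named integer vector tallying exclusion reasons.
#' @export
setClass("Freq4x4",
  representation(counts = "matrix", nExcluded = "numeric",
                 excludedReasons = "numeric"),
  prototype(nExcluded = 0, excludedReasons = c(gap = 0, ambiguous = 0))
)

setValidity("Freq4x4", function(object) {
  m <- object@counts
  msg <- character()
  if (!all(dim(m) == c(4L, 4L))) msg <- c(msg, "counts must be 4x4")
  else if (!identical(rownames(m), RNA_BASES) ||
           !identical(colnames(m), RNA_BASES))
    msg <- c(msg, "counts dimnames must be A,C,G,U by A,C,G,U")
  if (any(m < 0) || any(!is.finite(m))) msg <- c(msg, "counts must be >= 0")
  if (object@nExcluded < 0) msg <- c(msg, "nExcluded must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PredictionSummary: population-level conformation and folding fractions
#'
#' Aggregate of a [Freq4x4-class] profile through a [RuleTable-class]:
#' the fractions of a sequence population predicted to adopt the N3 or N1
#' conformation (or falling in unknown cells) and predicted to fold, or not,
#' in metal ions alone.  Produced by [summarizeProfile()].
#'
#' @slot fractions named numeric (percent): \code{N3}, \code{N1},
#'   \code{unknown}, \code{folds}, \code{nonfolds}.
#' @slot perCell data.frame of per-cell contributions (b, n, fraction,
#'   conformation, folds).
#' @slot nIncluded number of sequences behind the percentages.
#' @export
setClass("PredictionSummary",
  representation(fractions = "numeric", perCell = "data.frame",
                 nIncluded = "numeric")
)

setValidity("PredictionSummary", function(object) {
  fr <- object@fractions
  need <- c("N3", "N1", "unknown", "folds", "nonfolds")
  if (!all(need %in% names(fr)))
    return(sprintf("fractions must contain %s", paste(need, collapse = ", ")))
  msg <- character()
  if (abs(sum(fr[c("N3", "N1", "unknown")]) - 100) > 1e-6)
    msg <- c(msg, "N3 + N1 + unknown must equal 100%")
  if (abs(sum(fr[c("folds", "nonfolds")]) - 100) > 1e-6)
    msg <- c(msg, "folds + nonfolds must equal 100%")
  if (length(msg)) msg else TRUE
})
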