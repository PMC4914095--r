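#' @include AllClasses.R
NULL

#' Classify a k-turn core as N3, N1, ambiguous or extended
#'
#' The two k-turn conformational classes are named for the ring nitrogen of
#' the conserved 2b adenine that accepts the hydrogen bond donated by the
#' ribose O2' of position -1n: N3 or N1.  The classifier measures both
#' candidate donor-acceptor distances plus two supporting observables (the
#' A2b N6 to G2n N3 distance, which is hydrogen bonded only in the N3 class,
#' and the loop L1 O2' to A1n N1 bond common to kinked k-turns) and calls the
#' class:
#' \itemize{
#'   \item neither O2' distance within \code{bondedMax}: \code{extended}
#'     (the core is not kinked);
#'   \item exactly one within \code{bondedMax}: that class;
#'   \item both within \code{bondedMax}: the shorter wins unless the two
#'     distances differ by less than \code{ambiguityMargin}, in which case
#'     the call is \code{ambiguous};
#'   \item a secondary check on the N6-N3 distance (expected bonded for N3,
#'     not bonded for N1) downgrades an outright contradiction to
#'     \code{ambiguous}; a distance falling in the indeterminate zone between
#'     \code{bondedMax} and \code{brokenMin} is not treated as contradiction.
#' }
#'
#' @param x a [KTurnInstance-class], or a list of them.
#' @param bondedMax heavy-atom donor-acceptor distance (Angstrom) at or below
#'   which a contact is called hydrogen bonded. Default 3.5.
#' @param brokenMin distance at or above which a contact is called not
#'   bonded (the published negative criterion is "longer than 4 A").
#'   Default 4.0.
#' @param ambiguityMargin minimum separation (Angstrom) between the two
#'   candidate O2' distances when both are bonded. Default 0.3.
#' @return a data.frame with one row per instance: \code{instance_id},
#'   the four diagnostic distances \code{d_O2p_N3}, \code{d_O2p_N1},
#'   \code{d_N6_N3}, \code{d_L1_A1n}, the class \code{cls} in
#'   \{N3, N1, ambiguous, extended\}, the 3b,3n pair \code{pair_3b3n}, and a
#'   \code{reason} string for non-clean calls.
#' @examples
#' kt <- kturnTemplate("N3")
#' classifyConformation(kt)
#' @export
setGeneric("classifyConformation",
  function(x, bondedMax = 3.5, brokenMin = 4.0, ambiguityMargin = 0.3)
    standardGeneric("classifyConformation"))

#' C1'-C1' width of a named basepair
#'
#' Measures the C1'-C1' distance of the 2b/2n, 3b/3n or 4b/4n basepair of a
#' k-turn instance.  The rotation of the A2b base that distinguishes the N1
#' from the N3 class widens the NC helix locally, so these widths separate
#' the two classes into distinct clusters.
#'
#' @param x a [KTurnInstance-class] or a list of them.
#' @param pairLabel one or more of \code{"2b2n"}, \code{"3b3n"},
#'   \code{"4b4n"}.
#' @return data.frame with columns \code{instance_id}, \code{pair_label},
#'   \code{c1c1} (Angstrom) and \code{implausible} (TRUE when the width falls
#'   under a 4 Angstrom sanity floor, e.g. coincident atoms).
#' @examples
#' helixWidth(kturnTemplate("N3"), "2b2n")
#' @export
setGeneric("helixWidth", function(x, pairLabel = "2b2n")
  standardGeneric("helixWidth"))

#' Leontis-Westhof style family of the 3b,3n basepair
#'
#' Assigns a simplified Leontis-Westhof family to a basepair of the instance:
#' inter-base hydrogen bonds are enumerated by heavy-atom distance, each
#' base's bonded atoms vote for the edge they belong to (Watson-Crick,
#' Hoogsteen or sugar; atoms shared between edges vote for both), and the
#' glycosidic-bond orientation is read from the torsion of the two C1' atoms
#' about the axis joining the glycosidic nitrogens (same side, torsion under
#' 90 degrees: cis; opposite: trans).  This is deliberately lighter than full
#' reference-frame fitting: it distinguishes the two families actually
#' observed at the 3b,3n position (trans Hoogsteen/sugar and cis
#' Watson-Crick) plus an explicit "undetermined" state.
#'
#' @param x a [KTurnInstance-class] or list of them.
#' @param pairLabel basepair to type, default \code{"3b3n"}.
#' @param bondedMax,brokenMin hydrogen-bond distance cutoffs (Angstrom).
#' @return data.frame with columns \code{instance_id}, \code{pair_label},
#'   \code{orientation} (cis/trans/NA), \code{edge_b}, \code{edge_n},
#'   \code{n_hbonds}, \code{family} (e.g. \code{"trans Hoogsteen/sugar"},
#'   or \code{"undetermined"}).
#' @examples
#' bpFamily(kturnTemplate("N3"))   # A.G trans Hoogsteen/sugar
#' @export
setGeneric("bpFamily",
  function(x, pairLabel = "3b3n", bondedMax = 3.5, brokenMin = 4.0)
    standardGeneric("bpFamily"))

#' @rdname KTurnInstance-class
#' @param object,x a \code{KTurnInstance}.
#' @export
setGeneric("instanceId", function(x) standardGeneric("instanceId"))

#' Counts and fractions of a 3b,3n profile
#'
#' @param x a [Freq4x4-class].
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' @rdname pairCounts
#' @param percent return percentages (default) rather than proportions.
#' @param denominator \code{"included"} (default: sequences valid at both
#'   columns) or \code{"all"} (include excluded sequences in the
#'   denominator).
#' @export
setGeneric("pairFractions",
  function(x, percent = TRUE, denominator = c("included", "all"))
    standardGeneric("pairFractions"))
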