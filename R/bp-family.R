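## Leontis-Westhof edge membership of the polar base/sugar atoms used for
## hydrogen bonding.  Atoms sitting at an edge junction (e.g. adenine N6,
## guanine O6/N2, pyrimidine O2) belong to both adjacent edges and vote for
## both; the majority of bonded-atom votes picks the edge, ties broken by the
## edge holding the shortest hydrogen bond.
BASE_EDGE_ATOMS <- list(
  A = list(WC = c("N1", "N6"), Hoogsteen = c("N6", "N7"),
           sugar = c("N3", "O2'")),
  G = list(WC = c("N1", "O6", "N2"), Hoogsteen = c("N7", "O6"),
           sugar = c("N3", "N2", "O2'")),
  C = list(WC = c("N3", "N4", "O2"), Hoogsteen = "N4",
           sugar = c("O2", "O2'")),
  U = list(WC = c("N3", "O4", "O2"), Hoogsteen = "O4",
           sugar = c("O2", "O2'"))
)

## glycosidic nitrogen: N9 for purines, N1 for pyrimidines
glycosidicAtom <- function(base) {
  if (base %in% c("A", "G")) "N9" else "N1"
}

## All H-bond-capable atoms of one residue present on the instance.
.edgeAtomsPresent <- function(kti, label, base) {
  tab <- BASE_EDGE_ATOMS[[base]]
  if (is.null(tab)) return(NULL)
  atoms <- unique(unlist(tab))
  a <- kti@atoms
  a <- a[a$label == label & a$elety %in% atoms, , drop = FALSE]
  a
}

## Glycosidic-bond orientation about the axis joining the two glycosidic
## nitrogens: project each C1' offset perpendicular to the axis; a positive
## dot product (torsion C1'b-Nb-Nn-C1'n below 90 degrees) means cis.
bpOrientation <- function(c1b, nb, nn, c1n) {
  u <- nn - nb
  lu <- sqrt(sum(u^2))
  if (lu < 1e-9) return(NA_character_)
  u <- u / lu
  v1 <- (c1b - nb); v1 <- v1 - sum(v1 * u) * u
  v2 <- (c1n - nn); v2 <- v2 - sum(v2 * u) * u
  if (sqrt(sum(v1^2)) < 1e-9 || sqrt(sum(v2^2)) < 1e-9)
    return(NA_character_)
  if (sum(v1 * v2) > 0) "cis" else "trans"
}

## Majority-vote edge for one residue given its bonded atoms.
.edgeVote <- function(base, bondedAtoms, bondLengths) {
  tab <- BASE_EDGE_ATOMS[[base]]
  votes <- vapply(tab, function(atoms) sum(bondedAtoms %in% atoms), 0L)
  if (all(votes == 0L)) return(NA_character_)
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  ## tie: edge containing the atom with the shortest bond
  best <- bondedAtoms[which.min(bondLengths)]
  for (e in top) if (best %in% tab[[e]]) return(e)
  top[1L]
}

#' @rdname bpFamily
#' @export
setMethod("bpFamily", "KTurnInstance",
  function(x, pairLabel = "3b3n", bondedMax = 3.5, brokenMin = 4.0) {
    pairLabel <- match.arg(pairLabel, names(.PAIR_ATOMS))
    lab <- .PAIR_ATOMS[[pairLabel]]
    bb <- residueAt(x, lab[1L]); bn <- residueAt(x, lab[2L])

    undet <- function(why) data.frame(
      instance_id = instanceId(x), pair_label = pairLabel,
      orientation = NA_character_, edge_b = NA_character_,
      edge_n = NA_character_, n_hbonds = 0L,
      family = "undetermined", reason = why, stringsAsFactors = FALSE)

    if (is.na(bb) || is.na(bn)) return(undet("unknown base identity"))
    ab <- .edgeAtomsPresent(x, lab[1L], bb)
    an <- .edgeAtomsPresent(x, lab[2L], bn)
    if (is.null(ab) || is.null(an) || !nrow(ab) || !nrow(an))
      return(undet("base atoms absent"))

    ## enumerate inter-base contacts
    hb <- expand.grid(i = seq_len(nrow(ab)), j = seq_len(nrow(an)))
    hb$d <- sqrt((ab$x[hb$i] - an$x[hb$j])^2 +
                 (ab$y[hb$i] - an$y[hb$j])^2 +
                 (ab$z[hb$i] - an$z[hb$j])^2)
    hb$verdict <- vapply(hb$d, function(d)
      callHBond(d, bondedMax = bondedMax, brokenMin = brokenMin)$verdict, "")
    bonded <- hb[hb$verdict == "bonded", , drop = FALSE]
    if (!nrow(bonded)) return(undet("no inter-base hydrogen bond"))

    edgeB <- .edgeVote(bb, ab$elety[bonded$i], bonded$d)
    edgeN <- .edgeVote(bn, an$elety[bonded$j], bonded$d)

    c1b <- atomCoord(x, lab[1L], "C1'")
    c1n <- atomCoord(x, lab[2L], "C1'")
    ngb <- atomCoord(x, lab[1L], glycosidicAtom(bb))
    ngn <- atomCoord(x, lab[2L], glycosidicAtom(bn))
    orientation <- if (is.null(c1b) || is.null(c1n) ||
                       is.null(ngb) || is.null(ngn)) NA_character_
      else bpOrientation(c1b, ngb, ngn, c1n)

    family <- if (is.na(orientation) || is.na(edgeB) || is.na(edgeN))
      "undetermined"
    else paste0(orientation, " ", edgeB, "/", edgeN)

    data.frame(
      instance_id = instanceId(x), pair_label = pairLabel,
      orientation = orientation, edge_b = edgeB, edge_n = edgeN,
      n_hbonds = nrow(bonded), family = family, reason = "",
      stringsAsFactors = FALSE)
  })

#' @rdname bpFamily
#' @export
setMethod("bpFamily", "list",
  function(x, pairLabel = "3b3n", bondedMax = 3.5, brokenMin = 4.0) {
    do.call(rbind, c(lapply(x, bpFamily, pairLabel = pairLabel,
                            bondedMax = bondedMax, brokenMin = brokenMin),
                     list(make.row.names = FALSE)))
  })
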