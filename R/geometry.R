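#' Euclidean distance between two points
#'
#' @param a,b numeric(3) coordinates in Angstrom.
#' @return distance in Angstrom.
#' @export
atomDistance <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L,
            all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' Call a hydrogen bond from heavy-atom distance
#'
#' Crystal structures at typical RNA resolutions carry no hydrogens, so the
#' criterion is donor-acceptor heavy-atom distance alone: bonded at or below
#' \code{bondedMax}, not bonded at or above \code{brokenMin} (the published
#' negative criterion is a distance longer than 4 Angstrom), and an explicit
#' \code{ambiguous} verdict in between.
#'
#' @param donor numeric(3) donor heavy-atom coordinates, or a precomputed
#'   distance if \code{acceptor} is NULL.
#' @param acceptor numeric(3) acceptor coordinates, or NULL.
#' @param bondedMax,brokenMin distance cutoffs (Angstrom);
#'   \code{bondedMax < brokenMin} is required.
#' @return list with \code{distance} and \code{verdict} in
#'   \{bonded, not_bonded, ambiguous\}.
#' @examples
#' callHBond(c(0, 0, 0), c(2.9, 0, 0))$verdict   # bonded
#' callHBond(4.3)$verdict                        # not_bonded
#' @export
callHBond <- function(donor, acceptor = NULL, bondedMax = 3.5,
                      brokenMin = 4.0) {
  stopifnot(bondedMax < brokenMin)
  d <- if (is.null(acceptor)) {
    stopifnot(length(donor) == 1L, donor >= 0)
    as.numeric(donor)
  } else atomDistance(donor, acceptor)
  verdict <- if (d <= bondedMax) "bonded"
    else if (d >= brokenMin) "not_bonded"
    else "ambiguous"
  list(distance = d, verdict = verdict)
}

## required coordinates for classification, error if absent
.needCoord <- function(kti, label, atom) {
  p <- atomCoord(kti, label, atom)
  if (is.null(p))
    stop("incomplete instance ", instanceId(kti), ": missing ", label, ":",
         atom, call. = FALSE)
  p
}

#' @rdname classifyConformation
#' @export
setMethod("classifyConformation", "KTurnInstance",
  function(x, bondedMax = 3.5, brokenMin = 4.0, ambiguityMargin = 0.3) {
    o2p  <- .needCoord(x, "-1n", "O2'")
    a_n3 <- .needCoord(x, "2b", "N3")
    a_n1 <- .needCoord(x, "2b", "N1")
    a_n6 <- .needCoord(x, "2b", "N6")
    g_n3 <- .needCoord(x, "2n", "N3")
    l1   <- atomCoord(x, "L1", "O2'")
    a1n  <- atomCoord(x, "1n", "N1")

    dN3 <- atomDistance(o2p, a_n3)
    dN1 <- atomDistance(o2p, a_n1)
    dN6 <- atomDistance(a_n6, g_n3)
    dL1 <- if (!is.null(l1) && !is.null(a1n)) atomDistance(l1, a1n)
           else NA_real_

    bN3 <- dN3 <= bondedMax
    bN1 <- dN1 <= bondedMax
    reason <- ""
    if (!bN3 && !bN1) {
      cls <- "extended"
      reason <- "neither O2' acceptor distance is hydrogen bonded"
    } else if (bN3 && bN1 && abs(dN3 - dN1) < ambiguityMargin) {
      cls <- "ambiguous"
      reason <- sprintf("both acceptors bonded within %.2f A margin",
                        ambiguityMargin)
    } else {
      cls <- if (bN3 && (!bN1 || dN3 < dN1)) "N3" else "N1"
      ## secondary check: A2b N6 - G2n N3 is bonded only in the N3 class
      sec <- callHBond(dN6, bondedMax = bondedMax, brokenMin = brokenMin)
      contradiction <-
        (cls == "N3" && sec$verdict == "not_bonded") ||
        (cls == "N1" && sec$verdict == "bonded")
      if (contradiction) {
        reason <- sprintf(
          "primary acceptor says %s but N6-N3 = %.2f A says otherwise",
          cls, dN6)
        cls <- "ambiguous"
      }
    }

    pb <- residueAt(x, "3b"); pn <- residueAt(x, "3n")
    data.frame(
      instance_id = instanceId(x),
      d_O2p_N3 = dN3, d_O2p_N1 = dN1, d_N6_N3 = dN6, d_L1_A1n = dL1,
      cls = cls,
      pair_3b3n = paste0(pb, pn),
      reason = reason,
      stringsAsFactors = FALSE
    )
  })

#' @rdname classifyConformation
#' @export
setMethod("classifyConformation", "list",
  function(x, bondedMax = 3.5, brokenMin = 4.0, ambiguityMargin = 0.3) {
    out <- lapply(x, classifyConformation, bondedMax = bondedMax,
                  brokenMin = brokenMin, ambiguityMargin = ambiguityMargin)
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    res
  })

.PAIR_ATOMS <- list("2b2n" = c("2b", "2n"), "3b3n" = c("3b", "3n"),
                    "4b4n" = c("4b", "4n"))

#' @rdname helixWidth
#' @export
setMethod("helixWidth", "KTurnInstance", function(x, pairLabel = "2b2n") {
  pairLabel <- match.arg(pairLabel, names(.PAIR_ATOMS), several.ok = TRUE)
  rows <- lapply(pairLabel, function(pl) {
    lab <- .PAIR_ATOMS[[pl]]
    cb <- .needCoord(x, lab[1L], "C1'")
    cn <- .needCoord(x, lab[2L], "C1'")
    w <- atomDistance(cb, cn)
    if (w < 4)
      warning("instance ", instanceId(x), " ", pl, ": implausible C1'-C1' ",
              "width ", signif(w, 3), " A (< 4 A sanity floor)",
              call. = FALSE)
    data.frame(instance_id = instanceId(x), pair_label = pl, c1c1 = w,
               implausible = w < 4, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
})

#' @rdname helixWidth
#' @export
setMethod("helixWidth", "list", function(x, pairLabel = "2b2n") {
  do.call(rbind, c(lapply(x, helixWidth, pairLabel = pairLabel),
                   list(make.row.names = FALSE)))
})

#' Width records for a set of instances, with conformational class attached
#'
#' Convenience wrapper joining [helixWidth()] output with the class from
#' [classifyConformation()], one row per instance per pair.
#'
#' @param instances list of [KTurnInstance-class].
#' @param pairLabel pairs to measure (default all three).
#' @param calls optional precomputed classification data.frame.
#' @param ... cutoff parameters passed to [classifyConformation()].
#' @return data.frame with columns of [helixWidth()] plus \code{cls}.
#' @export
widthTable <- function(instances,
                       pairLabel = c("2b2n", "3b3n", "4b4n"),
                       calls = NULL, ...) {
  w <- helixWidth(instances, pairLabel = pairLabel)
  if (is.null(calls)) calls <- classifyConformation(instances, ...)
  w$cls <- calls$cls[match(w$instance_id, calls$instance_id)]
  w
}

#' Per-class width statistics
#'
#' Mean and sample (n-1) standard deviation of the C1'-C1' widths per
#' conformational class and basepair.  Groups with a single record report an
#' absent (NA) SD, not zero.
#'
#' @param records width records from [widthTable()] (columns
#'   \code{pair_label}, \code{cls}, \code{c1c1}).
#' @param groupBy grouping columns, default \code{c("pair_label", "cls")}.
#' @return data.frame with columns \code{pair_label}, \code{cls}, \code{n},
#'   \code{mean}, \code{sd}; attribute \code{sd_estimator = "sample"}.
#' @export
widthStatistics <- function(records, groupBy = c("pair_label", "cls")) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no width records to summarize")
  stopifnot(all(c(groupBy, "c1c1") %in% names(records)))
  key <- interaction(records[groupBy], drop = TRUE, lex.order = TRUE)
  parts <- split(records, key)
  out <- do.call(rbind, c(lapply(parts, function(p) {
    cbind(p[1L, groupBy, drop = FALSE],
          data.frame(n = nrow(p), mean = mean(p$c1c1),
                     sd = if (nrow(p) > 1L) stats::sd(p$c1c1) else NA_real_))
  }), list(make.row.names = FALSE)))
  attr(out, "sd_estimator") <- "sample"
  out
}

#' Test whether a classification call survives rigid motion
#'
#' Applies a rotation + translation to every atom of an instance.  Used for
#' invariance checks: all distances, verdicts and classes must be unchanged.
#'
#' @param x a [KTurnInstance-class].
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric(3).
#' @return the transformed [KTurnInstance-class].
#' @export
transformInstance <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is(x, "KTurnInstance"),
            all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L)
  xyz <- as.matrix(x@atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, "+")
  x@atoms$x <- xyz[, 1L]; x@atoms$y <- xyz[, 2L]; x@atoms$z <- xyz[, 3L]
  x
}

#' Random rotation matrix
#'
#' Uniform random rotation (QR of a Gaussian matrix, determinant fixed to
#' +1).  Seeded by the caller's RNG stream.
#'
#' @return 3x3 rotation matrix.
#' @export
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}
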