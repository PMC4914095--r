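#' Is a 3b,3n combination a Watson-Crick pair?
#'
#' Watson-Crick here means the ascending diagonal of the 4x4 array:
#' A-U, U-A, G-C and C-G.  The G/U wobble pairs are deliberately excluded.
#'
#' @param b,n one-letter bases at 3b and 3n (vectorized).
#' @return logical.
#' @examples
#' isWatsonCrick("G", "C")  # TRUE
#' isWatsonCrick("U", "G")  # FALSE: wobble is not on the diagonal
#' @export
isWatsonCrick <- function(b, n) {
  paste0(b, n) %in% c("AU", "UA", "GC", "CG")
}

#' Predict ion-induced foldability from the 3b,3n sequence
#'
#' The folding rules: a Watson-Crick 3b,3n pair is not folded by metal ions
#' alone (and this dominates: C-G does not fold despite 3b = C); otherwise
#' 3b = C or 3n = G confers ion-induced folding; anything else does not.
#' This is a total function over all sixteen combinations.
#'
#' @param b,n one-letter bases at 3b and 3n (vectorized).
#' @return \code{"yes"} or \code{"no"}.
#' @examples
#' predictFolding("U", "G")  # yes
#' predictFolding("C", "G")  # no: Watson-Crick wins
#' predictFolding("A", "G")  # yes, and the only N3 cell that folds
#' @export
predictFolding <- function(b, n) {
  stopifnot(all(b %in% RNA_BASES), all(n %in% RNA_BASES))
  ifelse(isWatsonCrick(b, n), "no",
         ifelse(b == "C" | n == "G", "yes", "no"))
}

.cellOrder <- function(cells) {
  cells[order(match(cells$b, RNA_BASES), match(cells$n, RNA_BASES)), ,
        drop = FALSE]
}

#' The packaged 3b,3n rule table
#'
#' Returns the default lookup table associating each 3b,3n combination with
#' its conformational class and ion-induced foldability.  The table ships as
#' a human-editable TSV (\code{system.file("extdata", "rule_table.tsv",
#' package = "kturnlab")}) with a provenance string per cell, so cells can be
#' overridden as new structures appear.  Fourteen cells are determined; two
#' (A-U and G.A) are unknown.
#'
#' @param path optional path to an alternative table in the same format.
#' @return a [RuleTable-class].
#' @examples
#' tab <- defaultRuleTable()
#' predictConformation("U", "G", tab)   # N1
#' @export
defaultRuleTable <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rule_table.tsv",
                                package = "kturnlab")
  cells <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  cells$n_n3 <- as.integer(cells$n_n3)
  cells$n_n1 <- as.integer(cells$n_n1)
  if (is.null(cells$notes)) cells$notes <- ""
  cells$notes[is.na(cells$notes)] <- ""
  rownames(cells) <- NULL
  new("RuleTable", cells = .cellOrder(cells))
}

#' Look up one cell of a rule table
#'
#' @param table a [RuleTable-class].
#' @param b,n bases at 3b and 3n.
#' @return one-row data.frame (the cell).
#' @export
ruleCell <- function(table, b, n) {
  stopifnot(is(table, "RuleTable"))
  i <- which(table@cells$b == b & table@cells$n == n)
  if (!length(i)) stop("no cell for pair ", b, ",", n)
  table@cells[i, , drop = FALSE]
}

#' Predict the conformational class from the 3b,3n sequence
#'
#' Pure lookup in the rule table; returns \code{"unknown"} for unpopulated
#' cells.
#'
#' @param b,n bases at 3b and 3n (vectorized).
#' @param table a [RuleTable-class], default [defaultRuleTable()].
#' @return character vector in \{N3, N1, unknown\}.
#' @export
predictConformation <- function(b, n, table = defaultRuleTable()) {
  stopifnot(is(table, "RuleTable"))
  cl <- table@cells
  cl$conformation[match(paste0(b, n), paste0(cl$b, cl$n))]
}

#' Build a rule table from classified structures
#'
#' Each cell takes the majority conformation of the calls landing in it;
#' split cells keep the majority with the minority recorded in the notes
#' (the single known real split, 3b,3n = A.G, is resolved this way: the
#' ribosomal copy is forced to N1 by its environment).  An exact tie sets
#' the cell to unknown with a tie warning; empty cells are unknown.
#' Foldability is filled from [predictFolding()].
#'
#' @param calls data.frame with columns \code{cls} (\code{"N3"} or
#'   \code{"N1"}; ambiguous/extended calls are rejected) and
#'   \code{pair_3b3n} (two-character string), as produced by
#'   [classifyConformation()].
#' @return a [RuleTable-class].
#' @export
buildRuleTable <- function(calls) {
  stopifnot(all(c("cls", "pair_3b3n") %in% names(calls)))
  bad <- !calls$cls %in% c("N3", "N1")
  if (any(bad))
    stop("calls must be non-ambiguous (N3/N1); got: ",
         paste(unique(calls$cls[bad]), collapse = ", "))
  grid <- expand.grid(n = RNA_BASES, b = RNA_BASES,
                      stringsAsFactors = FALSE)[, c("b", "n")]
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    b <- grid$b[i]; n <- grid$n[i]
    sub <- calls[calls$pair_3b3n == paste0(b, n), , drop = FALSE]
    n3 <- sum(sub$cls == "N3"); n1 <- sum(sub$cls == "N1")
    notes <- ""
    if (n3 + n1 == 0L) conf <- "unknown"
    else if (n3 == n1) {
      conf <- "unknown"
      notes <- sprintf("tie: %d N3 vs %d N1", n3, n1)
      warning("exact tie in cell ", b, ",", n, " (", n3, ":", n1,
              "); cell set unknown", call. = FALSE)
    } else {
      conf <- if (n3 > n1) "N3" else "N1"
      minority <- min(n3, n1)
      if (minority > 0L) {
        who <- sub$instance_id[sub$cls != conf]
        notes <- sprintf("%d minority %s call(s)%s", minority,
                         setdiff(c("N3", "N1"), conf),
                         if (!is.null(who))
                           paste0(": ", paste(who, collapse = ", "))
                         else "")
      }
    }
    data.frame(b = b, n = n, conformation = conf,
               folds = predictFolding(b, n), n_n3 = n3, n_n1 = n1,
               provenance = "built from classified structures",
               notes = notes, stringsAsFactors = FALSE)
  }))
  new("RuleTable", cells = .cellOrder(cells))
}

#' Expand a rule table's evidence counts into one call per structure
#'
#' Returns the per-structure pseudo-calls implied by the evidence counts of
#' a table (columns \code{n_n3}, \code{n_n1}): the packaged default expands
#' to the supporting-structure set of the default table, so that
#' \code{buildRuleTable(evidenceCalls(defaultRuleTable()))} round-trips the
#' table's conformation column.
#'
#' @param table a [RuleTable-class], default the packaged table.
#' @return data.frame with columns \code{instance_id}, \code{cls},
#'   \code{pair_3b3n}.
#' @export
evidenceCalls <- function(table = defaultRuleTable()) {
  cl <- table@cells
  rows <- lapply(seq_len(nrow(cl)), function(i) {
    pair <- paste0(cl$b[i], cl$n[i])
    cls <- c(rep("N3", cl$n_n3[i]), rep("N1", cl$n_n1[i]))
    if (!length(cls)) return(NULL)
    data.frame(instance_id = sprintf("%s_%02d", pair, seq_along(cls)),
               cls = cls, pair_3b3n = pair, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Render a rule table as a 4x4 text array
#'
#' Rows are the 3b base (A, C, G, U top to bottom), columns the 3n base, so
#' that 3b = C is row 2 and 3n = G is column 3.  Each cell shows the
#' conformation and a \code{+}/\code{-} flag for ion-induced folding.
#'
#' @param table a [RuleTable-class].
#' @return character matrix 4x4 (invisibly printed as a table).
#' @export
renderRuleTable <- function(table = defaultRuleTable()) {
  cl <- table@cells
  m <- matrix("", 4L, 4L, dimnames = list(`3b` = RNA_BASES,
                                          `3n` = RNA_BASES))
  for (i in seq_len(nrow(cl))) {
    mark <- if (cl$folds[i] == "yes") "+" else "-"
    conf <- if (cl$conformation[i] == "unknown") "?" else cl$conformation[i]
    m[cl$b[i], cl$n[i]] <- paste0(conf, mark)
  }
  m
}

setMethod("show", "RuleTable", function(object) {
  cl <- object@cells
  cat("RuleTable: 3b,3n -> (conformation, ion-induced folding)\n")
  cat("  determined cells:", sum(cl$conformation != "unknown"),
      " unknown:", sum(cl$conformation == "unknown"), "\n")
  print(renderRuleTable(object), quote = FALSE)
  cat("  (+ folds in metal ions alone, - does not; ? unknown class)\n")
})
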