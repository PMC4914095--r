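#' Read a multiple sequence alignment of a k-turn region
#'
#' Wraps the Biostrings readers for FASTA, Stockholm and Clustal.  On
#' ingest, sequences are case-folded to upper case and T is normalized to U;
#' a ragged FASTA alignment is an error naming the offending record.
#'
#' @param path alignment file.
#' @param format \code{"auto"} (from extension/content), \code{"fasta"},
#'   \code{"stockholm"} or \code{"clustal"}.
#' @return a [Biostrings::RNAMultipleAlignment-class].
#' @export
readAlignment <- function(path,
                          format = c("auto", "fasta", "stockholm",
                                     "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sto", "stk", "stockholm")) "stockholm"
      else if (ext %in% c("aln", "clustal", "clw")) "clustal"
      else if (ext %in% c("fa", "fasta", "afa", "fna", "mfa")) "fasta"
      else {
        head <- readLines(path, n = 1L, warn = FALSE)
        if (grepl("^# STOCKHOLM", head)) "stockholm"
        else if (grepl("^CLUSTAL", head)) "clustal"
        else "fasta"
      }
  }
  tmp <- .normalizeAlignmentFile(path, format)
  on.exit(unlink(tmp), add = TRUE)
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(tmp, format = "fasta")
    w <- Biostrings::width(seqs)
    if (length(unique(w)) > 1L) {
      off <- names(seqs)[which(w != w[1L])[1L]]
      stop("ragged alignment: record ", sQuote(off), " has width ",
           w[w != w[1L]][1L], ", expected ", w[1L])
    }
    Biostrings::RNAMultipleAlignment(
      Biostrings::RNAStringSet(as.character(seqs)))
  } else {
    Biostrings::readRNAMultipleAlignment(tmp, format = format)
  }
}

## Rewrite the sequence text of an alignment file with T -> U, upper case,
## leaving identifiers/markup untouched, so the RNA parser accepts DNA-
## alphabet inputs.
.normalizeAlignmentFile <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  tmp <- tempfile(fileext = paste0(".", format))
  fixSeq <- function(s) chartr("acgutT", "ACGUUU", s)
  if (format == "fasta") {
    isHdr <- startsWith(lines, ">")
    lines[!isHdr] <- fixSeq(lines[!isHdr])
  } else if (format == "stockholm") {
    body <- !startsWith(lines, "#") & !startsWith(lines, "//") &
            nzchar(trimws(lines))
    lines[body] <- vapply(lines[body], function(l) {
      m <- regexpr("^(\\S+)(\\s+)(\\S+)\\s*$", l, perl = TRUE)
      if (m == -1L) return(l)
      parts <- regmatches(l, regexec("^(\\S+)(\\s+)(\\S+)\\s*$", l))[[1L]]
      paste0(parts[2L], parts[3L], fixSeq(parts[4L]))
    }, "", USE.NAMES = FALSE)
  } else { # clustal
    body <- seq_along(lines) > 1L & grepl("^\\S+\\s+\\S+", lines) &
            !grepl("^\\s", lines)
    lines[body] <- vapply(lines[body], function(l) {
      parts <- regmatches(l, regexec("^(\\S+)(\\s+)(\\S+)(\\s*\\d*)\\s*$",
                                     l))[[1L]]
      if (!length(parts)) return(l)
      paste0(parts[2L], parts[3L], fixSeq(parts[4L]), parts[5L])
    }, "", USE.NAMES = FALSE)
  }
  writeLines(lines, tmp)
  tmp
}

#' Extract the 3b,3n base observations from an alignment
#'
#' Reads, for every sequence, the residues at the two stated 1-based
#' alignment columns.  A gap (\code{-} or \code{.}) or an ambiguity code at
#' either column excludes the sequence, with the reason recorded; included
#' observations have both bases in A, C, G, U.
#'
#' @param aln a [Biostrings::RNAMultipleAlignment-class] from
#'   [readAlignment()] (or a named character vector of aligned rows).
#' @param col3b,col3n 1-based alignment columns of the 3b and 3n positions.
#' @return data.frame with columns \code{id}, \code{b}, \code{n},
#'   \code{included}, \code{reason} (\code{""}, \code{"gap"} or
#'   \code{"ambiguous"}).
#' @export
extractPairs <- function(aln, col3b, col3n) {
  rows <- if (is.character(aln)) aln
    else as.character(Biostrings::unmasked(aln))
  if (!length(rows)) stop("empty alignment")
  len <- unique(nchar(rows))
  stopifnot(length(len) == 1L)
  for (col in c(col3b, col3n))
    if (col < 1L || col > len)
      stop("column ", col, " out of range (alignment length ", len, ")")
  b <- toupper(substr(rows, col3b, col3b))
  n <- toupper(substr(rows, col3n, col3n))
  b[b == "T"] <- "U"; n[n == "T"] <- "U"
  gap <- b %in% c("-", ".") | n %in% c("-", ".")
  ok <- b %in% RNA_BASES & n %in% RNA_BASES
  reason <- ifelse(ok, "", ifelse(gap, "gap", "ambiguous"))
  ids <- names(rows) %||% as.character(seq_along(rows))
  data.frame(id = ids, b = b, n = n, included = ok, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tabulate 3b,3n observations into a 4x4 frequency array
#'
#' @param obs observation data.frame from [extractPairs()].
#' @return a [Freq4x4-class]. Errors if no observation is included.
#' @export
profilePairs <- function(obs) {
  stopifnot(all(c("b", "n", "included") %in% names(obs)))
  inc <- obs[obs$included, , drop = FALSE]
  if (!nrow(inc)) stop("empty profile: no included observation")
  counts <- table(factor(inc$b, RNA_BASES), factor(inc$n, RNA_BASES))
  m <- matrix(as.numeric(counts), 4L, 4L,
              dimnames = list(RNA_BASES, RNA_BASES))
  reasons <- table(factor(obs$reason[!obs$included],
                          c("gap", "ambiguous")))
  new("Freq4x4", counts = m, nExcluded = sum(!obs$included),
      excludedReasons = c(gap = unname(reasons["gap"]),
                          ambiguous = unname(reasons["ambiguous"])))
}

#' Profile an alignment in one call
#'
#' @inheritParams extractPairs
#' @return a [Freq4x4-class].
#' @export
profileAlignment <- function(aln, col3b, col3n) {
  profilePairs(extractPairs(aln, col3b, col3n))
}

#' Construct a Freq4x4 from counts or fractions
#'
#' @param counts 4x4 numeric matrix (any dimnames in A,C,G,U order, or
#'   none).
#' @param nExcluded excluded-sequence tally, default 0.
#' @return a [Freq4x4-class].
#' @export
newFreq4x4 <- function(counts, nExcluded = 0) {
  m <- as.matrix(counts)
  dimnames(m) <- list(RNA_BASES, RNA_BASES)
  new("Freq4x4", counts = m, nExcluded = nExcluded,
      excludedReasons = c(gap = 0, ambiguous = 0))
}

#' Read a 4x4 frequency table from TSV
#'
#' Expects a header row \code{3b <tab> A C G U} and four data rows (3b base
#' then four values).  Values may be counts, proportions or percentages;
#' [pairFractions()] normalizes.
#'
#' @param path TSV file.
#' @return a [Freq4x4-class].
#' @export
readFreq <- function(path) {
  tab <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  if (!all(dim(m) == c(4L, 4L)))
    stop("frequency table must be 4x4, got ", nrow(m), "x", ncol(m))
  newFreq4x4(m)
}

#' @rdname pairCounts
#' @export
setMethod("pairCounts", "Freq4x4", function(x) x@counts)

#' @rdname pairCounts
#' @export
setMethod("pairFractions", "Freq4x4",
  function(x, percent = TRUE, denominator = c("included", "all")) {
    denominator <- match.arg(denominator)
    total <- sum(x@counts) +
      if (denominator == "all") x@nExcluded else 0
    if (total <= 0) stop("empty profile")
    f <- x@counts / total
    if (percent) f * 100 else f
  })

setMethod("show", "Freq4x4", function(object) {
  cat("Freq4x4: ", sum(object@counts), " included, ", object@nExcluded,
      " excluded\n", sep = "")
  print(round(pairFractions(object), 2))
})

#' Aggregate a 3b,3n profile through the rule table
#'
#' Projects the fraction of sequences in each cell onto the cell's
#' conformation and foldability: the population N3 fraction is the summed
#' fraction of cells whose rule-table conformation is N3, and likewise for
#' N1, unknown and the folding split.  Equivalent to classifying every
#' sequence individually and aggregating.
#'
#' @param freq a [Freq4x4-class].
#' @param table a [RuleTable-class], default [defaultRuleTable()].
#' @param denominator see [pairFractions()].
#' @return a [PredictionSummary-class].
#' @examples
#' aln <- simulateAlignment(kturnPopulationFreq("kt7"), n = 500, seed = 1)
#' summarizeProfile(profileAlignment(aln$aln, aln$col3b, aln$col3n))
#' @export
summarizeProfile <- function(freq, table = defaultRuleTable(),
                             denominator = c("included", "all")) {
  stopifnot(is(freq, "Freq4x4"), is(table, "RuleTable"))
  fr <- pairFractions(freq, percent = TRUE, denominator = denominator)
  cl <- table@cells
  perCell <- data.frame(
    b = rep(RNA_BASES, each = 4L), n = rep(RNA_BASES, 4L),
    stringsAsFactors = FALSE)
  perCell$fraction <- fr[cbind(perCell$b, perCell$n)]
  key <- match(paste0(perCell$b, perCell$n), paste0(cl$b, cl$n))
  perCell$conformation <- cl$conformation[key]
  perCell$folds <- predictFolding(perCell$b, perCell$n)
  tot <- sum(perCell$fraction)
  fractions <- c(
    N3 = sum(perCell$fraction[perCell$conformation == "N3"]),
    N1 = sum(perCell$fraction[perCell$conformation == "N1"]),
    unknown = sum(perCell$fraction[perCell$conformation == "unknown"]) +
      (100 - tot),
    folds = sum(perCell$fraction[perCell$folds == "yes"]),
    nonfolds = sum(perCell$fraction[perCell$folds == "no"]) + (100 - tot)
  )
  new("PredictionSummary", fractions = fractions,
      perCell = perCell[perCell$fraction > 0, , drop = FALSE],
      nIncluded = sum(pairCounts(freq)))
}

#' Render a prediction summary as two labeled text bars
#'
#' One bar for conformation (N3 / N1 / unknown) and one for ion-induced
#' folding (folds / does not fold), each labeled with the percentage of the
#' larger fraction.
#'
#' @param summary a [PredictionSummary-class].
#' @param width bar width in characters.
#' @return character vector of report lines (also printed).
#' @export
renderSummary <- function(summary, width = 50L) {
  stopifnot(is(summary, "PredictionSummary"))
  fr <- summary@fractions
  bar <- function(parts) {
    nch <- round(parts / 100 * width)
    seg <- mapply(function(k, ch) strrep(ch, max(k, 0)), nch,
                  substr(names(parts), 1L, 1L))
    top <- names(parts)[which.max(parts)]
    sprintf("[%s] %s %.1f%%", paste(seg, collapse = "|"), top,
            max(parts))
  }
  lines <- c(
    sprintf("n = %d sequences", as.integer(summary@nIncluded)),
    paste("conformation:", bar(fr[c("N3", "N1", "unknown")])),
    paste("folding:     ", bar(fr[c("folds", "nonfolds")]))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

setMethod("show", "PredictionSummary", function(object) {
  fr <- object@fractions
  cat("PredictionSummary (n = ", as.integer(object@nIncluded), ")\n",
      sep = "")
  cat(sprintf("  conformation: N3 %.2f%%  N1 %.2f%%  unknown %.2f%%\n",
              fr["N3"], fr["N1"], fr["unknown"]))
  cat(sprintf("  folding:      folds %.2f%%  does not fold %.2f%%\n",
              fr["folds"], fr["nonfolds"]))
})

## Bonferroni-adjusted exact binomial bounds giving simultaneous coverage
## >= level over the 16 multinomial cells.
#' Are observed cell counts within simultaneous confidence bounds?
#'
#' Checks every cell of an observed 4x4 count matrix against
#' Bonferroni-adjusted exact binomial bounds around the generating
#' probabilities, a Goodman-style simultaneous multinomial interval with
#' joint coverage at least \code{level}.
#'
#' @param counts observed 4x4 counts (or [Freq4x4-class]).
#' @param probs generating 4x4 probabilities (or [Freq4x4-class];
#'   normalized internally).
#' @param level simultaneous confidence level, default 0.99.
#' @return TRUE if every cell count lies within its bound.
#' @export
recoveryWithinCI <- function(counts, probs, level = 0.99) {
  if (is(counts, "Freq4x4")) counts <- pairCounts(counts)
  if (is(probs, "Freq4x4")) probs <- pairCounts(probs)
  probs <- probs / sum(probs)
  n <- sum(counts)
  k <- length(probs)
  alpha <- (1 - level) / k
  lo <- stats::qbinom(alpha / 2, n, probs)
  hi <- stats::qbinom(1 - alpha / 2, n, probs)
  all(counts >= lo & counts <= hi)
}
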