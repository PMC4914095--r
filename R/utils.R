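## Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a fixed RNG state without disturbing the caller's stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Stable md5 of an R object, for config provenance stamps.
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), f)
  unname(tools::md5sum(f))
}

## Modified nucleotide -> parent base. Deliberately small; unknown residue
## names are flagged by the caller, never silently dropped.
MODIFIED_BASE_ALIASES <- c(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  DA = "A", DC = "C", DG = "G", DT = "U", DU = "U",
  "1MA" = "A", "2MA" = "A", "6MA" = "A", "MIA" = "A", "RIA" = "A",
  "5MC" = "C", "OMC" = "C", "4OC" = "C", "CCC" = "C",
  "2MG" = "G", "M2G" = "G", "7MG" = "G", "OMG" = "G", "1MG" = "G",
  "G7M" = "G", "YG"  = "G",
  "PSU" = "U", "5MU" = "U", "OMU" = "U", "4SU" = "U", "H2U" = "U",
  "DHU" = "U", "UR3" = "U", "3MU" = "U"
)

normalizeBase <- function(resid) {
  r <- toupper(trimws(resid))
  out <- unname(MODIFIED_BASE_ALIASES[r])
  out[is.na(out)] <- NA_character_
  out
}

## Display form of a 3b,3n pair: en dash for Watson-Crick, bullet otherwise.
formatPair <- function(b, n) {
  sep <- ifelse(isWatsonCrick(b, n), "-", "•")
  paste0(b, sep, n)
}
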