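#' Load an RNA coordinate file
#'
#' Reads a PDB or mmCIF file through bio3d and returns a tidy atom table,
#' one row per atom per model, with alternate-location duplicates already
#' resolved: for each (model, chain, residue, insertion code, atom name) the
#' conformer with the highest occupancy is kept, ties broken by the
#' alphabetically first alt-loc identifier.
#'
#' @param path path to a coordinate file.
#' @param format \code{"auto"} (default; decided from the file extension,
#'   falling back to content sniffing), \code{"pdb"} or \code{"mmcif"}.
#' @return data.frame with columns \code{model}, \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety}, \code{x}, \code{y}, \code{z},
#'   \code{occupancy}, \code{alt}.
#' @examples
#' kt <- kturnTemplate("N3")
#' f <- tempfile(fileext = ".pdb")
#' writeKTurnPDB(kt, f)
#' atoms <- loadStructure(f)
#' head(atoms)
#' @seealso [extractInstance()], [enumerateInstances()]
#' @export
loadStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else {
        head <- readLines(path, n = 50L, warn = FALSE)
        if (any(grepl("^(data_|loop_|_atom_site)", head))) "mmcif" else "pdb"
      }
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))

  at <- pdb$atom
  nmodel <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  one <- function(m) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else as.numeric(pdb$xyz)
    data.frame(
      model = m,
      chain = as.character(at$chain),
      resno = as.integer(at$resno),
      insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
      resid = toupper(trimws(as.character(at$resid))),
      ## mmCIF atom names containing primes come back quoted ("O2'")
      elety = gsub('"', "", trimws(as.character(at$elety))),
      x = xyz[seq(1, length(xyz), 3)],
      y = xyz[seq(2, length(xyz), 3)],
      z = xyz[seq(3, length(xyz), 3)],
      occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
      alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
      stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, lapply(seq_len(nmodel), one))
  resolveAltLoc(atoms)
}

## Keep the highest-occupancy conformer per atom; ties -> first alt id.
resolveAltLoc <- function(atoms) {
  key <- paste(atoms$model, atoms$chain, atoms$resno, atoms$insert,
               atoms$elety, sep = "\r")
  ## order so the preferred conformer comes first within each key
  ord <- order(key, -atoms$occupancy, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Read k-turn position annotations
#'
#' An annotation maps nomenclature labels to residues of a structure.  The
#' flat format is TSV with columns \code{instance_id}, \code{label},
#' \code{chain}, \code{resnum} (author numbering, 1-based) and optional
#' \code{icode}; the JSON equivalent is an array of objects with the same
#' fields.
#'
#' @param path TSV or JSON annotation file.
#' @return data.frame with columns \code{instance_id}, \code{label},
#'   \code{chain}, \code{resnum}, \code{icode}.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  ann <- if (grepl("^\\s*[\\[{]", first)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  need <- c("instance_id", "label", "chain", "resnum")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns ", paste(need, collapse = ", "))
  ann$resnum <- as.integer(ann$resnum)
  if (is.null(ann$icode)) ann$icode <- ""
  ann$icode[is.na(ann$icode)] <- ""
  dup <- duplicated(paste(ann$instance_id, ann$chain, ann$resnum, ann$icode))
  if (any(dup))
    stop("two labels map to the same residue in instance ",
         ann$instance_id[dup][1L])
  ann
}

#' Extract one k-turn instance from an atom table
#'
#' Collects, for every annotated nomenclature position, the named atoms the
#' geometric analysis needs (exact atom-name match; the legacy \code{O2*}
#' spelling is accepted for \code{O2'}).  Missing required atoms flag the
#' instance as incomplete, with the missing names listed; they never fail the
#' extraction.  An annotation pointing at a residue absent from the structure
#' is an error.
#'
#' @param atoms atom table from [loadStructure()].
#' @param annotation annotation rows for one instance (see
#'   [readAnnotations()]); must cover at least the labels
#'   \code{-1n, 1n, 2b, 2n, 3b, 3n}.
#' @param model model number to extract from (default 1).
#' @return a [KTurnInstance-class].
#' @export
extractInstance <- function(atoms, annotation, model = 1L) {
  stopifnot(is.data.frame(annotation), nrow(annotation) > 0L)
  id <- unique(annotation$instance_id)
  if (length(id) != 1L)
    stop("annotation must describe a single instance, got: ",
         paste(id, collapse = ", "))
  missingLab <- setdiff(KT_REQUIRED_LABELS, annotation$label)
  if (length(missingLab))
    stop("annotation for ", id, " lacks required labels: ",
         paste(missingLab, collapse = ", "))
  at <- atoms[atoms$model == model, , drop = FALSE]
  if (!nrow(at)) stop("no atoms in model ", model)

  rows <- list(); residues <- character(); rawres <- character()
  missingAtoms <- character()
  for (i in seq_len(nrow(annotation))) {
    lab <- annotation$label[i]
    sel <- at$chain == annotation$chain[i] &
           at$resno == annotation$resnum[i] &
           at$insert == (annotation$icode[i] %||% "")
    res <- at[sel, , drop = FALSE]
    if (!nrow(res))
      stop("annotation error: residue for label ", lab, " (chain ",
           annotation$chain[i], " ", annotation$resnum[i],
           ") absent from structure ", id)
    rawres[lab] <- res$resid[1L]
    residues[lab] <- normalizeBase(res$resid[1L])
    ## accept legacy O2* spelling
    res$elety[res$elety == "O2*"] <- "O2'"
    keep <- unique(c(KT_REQUIRED_ATOMS[[lab]], "C1'",
                     intersect(res$elety,
                               c("N1", "N2", "N3", "N4", "N6", "N7", "N9",
                                 "O2", "O4", "O6", "O2'", "C1'"))))
    found <- res[res$elety %in% keep, , drop = FALSE]
    found <- found[!duplicated(found$elety), , drop = FALSE]
    if (nrow(found))
      rows[[lab]] <- data.frame(label = lab, elety = found$elety,
                                x = found$x, y = found$y, z = found$z,
                                stringsAsFactors = FALSE)
    req <- KT_REQUIRED_ATOMS[[lab]]
    if (length(req)) {
      miss <- setdiff(req, found$elety)
      if (length(miss))
        missingAtoms <- c(missingAtoms, paste0(lab, ":", miss))
    }
  }
  if (!is.na(residues["2b"]) && residues["2b"] != "A")
    warning("instance ", id, ": 2b is ", residues["2b"],
            ", expected the conserved adenine", call. = FALSE)
  if (!is.na(residues["2n"]) && residues["2n"] != "G")
    warning("instance ", id, ": 2n is ", residues["2n"],
            ", expected the conserved guanine", call. = FALSE)
  unknown <- names(residues)[is.na(residues)]
  if (length(unknown))
    warning("instance ", id, ": unrecognized residue name(s) at ",
            paste(unknown, collapse = ", "), " (kept, flagged)",
            call. = FALSE)

  new("KTurnInstance",
      instanceId = id,
      residues = residues,
      rawResidues = rawres,
      atoms = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      source = sprintf("model %d", model),
      incomplete = length(missingAtoms) > 0L,
      missingAtoms = missingAtoms)
}

#' Enumerate all k-turn instances of a structure
#'
#' Produces one [KTurnInstance-class] per (model, annotation) combination.
#' Crystallographically independent copies are never merged or averaged:
#' each counts as its own instance downstream.
#'
#' @param atoms atom table from [loadStructure()].
#' @param annotations annotation data.frame possibly covering several
#'   \code{instance_id}s (see [readAnnotations()]).
#' @param source optional provenance string recorded on each instance.
#' @return list of [KTurnInstance-class] objects, named
#'   \code{<instance_id>} or \code{<instance_id>.m<model>} when the file has
#'   several models.
#' @export
enumerateInstances <- function(atoms, annotations, source = "") {
  models <- sort(unique(atoms$model))
  ids <- unique(annotations$instance_id)
  out <- list()
  for (m in models) {
    for (id in ids) {
      kti <- extractInstance(atoms,
                             annotations[annotations$instance_id == id, ,
                                         drop = FALSE],
                             model = m)
      nm <- if (length(models) > 1L) sprintf("%s.m%d", id, m) else id
      kti@instanceId <- nm
      kti@source <- paste0(source, if (nzchar(source)) " ", "model ", m)
      out[[nm]] <- kti
    }
  }
  out
}

## ---- KTurnInstance methods ------------------------------------------------

#' @rdname KTurnInstance-class
#' @export
setMethod("instanceId", "KTurnInstance", function(x) x@instanceId)

#' Residue identity at a nomenclature position
#'
#' @param x a [KTurnInstance-class].
#' @param label nomenclature label, e.g. \code{"3b"}.
#' @return single character base, or NA if the position is not annotated.
#' @export
residueAt <- function(x, label) {
  stopifnot(is(x, "KTurnInstance"))
  if (label %in% names(x@residues)) unname(x@residues[label])
  else NA_character_
}

#' Coordinates of a named atom
#'
#' @param x a [KTurnInstance-class].
#' @param label nomenclature label.
#' @param atom atom name (PDB convention), e.g. \code{"C1'"}.
#' @return numeric(3) xyz in Angstrom, or NULL if absent.
#' @export
atomCoord <- function(x, label, atom) {
  a <- x@atoms
  i <- which(a$label == label & a$elety == atom)
  if (!length(i)) return(NULL)
  as.numeric(a[i[1L], c("x", "y", "z")])
}

setMethod("show", "KTurnInstance", function(object) {
  cat("KTurnInstance", sQuote(object@instanceId),
      if (object@incomplete) "[incomplete]" else "", "\n")
  res <- object@residues
  lab <- intersect(KT_LABELS, names(res))
  cat("  positions:", paste0(lab, "=", res[lab], collapse = " "), "\n")
  cat("  atoms:", nrow(object@atoms), " source:", object@source, "\n")
  if (length(object@missingAtoms))
    cat("  missing:", paste(object@missingAtoms, collapse = ", "), "\n")
})
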