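## Tiny text fixtures built in code.

## three-atom PDB: two residues on chain A
miniPDBLines <- function() c(
  "ATOM      1  C1'   A A   1       0.000   0.000   0.000  1.00  0.00",
  "ATOM      2  O2'   A A   1       1.000   0.000   0.000  1.00  0.00",
  "ATOM      3  N1    G A   2       1.000   2.000   2.000  1.00  0.00",
  "END"
)

## the same content serialized as mmCIF
miniCIFLines <- function() c(
  "data_mini",
  "loop_",
  "_atom_site.group_PDB",
  "_atom_site.id",
  "_atom_site.type_symbol",
  "_atom_site.label_atom_id",
  "_atom_site.label_alt_id",
  "_atom_site.label_comp_id",
  "_atom_site.label_asym_id",
  "_atom_site.label_entity_id",
  "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code",
  "_atom_site.Cartn_x",
  "_atom_site.Cartn_y",
  "_atom_site.Cartn_z",
  "_atom_site.occupancy",
  "_atom_site.B_iso_or_equiv",
  "_atom_site.pdbx_formal_charge",
  "_atom_site.auth_seq_id",
  "_atom_site.auth_comp_id",
  "_atom_site.auth_asym_id",
  "_atom_site.auth_atom_id",
  "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 C \"C1'\" . A A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 A A \"C1'\" 1",
  "ATOM 2 O \"O2'\" . A A 1 1 ? 1.000 0.000 0.000 1.00 0.00 ? 1 A A \"O2'\" 1",
  "ATOM 3 N N1 . G A 1 2 ? 1.000 2.000 2.000 1.00 0.00 ? 2 G A N1 1"
)

writeTemp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## canonical G-C Watson-Crick pair at 3b,3n (three WC-WC bonds, cis),
## packed into a minimal instance
gcPairInstance <- function(shift_n = 0) {
  atoms <- data.frame(
    label = c(rep("3b", 5L), rep("3n", 5L)),
    elety = c("O6", "N1", "N2", "N9", "C1'",
              "N4", "N3", "O2", "N1", "C1'"),
    x = c(0, 0, 0, -1.8, -2.9,
          c(2.9, 2.9, 2.9, 4.7, 5.8) + shift_n),
    y = c(2.3, 0, -2.3, -2.5, -3.3,
          2.3, 0, -2.3, -2.5, -3.3),
    z = 0,
    stringsAsFactors = FALSE
  )
  new("KTurnInstance", instanceId = "gc_fixture",
      residues = c("3b" = "G", "3n" = "C"),
      rawResidues = c("3b" = "G", "3n" = "C"),
      atoms = atoms, source = "fixture",
      incomplete = TRUE, missingAtoms = "2b:N1")
}

## modify one named atom of an instance
moveAtom <- function(kti, label, elety, xyz) {
  i <- which(kti@atoms$label == label & kti@atoms$elety == elety)
  stopifnot(length(i) == 1L)
  kti@atoms[i, c("x", "y", "z")] <- as.list(xyz)
  kti
}

## alignment fixture rows used across formats
alnRows <- function() c(s1 = "GAUGGC", s2 = "GACGGU", s3 = "GAAGGA")

writeFastaAln <- function(rows = alnRows(), ext = ".fa") {
  writeTemp(as.character(rbind(paste0(">", names(rows)), rows)), ext)
}

writeStockholmAln <- function(rows = alnRows()) {
  writeTemp(c("# STOCKHOLM 1.0",
              paste(formatC(names(rows), width = -10), rows), "//"),
            ".sto")
}

writeClustalAln <- function(rows = alnRows()) {
  pad <- formatC(names(rows), width = -16)
  writeTemp(c("CLUSTAL multiple sequence alignment", "", "",
              paste0(pad, rows), strrep(" ", 16 + nchar(rows[[1L]]))),
            ".aln")
}
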