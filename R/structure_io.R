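# Minimal reader for the fixed-width PDB coordinate format (ATOM records,
# C-alpha extraction only). No R cheminformatics/structure package ships a PDB
# parser in this package's dependency set, and the needs here are narrow: one
# chain, one C-alpha per residue, residue order preserved.

AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
              MSE = "M", SEC = "U", PYL = "O")

#' Extract one chain's sequence and C-alpha trace from a PDB file
#'
#' Reads fixed-width `ATOM` records for the requested chain, returning the
#' one-letter sequence and one C-alpha coordinate per residue in residue
#' order. Residues lacking a C-alpha atom are dropped with a warning;
#' alternate locations other than `' '`/`'A'` are ignored; parsing stops at
#' the first `ENDMDL` so only the first model of multi-model files is used.
#'
#' @param path Path to a PDB-format file.
#' @param chain_id Single chain identifier (column 22 of ATOM records).
#' @return A list with `sequence` (character scalar) and `coords`
#'   (numeric `L x 3` matrix, Angstroms).
#' @export
parse_structure_chain <- function(path, chain_id) {
  lines <- readLines(path, warn = FALSE)
  end <- grep("^ENDMDL", lines)
  if (length(end) > 0L) lines <- lines[seq_len(end[1L] - 1L)]
  atoms <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (length(atoms) == 0L) stop("parse_structure_chain: no ATOM records in file")
  chains <- substr(atoms, 22L, 22L)
  if (!chain_id %in% chains) {
    stop(sprintf("parse_structure_chain: chain '%s' not found; available chains: %s",
                 chain_id, paste(sort(unique(chains)), collapse = ", ")))
  }
  atoms <- atoms[chains == chain_id]
  res_key <- paste0(substr(atoms, 23L, 26L), substr(atoms, 27L, 27L))
  res_order <- unique(res_key)
  atom_name <- trimws(substr(atoms, 13L, 16L))
  alt <- substr(atoms, 17L, 17L)
  res_name <- trimws(substr(atoms, 18L, 20L))

  seq_chars <- character(0)
  coords <- matrix(numeric(0), 0L, 3L)
  dropped <- character(0)
  for (rk in res_order) {
    rows <- which(res_key == rk)
    ca <- rows[atom_name[rows] == "CA" & alt[rows] %in% c(" ", "A")]
    if (length(ca) == 0L) {
      dropped <- c(dropped, trimws(rk))
      next
    }
    ca <- ca[1L]
    aa <- AA3_TO_1[res_name[ca]]
    if (is.na(aa)) aa <- "X"
    seq_chars <- c(seq_chars, aa)
    coords <- rbind(coords, as.numeric(c(substr(atoms[ca], 31L, 38L),
                                         substr(atoms[ca], 39L, 46L),
                                         substr(atoms[ca], 47L, 54L))))
  }
  if (length(dropped) > 0L) {
    warning(sprintf("parse_structure_chain: dropped %d residue(s) lacking a C-alpha (%s)",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (length(seq_chars) == 0L) {
    stop(sprintf("parse_structure_chain: chain '%s' has no C-alpha atoms", chain_id))
  }
  dimnames(coords) <- NULL
  list(sequence = paste(seq_chars, collapse = ""), coords = coords)
}

# Writer used by tests/examples to build tiny synthetic PDB fixtures in code.
write_pdb_chain <- function(path, sequence, coords, chain_id = "A",
                            skip_ca = integer(0), append = FALSE) {
  aa1to3 <- stats::setNames(names(AA3_TO_1)[1:20], AA3_TO_1[1:20])
  lines <- character(0)
  serial <- 1L
  for (i in seq_len(nchar(sequence))) {
    res3 <- aa1to3[substr(sequence, i, i)]
    if (is.na(res3)) res3 <- "UNK"
    # N atom so that a residue record exists even when its CA is skipped
    lines <- c(lines, sprintf(
      "ATOM  %5d  N   %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
      serial, res3, chain_id, i, coords[i, 1] + 1, coords[i, 2], coords[i, 3]))
    serial <- serial + 1L
    if (!(i %in% skip_ca)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, res3, chain_id, i, coords[i, 1], coords[i, 2], coords[i, 3]))
      serial <- serial + 1L
    }
  }
  if (append && file.exists(path)) {
    existing <- readLines(path, warn = FALSE)
    existing <- existing[existing != "END"]
    lines <- c(existing, lines)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
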