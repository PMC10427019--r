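# PDB coordinate I/O via bio3d, with the spreading-amplitude convention
# applied on read: unit amplitude for heavy atoms, zero for hydrogens.

#' Read atomic coordinates from a PDB file
#'
#' Parses ATOM/HETATM records and assigns spreading amplitudes by element:
#' hydrogens get amplitude 0, every other element amplitude 1 (scattering
#' amplitudes are approximated by unity for heavy atoms; hydrogens
#' contribute negligibly to cryo-EM densities).  Coordinates are in
#' Angstrom.
#'
#' @param path path to a PDB file.
#' @return An [atom_set()] with element labels.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read structure: no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    return(atom_set(matrix(numeric(0), 0, 3), numeric(0),
                    labels = character(0)))
  }
  pos <- as.matrix(at[, c("x", "y", "z")])
  if (any(!is.finite(pos))) {
    bad <- which(!stats::complete.cases(pos))[1]
    stop("PDB parse error: non-finite coordinates at atom record ", bad)
  }
  ele <- at$elesy
  missing_ele <- is.na(ele) | !nzchar(trimws(as.character(ele)))
  if (any(missing_ele)) {
    guessed <- suppressWarnings(bio3d::atom2ele(pdb))
    ele[missing_ele] <- guessed[missing_ele]
  }
  ele <- toupper(trimws(as.character(ele)))
  amps <- ifelse(ele == "H" | ele == "D", 0, 1)
  atom_set(pos, amplitudes = amps, labels = ele)
}

#' Write an atom set to a PDB file
#'
#' Atoms are written as CA pseudo-atoms of sequential residues unless
#' element labels are present.  Intended for toy models and fixtures, not
#' full-featured PDB export.
#'
#' @param atoms an [atom_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  if (!inherits(atoms, "atom_set")) stop("expected an 'atom_set' object")
  n <- n_atoms(atoms)
  ele <- atoms$labels
  if (is.null(ele)) ele <- rep("C", n)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(atoms$positions)),
                   resno = seq_len(n),
                   resid = rep("GLY", n),
                   elety = rep("CA", n),
                   elesy = ele)
  invisible(path)
}
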