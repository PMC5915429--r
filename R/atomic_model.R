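#' Atomic model container
#'
#' A light container for atom records used by the map simulator and the
#' evaluation routines: one row per atom with element, residue numbering and
#' physical coordinates in Angstrom.
#'
#' @param atoms data frame with columns `element`, `resno`, `resid`, `chain`,
#'   `x`, `y`, `z`.
#' @param ca_only logical; `TRUE` when the model is a C-alpha trace.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, ca_only = all(atoms$element == "CA")) {
  need <- c("element", "resno", "resid", "chain", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (!all(is.finite(atoms$x + atoms$y + atoms$z)))
    stop("atom positions must be finite")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(r)) stop("residue numbers must be non-decreasing in chain ", ch)
  }
  structure(list(atoms = atoms, ca_only = isTRUE(ca_only)),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat("atomic_model:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues",
      if (x$ca_only) "(CA-only)" else "", "\n")
  invisible(x)
}

model_coords <- function(model, ca_only = FALSE) {
  at <- model$atoms
  if (ca_only) at <- at[at$element == "CA", , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

ca_table <- function(model) {
  at <- model$atoms
  at[at$element == "CA", c("resno", "resid", "x", "y", "z"), drop = FALSE]
}

#' Read an atomic model from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] that converts ATOM records into an
#' [atomic_model()]. Hydrogens are dropped (the simulator uses heavy atoms).
#'
#' @param path path to a PDB file.
#' @param ca_only keep only C-alpha atoms.
#' @return An [atomic_model()].
#' @export
read_model_pdb <- function(path, ca_only = FALSE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (ca_only) at <- at[at$elety == "CA", , drop = FALSE]
  at <- at[!grepl("^H", trimws(at$elety)), , drop = FALSE]
  atomic_model(data.frame(element = trimws(at$elety), resno = at$resno,
                          resid = at$resid, chain = at$chain,
                          x = at$x, y = at$y, z = at$z,
                          stringsAsFactors = FALSE))
}

#' Read a protein sequence from a FASTA file
#'
#' @param path path to a FASTA file (first record is used).
#' @return Single-character amino-acid string.
#' @export
read_sequence <- function(path) {
  fa <- bio3d::read.fasta(path)
  paste(toupper(fa$ali[1, fa$ali[1, ] != "-"]), collapse = "")
}

# write a CA-only model as PDB; b = per-residue B-factor column
write_ca_pdb <- function(coords, resno, resid, path, b = NULL, remarks = NULL) {
  n <- nrow(coords)
  if (is.null(b)) b <- rep(0, n)
  lines <- character(0)
  if (!is.null(remarks)) lines <- sprintf("REMARK   3 %s", remarks)
  lines <- c(lines, sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), resid, resno, coords[, 1], coords[, 2], coords[, 3],
    1.0, b))
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}
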