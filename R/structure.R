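## Structure container and PDB input/output.
##
## A Structure is a light S3 object: an atom table plus an n x 3 coordinate
## matrix.  Internal atom ids are 0-based and dense; author residue numbering
## (e.g. 69-204 for the KH-QUA2 fragment) is carried as data and never used
## as an array index.

## atomic masses (amu) for the elements found in biomolecular PDB files
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.973762, S = 32.06, F = 18.998, CL = 35.45,
                  BR = 79.904, I = 126.904, "NA" = 22.990, MG = 24.305,
                  K = 39.098, CA = 40.078, MN = 54.938, FE = 55.845,
                  ZN = 65.38, SE = 78.971)

## infer the element from a PDB atom name: strip digits/primes, take the
## leading letter(s); two-letter biomolecular cases are rare enough that
## the first letter is correct for standard residues (CA = carbon alpha).
element_from_name <- function(atom_name) {
  s <- gsub("[0-9'*\"]", "", trimws(atom_name))
  toupper(substr(s, 1, 1))
}

element_mass <- function(element) {
  m <- ELEMENT_MASS[toupper(element)]
  if (anyNA(m))
    stop("no mass for element: ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Construct a Structure object
#'
#' @param atoms data.frame with columns `atom_name`, `residue_seq`,
#'   `residue_name`, `chain_id` and optionally `element`, `bfactor`,
#'   `occupancy`, `mass`.  Missing optional columns are filled with
#'   defaults (element inferred from the atom name, bfactor 0, occupancy 1,
#'   mass from a standard element table).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return An object of class `"Structure"` with fields `atoms`
#'   (including a 0-based `atom_id` column) and `xyz`.
#' @export
new_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L || nrow(xyz) != nrow(atoms))
    stop("xyz must be an n x 3 matrix matching the atom table")
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("atom_name", "residue_seq", "residue_name", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$element) || any(is.na(atoms$element)) ||
      any(!nzchar(atoms$element))) {
    ele <- element_from_name(atoms$atom_name)
    if (is.null(atoms$element)) atoms$element <- ele
    else {
      bad <- is.na(atoms$element) | !nzchar(atoms$element)
      atoms$element[bad] <- ele[bad]
    }
  }
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atom masses must be positive")
  atoms$atom_id <- seq_len(nrow(atoms)) - 1L
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue_seq, atom_name): ",
         key[duplicated(key)][1L])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "Structure")
}

#' Number of atoms in a Structure or Trajectory topology
#' @param x Structure or Trajectory.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure: %d atoms, %d residues, chains %s\n",
              nrow(a), length(unique(paste(a$chain_id, a$residue_seq))),
              paste(unique(a$chain_id), collapse = ",")))
  invisible(x)
}

## Validate ATOM/HETATM coordinate fields before handing the file to the
## parser, so malformed records are reported with their line number.
check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed %s record at line %d: too short",
                   trimws(rec[i]), i))
    co <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                        substr(ln, 39, 46),
                                        substr(ln, 47, 54))))
    if (any(is.na(co)))
      stop(sprintf("malformed %s record at line %d: bad coordinate field",
                   trimws(rec[i]), i))
  }
  invisible(TRUE)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) and returns one model as a
#' [new_structure()] object.  Alternate-location indicators are resolved by
#' keeping the highest-occupancy copy of each (chain, residue, atom name),
#' first on ties.  Missing B-factor/occupancy default to 0 and 1; the
#' element is inferred from the atom name when the element column is absent.
#'
#' @param path PDB file path.
#' @param model 1-based model number to extract (for multi-MODEL files).
#' @return A `Structure`.
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_pdb_records(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  nmod <- nrow(pdb$xyz)
  if (model < 1L || model > nmod)
    stop(sprintf("model %d not present (file has %d model(s))", model, nmod))
  xyz_all <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)

  ## alt-loc resolution: keep highest occupancy, ties -> first occurrence
  occ <- ifelse(is.na(a$o), 1, a$o)
  key <- paste(a$chain, a$resno, a$elety)
  keep <- rep(TRUE, nrow(a))
  if (anyDuplicated(key)) {
    ord <- order(key, -occ, seq_len(nrow(a)))
    first <- !duplicated(key[ord])
    keep <- logical(nrow(a))
    keep[ord[first]] <- TRUE
  }
  a <- a[keep, , drop = FALSE]
  xyz_all <- xyz_all[keep, , drop = FALSE]

  chain <- ifelse(is.na(a$chain), " ", a$chain)
  ele <- a$elesy
  if (is.null(ele)) ele <- NA_character_
  ele <- trimws(ifelse(is.na(ele) | !nzchar(trimws(ele)),
                       element_from_name(a$elety), ele))
  atoms <- data.frame(
    atom_name = a$elety, residue_seq = a$resno, residue_name = a$resid,
    chain_id = chain, element = ele,
    bfactor = ifelse(is.na(a$b), 0, a$b),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    stringsAsFactors = FALSE)
  new_structure(atoms, xyz_all)
}

#' Write a structure to a PDB file
#'
#' @param structure A `Structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$xyz)),
                   resno = a$residue_seq, resid = a$residue_name,
                   eleno = a$atom_id + 1L, elety = a$atom_name,
                   chain = a$chain_id, o = a$occupancy, b = a$bfactor,
                   elesy = a$element)
  invisible(path)
}
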