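#' Parse a PDB-format text into a molecular structure
#'
#' Reads `ATOM` and `HETATM` records from PDB-format text (fixed-column
#' dialect: x, y, z in columns 31--54, element symbol in columns 77--78) and
#' returns the ordered atom table downstream feature extraction works from.
#' Only the first `MODEL` is kept and alternate locations other than `' '`
#' or `'A'` are dropped, the usual single-conformer convention. When the
#' element columns are blank the element falls back to the first alphabetic
#' character of the atom name.
#'
#' @param text Character scalar (or vector of lines) holding PDB-format text.
#' @param kind Either `"protein"` or `"ligand"`; tags how coordinates are
#'   extracted later (alpha carbons vs. all atoms).
#' @param id Identifier used in error messages and stored on the structure.
#' @return An object of class `mol_structure`: a list with elements `id`,
#'   `kind` and `atoms` (a data frame with columns `serial`, `name`,
#'   `element`, `residue_index`, `x`, `y`, `z`, one row per atom in file
#'   order).
#' @seealso [read_pdb()], [alpha_carbon_coordinates()], [all_atom_coordinates()]
#' @examples
#' txt <- paste(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000           C",
#'   "ATOM      2  CA  ALA A   2       3.800   0.000   0.000           C",
#'   sep = "\n")
#' s <- parse_pdb(txt, "protein", id = "toy")
#' nrow(s$atoms)
#' @export
parse_pdb <- function(text, kind = c("protein", "ligand"), id = "structure") {
  kind <- match.arg(kind)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  # honour only the first MODEL when several are present
  end <- grep("^ENDMDL", lines)
  if (length(end)) lines <- lines[seq_len(end[1] - 1L)]
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec)) {
    altloc <- substr(rec, 17, 17)
    rec <- rec[altloc %in% c(" ", "A", "")]
  }
  if (!length(rec)) {
    stop("no parseable ATOM/HETATM records in input '", id, "'", call. = FALSE)
  }
  field <- function(from, to) trimws(substr(rec, from, to))
  x <- suppressWarnings(as.numeric(field(31, 38)))
  y <- suppressWarnings(as.numeric(field(39, 46)))
  z <- suppressWarnings(as.numeric(field(47, 54)))
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  if (!any(ok)) {
    stop("no ATOM/HETATM records with parseable coordinates in input '",
         id, "'", call. = FALSE)
  }
  name <- field(13, 16)[ok]
  element <- toupper(field(77, 78)[ok])
  fallback <- toupper(substr(gsub("[^A-Za-z].*$", "", sub("^[^A-Za-z]*", "", name)), 1, 1))
  element[element == ""] <- fallback[element == ""]
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(field(7, 11)))[ok],
    name = name,
    element = element,
    residue_index = suppressWarnings(as.integer(field(23, 26)))[ok],
    x = x[ok], y = y[ok], z = z[ok],
    stringsAsFactors = FALSE
  )
  structure(list(id = id, kind = kind, atoms = atoms), class = "mol_structure")
}

#' Read a PDB file from disk
#'
#' @param path Path to a PDB-format file.
#' @inheritParams parse_pdb
#' @return A `mol_structure`; see [parse_pdb()].
#' @export
read_pdb <- function(path, kind = c("protein", "ligand"),
                     id = sub("\\.[^.]*$", "", basename(path))) {
  parse_pdb(readLines(path, warn = FALSE), kind = match.arg(kind), id = id)
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("<mol_structure '%s'> %s, %d atoms (%d CA)\n",
              x$id, x$kind, nrow(x$atoms), sum(x$atoms$name == "CA")))
  invisible(x)
}

#' Alpha-carbon coordinates of a protein structure
#'
#' Returns the coordinates of atoms named `CA` in file order; these are the
#' per-residue representative points from which the protein distance-matrix
#' image is built.
#'
#' @param s A `mol_structure` of kind `"protein"`.
#' @return An n x 3 numeric matrix, one row per alpha carbon.
#' @export
alpha_carbon_coordinates <- function(s) {
  stopifnot(inherits(s, "mol_structure"))
  if (s$kind != "protein") {
    stop("alpha_carbon_coordinates() expects a protein structure", call. = FALSE)
  }
  ca <- s$atoms[s$atoms$name == "CA", , drop = FALSE]
  if (!nrow(ca)) {
    stop("structure '", s$id, "' has no alpha-carbon (CA) atoms", call. = FALSE)
  }
  as.matrix(ca[, c("x", "y", "z")])
}

#' All-atom coordinates of a structure
#'
#' Ligand images use every atom, since small molecules have too few atoms for
#' an alpha-carbon reduction to be meaningful.
#'
#' @param s A `mol_structure`.
#' @return An n x 3 numeric matrix, one row per atom in file order.
#' @export
all_atom_coordinates <- function(s) {
  stopifnot(inherits(s, "mol_structure"))
  if (!nrow(s$atoms)) stop("structure '", s$id, "' has no atoms", call. = FALSE)
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Structure coordinates under the standard extraction policy
#'
#' Proteins contribute their alpha carbons, ligands all their atoms.
#'
#' @param s A `mol_structure`.
#' @return An n x 3 numeric matrix.
#' @export
structure_coordinates <- function(s) {
  if (s$kind == "protein") alpha_carbon_coordinates(s) else all_atom_coordinates(s)
}
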