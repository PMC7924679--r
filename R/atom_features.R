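# Standard atomic masses (IUPAC 2021 conventional values, u) for elements
# commonly seen in protein and small-molecule PDB files.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, MG = 24.305, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38,
  MO = 95.95, CD = 112.414, W = 183.84, B = 10.81, SI = 28.085
)

#' Atom-bond feature configuration
#'
#' @param vocabulary Ordered character vector of element symbols that define
#'   the composition and bond-pair feature slots. The default `[C, N, O, S]`
#'   covers the heavy atoms of the twenty standard amino acids and keeps the
#'   feature length fixed across datasets.
#' @param bond_threshold Distance (Angstrom) at or under which two vocabulary
#'   atoms are counted as bonded; 2.0 A covers covalent bonds between heavy
#'   atoms.
#' @param mass_prefix_length Number of leading atoms whose atomic masses are
#'   used as sequential features (zero-padded when the structure is shorter).
#' @return A list of class `atom_bond_config`.
#' @export
atom_bond_config <- function(vocabulary = c("C", "N", "O", "S"),
                             bond_threshold = 2.0,
                             mass_prefix_length = 100L) {
  vocabulary <- toupper(vocabulary)
  stopifnot(!anyDuplicated(vocabulary), length(vocabulary) >= 1L,
            bond_threshold > 0, mass_prefix_length >= 1L)
  structure(list(vocabulary = vocabulary,
                 bond_threshold = bond_threshold,
                 mass_prefix_length = as.integer(mass_prefix_length)),
            class = "atom_bond_config")
}

#' Scan structures for the element vocabulary they use
#'
#' Dataset-scan mode: returns the sorted set of element symbols occurring in
#' the given structures, for building an [atom_bond_config()] whose feature
#' length matches a particular dataset.
#'
#' @param structures A list of `mol_structure` objects.
#' @return Character vector of element symbols, sorted.
#' @export
scan_element_vocabulary <- function(structures) {
  sort(unique(toupper(unlist(lapply(structures, function(s) s$atoms$element)))))
}

#' Element composition percentages
#'
#' Percentage of the structure's atoms carrying each vocabulary element.
#' Atoms whose element is outside the vocabulary still count in the
#' denominator, so the vector sums to at most 100.
#'
#' @param s A `mol_structure`.
#' @param vocabulary Ordered element symbols.
#' @return Numeric vector of length `length(vocabulary)` with values in
#'   \[0, 100\].
#' @export
element_composition <- function(s, vocabulary = c("C", "N", "O", "S")) {
  stopifnot(inherits(s, "mol_structure"))
  n <- nrow(s$atoms)
  if (!n) stop("structure '", s$id, "' has no atoms", call. = FALSE)
  counts <- vapply(toupper(vocabulary),
                   function(e) sum(s$atoms$element == e), numeric(1))
  out <- 100 * counts / n
  names(out) <- paste0("comp_", vocabulary)
  out
}

#' Atomic-mass sequence of the first n atoms
#'
#' Standard atomic masses of the structure's atoms in file order, truncated
#' or zero-padded to length `n`.
#'
#' @param s A `mol_structure`.
#' @param n Length of the returned vector.
#' @return Numeric vector of length `n`.
#' @export
mass_sequence <- function(s, n = 100L) {
  stopifnot(inherits(s, "mol_structure"), n >= 1L)
  el <- toupper(s$atoms$element)
  el <- el[seq_len(min(length(el), n))]
  unknown <- setdiff(el, names(.atomic_masses))
  if (length(unknown)) {
    stop("no atomic mass known for element symbol(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- numeric(n)
  # [[ ]]-style name lookup; unname to keep a clean vector
  out[seq_along(el)] <- unname(.atomic_masses[el])
  names(out) <- sprintf("mass_%03d", seq_len(n))
  out
}

# Unordered vocabulary pairs (e, f) with e <= f in vocabulary order.
.vocab_pairs <- function(vocabulary) {
  k <- length(vocabulary)
  pairs <- list()
  for (i in seq_len(k)) for (j in i:k) {
    pairs[[length(pairs) + 1L]] <- c(vocabulary[i], vocabulary[j])
  }
  pairs
}

#' Bonded-pair percentages under a distance threshold
#'
#' Two atoms are counted as bonded when both elements are in the vocabulary
#' and their Euclidean distance is at or below `cfg$bond_threshold`. The
#' feature is the percentage of all such bonds falling on each unordered
#' element pair, in vocabulary order; a structure with no bonds yields an
#' all-zero vector.
#'
#' @param s A `mol_structure`.
#' @param cfg An [atom_bond_config()].
#' @return Numeric vector of length `k (k + 1) / 2` for a k-element
#'   vocabulary, values in \[0, 100\].
#' @export
bond_pair_percentages <- function(s, cfg = atom_bond_config()) {
  stopifnot(inherits(s, "mol_structure"), inherits(cfg, "atom_bond_config"))
  if (!nrow(s$atoms)) stop("structure '", s$id, "' has no atoms", call. = FALSE)
  v <- cfg$vocabulary
  pairs <- .vocab_pairs(v)
  counts <- stats::setNames(numeric(length(pairs)),
                            vapply(pairs, function(p) paste0("bond_", p[1], p[2]),
                                   character(1)))
  keep <- s$atoms$element %in% v
  el <- s$atoms$element[keep]
  n <- length(el)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(s$atoms[keep, c("x", "y", "z")]))
    hit <- which(upper.tri(d) & d <= cfg$bond_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      r1 <- match(el[hit[, 1]], v)
      r2 <- match(el[hit[, 2]], v)
      lo <- pmin(r1, r2)
      hi <- pmax(r1, r2)
      key <- paste0("bond_", v[lo], v[hi])
      tab <- table(key)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  total <- sum(counts)
  if (total > 0) counts <- 100 * counts / total
  counts
}

#' Atom-bond feature vector
#'
#' Concatenation of [element_composition()], [mass_sequence()] and
#' [bond_pair_percentages()]; with the default configuration the vector is
#' 4 + 100 + 10 = 114 long. All parts depend only on elements and pairwise
#' distances, so the features are invariant under rigid motion.
#'
#' @param s A `mol_structure`.
#' @param cfg An [atom_bond_config()].
#' @return Named numeric vector.
#' @export
atom_bond_features <- function(s, cfg = atom_bond_config()) {
  c(element_composition(s, cfg$vocabulary),
    mass_sequence(s, cfg$mass_prefix_length),
    bond_pair_percentages(s, cfg))
}
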