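#' Extract one feature group from a structure
#'
#' The five groups are:
#' \describe{
#'   \item{A}{256-bin LBP histogram of the distance-matrix image.}
#'   \item{B}{256-bin LBP histogram of the Gabor-filtered image.}
#'   \item{C}{atom-bond features (composition, mass sequence, bond pairs);
#'     image-free, so `scaled` is ignored.}
#'   \item{D}{59-bin uniform-LBP histogram of the SRM-filtered image
#'     (always on the 128 x 128 rescaled image).}
#'   \item{E}{59-bin uniform-LBP histogram of the NBS-filtered image
#'     (always on the 128 x 128 rescaled image).}
#' }
#'
#' @param s A `mol_structure`.
#' @param group One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param scaled Use the 128 x 128 rescaled image for groups A/B? Groups D
#'   and E always use the rescaled image; group C ignores this.
#' @param cfg An [atom_bond_config()] (group C only).
#' @param gabor A [gabor_params()] object (group B only).
#' @param side Side length of the rescaled image.
#' @return A named numeric feature vector; names are prefixed with the group
#'   letter and the scaling provenance (`s`/`n`).
#' @export
extract_group <- function(s, group = c("A", "B", "C", "D", "E"),
                          scaled = FALSE, cfg = atom_bond_config(),
                          gabor = gabor_params(), side = 128L) {
  group <- match.arg(group)
  if (group == "C") {
    v <- atom_bond_features(s, cfg)
    names(v) <- paste0("C_", names(v))
    return(v)
  }
  use_scaled <- scaled || group %in% c("D", "E")
  img <- structure_image(s, scaled = use_scaled, side = side)
  v <- switch(group,
    A = histogram_256(lbp_transform(img)),
    B = histogram_256(lbp_transform(gabor_filter_image(img, gabor))),
    D = uniform_histogram_59(lbp_transform(srm_filter(img))),
    E = uniform_histogram_59(lbp_transform(nbs_filter(img)))
  )
  names(v) <- paste0(group, "_", if (use_scaled) "s" else "n", "_", names(v))
  stats::setNames(as.numeric(v), names(v))
}

#' Feature-group specification
#'
#' @param groups Character vector of group letters in extraction order.
#' @param scaled Logical vector (recycled) saying whether each image-based
#'   group uses the rescaled image. The default policy is the hybrid one:
#'   A and B from the non-scaled image, D and E from the scaled image, C
#'   image-free.
#' @return A data frame with columns `group` and `scaled`.
#' @export
feature_spec <- function(groups = c("A", "B", "C", "D", "E"),
                         scaled = NULL) {
  groups <- match.arg(toupper(groups), c("A", "B", "C", "D", "E"),
                      several.ok = TRUE)
  if (is.null(scaled)) scaled <- groups %in% c("D", "E")
  data.frame(group = groups, scaled = rep_len(scaled, length(groups)),
             stringsAsFactors = FALSE)
}

#' Extract a multi-group feature vector from one structure
#'
#' Concatenates the groups of `spec` in order. With the default hybrid
#' specification (A, B non-scaled; C; D, E scaled) and the default atom-bond
#' configuration the vector is 256 + 256 + 114 + 59 + 59 = 744 long.
#'
#' @param s A `mol_structure`.
#' @param spec A [feature_spec()] data frame.
#' @inheritParams extract_group
#' @return A named numeric vector whose length depends only on `spec` and
#'   the configuration, never on the structure.
#' @export
extract_features <- function(s, spec = feature_spec(),
                             cfg = atom_bond_config(),
                             gabor = gabor_params(), side = 128L) {
  if (!nrow(spec)) stop("empty feature specification", call. = FALSE)
  parts <- lapply(seq_len(nrow(spec)), function(i) {
    extract_group(s, spec$group[i], scaled = spec$scaled[i],
                  cfg = cfg, gabor = gabor, side = side)
  })
  out <- unlist(parts)
  names(out) <- unlist(lapply(parts, names))
  out
}

#' Hybrid feature vector of a structure
#'
#' The full five-group descriptor: LBP and Gabor-LBP histograms from the
#' non-scaled image, atom-bond features, and SRM/NBS uniform-LBP histograms
#' from the 128 x 128 rescaled image.
#'
#' @inheritParams extract_features
#' @return A named numeric vector (length 744 with defaults).
#' @export
hybrid_features <- function(s, cfg = atom_bond_config(),
                            gabor = gabor_params(), side = 128L) {
  extract_features(s, feature_spec(), cfg = cfg, gabor = gabor, side = side)
}

#' Concatenate protein and ligand features into a pair vector
#'
#' @param p Feature vector of the protein.
#' @param l Feature vector of the ligand.
#' @return Named numeric vector: protein block (names prefixed `P.`) then
#'   ligand block (prefixed `L.`).
#' @export
pair_features <- function(p, l) {
  if (!length(p) || !length(l)) {
    stop("pair_features needs non-empty protein and ligand vectors",
         call. = FALSE)
  }
  out <- c(p, l)
  names(out) <- c(paste0("P.", names(p)), paste0("L.", names(l)))
  out
}

#' Batch-extract features for a list of structures
#'
#' @param structures A named list of `mol_structure` objects (names become
#'   row names; unnamed lists use each structure's `id`).
#' @inheritParams extract_features
#' @return A numeric matrix, one row per structure.
#' @export
extract_feature_matrix <- function(structures, spec = feature_spec(),
                                   cfg = atom_bond_config(),
                                   gabor = gabor_params(), side = 128L) {
  rows <- lapply(structures, extract_features, spec = spec, cfg = cfg,
                 gabor = gabor, side = side)
  m <- do.call(rbind, rows)
  ids <- names(structures)
  if (is.null(ids)) ids <- vapply(structures, function(s) s$id, character(1))
  rownames(m) <- ids
  m
}

#' Write a feature matrix as a TSV file
#'
#' One row per structure with an `id` column followed by the named feature
#' columns.
#'
#' @param m Feature matrix from [extract_feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
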