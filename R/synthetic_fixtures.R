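# Fixed-column PDB line for one atom.
format_pdb_atom <- function(record, serial, name, resname, chain, resseq,
                            x, y, z, element) {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resname, chain, resseq, x, y, z, 1, 0, element)
}

#' Generate a synthetic protein chain as PDB text
#'
#' Builds an alpha-carbon trace along either an ideal alpha helix (radius
#' 2.3 A, rise 1.5 A and 100 degree turn per residue, giving the canonical
#' ~3.8 A consecutive-CA spacing) or a fixed-step random walk, adds
#' Gaussian coordinate noise, and attaches backbone N and O decoy atoms to
#' each residue so atom-composition features have something to count. The
#' written file and the returned coordinate log are identical up to the
#' 3-decimal PDB coordinate precision.
#'
#' @param n_residues Number of residues (>= 2).
#' @param geometry `"helix"` or `"random_walk"`.
#' @param step Target consecutive-CA distance for the random walk, Angstrom.
#' @param rise,turn,radius Helix rise (A/residue), turn (degrees/residue)
#'   and radius (A).
#' @param noise_sigma Standard deviation of isotropic coordinate noise, A.
#' @param seed Integer seed; identical seeds give identical files.
#' @param id Structure identifier.
#' @return A list with `pdb` (the PDB text), `ca_coords` (the n x 3 CA
#'   coordinate log as written), `id`, and `ideal_step` (the noise-free
#'   consecutive-CA distance of the recipe).
#' @export
synthetic_protein <- function(n_residues, geometry = c("helix", "random_walk"),
                              step = 3.8, rise = 1.5, turn = 100,
                              radius = 2.3, noise_sigma = 0.1, seed = 1L,
                              id = "synthetic_protein") {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 2)
  with_seed(seed, {
    if (geometry == "helix") {
      ang <- (seq_len(n_residues) - 1) * turn * pi / 180
      ca <- cbind(radius * cos(ang), radius * sin(ang),
                  (seq_len(n_residues) - 1) * rise)
      ideal_step <- sqrt((2 * radius * sin(turn * pi / 360))^2 + rise^2)
    } else {
      dirs <- matrix(stats::rnorm(3 * (n_residues - 1)), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      ca <- rbind(0, apply(dirs * step, 2, cumsum))
      ideal_step <- step
    }
    ca <- ca + matrix(stats::rnorm(3 * n_residues, sd = noise_sigma), ncol = 3)
    list(pdb = protein_pdb_text(ca), ca_coords = round(ca, 3), id = id,
         ideal_step = ideal_step)
  })
}

# PDB text for a CA trace: each residue gets a decoy backbone N (~1.46 A)
# and O (~1.23 A) around its CA so atom-composition features have several
# element kinds to count. Residues listed in `extra_elements` (a character
# vector indexed by residue, NA = none) additionally carry `extra_per_res`
# side-chain-like decoy atoms of that element in a ~1.8 A shell, emulating
# family-specific residue content. Uses the current RNG stream for decoy
# directions.
protein_pdb_text <- function(ca, extra_elements = NULL, extra_per_res = 4L) {
  n_residues <- nrow(ca)
  unit <- function(n) {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u / sqrt(rowSums(u^2))
  }
  off_n <- 1.46 * unit(n_residues)
  off_o <- 1.23 * unit(n_residues)
  lines <- character(0)
  serial <- 0L
  add <- function(name, res, pos, el) {
    serial <<- serial + 1L
    lines[[length(lines) + 1L]] <<- format_pdb_atom(
      "ATOM", serial, name, "ALA", "A", res, pos[1], pos[2], pos[3], el)
  }
  for (i in seq_len(n_residues)) {
    add("N", i, ca[i, ] + off_n[i, ], "N")
    add("CA", i, ca[i, ], "C")
    add("O", i, ca[i, ] + off_o[i, ], "O")
    el <- if (!is.null(extra_elements)) extra_elements[i] else NA
    if (!is.na(el)) {
      off_x <- 1.8 * unit(extra_per_res)
      for (j in seq_len(extra_per_res)) {
        add(paste0(el, "D", j), i, ca[i, ] + off_x[j, ], el)
      }
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

#' Generate a synthetic small-molecule ligand as PDB text
#'
#' Atoms are placed uniformly in a compact sphere and written as HETATM
#' records. `n_atoms = 1` is supported deliberately: a single-atom ligand
#' yields a 1 x 1 distance image and exercises the downstream exclusion
#' path.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param spread Radius of the placement sphere, Angstrom.
#' @param elements Element pool sampled per atom.
#' @param seed Integer seed.
#' @param id Structure identifier.
#' @return A list with `pdb`, `coords` (as written) and `id`.
#' @export
synthetic_ligand <- function(n_atoms, spread = 1.5,
                             elements = c("C", "N", "O", "S"), seed = 1L,
                             id = "synthetic_ligand") {
  stopifnot(n_atoms >= 1)
  with_seed(seed, {
    pts <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
    r <- spread * stats::runif(n_atoms)^(1 / 3)
    pts <- pts / sqrt(rowSums(pts^2)) * r
    el <- sample(elements, n_atoms, replace = TRUE)
    lines <- vapply(seq_len(n_atoms), function(i) {
      format_pdb_atom("HETATM", i, paste0(el[i], i), "LIG", "A", 1,
                      pts[i, 1], pts[i, 2], pts[i, 3], el[i])
    }, character(1))
    list(pdb = paste(c(lines, "END"), collapse = "\n"),
         coords = round(pts, 3), id = id)
  })
}

#' Generate a planted-group protein-ligand binding dataset
#'
#' Builds `n_groups` exchangeable families of synthetic structures sharing
#' a common geometry (a helix for proteins, an extended chain for ligands,
#' plus per-member Gaussian coordinate noise) and differing chemically:
#' each group leans towards its own dominant element from a near-equal-mass
#' pool (B, C, N, O, F), carried by the ligand atoms and by
#' family-specific decoration atoms on the protein residues past the
#' 100-atom mass prefix. Because every group has a distinct dominant
#' element, all group pairs are (near-)equidistant in the atom-composition
#' and bond-pair feature blocks -- the planted structure the similarity
#' predictor assumes (similar proteins bind similar ligands), with no
#' group pair systematically closer than another. `separation` blends the
#' per-group element bias from none (0: all groups drawn from one common
#' distribution, no signal) to pure (1: clear separation).
#'
#' Positive pairs are exactly the within-group pairs: the training list
#' pairs each protein one-to-one with its same-index ligand, and
#' evaluation pairs are held-out within-group pairs (true positives) plus
#' cross-group pairs (true negatives).
#'
#' @param n_groups Number of groups (>= 2).
#' @param proteins_per_group,ligands_per_group Structures per group.
#' @param separation Group element-bias weight in \[0, 1\].
#' @param noise Coordinate noise sigma added to each member structure, A.
#' @param n_residues Residues per synthetic protein (128 by default so the
#'   protein image needs no rescaling for the scaled feature groups).
#' @param n_atoms Atoms per synthetic ligand.
#' @param decor_per_res Decoration atoms per decorated protein residue.
#' @param n_eval_pos,n_eval_neg Number of held-out evaluation pairs of each
#'   label.
#' @param seed Integer seed.
#' @return A list with `proteins` and `ligands` (named lists of
#'   `mol_structure`), `positives` (training pair data frame), `held_out`
#'   (data frame with `protein_id`, `ligand_id`, `label`), and
#'   `protein_group` / `ligand_group` (named group assignments).
#' @export
synthetic_binding_dataset <- function(n_groups = 5L, proteins_per_group = 20L,
                                      ligands_per_group = 20L, separation = 1,
                                      noise = 0.002, n_residues = 128L,
                                      n_atoms = 16L, decor_per_res = 6L,
                                      n_eval_pos = 50L,
                                      n_eval_neg = 50L, seed = 1L) {
  stopifnot(n_groups >= 2)
  # extended base shapes: their diameter (the end-to-end distance) is stable
  # under small perturbations, so the min-max intensity scale of the images
  # stays comparable across all structures of the dataset
  base_helix <- synthetic_protein(n_residues, "helix", noise_sigma = 0,
                                  seed = mix_seed(seed, 0, 0, 3))$ca_coords
  base_cluster <- with_seed(mix_seed(seed, 0, 0, 4), {
    cbind(1.4 * (seq_len(n_atoms) - 1),
          stats::rnorm(n_atoms, sd = 0.3),
          stats::rnorm(n_atoms, sd = 0.3))
  })
  # the group signal is chemical: each group leans towards its own element,
  # so membership shows up in the atom-composition and bond-pair feature
  # blocks, and (because every group has a distinct dominant element) all
  # group pairs are equally far apart there. Proteins carry the signal as
  # family-specific decoration atoms on residues past the atomic-mass
  # prefix, so their first-100-atom mass features stay family-neutral.
  el_pool <- c("B", "C", "N", "O", "F")
  base_el_probs <- rep(1 / length(el_pool), length(el_pool))
  pure <- function(g) {
    p <- numeric(length(el_pool))
    p[(g - 1L) %% length(el_pool) + 1L] <- 1
    p
  }
  decor_start <- 35L  # first decorated residue; 3 * 34 = 102 atoms before it

  proteins <- list()
  ligands <- list()
  protein_group <- integer(0)
  ligand_group <- integer(0)
  for (g in seq_len(n_groups)) {
    el_probs <- (1 - min(separation, 1)) * base_el_probs +
      min(separation, 1) * pure(g)
    for (i in seq_len(proteins_per_group)) {
      pid <- sprintf("P_g%d_%02d", g, i)
      pdb <- with_seed(mix_seed(seed, g, i, 1), {
        ca <- base_helix + matrix(stats::rnorm(3 * n_residues, sd = noise),
                                  ncol = 3)
        extra <- rep(NA_character_, n_residues)
        if (n_residues >= decor_start) {
          idx <- decor_start:n_residues
          extra[idx] <- sample(el_pool, length(idx), replace = TRUE,
                               prob = el_probs)
        }
        protein_pdb_text(ca, extra_elements = extra,
                         extra_per_res = decor_per_res)
      })
      proteins[[pid]] <- parse_pdb(pdb, "protein", id = pid)
      protein_group[pid] <- g
    }
    for (i in seq_len(ligands_per_group)) {
      lid <- sprintf("L_g%d_%02d", g, i)
      pdb <- with_seed(mix_seed(seed, g, i, 2), {
        pts <- base_cluster + matrix(stats::rnorm(3 * n_atoms, sd = noise),
                                     ncol = 3)
        el <- sample(el_pool, n_atoms, replace = TRUE, prob = el_probs)
        lines <- vapply(seq_len(n_atoms), function(a) {
          format_pdb_atom("HETATM", a, paste0(el[a], a), "LIG", "A", 1,
                          pts[a, 1], pts[a, 2], pts[a, 3], el[a])
        }, character(1))
        paste(c(lines, "END"), collapse = "\n")
      })
      ligands[[lid]] <- parse_pdb(pdb, "ligand", id = lid)
      ligand_group[lid] <- g
    }
  }

  # one-to-one training positives within each group
  n_pair <- min(proteins_per_group, ligands_per_group)
  positives <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    data.frame(protein_id = sprintf("P_g%d_%02d", g, seq_len(n_pair)),
               ligand_id = sprintf("L_g%d_%02d", g, seq_len(n_pair)),
               stringsAsFactors = FALSE)
  }))

  pos_key <- paste(positives$protein_id, positives$ligand_id, sep = "\r")
  held_out <- with_seed(seed + 1L, {
    pos <- data.frame(protein_id = character(0), ligand_id = character(0))
    while (nrow(pos) < n_eval_pos) {
      g <- sample.int(n_groups, 1)
      p <- sprintf("P_g%d_%02d", g, sample.int(proteins_per_group, 1))
      l <- sprintf("L_g%d_%02d", g, sample.int(ligands_per_group, 1))
      key <- paste(p, l, sep = "\r")
      if (key %in% c(pos_key, paste(pos$protein_id, pos$ligand_id, sep = "\r"))) next
      pos <- rbind(pos, data.frame(protein_id = p, ligand_id = l,
                                   stringsAsFactors = FALSE))
    }
    neg <- data.frame(protein_id = character(0), ligand_id = character(0))
    while (nrow(neg) < n_eval_neg) {
      gp <- sample.int(n_groups, 1)
      gl <- sample.int(n_groups, 1)
      if (gp == gl) next
      p <- sprintf("P_g%d_%02d", gp, sample.int(proteins_per_group, 1))
      l <- sprintf("L_g%d_%02d", gl, sample.int(ligands_per_group, 1))
      key <- paste(p, l, sep = "\r")
      if (key %in% paste(neg$protein_id, neg$ligand_id, sep = "\r")) next
      neg <- rbind(neg, data.frame(protein_id = p, ligand_id = l,
                                   stringsAsFactors = FALSE))
    }
    rbind(cbind(pos, label = "positive"), cbind(neg, label = "negative"))
  })

  list(proteins = proteins, ligands = ligands, positives = positives,
       held_out = held_out, protein_group = protein_group,
       ligand_group = ligand_group)
}

#' Write a synthetic binding dataset to a directory of PDB files
#'
#' One PDB file per structure plus `positives.tsv` and `held_out.tsv` truth
#' tables.
#'
#' @param dataset A [synthetic_binding_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_structs <- c(dataset$proteins, dataset$ligands)
  for (id in names(all_structs)) {
    s <- all_structs[[id]]
    rec <- ifelse(s$kind == "protein", "ATOM", "HETATM")
    lines <- vapply(seq_len(nrow(s$atoms)), function(i) {
      a <- s$atoms[i, ]
      format_pdb_atom(rec, a$serial, a$name, "ALA", "A", a$residue_index,
                      a$x, a$y, a$z, a$element)
    }, character(1))
    writeLines(c(lines, "END"), file.path(dir, paste0(id, ".pdb")))
  }
  utils::write.table(dataset$positives, file.path(dir, "positives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$held_out, file.path(dir, "held_out.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
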