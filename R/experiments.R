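#' Binding-recovery experiment on a planted-group dataset
#'
#' End-to-end run of the similarity-based binding predictor on a
#' [synthetic_binding_dataset()]: extract hybrid features for every
#' structure (with the atom-bond vocabulary scanned from the dataset),
#' generate random negative training pairs, fit [binding_model()] and
#' evaluate on the held-out pairs against the planted ground truth.
#'
#' @param separation Group separation passed to the generator.
#' @param seed Integer seed driving the generator, the negative sampling
#'   and threshold fitting.
#' @param k Neighbour count of the binding model.
#' @param negative_scheme `"random"` or `"cluster"` negative-pair
#'   undersampling for the training negatives.
#' @param ... Further arguments passed to [synthetic_binding_dataset()].
#' @return A list with `sensitivity`, `specificity` (proportions in
#'   \[0, 1\]), `confusion` (2 x 2 table), `model` and `dataset`.
#' @export
binding_recovery_experiment <- function(separation = 1, seed = 1L, k = 3L,
                                        negative_scheme = c("random",
                                                            "cluster"),
                                        ...) {
  negative_scheme <- match.arg(negative_scheme)
  ds <- synthetic_binding_dataset(separation = separation, seed = seed, ...)
  cfg <- atom_bond_config(
    vocabulary = scan_element_vocabulary(c(ds$proteins, ds$ligands)))
  pf <- extract_feature_matrix(ds$proteins, cfg = cfg)
  lf <- extract_feature_matrix(ds$ligands, cfg = cfg)
  negatives <- if (negative_scheme == "random") {
    random_negative_pairs(ds$positives, rownames(pf), rownames(lf),
                          nrow(ds$positives), seed = mix_seed(seed, 1, 0, 6))
  } else {
    cluster_negative_pairs(ds$positives, pf, lf,
                           seed = mix_seed(seed, 1, 0, 6))
  }
  model <- binding_model(ds$positives, negatives, pf, lf, k = k)
  pred <- predict(model, ds$held_out)
  cm <- table(truth = factor(ds$held_out$label, c("positive", "negative")),
              predicted = factor(pred, c("positive", "negative")))
  list(
    sensitivity = cm["positive", "positive"] / sum(cm["positive", ]),
    specificity = cm["negative", "negative"] / sum(cm["negative", ]),
    confusion = cm,
    model = model,
    dataset = ds
  )
}

#' Synthetic structural-class dataset (helix vs. random walk)
#'
#' Generates two classes of synthetic proteins with distinct distance-map
#' textures: regular alpha-helical chains (periodic texture) and fixed-step
#' random walks (irregular texture). Class sizes are unequal on purpose so
#' the training folds exercise SMOTE balancing.
#'
#' @param n_helix,n_walk Number of structures per class.
#' @param n_residues_range Inclusive range chain lengths are drawn from.
#' @param seed Integer seed.
#' @return A list with `structures` (named list of `mol_structure`) and
#'   `labels` (character vector, `"helix"` / `"walk"`).
#' @export
synthetic_class_dataset <- function(n_helix = 60L, n_walk = 40L,
                                    n_residues_range = c(40L, 60L),
                                    seed = 1L) {
  n <- n_helix + n_walk
  lens <- with_seed(mix_seed(seed, 0, 0, 7), {
    sample(seq(n_residues_range[1], n_residues_range[2]), n, replace = TRUE)
  })
  labels <- c(rep("helix", n_helix), rep("walk", n_walk))
  structures <- lapply(seq_len(n), function(i) {
    id <- sprintf("%s_%03d", labels[i], i)
    sp <- synthetic_protein(lens[i], geometry = if (labels[i] == "helix")
      "helix" else "random_walk", seed = mix_seed(seed, i, 0, 8), id = id)
    parse_pdb(sp$pdb, "protein", id = id)
  })
  names(structures) <- vapply(structures, function(s) s$id, character(1))
  list(structures = structures, labels = labels)
}

#' Structural-class experiment on synthetic helix/walk data
#'
#' Extracts group-A (LBP histogram) features for a [synthetic_class_dataset()]
#' and runs the stratified cross-validated classification harness with
#' SMOTE-balanced training folds.
#'
#' @param classifier Classifier spec passed to [run_class_experiment()].
#' @param n_folds Number of stratified folds.
#' @param seed Integer seed.
#' @param shuffle_labels Permute the labels first (negative control)?
#' @param dataset Optionally a precomputed [synthetic_class_dataset()].
#' @param features Optionally a precomputed feature matrix for `dataset`.
#' @param ... Passed to [run_class_experiment()].
#' @return A `class_experiment` object.
#' @export
class_recovery_experiment <- function(classifier = "svm", n_folds = 10L,
                                      seed = 1L, shuffle_labels = FALSE,
                                      dataset = NULL, features = NULL, ...) {
  if (is.null(dataset)) dataset <- synthetic_class_dataset(seed = seed)
  if (is.null(features)) {
    features <- extract_feature_matrix(dataset$structures,
                                       spec = feature_spec("A"))
  }
  labels <- dataset$labels
  if (shuffle_labels) {
    labels <- with_seed(mix_seed(seed, 0, 0, 9), sample(labels))
  }
  run_class_experiment(features, labels, classifier = classifier,
                       n_folds = n_folds, seed = seed, ...)
}
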