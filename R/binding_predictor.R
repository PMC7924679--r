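#' The eight distance categories of the binding predictor
#'
#' A category is a (side, metric, aggregation) triple: the query side whose
#' related set is measured (`ligand` or `protein`), the distance metric
#' (`euclidean` or `manhattan`), and how the distance to the related set is
#' aggregated (`cluster_mean`: distance to the centroid;
#' `mean_of_distances`: mean of member distances). Each category casts one
#' vote in [predict.binding_model()].
#'
#' @return A data frame with columns `id`, `side`, `metric`, `aggregation`.
#' @export
binding_categories <- function() {
  g <- expand.grid(
    aggregation = c("cluster_mean", "mean_of_distances"),
    metric = c("euclidean", "manhattan"),
    side = c("ligand", "protein"),
    stringsAsFactors = FALSE
  )[, 3:1]
  g$id <- paste(g$side, g$metric, g$aggregation, sep = ".")
  g[, c("id", "side", "metric", "aggregation")]
}

# Distances from a query vector to each row of a matrix.
row_distances <- function(query, m, metric) {
  diffs <- sweep(m, 2, query)
  switch(metric,
    euclidean = sqrt(rowSums(diffs^2)),
    manhattan = rowSums(abs(diffs)),
    stop("unknown metric '", metric, "'", call. = FALSE)
  )
}

#' k nearest stored structures to a query feature vector
#'
#' Ties are broken by stable identifier order, so results are deterministic.
#'
#' @param query Numeric feature vector.
#' @param features Numeric matrix of stored feature vectors, identifiers as
#'   row names.
#' @param k Number of neighbours (`k <= nrow(features)`).
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return Character vector of the k nearest identifiers, nearest first.
#' @export
k_nearest <- function(query, features, k = 3L, metric = "euclidean") {
  if (nrow(features) < k) {
    stop("only ", nrow(features), " stored structures but k = ", k,
         call. = FALSE)
  }
  d <- row_distances(query, features, metric)
  rownames(features)[order(d, rownames(features))[seq_len(k)]]
}

#' Related ligands of a protein neighbourhood
#'
#' The ligands appearing in training positive pairs with any protein of the
#' neighbourhood, duplicates removed, in first-appearance order. An empty
#' result (no positive pair touches the neighbourhood) is returned as a
#' zero-length vector so the caller can abstain from that vote side.
#'
#' @param protein_ids Character vector of neighbourhood protein identifiers.
#' @param positives Data frame of training positives with columns
#'   `protein_id`, `ligand_id`.
#' @return Character vector of ligand identifiers (possibly empty).
#' @export
related_ligands <- function(protein_ids, positives) {
  stopifnot(length(protein_ids) >= 1L)
  unique(positives$ligand_id[positives$protein_id %in% protein_ids])
}

#' Related proteins of a ligand neighbourhood
#'
#' Mirror of [related_ligands()]: proteins positively paired with any ligand
#' of the neighbourhood.
#'
#' @param ligand_ids Character vector of neighbourhood ligand identifiers.
#' @inheritParams related_ligands
#' @return Character vector of protein identifiers (possibly empty).
#' @export
related_proteins <- function(ligand_ids, positives) {
  stopifnot(length(ligand_ids) >= 1L)
  unique(positives$protein_id[positives$ligand_id %in% ligand_ids])
}

#' Distance from a query to a related set under one category
#'
#' @param query Numeric feature vector.
#' @param related Numeric matrix of related feature vectors (>= 1 row).
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param aggregation `"cluster_mean"` or `"mean_of_distances"`.
#' @return A single non-negative number.
#' @export
category_distance <- function(query, related, metric = "euclidean",
                              aggregation = "cluster_mean") {
  related <- rbind(related)
  if (!nrow(related)) stop("empty related set", call. = FALSE)
  switch(aggregation,
    cluster_mean = row_distances(query, rbind(colMeans(related)), metric),
    mean_of_distances = mean(row_distances(query, related, metric)),
    stop("unknown aggregation '", aggregation, "'", call. = FALSE)
  )[[1]]
}

# One category's raw distance for a pair, or NA when the vote side must
# abstain (no related structures).
.pair_category_distance <- function(p_vec, l_vec, cat, positives,
                                    protein_features, ligand_features, k,
                                    relation_pairs = positives) {
  if (cat$side == "ligand") {
    np <- k_nearest(p_vec, protein_features, k, cat$metric)
    rl <- related_ligands(np, relation_pairs)
    if (!length(rl)) return(NA_real_)
    category_distance(l_vec, ligand_features[rl, , drop = FALSE],
                      cat$metric, cat$aggregation)
  } else {
    nl <- k_nearest(l_vec, ligand_features, k, cat$metric)
    rp <- related_proteins(nl, relation_pairs)
    if (!length(rp)) return(NA_real_)
    category_distance(p_vec, protein_features[rp, , drop = FALSE],
                      cat$metric, cat$aggregation)
  }
}

#' Fit a similarity-based protein-ligand binding model
#'
#' Trains the nearest-neighbour voting predictor: for a query pair (p, l)
#' the model finds the k training proteins most similar to p, collects the
#' ligands those proteins are known to bind (the related ligands), and
#' measures how far l falls from that set -- and symmetrically from the
#' protein side. Each of the eight distance categories
#' ([binding_categories()]) gets a threshold learned from the training
#' distances; at prediction time a distance below its category threshold
#' votes for a positive bind and the majority of non-abstaining votes
#' decides.
#'
#' Thresholds are fitted from both positive and negative training pairs:
#' under the default `"mixed"` protocol the related set of each training
#' pair is derived from the pairs of the opposite label, and the threshold
#' of a category is the grand mean of the resulting distances. The
#' alternative protocols use only one label with the positive relation
#' table.
#'
#' @param positives Data frame of positive training pairs (columns
#'   `protein_id`, `ligand_id`).
#' @param negatives Data frame of negative training pairs (same columns).
#'   Required for threshold fitting; generate with
#'   [random_negative_pairs()] or [cluster_negative_pairs()] when only
#'   positives are known.
#' @param protein_features,ligand_features Numeric matrices of feature
#'   vectors with structure identifiers as row names; every identifier
#'   referenced by a pair must be present.
#' @param k Number of nearest neighbours used on both sides.
#' @param categories Subset of [binding_categories()] to use.
#' @param threshold_protocol `"mixed"` (default), `"positives"` or
#'   `"negatives"`.
#' @param vote_scheme `"categories"` (one vote per category, default) or
#'   `"sides"` (each side aggregated to one vote first).
#' @return An object of class `binding_model` with components including
#'   `thresholds` (named per-category vector) and `training_distances`.
#' @seealso [predict.binding_model()]
#' @export
binding_model <- function(positives, negatives, protein_features,
                          ligand_features, k = 3L,
                          categories = binding_categories(),
                          threshold_protocol = c("mixed", "positives",
                                                 "negatives"),
                          vote_scheme = c("categories", "sides")) {
  threshold_protocol <- match.arg(threshold_protocol)
  vote_scheme <- match.arg(vote_scheme)
  stopifnot(all(c("protein_id", "ligand_id") %in% names(positives)))
  if (missing(negatives) || is.null(negatives) || !nrow(negatives)) {
    stop("threshold fitting needs negative training pairs; generate them ",
         "with random_negative_pairs() or cluster_negative_pairs()",
         call. = FALSE)
  }
  ref <- unique(c(positives$protein_id, negatives$protein_id))
  if (!all(ref %in% rownames(protein_features))) {
    stop("missing protein feature vectors for some training pairs",
         call. = FALSE)
  }
  refl <- unique(c(positives$ligand_id, negatives$ligand_id))
  if (!all(refl %in% rownames(ligand_features))) {
    stop("missing ligand feature vectors for some training pairs",
         call. = FALSE)
  }

  train <- switch(threshold_protocol,
    mixed = rbind(cbind(positives[c("protein_id", "ligand_id")], label = "positive"),
                  cbind(negatives[c("protein_id", "ligand_id")], label = "negative")),
    positives = cbind(positives[c("protein_id", "ligand_id")], label = "positive"),
    negatives = cbind(negatives[c("protein_id", "ligand_id")], label = "negative")
  )

  dists <- matrix(NA_real_, nrow(train), nrow(categories),
                  dimnames = list(NULL, categories$id))
  for (ci in seq_len(nrow(categories))) {
    cat <- categories[ci, ]
    for (ti in seq_len(nrow(train))) {
      relation <- if (threshold_protocol == "mixed") {
        if (train$label[ti] == "positive") negatives else positives
      } else {
        positives
      }
      dists[ti, ci] <- .pair_category_distance(
        protein_features[train$protein_id[ti], ],
        ligand_features[train$ligand_id[ti], ],
        cat, positives, protein_features, ligand_features, k,
        relation_pairs = relation
      )
    }
  }
  thresholds <- colMeans(dists, na.rm = TRUE)

  structure(list(
    positives = positives[c("protein_id", "ligand_id")],
    negatives = negatives[c("protein_id", "ligand_id")],
    protein_features = protein_features,
    ligand_features = ligand_features,
    k = as.integer(k),
    categories = categories,
    thresholds = thresholds,
    threshold_protocol = threshold_protocol,
    vote_scheme = vote_scheme,
    training_distances = data.frame(label = train$label, dists,
                                    check.names = FALSE)
  ), class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat("Similarity-based protein-ligand binding model\n")
  cat(sprintf("  training pairs: %d positive, %d negative\n",
              nrow(x$positives), nrow(x$negatives)))
  cat(sprintf("  stored features: %d proteins, %d ligands (%d-dimensional)\n",
              nrow(x$protein_features), nrow(x$ligand_features),
              ncol(x$protein_features)))
  cat(sprintf("  k = %d, %d vote categories, protocol = %s, votes = %s\n",
              x$k, nrow(x$categories), x$threshold_protocol, x$vote_scheme))
  invisible(x)
}

#' @export
summary.binding_model <- function(object, ...) {
  print(object)
  cat("  per-category thresholds:\n")
  for (id in names(object$thresholds)) {
    cat(sprintf("    %-38s %.4f\n", id, object$thresholds[[id]]))
  }
  invisible(object$thresholds)
}

#' @export
coef.binding_model <- function(object, ...) object$thresholds

#' Training distance distributions against fitted thresholds
#'
#' One panel per distance category showing the training distances (split by
#' pair label) with the fitted threshold as a vertical line.
#'
#' @param x A `binding_model`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.binding_model <- function(x, ...) {
  ids <- names(x$thresholds)
  old <- graphics::par(mfrow = c(2, ceiling(length(ids) / 2)),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (id in ids) {
    d <- x$training_distances[[id]]
    graphics::hist(d[is.finite(d)], main = id, xlab = "distance",
                   col = "grey85", border = "white", cex.main = 0.8, ...)
    graphics::abline(v = x$thresholds[[id]], col = "red3", lwd = 2)
  }
  invisible(x)
}

#' Predict binding for protein-ligand pairs
#'
#' For every pair each distance category votes positive when its category
#' distance falls below the fitted threshold; a side with no related
#' structures abstains. The majority of non-abstaining votes decides, with
#' ties resolved towards `"positive"`; when every vote abstains the outcome
#' is `"undecidable"`.
#'
#' @param object A fitted [binding_model()].
#' @param pairs Data frame of query pairs (columns `protein_id`,
#'   `ligand_id`).
#' @param protein_features,ligand_features Optional feature matrices for
#'   query structures not already stored in the model (row-bound onto the
#'   stored ones for lookup; the neighbour stores stay the training ones).
#' @param details Return per-category distances and votes as well?
#' @param ... Unused.
#' @return A character vector of labels (`"positive"`, `"negative"` or
#'   `"undecidable"`), or when `details = TRUE` a data frame with the label,
#'   vote counts and one distance column per category.
#' @export
predict.binding_model <- function(object, pairs, protein_features = NULL,
                                  ligand_features = NULL, details = FALSE,
                                  ...) {
  stopifnot(all(c("protein_id", "ligand_id") %in% names(pairs)))
  pf_all <- object$protein_features
  if (!is.null(protein_features)) {
    pf_all <- rbind(pf_all,
                    protein_features[setdiff(rownames(protein_features),
                                             rownames(pf_all)), , drop = FALSE])
  }
  lf_all <- object$ligand_features
  if (!is.null(ligand_features)) {
    lf_all <- rbind(lf_all,
                    ligand_features[setdiff(rownames(ligand_features),
                                            rownames(lf_all)), , drop = FALSE])
  }
  cats <- object$categories
  n <- nrow(pairs)
  dist_mat <- matrix(NA_real_, n, nrow(cats),
                     dimnames = list(NULL, cats$id))
  labels <- character(n)
  pos_votes <- integer(n)
  neg_votes <- integer(n)
  for (i in seq_len(n)) {
    p_vec <- pf_all[pairs$protein_id[i], ]
    l_vec <- lf_all[pairs$ligand_id[i], ]
    votes <- rep(NA, nrow(cats))
    for (ci in seq_len(nrow(cats))) {
      d <- .pair_category_distance(p_vec, l_vec, cats[ci, ],
                                   object$positives,
                                   object$protein_features,
                                   object$ligand_features, object$k)
      dist_mat[i, ci] <- d
      if (is.finite(d)) votes[ci] <- d < object$thresholds[[cats$id[ci]]]
    }
    if (object$vote_scheme == "sides") {
      side_votes <- vapply(c("ligand", "protein"), function(sd) {
        v <- votes[cats$side == sd]
        v <- v[!is.na(v)]
        if (!length(v)) NA else sum(v) >= length(v) / 2
      }, logical(1))
      votes <- side_votes
    }
    v <- votes[!is.na(votes)]
    pos_votes[i] <- sum(v)
    neg_votes[i] <- length(v) - sum(v)
    labels[i] <- if (!length(v)) {
      "undecidable"
    } else if (sum(v) >= length(v) / 2) "positive" else "negative"
  }
  if (!details) return(labels)
  data.frame(protein_id = pairs$protein_id, ligand_id = pairs$ligand_id,
             label = labels, positive_votes = pos_votes,
             negative_votes = neg_votes, dist_mat, check.names = FALSE,
             stringsAsFactors = FALSE)
}
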