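# Run `expr` under a deterministic RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministically derive a sub-seed (kept within 32-bit integer range)
# from a base seed and stream identifiers.
mix_seed <- function(...) {
  v <- as.numeric(c(...))
  as.integer(sum(v * c(1, 7919, 104729, 1299709)[seq_along(v)]) %% 2147483647)
}

#' SMOTE oversampling percentage
#'
#' Given the majority-class size `x` and a minority-class size `y`, the
#' oversampling percentage that brings the minority up to the majority is
#' `(x - y) / y * 100`.
#'
#' @param x Majority-class instance count.
#' @param y Minority-class instance count (`1 <= y <= x`).
#' @return The percentage as a plain number.
#' @export
smote_percentage <- function(x, y) {
  if (any(y < 1)) stop("class size y must be >= 1", call. = FALSE)
  if (any(x < y)) stop("x must be the largest class count (x >= y)", call. = FALSE)
  (x - y) / y * 100
}

#' Generate SMOTE synthetic samples for one class
#'
#' Each synthetic vector lies on the segment between a class sample `s` and
#' one of its `k` nearest same-class neighbours `nn` (Euclidean):
#' `s + u * (nn - s)` with `u` uniform on \[0, 1\]. The number of synthetics
#' is `round(percent / 100 * n)`; base samples are used as evenly as
#' possible and the neighbour is drawn uniformly among the k nearest for
#' each draw. Original samples are never modified.
#'
#' @param samples Numeric matrix, one row per class sample (n >= 2 when
#'   `percent > 0`).
#' @param percent Oversampling percentage, >= 0.
#' @param k Number of nearest neighbours to interpolate towards.
#' @param seed Integer seed making the draw reproducible.
#' @return A numeric matrix of synthetic rows (possibly 0-row).
#' @export
smote_oversample <- function(samples, percent, k = 5L, seed = 1L) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  n_new <- round(percent / 100 * n)
  if (n_new == 0) {
    return(samples[integer(0), , drop = FALSE])
  }
  if (n < 2L) {
    stop("SMOTE needs at least 2 samples to interpolate between", call. = FALSE)
  }
  k_eff <- min(k, n - 1L)
  d <- as.matrix(stats::dist(samples))
  diag(d) <- Inf
  nn_idx <- t(apply(d, 1, function(r) order(r)[seq_len(k_eff)]))
  with_seed(seed, {
    base <- rep(seq_len(n), n_new %/% n)
    extra <- n_new - length(base)
    if (extra > 0) base <- c(base, sample.int(n, extra))
    nb <- nn_idx[cbind(base, sample.int(k_eff, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    samples[base, , drop = FALSE] +
      u * (samples[nb, , drop = FALSE] - samples[base, , drop = FALSE])
  })
}

#' SMOTE-balance a training partition
#'
#' Every minority class is oversampled by [smote_oversample()] with the
#' percentage `(x - y) / y * 100` (majority count x, class count y), which
#' brings each class to the majority count up to rounding. This is meant to
#' be called on a training partition only, after the train/test split, so no
#' synthetic instance can reach a test fold; the returned `synthetic` flag
#' makes that auditable.
#'
#' @param x Numeric feature matrix of the training partition.
#' @param labels Class labels (factor or character), one per row of `x`.
#' @param k Neighbour count passed to [smote_oversample()].
#' @param seed Integer seed.
#' @return A list with `x` (original rows then synthetic rows), `labels`,
#'   and `synthetic` (logical flag per row, `FALSE` for every original row).
#' @export
balance_training_set <- function(x, labels, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  counts <- table(labels)
  target <- max(counts)
  new_x <- list()
  new_lab <- character(0)
  for (cl in names(counts)) {
    y <- counts[[cl]]
    if (y == target) next
    pct <- smote_percentage(target, y)
    syn <- smote_oversample(x[labels == cl, , drop = FALSE], pct, k = k,
                            seed = seed + match(cl, names(counts)))
    if (nrow(syn)) {
      new_x[[cl]] <- syn
      new_lab <- c(new_lab, rep(cl, nrow(syn)))
    }
  }
  add <- if (length(new_x)) do.call(rbind, new_x) else x[integer(0), , drop = FALSE]
  list(
    x = rbind(x, add),
    labels = c(labels, new_lab),
    synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(add)))
  )
}

#' Random negative protein-ligand pairs
#'
#' Samples `n` distinct (protein, ligand) pairs uniformly from the
#' complement of the positive pair set.
#'
#' @param positives Data frame with columns `protein_id` and `ligand_id`.
#' @param protein_ids,ligand_ids Candidate identifier pools.
#' @param n Number of negative pairs to draw.
#' @param seed Integer seed.
#' @return A data frame with columns `protein_id`, `ligand_id`.
#' @export
random_negative_pairs <- function(positives, protein_ids, ligand_ids, n,
                                  seed = 1L) {
  stopifnot(all(c("protein_id", "ligand_id") %in% names(positives)))
  n_p <- length(protein_ids)
  n_l <- length(ligand_ids)
  pos_key <- paste(positives$protein_id, positives$ligand_id, sep = "\r")
  total <- n_p * n_l
  if (total - length(unique(pos_key)) < n) {
    stop("not enough unseen protein-ligand pairs to sample ", n, " negatives",
         call. = FALSE)
  }
  if (n == 0) {
    return(data.frame(protein_id = character(0), ligand_id = character(0),
                      stringsAsFactors = FALSE))
  }
  all_key <- as.vector(outer(protein_ids, ligand_ids, paste, sep = "\r"))
  candidates <- setdiff(all_key, pos_key)
  with_seed(seed, {
    pick <- sample(candidates, n)
    parts <- strsplit(pick, "\r", fixed = TRUE)
    data.frame(protein_id = vapply(parts, `[`, character(1), 1),
               ligand_id = vapply(parts, `[`, character(1), 2),
               stringsAsFactors = FALSE)
  })
}

#' Clustering-based negative protein-ligand pairs
#'
#' The positive pairs' feature vectors are k-means clustered; unseen pairs
#' are then sampled at random, assigned to the nearest centroid, and kept
#' until every cluster holds as many negatives as it holds positives, so the
#' negative set mirrors the positive set's structure cluster by cluster.
#'
#' @param positives Data frame with columns `protein_id`, `ligand_id`.
#' @param protein_features,ligand_features Numeric matrices of per-structure
#'   feature vectors with identifiers as row names.
#' @param n_clusters Number of k-means clusters.
#' @param seed Integer seed.
#' @param max_draws Cap on candidate draws before a cluster is declared
#'   exhausted.
#' @return A data frame with columns `protein_id`, `ligand_id`, `cluster`.
#' @export
cluster_negative_pairs <- function(positives, protein_features,
                                   ligand_features, n_clusters = 10L,
                                   seed = 1L, max_draws = 100000L) {
  stopifnot(nrow(positives) >= n_clusters)
  pf <- function(p, l) c(protein_features[p, ], ligand_features[l, ])
  pos_feat <- t(mapply(pf, positives$protein_id, positives$ligand_id))
  pos_key <- paste(positives$protein_id, positives$ligand_id, sep = "\r")
  protein_ids <- rownames(protein_features)
  ligand_ids <- rownames(ligand_features)
  with_seed(seed, {
    km <- stats::kmeans(pos_feat, centers = n_clusters, nstart = 5)
    need <- tabulate(km$cluster, nbins = n_clusters)
    got <- integer(n_clusters)
    out_p <- character(0)
    out_l <- character(0)
    out_c <- integer(0)
    seen <- pos_key
    draws <- 0L
    while (any(got < need)) {
      draws <- draws + 1L
      if (draws > max_draws) {
        short <- which(got < need)[1]
        stop("cluster ", short, " exhausted its candidate unseen pairs (",
             got[short], "/", need[short], " negatives found)", call. = FALSE)
      }
      p <- protein_ids[sample.int(length(protein_ids), 1)]
      l <- ligand_ids[sample.int(length(ligand_ids), 1)]
      key <- paste(p, l, sep = "\r")
      if (key %in% seen) next
      v <- pf(p, l)
      cl <- which.min(colSums((t(km$centers) - v)^2))
      if (got[cl] >= need[cl]) next
      seen <- c(seen, key)
      got[cl] <- got[cl] + 1L
      out_p <- c(out_p, p)
      out_l <- c(out_l, l)
      out_c <- c(out_c, cl)
    }
    data.frame(protein_id = out_p, ligand_id = out_l, cluster = out_c,
               stringsAsFactors = FALSE)
  })
}
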