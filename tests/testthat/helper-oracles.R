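# Independent brute-force implementations used as oracles. These stay
# deliberately naive (per-pixel loops, full sorts, string bit-twiddling) and
# share no code with the package internals they check.

oracle_lbp_code <- function(window) {
  centre <- window[2, 2]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- 0
  for (i in seq_along(offs)) {
    nb <- window[2 + offs[[i]][1], 2 + offs[[i]][2]]
    bit <- if (centre > nb) 0 else 1
    code <- code * 2 + bit
  }
  as.integer(code)
}

oracle_lbp_transform <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- img
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- oracle_lbp_code(pad[i:(i + 2), j:(j + 2)])
    }
  }
  out
}

oracle_histogram <- function(img, n_bins = 256) {
  sapply(0:(n_bins - 1), function(k) sum(img == k))
}

oracle_transitions <- function(code) {
  bits <- strsplit(paste(rev(as.integer(intToBits(code)[1:8])), collapse = ""),
                   "")[[1]]
  circ <- c(bits, bits[1])
  sum(circ[-1] != circ[-length(circ)])
}

oracle_dist_matrix <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  d
}

oracle_bond_census <- function(s, vocabulary, threshold) {
  atoms <- s$atoms
  counts <- list()
  n <- nrow(atoms)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ei <- atoms$element[i]
      ej <- atoms$element[j]
      if (!(ei %in% vocabulary) || !(ej %in% vocabulary)) next
      d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                  (atoms$z[i] - atoms$z[j])^2)
      if (d > threshold) next
      pair <- paste(sort(factor(c(ei, ej), levels = vocabulary)),
                    collapse = "")
      counts[[pair]] <- (counts[[pair]] %||% 0) + 1
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_knn <- function(query, features, k, metric) {
  d <- apply(features, 1, function(row) {
    if (metric == "euclidean") sqrt(sum((row - query)^2))
    else sum(abs(row - query))
  })
  names(sort(d))[seq_len(k)]  # base sort is stable; names break ties
}

oracle_category_distance <- function(query, related, metric, aggregation) {
  one <- function(a, b) {
    if (metric == "euclidean") sqrt(sum((a - b)^2)) else sum(abs(a - b))
  }
  if (aggregation == "cluster_mean") {
    one(query, colMeans(related))
  } else {
    mean(apply(related, 1, one, b = query))
  }
}

# Build a mol_structure directly from coordinates and element symbols.
make_structure <- function(coords, elements = rep("C", nrow(coords)),
                           kind = "protein", id = "fixture",
                           names = if (kind == "protein")
                             rep("CA", nrow(coords)) else elements) {
  coords <- as.matrix(coords)
  structure(list(
    id = id, kind = kind,
    atoms = data.frame(serial = seq_len(nrow(coords)), name = names,
                       element = elements,
                       residue_index = seq_len(nrow(coords)),
                       x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       stringsAsFactors = FALSE)
  ), class = "mol_structure")
}

random_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}
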