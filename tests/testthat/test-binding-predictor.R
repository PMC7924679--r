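# Small deterministic feature store for predictor unit tests: three
# well-separated families (orthogonal centres, so every family pair is
# equally far apart), one-to-one positives within families, and random
# unseen pairs as negatives.
toy_store <- function(n_per = 6, sep = 30, seed = 61) {
  set.seed(seed)
  fam_centre <- function(k) sep * (seq_len(4) == k)
  mk <- function(prefix) {
    m <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rnorm(n_per * 4), n_per, 4) + rep(fam_centre(k), each = n_per)
    }))
    rownames(m) <- paste0(prefix, seq_len(3 * n_per))
    m
  }
  pf <- mk("p")
  lf <- mk("l")
  pos <- data.frame(protein_id = rownames(pf), ligand_id = rownames(lf),
                    stringsAsFactors = FALSE)
  neg <- random_negative_pairs(pos, rownames(pf), rownames(lf), nrow(pos),
                               seed = seed)
  list(pf = pf, lf = lf, pos = pos, neg = neg)
}

test_that("k_nearest returns the k closest ids with stable ties", {
  set.seed(62)
  f <- matrix(rnorm(200), 50, 4)
  rownames(f) <- sprintf("s%02d", 1:50)
  q <- f[7, ]
  expect_equal(k_nearest(q, f, 1)[1], "s07")
  expect_equal(sort(k_nearest(q, f, 50)), sort(rownames(f)))
  for (metric in c("euclidean", "manhattan")) {
    expect_equal(k_nearest(q + 0.1, f, 3, metric),
                 oracle_knn(q + 0.1, f, 3, metric))
  }
  expect_error(k_nearest(q, f[1:2, ], 3), "k = 3")
  # exact ties resolved by id order
  tied <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  rownames(tied) <- c("b_id", "a_id", "c_id")
  expect_equal(k_nearest(c(0.5, 0.5), tied, 3),
               c("a_id", "b_id", "c_id"))
})

test_that("related structures come from the positive interaction join", {
  pos <- data.frame(protein_id = c("p1", "p2", "p3", "p1"),
                    ligand_id = c("l1", "l2", "l3", "l9"),
                    stringsAsFactors = FALSE)
  expect_equal(related_ligands(c("p1", "p2"), pos), c("l1", "l2", "l9"))
  expect_equal(related_ligands("p7", pos), character(0))
  expect_equal(related_proteins(c("l3", "l9"), pos), c("p3", "p1"))
  # one-to-one pairing: |related ligands| = |neighbourhood|
  one2one <- data.frame(protein_id = paste0("p", 1:5),
                        ligand_id = paste0("l", 1:5))
  expect_length(related_ligands(c("p2", "p4"), one2one), 2)
  # brute-force join oracle on a random bipartite table
  set.seed(63)
  tab <- data.frame(protein_id = sample(paste0("p", 1:8), 30, replace = TRUE),
                    ligand_id = sample(paste0("l", 1:8), 30, replace = TRUE),
                    stringsAsFactors = FALSE)
  np <- c("p3", "p5")
  expected <- unique(unlist(lapply(seq_len(nrow(tab)), function(i)
    if (tab$protein_id[i] %in% np) tab$ligand_id[i] else NULL)))
  expect_equal(related_ligands(np, tab), expected)
})

test_that("category distances agree with direct-loop computation", {
  set.seed(64)
  q <- rnorm(6)
  rel <- matrix(rnorm(60), 10, 6)
  for (metric in c("euclidean", "manhattan")) {
    for (agg in c("cluster_mean", "mean_of_distances")) {
      expect_equal(category_distance(q, rel, metric, agg),
                   oracle_category_distance(q, rel, metric, agg))
    }
    # singleton related set: both aggregations coincide
    expect_equal(category_distance(q, rel[3, , drop = FALSE], metric,
                                   "cluster_mean"),
                 category_distance(q, rel[3, , drop = FALSE], metric,
                                   "mean_of_distances"))
    expect_equal(category_distance(q, rbind(q), metric, "cluster_mean"), 0)
  }
  expect_error(category_distance(q, rel[0, , drop = FALSE]), "empty")
})

test_that("binding_model fits eight thresholds and is reproducible", {
  st <- toy_store()
  m <- binding_model(st$pos, st$neg, st$pf, st$lf, k = 3)
  expect_s3_class(m, "binding_model")
  expect_length(coef(m), 8)
  expect_true(all(is.finite(coef(m)) & coef(m) > 0))
  m2 <- binding_model(st$pos, st$neg, st$pf, st$lf, k = 3)
  expect_identical(coef(m), coef(m2))
  expect_error(binding_model(st$pos, NULL, st$pf, st$lf),
               "negative training pairs")
  expect_output(print(m), "binding model")
})

test_that("thresholds land between within- and between-family distances", {
  st <- toy_store()
  m <- binding_model(st$pos, st$neg, st$pf, st$lf, k = 3)
  within <- mean(dist(st$lf[1:6, ]))
  between <- mean(as.matrix(dist(st$lf))[1:6, 7:12])
  thr <- coef(m)[["ligand.euclidean.mean_of_distances"]]
  expect_gt(thr, within)
  expect_lt(thr, between)
})

test_that("identical training vectors give all-zero thresholds", {
  pf <- matrix(1, 6, 4, dimnames = list(paste0("p", 1:6), NULL))
  lf <- matrix(2, 6, 4, dimnames = list(paste0("l", 1:6), NULL))
  pos <- data.frame(protein_id = paste0("p", 1:3), ligand_id = paste0("l", 1:3))
  neg <- data.frame(protein_id = paste0("p", 4:6), ligand_id = paste0("l", 4:6))
  m <- binding_model(pos, neg, pf, lf, k = 2)
  expect_true(all(coef(m) == 0))
})

test_that("prediction recovers planted structure on the toy store", {
  st <- toy_store()
  m <- binding_model(st$pos, st$neg, st$pf, st$lf, k = 3)
  # a stored positive pair is predicted positive
  expect_equal(predict(m, st$pos[1, ]), "positive")
  # far-out query votes negative everywhere
  far_p <- matrix(rnorm(4) + 500, 1, dimnames = list("pq", NULL))
  far_l <- matrix(rnorm(4) + 900, 1, dimnames = list("lq", NULL))
  expect_equal(predict(m, data.frame(protein_id = "pq", ligand_id = "lq"),
                       protein_features = far_p, ligand_features = far_l),
               "negative")
  # held-out within-family vs cross-family pairs
  hold <- data.frame(protein_id = c("p1", "p2", "p8", "p14", "p1", "p9"),
                     ligand_id = c("l2", "l3", "l9", "l15", "l8", "l14"))
  got <- predict(m, hold)
  expect_equal(got, c("positive", "positive", "positive", "positive",
                      "negative", "negative"))
  det <- predict(m, hold, details = TRUE)
  expect_equal(det$label, got)
  expect_equal(det$positive_votes + det$negative_votes, rep(8L, 6))
})

test_that("prediction is deterministic and threshold-monotone", {
  st <- toy_store()
  m <- binding_model(st$pos, st$neg, st$pf, st$lf, k = 3)
  hold <- data.frame(protein_id = c("p1", "p3", "p8"),
                     ligand_id = c("l8", "l4", "l2"))
  expect_identical(predict(m, hold), predict(m, hold))
  # raising every threshold can only move labels towards positive
  m_hi <- m
  m_hi$thresholds <- m$thresholds * 10
  before <- predict(m, hold)
  after <- predict(m_hi, hold)
  expect_true(all(!(before == "positive" & after == "negative")))
})

test_that("scaling features and thresholds together leaves votes unchanged", {
  st <- toy_store()
  m <- binding_model(st$pos, st$neg, st$pf, st$lf, k = 3)
  hold <- data.frame(protein_id = c("p1", "p2", "p8", "p1"),
                     ligand_id = c("l2", "l8", "l9", "l9"))
  m_scaled <- binding_model(st$pos, st$neg, st$pf * 7, st$lf * 7, k = 3)
  expect_equal(m_scaled$thresholds, m$thresholds * 7, tolerance = 1e-10)
  expect_identical(predict(m, hold), predict(m_scaled, hold))
})

test_that("queries with no related structures abstain or are undecidable", {
  # positives confined to family 1; a family-2 query finds neighbours whose
  # proteins have no positive pairs -> both sides abstain
  st <- toy_store()
  pos1 <- st$pos[1:6, ]
  neg1 <- data.frame(protein_id = paste0("p", 1:6),
                     ligand_id = paste0("l", c(2:6, 1)))
  m <- binding_model(pos1, neg1, st$pf, st$lf, k = 3)
  res <- predict(m, data.frame(protein_id = "p15", ligand_id = "l15"))
  expect_equal(res, "undecidable")
})

test_that("the two-sided vote scheme aggregates within sides first", {
  st <- toy_store()
  m <- binding_model(st$pos, st$neg, st$pf, st$lf, k = 3,
                     vote_scheme = "sides")
  hold <- data.frame(protein_id = c("p1", "p8"), ligand_id = c("l2", "l14"))
  expect_equal(predict(m, hold), c("positive", "negative"))
})
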