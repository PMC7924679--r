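test_that("smote percentage follows (x - y) / y * 100", {
  expect_equal(smote_percentage(50, 50), 0)
  expect_equal(smote_percentage(100, 50), 100)
  expect_equal(smote_percentage(3305, 640), 416.40625)
  expect_error(smote_percentage(10, 0), ">= 1")
  expect_error(smote_percentage(5, 10), "largest")
})

test_that("smote synthetics lie on segments towards nearest neighbours", {
  set.seed(51)
  x <- matrix(rnorm(40), 20, 2)
  expect_equal(nrow(smote_oversample(x, 0, seed = 1)), 0)
  same <- matrix(3, 5, 4)
  syn <- smote_oversample(same, 200, seed = 2)
  expect_equal(nrow(syn), 10)
  expect_true(all(syn == 3))
  syn2 <- smote_oversample(x, 150, k = 5, seed = 3)
  expect_equal(nrow(syn2), 30)
  # geometric oracle: each synthetic is s + u (nn - s) for some sample s and
  # one of its 5 brute-force nearest neighbours
  d <- as.matrix(dist(x)); diag(d) <- Inf
  on_segment <- vapply(seq_len(nrow(syn2)), function(i) {
    p <- syn2[i, ]
    any(vapply(seq_len(nrow(x)), function(s) {
      nns <- order(d[s, ])[1:5]
      any(vapply(nns, function(nn) {
        seg <- x[nn, ] - x[s, ]
        rel <- p - x[s, ]
        if (all(seg == 0)) return(all(rel == 0))
        u <- sum(rel * seg) / sum(seg^2)
        u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((rel - u * seg)^2)) < 1e-8
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  expect_true(all(on_segment))
  expect_error(smote_oversample(x[1, , drop = FALSE], 100, seed = 1),
               "at least 2")
})

test_that("smote is reproducible and never alters originals", {
  x <- matrix(rnorm(30), 15, 2)
  a <- smote_oversample(x, 120, seed = 9)
  b <- smote_oversample(x, 120, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, smote_oversample(x, 120, seed = 10)))
})

test_that("balancing a training partition reaches the majority count", {
  x <- matrix(rnorm(300), 150, 2)
  lab <- rep(c("a", "b"), c(100, 50))
  bal <- balance_training_set(x, lab, seed = 4)
  expect_equal(unname(table(bal$labels)[["b"]]), 100)
  expect_equal(unname(table(bal$labels)[["a"]]), 100)
  expect_false(any(bal$synthetic[seq_len(150)]))
  expect_equal(bal$x[1:150, ], x)
  # already balanced input comes back unchanged
  even <- balance_training_set(x[1:100, ], rep(c("a", "b"), 50), seed = 5)
  expect_equal(nrow(even$x), 100)
  expect_false(any(even$synthetic))
})

test_that("a seven-class partition with benchmark-like proportions balances", {
  # class sizes proportional to a SCOP-style class table, scaled down 1/20
  sizes <- c(small = 32, all_a = 110, a_slash_b = 165, a_plus_b = 150,
             membrane = 10, all_b = 74, multi = 11)
  set.seed(6)
  x <- matrix(rnorm(2 * sum(sizes)), sum(sizes), 2)
  lab <- rep(names(sizes), sizes)
  bal <- balance_training_set(x, lab, seed = 6)
  counts <- table(bal$labels)
  expect_true(all(abs(counts - max(sizes)) <= 1))
})

test_that("random negative pairs avoid positives and duplicates", {
  pos <- data.frame(protein_id = c("p1", "p2", "p3"),
                    ligand_id = c("l1", "l2", "l3"))
  neg <- random_negative_pairs(pos, paste0("p", 1:3), paste0("l", 1:3), 3,
                               seed = 7)
  expect_equal(nrow(neg), 3)
  key <- function(df) paste(df$protein_id, df$ligand_id)
  expect_length(intersect(key(neg), key(pos)), 0)
  expect_equal(anyDuplicated(key(neg)), 0)
  expect_equal(nrow(random_negative_pairs(pos, paste0("p", 1:3),
                                          paste0("l", 1:3), 0)), 0)
  expect_error(random_negative_pairs(pos, paste0("p", 1:3), paste0("l", 1:3),
                                     7, seed = 1), "not enough")
  set.seed(8)
  big_pos <- data.frame(protein_id = paste0("p", 1:20),
                        ligand_id = paste0("l", 1:20))
  big_neg <- random_negative_pairs(big_pos, paste0("p", 1:20),
                                   paste0("l", 1:20), 50, seed = 9)
  expect_equal(nrow(big_neg), 50)
  expect_length(intersect(key(big_neg), key(big_pos)), 0)
  expect_equal(anyDuplicated(key(big_neg)), 0)
  expect_identical(big_neg, random_negative_pairs(big_pos, paste0("p", 1:20),
                                                  paste0("l", 1:20), 50,
                                                  seed = 9))
})

test_that("cluster-based negatives mirror per-cluster positive counts", {
  set.seed(10)
  # two well-separated synthetic families of pairs
  pf <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40) + 20, 20, 2))
  lf <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40) + 20, 20, 2))
  rownames(pf) <- paste0("p", 1:40)
  rownames(lf) <- paste0("l", 1:40)
  pos <- data.frame(protein_id = paste0("p", 1:40),
                    ligand_id = paste0("l", 1:40),
                    stringsAsFactors = FALSE)
  neg <- cluster_negative_pairs(pos, pf, lf, n_clusters = 2, seed = 11)
  expect_equal(nrow(neg), 40)
  expect_equal(as.integer(sort(table(neg$cluster))), c(20L, 20L))
  key <- function(df) paste(df$protein_id, df$ligand_id)
  expect_length(intersect(key(neg), key(pos)), 0)
  # degenerate single cluster reduces to plain random undersampling
  neg1 <- cluster_negative_pairs(pos[1:10, ], pf, lf, n_clusters = 1,
                                 seed = 12)
  expect_equal(nrow(neg1), 10)
})
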