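test_that("lbp_code follows the clockwise MSB-first convention", {
  expect_equal(lbp_code(matrix(5, 3, 3)), 255L)      # ties count as 1
  w <- matrix(1, 3, 3); w[2, 2] <- 9
  expect_equal(lbp_code(w), 0L)                       # centre strictly greater
  w2 <- matrix(0, 3, 3); w2[2, 2] <- 1; w2[1, 1] <- 7
  expect_equal(lbp_code(w2), 128L)                    # top-left is the MSB
})

test_that("lbp_code matches independent bit assembly on random windows", {
  set.seed(31)
  for (i in 1:300) {
    w <- matrix(sample(0:255, 9, replace = TRUE), 3, 3)
    expect_identical(lbp_code(w), oracle_lbp_code(w))
  }
})

test_that("lbp_transform equals the per-pixel oracle and handles 1x1 input", {
  expect_equal(lbp_transform(matrix(0, 1, 1)), matrix(255L, 1, 1))
  expect_equal(lbp_transform(matrix(7, 1, 1)), matrix(0L, 1, 1))
  img <- random_image(16, 16, seed = 7)
  expect_identical(lbp_transform(img), oracle_lbp_transform(img))
  img2 <- random_image(9, 13, seed = 8)   # non-square
  expect_identical(lbp_transform(img2), oracle_lbp_transform(img2))
})

test_that("histograms conserve pixel counts and match direct counting", {
  img <- matrix(255L, 10, 10)
  h <- histogram_256(img)
  expect_equal(unname(h[256]), 100)
  expect_equal(sum(h), 100)
  r <- random_image(12, 12, seed = 9)
  expect_equal(unname(histogram_256(r)), oracle_histogram(r))
  expect_equal(sum(histogram_256(r)), 144)
})

test_that("circular transition counts reproduce the worked bit patterns", {
  # 01000000, 00000111, 01010100, 11001001
  expect_equal(circular_transitions(c(64L, 7L, 84L, 201L)), c(2L, 2L, 6L, 4L))
  expect_equal(circular_transitions(0L), 0L)
  expect_equal(circular_transitions(255L), 0L)
  # transitions of a circular pattern are always even
  expect_true(all(circular_transitions(0:255) %% 2 == 0))
  expect_equal(circular_transitions(0:255),
               vapply(0:255, oracle_transitions, numeric(1)))
})

test_that("exactly 58 of the 256 codes are uniform", {
  expect_true(is_uniform(7))     # 00000111
  expect_false(is_uniform(84))   # 01010100
  expect_equal(sum(is_uniform(0:255)), 58)
})

test_that("uniform histogram routes codes to 58 + 1 bins", {
  img255 <- matrix(255L, 8, 8)
  h <- uniform_histogram_59(img255)
  expect_equal(length(h), 59)
  expect_equal(unname(h[names(h) == "u255"]), 64)
  expect_equal(sum(h), 64)
  img85 <- matrix(85L, 8, 8)   # 01010101: 8 transitions, non-uniform
  h2 <- uniform_histogram_59(img85)
  expect_equal(unname(h2[["nonuniform"]]), 64)
  # oracle: assemble from is_uniform + counting
  r <- random_image(20, 20, seed = 10)
  codes <- lbp_transform(r)
  h3 <- uniform_histogram_59(codes)
  uc <- (0:255)[is_uniform(0:255)]
  expect_equal(unname(h3[seq_len(58)]),
               vapply(uc, function(k) sum(codes == k), numeric(1)))
  expect_equal(unname(h3[[59]]), sum(!is_uniform(codes)))
  expect_equal(sum(h3), 400)
})

test_that("gabor kernel matches the analytic formula", {
  p <- gabor_params()
  k <- gabor_kernel(p)
  half <- (p$kernel_side + 1) / 2
  expect_equal(k[half, half], 1)                      # centre value
  expect_equal(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))])  # even
  # independent scalar evaluation at offsets (x=1,y=0) and (x=0,y=1)
  g <- function(x, y) {
    xp <- x * cos(p$theta) + y * sin(p$theta)
    yp <- -x * sin(p$theta) + y * cos(p$theta)
    exp(-(xp^2 + p$gamma^2 * yp^2) / (2 * p$sigma^2)) *
      cos(2 * pi * xp / p$lambda + p$phi)
  }
  expect_equal(k[half, half + 1], g(1, 0))   # one column right
  expect_equal(k[half + 1, half], g(0, 1))   # one row down
  expect_equal(k[half + 3, half - 2], g(-2, 3))
})

test_that("gabor filtering keeps dimensions and valid intensity range", {
  z <- matrix(0L, 20, 20)
  expect_equal(gabor_filter_image(z), z)
  r <- random_image(24, 24, seed = 12)
  out <- gabor_filter_image(r)
  expect_equal(dim(out), dim(r))
  expect_true(all(out >= 0 & out <= 255))
})

test_that("a centred impulse reproduces the rescaled kernel", {
  p <- gabor_params(kernel_side = 11)
  img <- matrix(0, 31, 31)
  img[16, 16] <- 255
  out <- gabor_filter_image(img, p)
  k <- gabor_kernel(p)
  expected <- matrix_to_image(255 * k[rev(1:11), rev(1:11)])
  expect_equal(out[11:21, 11:21], expected)
})

test_that("srm filter implements the row-times-block transform", {
  z <- matrix(0L, 6, 6)
  expect_equal(srm_filter(z), z)
  # all-100 block: every cell (100*100*3)/100 = 300 -> clamped to 255
  b <- matrix(100L, 3, 3)
  expect_equal(srm_filter(b), matrix(255L, 3, 3))
  # hand-computed block
  m <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90), 3, byrow = TRUE)
  got <- srm_filter(m)
  expected <- floor((m %*% m) / 100)
  expect_equal(got, matrix(as.integer(pmin(expected, 255)), 3))
  # remainder rows/columns pass through untouched (128 mod 3 = 2)
  big <- random_image(128, 128, seed = 13)
  out <- srm_filter(big)
  expect_equal(out[127:128, ], big[127:128, ])
  expect_equal(out[, 127:128], big[, 127:128])
  expect_true(all(out >= 0 & out <= 255))
})

test_that("nbs filter is right-neighbour subtraction clamped at zero", {
  cst <- matrix(99L, 5, 5)
  expect_equal(nbs_filter(cst), matrix(0L, 5, 5))
  dec <- matrix(rep(c(9L, 5L, 1L), each = 3), 3, byrow = FALSE)
  out <- nbs_filter(dec)
  expect_equal(out[, 1], rep(4L, 3))
  expect_equal(out[, 2], rep(4L, 3))
  expect_equal(out[, 3], rep(0L, 3))   # last column has no right neighbour
  inc <- matrix(rep(1:5 * 10L, each = 4), 4)
  expect_equal(nbs_filter(inc), matrix(0L, 4, 5))
  r <- random_image(10, 10, seed = 14)
  out2 <- nbs_filter(r)
  expect_equal(out2[, 1:9], matrix(pmax(r[, 1:9] - r[, 2:10], 0L), 10))
  expect_true(all(out2 >= 0 & out2 <= 255))
})
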