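# Neighbour offsets (row, col) clockwise from top-left; the first-visited
# neighbour (top-left) contributes the most significant bit.
.lbp_offsets <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L),
  dc = c(-1L, 0L, 1L, 1L, 1L, 0L, -1L, -1L)
)
.lbp_weights <- 2L^(7:0)

#' Local binary pattern code of a 3 x 3 window
#'
#' Each of the eight neighbours is compared with the centre pixel: the bit is
#' 0 when the centre is strictly greater than the neighbour and 1 otherwise.
#' Neighbours are visited clockwise starting at the top-left corner, which
#' contributes the most significant bit of the resulting 8-bit code.
#'
#' @param window A 3 x 3 numeric matrix of intensities.
#' @return An integer in 0..255.
#' @export
lbp_code <- function(window) {
  window <- as.matrix(window)
  stopifnot(all(dim(window) == c(3L, 3L)), all(is.finite(window)))
  centre <- window[2L, 2L]
  bits <- integer(8)
  for (i in 1:8) {
    nb <- window[2L + .lbp_offsets[i, "dr"], 2L + .lbp_offsets[i, "dc"]]
    bits[i] <- as.integer(nb >= centre)
  }
  as.integer(sum(bits * .lbp_weights))
}

#' Local binary pattern transform of an image
#'
#' Replaces every pixel by the LBP code of its 3 x 3 neighbourhood; the image
#' border is zero-padded, so edge pixels compare against implicit zeros.
#'
#' @param img A numeric matrix of intensities.
#' @return An integer matrix of the same dimensions with values in 0..255.
#' @export
lbp_transform <- function(img) {
  img <- as.matrix(img)
  h <- nrow(img)
  w <- ncol(img)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- img
  codes <- matrix(0L, h, w)
  for (i in 1:8) {
    nb <- pad[(2:(h + 1L)) + .lbp_offsets[i, "dr"],
              (2:(w + 1L)) + .lbp_offsets[i, "dc"], drop = FALSE]
    codes <- codes + .lbp_weights[i] * (nb >= img)
  }
  matrix(as.integer(codes), h, w)
}

#' 256-bin histogram of an LBP-coded image
#'
#' @param lbp_img Integer matrix with values in 0..255.
#' @return An integer vector of length 256 (named `lbp000`..`lbp255`); bin k+1
#'   counts the pixels with code k, and the bins sum to the pixel count.
#' @export
histogram_256 <- function(lbp_img) {
  v <- as.integer(lbp_img)
  stopifnot(all(v >= 0L & v <= 255L))
  h <- tabulate(v + 1L, nbins = 256L)
  names(h) <- sprintf("lbp%03d", 0:255)
  h
}

#' Number of circular 0-1 transitions in an 8-bit code
#'
#' The 8-bit pattern is read circularly (bit 7 adjacent to bit 0) and the
#' number of adjacent bit changes is counted; the count is always even.
#'
#' @param code Integer vector with values in 0..255.
#' @return Integer vector of transition counts.
#' @export
circular_transitions <- function(code) {
  stopifnot(all(code >= 0 & code <= 255))
  vapply(as.integer(code), function(v) {
    bits <- as.integer(intToBits(v)[1:8])
    sum(bits != bits[c(2:8, 1)])
  }, integer(1))
}

#' Is an LBP code a uniform pattern?
#'
#' A pattern is uniform when its circular bit string has at most two 0-1 or
#' 1-0 transitions; exactly 58 of the 256 codes qualify.
#'
#' @param code Integer vector with values in 0..255.
#' @return Logical vector.
#' @export
is_uniform <- function(code) {
  circular_transitions(code) <= 2L
}

# Ascending list of the 58 uniform codes, computed once at load time.
.uniform_codes <- function() {
  which(vapply(0:255, function(v) {
    bits <- as.integer(intToBits(v)[1:8])
    sum(bits != bits[c(2:8, 1)]) <= 2L
  }, logical(1))) - 1L
}

#' 59-bin uniform-LBP histogram
#'
#' The 58 uniform codes get one bin each (in ascending code order); a single
#' catch-all 59th bin aggregates every non-uniform code.
#'
#' @param lbp_img Integer matrix with values in 0..255.
#' @return An integer vector of length 59 (named `u<code>` for the uniform
#'   bins plus `nonuniform`); the bins sum to the pixel count.
#' @export
uniform_histogram_59 <- function(lbp_img) {
  full <- histogram_256(lbp_img)
  uc <- .uniform_codes()
  h <- c(full[uc + 1L], sum(full[-(uc + 1L)]))
  names(h) <- c(sprintf("u%03d", uc), "nonuniform")
  h
}

#' Gabor filter parameters
#'
#' Defaults are the band-pass configuration used throughout the package:
#' wavelength `lambda = 10` pixels, orientation `theta = 0`, phase `phi = 0`,
#' aspect ratio `gamma = 0.02` and Gaussian envelope `sigma = 5` pixels, with
#' a 31 x 31 kernel (about six sigma across).
#'
#' @param lambda Sinusoid wavelength in pixels.
#' @param theta Orientation angle of the normal to the sinusoid, radians.
#' @param phi Phase offset of the sinusoid, radians.
#' @param gamma Spatial aspect ratio of the Gaussian envelope.
#' @param sigma Standard deviation of the Gaussian envelope, pixels.
#' @param kernel_side Odd kernel side length, >= 3.
#' @return A list of class `gabor_params`.
#' @export
gabor_params <- function(lambda = 10, theta = 0, phi = 0, gamma = 0.02,
                         sigma = 5, kernel_side = 31L) {
  stopifnot(lambda > 0, gamma > 0, sigma > 0,
            kernel_side >= 3L, kernel_side %% 2L == 1L)
  structure(list(lambda = lambda, theta = theta, phi = phi, gamma = gamma,
                 sigma = sigma, kernel_side = as.integer(kernel_side)),
            class = "gabor_params")
}

#' Real-valued Gabor kernel
#'
#' Entry at offset (x, y) from the kernel centre is
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + phi)`
#' with the rotated frame `x' = x cos(theta) + y sin(theta)`,
#' `y' = -x sin(theta) + y cos(theta)`; x runs along columns and y along
#' rows. This is the real (cosine) part of the complex Gabor function.
#'
#' @param p A [gabor_params()] object.
#' @return A numeric `kernel_side` x `kernel_side` matrix.
#' @export
gabor_kernel <- function(p = gabor_params()) {
  stopifnot(inherits(p, "gabor_params"))
  half <- (p$kernel_side - 1L) %/% 2L
  off <- -half:half
  x <- matrix(off, p$kernel_side, p$kernel_side, byrow = TRUE)  # column offset
  y <- matrix(off, p$kernel_side, p$kernel_side)                # row offset
  xp <- x * cos(p$theta) + y * sin(p$theta)
  yp <- -x * sin(p$theta) + y * cos(p$theta)
  exp(-(xp^2 + p$gamma^2 * yp^2) / (2 * p$sigma^2)) *
    cos(2 * pi * xp / p$lambda + p$phi)
}

# Zero-padded 2D cross-correlation of an image with a (symmetric) kernel,
# vectorised as a shift-and-accumulate over kernel entries.
convolve2_zero <- function(img, kernel) {
  h <- nrow(img)
  w <- ncol(img)
  kh <- nrow(kernel)
  kw <- ncol(kernel)
  rh <- (kh - 1L) %/% 2L
  rw <- (kw - 1L) %/% 2L
  pad <- matrix(0, h + 2L * rh, w + 2L * rw)
  pad[(rh + 1L):(rh + h), (rw + 1L):(rw + w)] <- img
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      kij <- kernel[i, j]
      if (kij == 0) next
      out <- out + kij * pad[(i):(i + h - 1L), (j):(j + w - 1L), drop = FALSE]
    }
  }
  out
}

#' Gabor-filter a grayscale image
#'
#' Convolves the image with the real Gabor kernel (zero-padded borders) and
#' min-max rescales the response back to integer intensities in \[0, 255\]
#' so that the LBP transform can be applied to the filtered image.
#'
#' @param img A numeric matrix of intensities.
#' @param p A [gabor_params()] object.
#' @return An integer matrix of the same dimensions with values in 0..255.
#' @export
gabor_filter_image <- function(img, p = gabor_params()) {
  img <- as.matrix(img)
  resp <- convolve2_zero(img, gabor_kernel(p))
  matrix_to_image(resp)
}

#' Separate-row-multiplication (SRM) filter
#'
#' The image is tiled with non-overlapping 3 x 3 blocks. Within each block B
#' every row r is replaced by `floor((r %*% B) / 100)`, clamped to 255, and
#' the transformed rows are reassembled in order. Trailing rows/columns not
#' covered by a complete block pass through unchanged. The result is a
#' nonlinear local-contrast map that is then summarised with a uniform-LBP
#' histogram.
#'
#' @param img An integer matrix with values in 0..255, at least 3 x 3.
#' @return An integer matrix of the same dimensions with values in 0..255.
#' @export
srm_filter <- function(img) {
  img <- as.matrix(img)
  h <- nrow(img)
  w <- ncol(img)
  if (h < 3L || w < 3L) stop("srm_filter requires an image of at least 3 x 3",
                             call. = FALSE)
  out <- img
  for (bi in seq_len(h %/% 3L)) {
    rows <- (3L * bi - 2L):(3L * bi)
    for (bj in seq_len(w %/% 3L)) {
      cols <- (3L * bj - 2L):(3L * bj)
      B <- img[rows, cols, drop = FALSE]
      res <- floor((B %*% B) / 100)  # row i of B %*% B is (r_i . B)
      out[rows, cols] <- pmin(res, 255)
    }
  }
  matrix(as.integer(out), h, w)
}

#' Neighbor-block-subtraction (NBS) filter
#'
#' Each 3 x 3 block is subtracted from the block whose centre sits one pixel
#' to its right; since the sliding blocks overlap in all but one column and
#' every difference is computed from the original image, the transform
#' reduces to the per-pixel closed form
#' `out(x, y) = max(0, in(x, y) - in(x, y + 1))`, with the last column
#' (which has no right-hand neighbour) set to 0. Negative differences are
#' clamped to zero so the result remains a valid intensity image.
#'
#' @param img An integer matrix with values in 0..255, at least 3 x 3.
#' @return An integer matrix of the same dimensions with values in 0..255.
#' @export
nbs_filter <- function(img) {
  img <- as.matrix(img)
  h <- nrow(img)
  w <- ncol(img)
  if (h < 3L || w < 3L) stop("nbs_filter requires an image of at least 3 x 3",
                             call. = FALSE)
  out <- matrix(0L, h, w)
  out[, seq_len(w - 1L)] <- pmax(img[, seq_len(w - 1L), drop = FALSE] -
                                   img[, 2:w, drop = FALSE], 0L)
  matrix(as.integer(out), h, w)
}
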