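#' Pairwise Euclidean distance matrix of a coordinate set
#'
#' The tertiary structure is flattened to a symmetric matrix of pairwise
#' Euclidean distances (in Angstrom) between its representative coordinates;
#' rendered as a grayscale image this matrix is the input of every texture
#' descriptor in the package.
#'
#' @param coords An n x 3 numeric matrix of coordinates.
#' @return An n x n symmetric numeric matrix with a zero diagonal.
#' @export
pairwise_distance_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) < 1L) {
    stop("coords must be an n x 3 numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("non-finite coordinate", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  d
}

#' Map a distance matrix to an 8-bit grayscale image
#'
#' Linear min-max scaling of the matrix entries to integer intensities in
#' \[0, 255\]. A constant matrix (no dynamic range) maps to an all-zero
#' image. The full symmetric matrix is imaged, so the characteristic
#' diagonal / symmetric texture of a contact-map image is preserved.
#'
#' @param d A numeric matrix (typically from [pairwise_distance_matrix()]).
#' @return An integer matrix of the same dimensions with values in 0..255.
#' @export
matrix_to_image <- function(d) {
  d <- as.matrix(d)
  if (!all(is.finite(d))) stop("non-finite matrix entry", call. = FALSE)
  rng <- range(d)
  if (rng[1] == rng[2]) {
    img <- matrix(0L, nrow(d), ncol(d))
  } else {
    img <- matrix(as.integer(round(255 * (d - rng[1]) / (rng[2] - rng[1]))),
                  nrow(d), ncol(d))
  }
  img
}

# Keys cubic-convolution kernel, a = -0.5 (the standard bicubic resampler).
cubic_weight <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

# Resample the columns of `m` (length `n_src` each) to `n_dst` rows by cubic
# convolution with half-pixel centre alignment and clamped borders.
cubic_resample_rows <- function(m, n_dst) {
  n_src <- nrow(m)
  scale <- n_src / n_dst
  centre <- (seq_len(n_dst) - 0.5) * scale - 0.5
  base <- floor(centre)
  frac <- centre - base
  out <- matrix(0, n_dst, ncol(m))
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 0), n_src - 1L) + 1L
    out <- out + cubic_weight(k - frac) * m[idx, , drop = FALSE]
  }
  out
}

#' Rescale a grayscale image by bicubic interpolation
#'
#' Separable cubic-convolution resampling (Keys kernel, a = -0.5) with
#' half-pixel centre alignment and edge replication, then rounding and
#' clamping back to \[0, 255\]. Structures of different sizes thereby map to
#' images of one common dimension (128 x 128 by default) so their texture
#' histograms are comparable. A 1 x 1 input is rejected: a single-atom
#' structure carries no pairwise-distance texture and is excluded upstream.
#'
#' @param img An integer matrix with values in 0..255, at least 2 x 2.
#' @param side Output side length (the output is `side` x `side`).
#' @return An integer `side` x `side` matrix with values in 0..255.
#' @export
rescale_image <- function(img, side = 128L) {
  img <- as.matrix(img)
  if (nrow(img) < 2L || ncol(img) < 2L) {
    stop("cannot rescale a ", nrow(img), " x ", ncol(img),
         " image: structures yielding images smaller than 2 x 2 are excluded",
         call. = FALSE)
  }
  side <- as.integer(side)
  stopifnot(side >= 1L)
  out <- cubic_resample_rows(img, side)
  out <- t(cubic_resample_rows(t(out), side))
  matrix(as.integer(pmin(pmax(round(out), 0), 255)), side, side)
}

#' Distance-matrix image of a molecular structure
#'
#' Convenience pipeline: coordinates (alpha carbons for proteins, all atoms
#' for ligands) -> pairwise distance matrix -> grayscale image, optionally
#' rescaled to `side` x `side`.
#'
#' @param s A `mol_structure`.
#' @param scaled Rescale to `side` x `side`?
#' @param side Side length used when `scaled = TRUE`.
#' @return An integer matrix with values in 0..255.
#' @export
structure_image <- function(s, scaled = FALSE, side = 128L) {
  coords <- structure_coordinates(s)
  if (nrow(coords) < 2L) {
    stop("structure '", s$id, "' has a single coordinate; its 1 x 1 image is",
         " excluded from feature extraction", call. = FALSE)
  }
  img <- matrix_to_image(pairwise_distance_matrix(coords))
  if (scaled) img <- rescale_image(img, side)
  img
}

#' Write a grayscale image to a PNG file
#'
#' Inspection helper; requires the `png` package.
#'
#' @param img Integer matrix with values in 0..255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  png::writePNG(img / 255, path)
  invisible(path)
}
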