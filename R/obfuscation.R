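## Data-level obfuscation behind privacy-preserving visualization: points are
## either replaced by the centroid of their k-nearest neighbourhood or
## perturbed with seeded Gaussian noise whose variance is a controlled
## fraction of the data variance. Both methods are gated by the corresponding
## disclosure filters.

#' Replace points by their k-nearest-neighbour centroids
#'
#' Each point's neighbourhood is the point itself plus its `k - 1` nearest
#' other points by Euclidean distance, computed on per-dimension standardized
#' coordinates (each dimension divided by its standard deviation, so axis
#' units do not dominate); the output is the arithmetic centroid of the
#' neighbourhood on the original scale. Fully deterministic: distance ties
#' are broken by lowest input index. With `k = n` every output collapses to
#' the global centroid.
#'
#' @param points An n x d numeric matrix (d = 1 or 2); a plain vector is
#'   treated as one-dimensional.
#' @param k Neighbourhood size (self included); must pass [check_knn()].
#' @param s Disclosure settings.
#' @return An object of class `obfuscated_points` with `coords` (n x d),
#'   `method = "knn"` and `k`.
#' @export
knn_centroid_obfuscate <- function(points, k, s = default_settings()) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  points <- as.matrix(points)
  n <- nrow(points)
  dec <- check_knn(k, n, s)
  if (!dec$allowed) {
    stop_sdc(if (k > n) "KNN_INFEASIBLE" else "KNN_BLOCKED")
  }
  sds <- apply(points, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  std <- sweep(points, 2, sds, "/")
  d2 <- as.matrix(stats::dist(std))^2
  coords <- points
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d2[i, others], others)]
    nb <- c(i, ord[seq_len(k - 1L)])
    coords[i, ] <- colMeans(points[nb, , drop = FALSE])
  }
  dimnames(coords) <- dimnames(points)
  structure(list(coords = coords, method = "knn", k = k),
            class = "obfuscated_points")
}

#' Perturb a variable with seeded Gaussian noise
#'
#' Returns `x + e` where `e` is zero-mean Gaussian with variance
#' `noise_fraction * var(x)`, drawn with the given seed (reproducible). A
#' constant input has zero variance, hence mathematically zero noise, and is
#' returned unchanged. The fraction must pass [check_noise_fraction()]:
#' too-small noise leaves values effectively un-obfuscated.
#'
#' @param x Numeric vector, length at least 2.
#' @param noise_fraction Noise variance as a fraction of `var(x)`.
#' @param seed Integer seed for the draw.
#' @param s Disclosure settings.
#' @return An object of class `obfuscated_points` with `coords` (n x 1),
#'   `method = "noise"`, `noise_fraction` and `seed`.
#' @export
gaussian_noise_obfuscate <- function(x, noise_fraction, seed,
                                     s = default_settings()) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x)) stop_sdc("BAD_ARGUMENT")
  dec <- check_noise_fraction(noise_fraction, s)
  if (!dec$allowed) stop_sdc("NOISE_BLOCKED")
  v <- stats::var(x)
  out <- if (v == 0) x else {
    x + with_seed(seed, stats::rnorm(length(x), 0, sqrt(noise_fraction * v)))
  }
  structure(list(coords = matrix(out, ncol = 1), method = "noise",
                 noise_fraction = noise_fraction, seed = seed),
            class = "obfuscated_points")
}

#' @export
print.obfuscated_points <- function(x, ...) {
  cat(sprintf("<obfuscated_points: %d x %d, method = %s>\n",
              nrow(x$coords), ncol(x$coords), x$method))
  invisible(x)
}

#' Write obfuscated points as CSV for external plotting
#'
#' @param x An `obfuscated_points` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obfuscated_csv <- function(x, path) {
  df <- as.data.frame(x$coords)
  names(df) <- c("x", "y")[seq_len(ncol(df))]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
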