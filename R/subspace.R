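# Affine-subspace modelling in LPC-coefficient space.  Each cognitive class
# (normal / impaired) is summarized by the best-fit flat of its training
# vectors: centroid plus the top-k principal directions.  A test vector is
# scored by its Euclidean distances to the two flats, combined into a
# bounded index.

#' Fit an affine subspace to a cloud of vectors
#'
#' Centroid is the mean; the basis holds the top-`k` principal directions of
#' the centred scatter (left singular vectors). `k = 0` gives a centroid-only
#' model whose distance is plain Euclidean distance to the mean.
#'
#' @param vectors Numeric matrix (rows = vectors) or list of numeric vectors.
#' @param k Subspace dimension, `0 <= k <= ncol` and `k < nrow`.
#' @param class_label Optional label ("normal"/"impaired") carried on the fit.
#' @return An object of class `affine_subspace`: list with `centroid`,
#'   `basis` (p x k, orthonormal columns), `dim`, `class_label`.
#' @export
fit_affine_subspace <- function(vectors, k, class_label = NA_character_) {
  if (is.list(vectors) && !is.matrix(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1L)
  check_finite_numeric(vectors, "vectors")
  n <- nrow(vectors); p <- ncol(vectors)
  check_scalar(k, "k", 0, Inf)
  k <- as.integer(k)
  if (k > p) stop_leapd("k (%d) exceeds vector dimension (%d)", k, p)
  if (k >= n) stop_leapd("k (%d) must be < number of vectors (%d)", k, n)
  centroid <- colMeans(vectors)
  basis <- matrix(numeric(0), nrow = p, ncol = 0L)
  if (k > 0L) {
    centred <- sweep(vectors, 2L, centroid)
    sv <- svd(centred, nu = 0L, nv = k)
    basis <- sv$v[, seq_len(k), drop = FALSE]
  }
  structure(
    list(centroid = centroid, basis = basis, dim = k,
         class_label = class_label),
    class = "affine_subspace"
  )
}

#' @export
print.affine_subspace <- function(x, ...) {
  cat(sprintf("<affine subspace: dim %d in R^%d, class %s>\n",
              x$dim, length(x$centroid), x$class_label))
  invisible(x)
}

#' Distance from a point to an affine subspace
#'
#' Euclidean norm of the component of `v - centroid` orthogonal to the
#' basis: the minimum distance from `v` to any point of the flat.
#'
#' @param v Numeric vector, same dimension as the centroid.
#' @param s An `affine_subspace`.
#' @return Nonnegative scalar.
#' @export
distance_to_subspace <- function(v, s) {
  check_finite_numeric(v, "v")
  if (length(v) != length(s$centroid)) {
    stop_leapd("vector dimension %d does not match subspace dimension %d",
               length(v), length(s$centroid))
  }
  d <- v - s$centroid
  if (s$dim > 0L) {
    # explicit residual vector avoids cancellation when v lies on the flat
    d <- d - drop(s$basis %*% crossprod(s$basis, d))
  }
  sqrt(sum(d^2))
}

# Vectorized distances for a matrix of points (rows); used by training.
distances_to_subspace <- function(V, s) {
  D <- sweep(V, 2L, s$centroid)
  if (s$dim > 0L) {
    D <- D - (D %*% s$basis) %*% t(s$basis)
  }
  sqrt(rowSums(D^2))
}

#' Bounded per-electrode index from two subspace distances
#'
#' `index = d_impaired / (d_normal + d_impaired)`: 1 when the vector lies on
#' the normal-class flat, 0 when it lies on the impaired-class flat, 0.5 for
#' the degenerate 0/0 case.  Larger index means farther from the impaired
#' subspace, i.e. better cognition, which makes the index correlate
#' positively with cognitive scores.
#'
#' @param d_normal Distance to the normal-class subspace (D1), >= 0.
#' @param d_impaired Distance to the impaired-class subspace (D2), >= 0.
#' @return Scalar in [0, 1]. Vectorized over both arguments.
#' @export
leapd_index <- function(d_normal, d_impaired) {
  check_finite_numeric(d_normal, "d_normal")
  check_finite_numeric(d_impaired, "d_impaired")
  if (any(d_normal < 0) || any(d_impaired < 0)) {
    stop_leapd("distances must be nonnegative")
  }
  tot <- d_normal + d_impaired
  out <- ifelse(tot > 0, d_impaired / tot, 0.5)
  as.numeric(out)
}

#' Fuse per-electrode indices by geometric mean
#'
#' `(prod indices)^(1/n)` with an explicit zero short-circuit so an exact
#' pole (index 0) propagates instead of being log-flooring'd away.
#'
#' @param indices Numeric vector of per-electrode indices in [0, 1].
#' @return Scalar in [0, 1].
#' @export
combine_channels <- function(indices) {
  check_finite_numeric(indices, "indices")
  if (length(indices) == 0L) stop_leapd("no indices to combine")
  if (any(indices < 0 | indices > 1)) {
    stop_leapd("indices must lie in [0, 1]")
  }
  if (any(indices == 0)) return(0)
  exp(mean(log(indices)))
}
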