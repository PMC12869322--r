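# Lower-triangle feature indexing for region-pair (FC) features.
#
# Feature order is fixed package-wide as column-major over the strict lower
# triangle of the R x R connectivity matrix: (2,1),(3,1),...,(R,1),(3,2),...
# This is exactly the order produced by `M[lower.tri(M)]` in R, so vectorized
# matrices and indexed features can never disagree.

#' Number of region-pair features for R regions
#'
#' @param n_rois number of regions (ROIs).
#' @return `n_rois * (n_rois - 1) / 2`.
#' @examples
#' n_fc_features(379)  # 71631
#' @export
n_fc_features <- function(n_rois) {
  stopifnot(is.numeric(n_rois), n_rois >= 2)
  as.integer(n_rois * (n_rois - 1) / 2)
}

#' Map a region pair to its feature position
#'
#' Regions are labelled 1..R; a pair (i, j) with i > j maps to a 1-based
#' position in the column-major lower-triangle order.
#'
#' @param i,j region labels, `i > j >= 1`. Vectorized.
#' @param n_rois total region count R.
#' @return integer feature positions in `1..n_fc_features(n_rois)`.
#' @seealso [inverse_pair_index()]
#' @export
pair_index <- function(i, j, n_rois) {
  stopifnot(length(n_rois) == 1, n_rois >= 2)
  if (any(i <= j)) stop("pair_index() requires i > j (strict lower triangle)")
  if (any(j < 1) || any(i > n_rois)) {
    stop("region labels out of range 1..", n_rois)
  }
  as.integer((j - 1) * n_rois - j * (j - 1) / 2 + (i - j))
}

#' Recover the region pair from a feature position
#'
#' Inverse of [pair_index()]: round-trips exactly for every position.
#'
#' @param position 1-based feature position(s).
#' @param n_rois total region count R.
#' @return a two-column integer matrix with columns `i`, `j` (`i > j`).
#' @export
inverse_pair_index <- function(position, n_rois) {
  stopifnot(length(n_rois) == 1, n_rois >= 2)
  m <- n_fc_features(n_rois)
  if (any(position < 1) || any(position > m)) {
    stop("position out of range 1..", m)
  }
  # invert the quadratic column-offset formula, then fix up float edge cases
  jj <- ceiling(n_rois - 0.5 - sqrt((n_rois - 0.5)^2 - 2 * position))
  start <- (jj - 1) * n_rois - jj * (jj - 1) / 2  # last position before column jj
  jj <- jj - (position <= start)
  jj <- jj + (position > jj * n_rois - jj * (jj + 1) / 2)
  start <- (jj - 1) * n_rois - jj * (jj - 1) / 2
  ii <- position - start + jj
  cbind(i = as.integer(ii), j = as.integer(jj))
}

#' Names of all region-pair features
#'
#' @param n_rois region count R.
#' @return character vector `"ROI<i>_ROI<j>"` in feature order.
#' @export
fc_pair_names <- function(n_rois) {
  j <- rep.int(seq_len(n_rois - 1), (n_rois - 1):1)
  i <- sequence((n_rois - 1):1, from = 2:n_rois)
  paste0("ROI", i, "_ROI", j)
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the strict lower triangle in the package's fixed feature order.
#'
#' @param m symmetric matrix with zero (or ignorable) diagonal.
#' @return numeric feature vector of length `n_fc_features(nrow(m))`.
#' @export
fc_vectorize <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2)
  v <- m[lower.tri(m)]
  names(v) <- fc_pair_names(nrow(m))
  v
}

#' Rebuild a symmetric connectivity matrix from a feature vector
#'
#' Inverse of [fc_vectorize()]; the diagonal is set to zero.
#'
#' @param v feature vector of length `R(R-1)/2`.
#' @return an `R x R` symmetric matrix.
#' @export
fc_matrixize <- function(v) {
  m_feat <- length(v)
  r <- (1 + sqrt(1 + 8 * m_feat)) / 2
  if (abs(r - round(r)) > 1e-8) {
    stop("length ", m_feat, " is not R(R-1)/2 for any integer R")
  }
  r <- as.integer(round(r))
  out <- matrix(0, r, r)
  out[lower.tri(out)] <- v
  out + t(out)
}
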