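# PCA of FC tables via singular value decomposition of the centered data
# matrix. Features are not standardized: FC features share the Fisher-z
# scale, so the covariance (not correlation) structure is the object of
# interest.

#' Principal component analysis of an FC table
#'
#' SVD of the column-centered subjects x features matrix. At most
#' `min(n - 1, features)` components are kept (centering removes one
#' dimension). The sign of each component is fixed by requiring its
#' largest-magnitude weight to be positive, so results are reproducible
#' across platforms; all downstream direction labels are computed from
#' group means and are therefore sign-invariant anyway.
#'
#' @param x subjects x features numeric matrix (n >= 3).
#' @return an object of class `fc_pca`: `weights` (components x features,
#'   orthonormal rows), `scores` (subjects x components), `explained`
#'   (variance fractions, non-increasing), `feature_means` (centering
#'   vector).
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("PCA needs at least 3 subjects")
  if (ncol(x) < 1) stop("need at least one feature")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  k <- min(n - 1L, ncol(x))
  sv <- svd(xc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  weights <- t(sv$v)
  scores <- sv$u %*% diag(d, k, k)
  # deterministic sign: largest-|weight| entry positive per component
  for (comp in seq_len(k)) {
    j <- which.max(abs(weights[comp, ]))
    if (weights[comp, j] < 0) {
      weights[comp, ] <- -weights[comp, ]
      scores[, comp] <- -scores[, comp]
    }
  }
  rownames(weights) <- paste0("PC", seq_len(k))
  colnames(weights) <- colnames(x)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  structure(list(weights = weights, scores = scores,
                 explained = d^2 / sum(sv$d^2), feature_means = mu,
                 n_subjects = n),
            class = "fc_pca")
}

#' @export
print.fc_pca <- function(x, ...) {
  cat("<fc_pca> ", nrow(x$weights), " components x ", ncol(x$weights),
      " features (", x$n_subjects, " subjects)\n", sep = "")
  cat("explained variance, top 5: ",
      paste(signif(utils::head(x$explained, 5), 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Project new subjects onto a fitted component
#'
#' Scores new data against a discovery-derived component: subjects are
#' centered with the MODEL's feature means (never the new data's own), then
#' projected onto the component's weight vector.
#'
#' @param pc an [fit_pca()] model.
#' @param component component number.
#' @param newdata subjects x features matrix with the model's feature
#'   count.
#' @return numeric vector of per-subject scores.
#' @export
project_scores <- function(pc, component, newdata) {
  stopifnot(inherits(pc, "fc_pca"))
  component <- check_component(pc, component)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(pc$weights)) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         ncol(pc$weights))
  }
  drop(sweep(newdata, 2, pc$feature_means) %*% pc$weights[component, ])
}

check_component <- function(pc, component) {
  component <- as.integer(component)
  if (length(component) != 1 || is.na(component) || component < 1 ||
      component > nrow(pc$weights)) {
    stop("component must be a single index in 1..", nrow(pc$weights))
  }
  component
}

#' Benjamini-Hochberg FDR step-up
#'
#' Rejection set of the BH step-up rule at level `q` (largest k with
#' `p_(k) <= k q / m`; reject everything at or below `p_(k)`) together with
#' the BH-adjusted q-values.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with logical `reject` and numeric `q_value` (both empty for
#'   empty input).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(list(reject = logical(0), q_value = numeric(0)))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p, method = "BH")
  list(reject = !is.na(qv) & qv <= q, q_value = qv)
}
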