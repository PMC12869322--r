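# Effect-size computation and robustness audits: Hedge's g per feature,
# per-method effect summaries across discovery/validation cohorts,
# selection overlap, and cross-dataset effect consistency.

#' Per-feature Hedge's g
#'
#' Standardized patient-minus-control mean difference with the
#' small-sample correction `J = 1 - 3 / (4 N - 9)` applied to the pooled-SD
#' Cohen's d. Features with zero pooled SD get `NA` (flagged, excluded
#' from summaries).
#'
#' @param x subjects x features matrix.
#' @param labels binary diagnosis labels, both groups >= 2.
#' @param small_sample apply the correction `J` (set `FALSE` for plain
#'   Cohen's d).
#' @return numeric vector of per-feature effect sizes.
#' @export
hedges_g <- function(x, labels, small_sample = TRUE) {
  x <- as.matrix(x)
  y <- binary_labels(labels, nrow(x))
  n1 <- sum(y$patient); n0 <- sum(!y$patient)
  if (n1 < 2 || n0 < 2) stop("both groups need >= 2 subjects")
  m1 <- colMeans(x[y$patient, , drop = FALSE])
  m0 <- colMeans(x[!y$patient, , drop = FALSE])
  v1 <- apply(x[y$patient, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[!y$patient, , drop = FALSE], 2, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  g <- (m1 - m0) / sp
  g[sp == 0] <- NA_real_
  if (any(sp == 0)) {
    warning(sum(sp == 0), " feature(s) with zero pooled SD set to NA")
  }
  if (small_sample) g <- g * (1 - 3 / (4 * (n1 + n0) - 9))
  g
}

#' Summarize effect sizes of selected features across datasets
#'
#' For every selection method and every dataset, the mean, median, and SD
#' of the selected features' |g| (absolute values by default, since
#' selections mix over- and under-connectivity; signed summaries via
#' `absolute = FALSE`).
#'
#' @param g_tables named list of per-feature effect-size vectors, one per
#'   dataset (e.g. `list(discovery = ..., validation = ...)`), all over
#'   the same feature space.
#' @param selections named list of [fc_selection()] objects.
#' @param absolute summarize |g| (default) or signed g.
#' @return a data frame with one row per (method, dataset).
#' @export
effect_summary <- function(g_tables, selections, absolute = TRUE) {
  stopifnot(is.list(g_tables), length(g_tables) >= 1,
            is.list(selections), length(selections) >= 1)
  p <- length(g_tables[[1]])
  if (!all(vapply(g_tables, length, 1L) == p)) {
    stop("all effect-size vectors must share one feature space")
  }
  rows <- lapply(names(selections), function(meth) {
    sel <- selections[[meth]]
    stopifnot(inherits(sel, "fc_selection"))
    if (sel$n_features != p) stop("selection '", meth,
                                  "' is over a different feature space")
    do.call(rbind, lapply(names(g_tables), function(ds) {
      if (length(sel$positions) == 0) {
        warning("empty selection for method '", meth, "'")
        return(data.frame(method = meth, dataset = ds, n_selected = 0L,
                          mean = NA_real_, median = NA_real_,
                          sd = NA_real_))
      }
      g <- g_tables[[ds]][sel$positions]
      g <- g[!is.na(g)]
      if (absolute) g <- abs(g)
      data.frame(method = meth, dataset = ds,
                 n_selected = length(sel$positions), mean = mean(g),
                 median = stats::median(g), sd = stats::sd(g))
    }))
  })
  do.call(rbind, rows)
}

#' Overlap between two selections
#'
#' @param a,b [fc_selection()] objects over the same feature space.
#' @return list with `count` and the `common` positions.
#' @export
selection_overlap <- function(a, b) {
  stopifnot(inherits(a, "fc_selection"), inherits(b, "fc_selection"))
  if (a$n_features != b$n_features) {
    stop("selections live in different feature spaces (",
         a$n_features, " vs ", b$n_features, ")")
  }
  common <- intersect(a$positions, b$positions)
  list(count = length(common), common = sort(common))
}

#' Cross-dataset effect-size consistency
#'
#' Pearson correlation between two per-feature effect-size vectors (e.g.
#' discovery vs validation Hedge's g over all features).
#'
#' @param g_discovery,g_validation numeric vectors over the same feature
#'   space.
#' @return correlation coefficient.
#' @export
cross_dataset_consistency <- function(g_discovery, g_validation) {
  if (length(g_discovery) != length(g_validation)) {
    stop("effect-size vectors differ in length")
  }
  ok <- stats::complete.cases(g_discovery, g_validation)
  if (stats::sd(g_discovery[ok]) == 0 || stats::sd(g_validation[ok]) == 0) {
    stop("consistency undefined for a constant effect-size vector")
  }
  stats::cor(g_discovery[ok], g_validation[ok])
}
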