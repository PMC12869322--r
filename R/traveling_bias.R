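# Traveling-subject site-bias correction: because the same participants are
# scanned at several sites, the additive two-way model
#   value = participant effect + site effect + residual
# separates pure measurement bias (the site effect) from participant
# identity. This is a deliberately simplified version of full
# traveling-subject GLM harmonization: sampling bias and protocol terms are
# folded into the residual.

#' Estimate per-site measurement bias from traveling-subject runs
#'
#' Least-squares fit of the additive participant + site model, feature by
#' feature (one shared design, so all features are solved in one pass).
#' Site effects carry a run-count-weighted sum-to-zero constraint, making
#' them interpretable as deviations from the design-wide mean.
#'
#' @param ts a `traveling_set` (see [gen_traveling_subject()]) or a list
#'   with `values` (runs x features) and `labels` (with `participant`,
#'   `site`).
#' @return an object of class `site_bias`: sites x features bias matrix
#'   plus per-site run counts.
#' @export
traveling_bias_estimate <- function(ts) {
  values <- as.matrix(ts$values)
  labels <- ts$labels
  participant <- factor(labels$participant)
  site <- factor(labels$site)
  per_pt <- tapply(site, participant, function(s) length(unique(s)))
  if (any(per_pt < 2)) {
    stop("participant(s) with runs at < 2 sites: ",
         paste(names(per_pt)[per_pt < 2], collapse = ", "))
  }
  if (!incidence_connected(participant, site)) {
    stop("participant-site incidence graph is disconnected; ",
         "site biases are not identifiable across components")
  }
  # participant dummies absorb the intercept; site uses a reference level
  d_pt <- stats::model.matrix(~ participant - 1)
  d_site <- stats::model.matrix(~ site)[, -1, drop = FALSE]
  design <- cbind(d_pt, d_site)
  coefs <- qr.coef(qr(design), values)
  s_eff <- rbind(0, coefs[ncol(d_pt) + seq_len(ncol(d_site)), ,
                          drop = FALSE])
  counts <- as.integer(table(site))
  shift <- drop(crossprod(counts / sum(counts), s_eff))
  bias <- sweep(s_eff, 2, shift)  # weighted sum-to-zero
  rownames(bias) <- levels(site)
  structure(list(bias = bias, run_counts = stats::setNames(counts,
                                                           levels(site))),
            class = "site_bias")
}

# connectivity of the bipartite participant-site graph via label flooding
incidence_connected <- function(participant, site) {
  pairs <- unique(data.frame(p = as.integer(participant),
                             s = as.integer(site)))
  comp <- seq_len(nlevels(participant))
  repeat {
    site_comp <- tapply(comp[pairs$p], pairs$s, min)
    new_comp <- comp
    for (k in seq_len(nrow(pairs))) {
      new_comp[pairs$p[k]] <- min(new_comp[pairs$p[k]],
                                  site_comp[[as.character(pairs$s[k])]])
    }
    if (identical(new_comp, comp)) break
    comp <- new_comp
  }
  length(unique(comp)) == 1
}

#' Subtract traveling-subject site biases from an FC table
#'
#' @param x subjects x features matrix.
#' @param site per-subject site labels; every label must appear in `bias`.
#' @param bias a [traveling_bias_estimate()] result.
#' @return `x` minus the per-site bias vector, feature-wise.
#' @export
traveling_bias_subtract <- function(x, site, bias) {
  stopifnot(inherits(bias, "site_bias"))
  x <- as.matrix(x)
  site <- as.character(site)
  missing_sites <- setdiff(unique(site), rownames(bias$bias))
  if (length(missing_sites)) {
    stop("site(s) not covered by the bias table: ",
         paste(missing_sites, collapse = ", "))
  }
  if (ncol(x) != ncol(bias$bias)) stop("feature count mismatch")
  x - bias$bias[site, , drop = FALSE]
}

#' @export
print.site_bias <- function(x, ...) {
  cat("<site_bias> ", nrow(x$bias), " sites x ", ncol(x$bias),
      " features (run-count-weighted sum-to-zero)\n", sep = "")
  invisible(x)
}
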