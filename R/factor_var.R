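# Per-factor FC variability on traveling-subject data: how much of each
# feature's variation is attributable to who was scanned (participant),
# on what (scanner), how (protocol), and when (session, the run-level
# residual). The decomposition is an additive least-squares fit with
# sum-to-zero constraints -- an explicit simplification of full
# traveling-subject GLM variance modelling, flagged as such in the output.

#' Per-factor variability of traveling-subject FC
#'
#' For every feature, fits `value = grand mean + participant + scanner +
#' protocol + residual` by least squares with sum-to-zero contrasts (one
#' shared design; all features solved in a single pass). The variability
#' attributed to a factor is the SD of its fitted level effects; the
#' session variability is the residual SD. A factor observed at a single
#' level gets variability 0 with a warning.
#'
#' @param ts a `traveling_set` or list with `values` (runs x features) and
#'   `labels` (with `participant`, `scanner`, `protocol`).
#' @return an object of class `factor_variability`: features x 4 matrix
#'   with columns `participant`, `scanner`, `session`, `protocol`.
#' @export
factor_variability <- function(ts) {
  values <- as.matrix(ts$values)
  labels <- ts$labels
  fac_names <- c("participant", "scanner", "protocol")
  facs <- lapply(fac_names, function(f) factor(labels[[f]]))
  names(facs) <- fac_names
  active <- vapply(facs, nlevels, 1L) >= 2
  if (!all(active)) {
    warning("factor(s) with a single level reported as 0: ",
            paste(fac_names[!active], collapse = ", "))
  }
  for (f in fac_names[active]) {
    if (min(table(facs[[f]])) < 2) {
      stop("factor '", f, "' has level(s) with < 2 runs")
    }
  }
  dat <- as.data.frame(facs[active])
  design <- stats::model.matrix(
    ~ ., data = dat,
    contrasts.arg = lapply(dat, function(.) "contr.sum"))
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    stop("confounded design: factor effects are not separable")
  }
  coefs <- qr.coef(qd, values)
  resid <- values - design %*% coefs
  res_sd <- sqrt(colSums(resid^2) / (nrow(values) - qd$rank))

  out <- matrix(0, ncol(values), 4,
                dimnames = list(colnames(values),
                                c("participant", "scanner", "session",
                                  "protocol")))
  offset <- 1L  # skip intercept
  for (f in fac_names) {
    if (!active[[f]]) next
    nl <- nlevels(facs[[f]])
    rows <- offset + seq_len(nl - 1)
    eff <- coefs[rows, , drop = FALSE]
    eff <- rbind(eff, -colSums(eff))  # recover the dropped level
    out[, f] <- apply(eff, 2, stats::sd)
    offset <- offset + nl - 1L
  }
  out[, "session"] <- res_sd
  structure(out, class = c("factor_variability", "matrix"),
            note = paste("additive sum-to-zero least-squares",
                         "decomposition (simplified)"))
}

#' Compare per-factor variability across selections
#'
#' For each selection method and factor, summarizes the distribution of
#' per-feature variability over the selected features, and runs two-sided
#' Wilcoxon rank-sum tests between every pair of selections. Selections
#' with fewer than 3 features are skipped with a warning.
#'
#' @param fv a [factor_variability()] result.
#' @param selections named list of [fc_selection()] objects over the same
#'   feature space.
#' @return list with `summary` (method x factor means/SDs) and `tests`
#'   (pairwise rank-sum p-values per factor).
#' @export
variability_compare <- function(fv, selections) {
  stopifnot(inherits(fv, "factor_variability"))
  p <- nrow(fv)
  ok <- vapply(selections, function(s) {
    stopifnot(inherits(s, "fc_selection"))
    if (s$n_features != p) stop("selection feature space mismatch")
    length(s$positions) >= 3
  }, logical(1))
  if (any(!ok)) {
    warning("selection(s) with < 3 features skipped: ",
            paste(names(selections)[!ok], collapse = ", "))
  }
  selections <- selections[ok]
  factors <- colnames(fv)
  summary_df <- do.call(rbind, lapply(names(selections), function(meth) {
    v <- fv[selections[[meth]]$positions, , drop = FALSE]
    data.frame(method = meth, factor = factors,
               n_selected = length(selections[[meth]]$positions),
               mean = colMeans(v), sd = apply(v, 2, stats::sd),
               row.names = NULL)
  }))
  tests <- NULL
  if (length(selections) >= 2) {
    pairs <- utils::combn(names(selections), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      do.call(rbind, lapply(factors, function(fac) {
        wt <- stats::wilcox.test(fv[selections[[a]]$positions, fac],
                                 fv[selections[[b]]$positions, fac],
                                 exact = FALSE)
        data.frame(method_a = a, method_b = b, factor = fac,
                   statistic = unname(wt$statistic), p = wt$p.value)
      }))
    }))
  }
  list(summary = summary_df, tests = tests)
}
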