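# Selection results and the two FC selectors that operate feature-wise:
# weight-based selection from a chosen principal component, and the
# mass-univariate t-test baseline.

#' Construct a selection result
#'
#' Shared container for every feature-selection method in the package.
#'
#' @param method method name.
#' @param positions selected feature positions (unique, in range).
#' @param n_features size of the feature space.
#' @param weight,z,q_value optional per-selected-feature metadata.
#' @param direction optional per-feature `"over"`/`"under"` labels.
#' @param component chosen component (PCA method) or `NULL`.
#' @param q_level significance level used.
#' @return an object of class `fc_selection`.
#' @export
fc_selection <- function(method, positions, n_features, weight = NULL,
                         z = NULL, q_value = NULL, direction = NULL,
                         component = NULL, q_level = NA_real_) {
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stop("duplicated selected positions")
  if (length(positions) && (min(positions) < 1 ||
                            max(positions) > n_features)) {
    stop("selected positions out of range 1..", n_features)
  }
  structure(list(method = method, positions = positions,
                 n_features = as.integer(n_features), weight = weight,
                 z = z, q_value = q_value, direction = direction,
                 component = component, q_level = q_level),
            class = "fc_selection")
}

#' @export
print.fc_selection <- function(x, ...) {
  cat("<fc_selection> ", x$method, ": ", length(x$positions), " of ",
      x$n_features, " features", sep = "")
  if (!is.null(x$component)) cat(" (component ", x$component, ")", sep = "")
  if (!is.null(x$direction)) {
    cat("; ", sum(x$direction == "over"), " over / ",
        sum(x$direction == "under"), " under", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.fc_selection <- function(x, ...) {
  data.frame(position = x$positions,
             weight = x$weight %||% NA_real_,
             z = x$z %||% NA_real_,
             q_value = x$q_value %||% NA_real_,
             direction = x$direction %||% NA_character_)
}

#' Select FC features from a component's weights
#'
#' The core selection step of the PCA-based method: the chosen component's
#' weights are standardized across features (z-scored with the sample mean
#' and SD of the weights), each feature receives a two-tailed
#' standard-normal occurrence probability, and the BH step-up at level `q`
#' over all features determines the selected set. The alternative
#' `"percentile"` mode keeps the top share of |z| instead -- a deliberately
#' more permissive ("aggressive") variant for classifier feature supply.
#'
#' @param pc an [fit_pca()] model.
#' @param component component to read weights from.
#' @param q FDR level (`"fdr"` mode).
#' @param mode `"fdr"` (default) or `"percentile"`.
#' @param percentile |z| quantile kept under `"percentile"` mode.
#' @return an [fc_selection()] (directions unset; see
#'   [label_direction()]).
#' @export
select_features <- function(pc, component, q = 0.05,
                            mode = c("fdr", "percentile"),
                            percentile = 0.98) {
  stopifnot(inherits(pc, "fc_pca"))
  component <- check_component(pc, component)
  mode <- match.arg(mode)
  w <- pc$weights[component, ]
  sw <- stats::sd(w)
  if (sw == 0) stop("degenerate component ", component,
                    ": all weights equal")
  z <- (w - mean(w)) / sw
  if (mode == "fdr") {
    p <- 2 * stats::pnorm(-abs(z))
    bh <- bh_fdr(p, q)
    keep <- which(bh$reject)
    qv <- bh$q_value[keep]
  } else {
    keep <- which(abs(z) >= stats::quantile(abs(z), percentile))
    qv <- NULL
  }
  fc_selection(method = if (mode == "fdr") "pca" else "pca_aggressive",
               positions = keep, n_features = length(w),
               weight = unname(w[keep]), z = unname(z[keep]),
               q_value = qv, component = component, q_level = q)
}

#' Label selected features as over- or under-connectivity
#'
#' A selected FC is `"over"` when its patient-group mean exceeds the
#' control-group mean and `"under"` otherwise; exact ties are labelled
#' `"under"` and reported via a message. Directions come from group means,
#' not component weight signs, so they are invariant to the PCA sign
#' convention.
#'
#' @param x subjects x features matrix.
#' @param labels per-subject diagnosis labels (or a phenotype table with a
#'   `diagnosis` column); the patient group is the non-control level.
#' @param selection an [fc_selection()].
#' @return the selection with `direction` filled in.
#' @export
label_direction <- function(x, labels, selection) {
  stopifnot(inherits(selection, "fc_selection"))
  if (length(selection$positions) == 0) {
    warning("empty selection: nothing to label")
    return(selection)
  }
  y <- binary_labels(labels, nrow(as.matrix(x)))
  xm <- as.matrix(x)[, selection$positions, drop = FALSE]
  dd <- colMeans(xm[y$patient, , drop = FALSE]) -
    colMeans(xm[!y$patient, , drop = FALSE])
  if (any(dd == 0)) message(sum(dd == 0), " exact tie(s) labelled 'under'")
  selection$direction <- ifelse(dd > 0, "over", "under")
  selection
}

# normalize diagnosis input: factor/character vector or phenotype table
binary_labels <- function(labels, n) {
  if (is.data.frame(labels)) labels <- labels$diagnosis
  f <- factor(labels)
  if (length(f) != n) stop("labels length must match subject count")
  if (nlevels(f) != 2) stop("need exactly 2 diagnosis groups, got ",
                            nlevels(f))
  lv <- levels(f)
  ctrl <- grep("^(control|hc)$", lv, ignore.case = TRUE, value = TRUE)
  control_level <- if (length(ctrl) == 1) ctrl else lv[1]
  list(patient = f != control_level,
       control_level = control_level,
       patient_level = setdiff(lv, control_level))
}

#' Mass-univariate t-test feature selection
#'
#' Each feature is tested for a patient-vs-control group difference with a
#' two-sample t-test (pooled variance by default); the selected set is the
#' significant set after the chosen multiplicity correction.
#'
#' @param x subjects x features matrix.
#' @param labels diagnosis labels (two groups, each >= 2 subjects).
#' @param correction `"fdr_bh"`, `"bonferroni"`, or `"none"`.
#' @param alpha significance level.
#' @param welch use Welch instead of pooled t-tests.
#' @return an [fc_selection()] with per-feature `t` statistics in `z` and
#'   adjusted p-values in `q_value`.
#' @export
ttest_select <- function(x, labels,
                         correction = c("fdr_bh", "bonferroni", "none"),
                         alpha = 0.05, welch = FALSE) {
  correction <- match.arg(correction)
  x <- as.matrix(x)
  y <- binary_labels(labels, nrow(x))
  if (sum(y$patient) < 2 || sum(!y$patient) < 2) {
    stop("both groups need >= 2 subjects")
  }
  tt <- col_ttest(x, y$patient, welch = welch)
  adj <- switch(correction,
                fdr_bh = bh_fdr(tt$p, alpha)$q_value,
                bonferroni = stats::p.adjust(tt$p, "bonferroni"),
                none = tt$p)
  keep <- which(adj <= alpha)
  fc_selection(method = paste0("ttest_", correction), positions = keep,
               n_features = ncol(x), z = unname(tt$t[keep]),
               q_value = unname(adj[keep]), q_level = alpha)
}

# vectorized two-sample t-test over columns (patient minus control)
col_ttest <- function(x, patient, welch = FALSE) {
  n1 <- sum(patient); n0 <- sum(!patient)
  m1 <- colMeans(x[patient, , drop = FALSE])
  m0 <- colMeans(x[!patient, , drop = FALSE])
  v1 <- apply(x[patient, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[!patient, , drop = FALSE], 2, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v0 / n0
    tval <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    tval <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
  }
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}
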