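# The user-facing model object: PCA-based FC selection as one fit.

#' PCA-based feature selection for FC data
#'
#' Fits the full unsupervised selection pipeline in one call: PCA of the
#' FC table, association screening of every component against diagnosis
#' and nuisance factors, choice of the diagnosis component (largest
#' explained variance among BH-significant ones), weight-based FC
#' selection at FDR `q`, and over/under-connectivity labelling from group
#' means. A null outcome -- no diagnosis-significant component, hence no
#' selected features -- is a valid fit.
#'
#' @param x subjects x features Fisher-z FC matrix.
#' @param pheno phenotype table with at least `subject_id`, `diagnosis`,
#'   `site` (see [check_phenotype()]).
#' @param q FDR level used both for component screening and weight
#'   selection.
#' @param factors phenotype factors to screen components against.
#' @param welch use Welch t-tests for binary factors.
#' @return an object of class `pcafs` with elements `pca` ([fit_pca()]),
#'   `association` ([associate()]), `component` (chosen component or
#'   `NULL`), `selection` ([fc_selection()]).
#' @examples
#' sim <- gen_clinical_dataset(clinical_sim_config(
#'   n_control = 60, n_patient = 60, n_features = 200,
#'   n_disorder_fcs = 20, disorder_effect = 1, seed = 3))
#' fit <- pcafs(sim$fc, sim$pheno)
#' fit
#' @export
pcafs <- function(x, pheno, q = 0.05,
                  factors = intersect(c("diagnosis", "symptom_score",
                                        "age", "sex", "mean_fd", "site"),
                                      names(pheno)),
                  welch = FALSE) {
  if (!"diagnosis" %in% factors) {
    stop("'diagnosis' must be among the screened factors")
  }
  x <- as.matrix(x)
  fit <- fit_pca(x)
  assoc <- associate(fit, pheno, factors = factors, q = q, welch = welch)
  comp <- choose_diagnosis_pc(assoc)
  sel <- if (is.null(comp)) {
    fc_selection("pca", integer(0), ncol(x), component = NULL, q_level = q)
  } else {
    label_direction(x, pheno, select_features(fit, comp, q = q))
  }
  structure(list(pca = fit, association = assoc, component = comp,
                 selection = sel, q = q, call = match.call()),
            class = "pcafs")
}

#' @export
print.pcafs <- function(x, ...) {
  cat("PCA-based FC selection\n")
  if (is.null(x$component)) {
    cat("no component significantly associated with diagnosis at q = ",
        x$q, " (null result; no features selected)\n", sep = "")
  } else {
    cat("diagnosis component: PC", x$component, " (explained variance ",
        signif(x$pca$explained[x$component], 3), ")\n", sep = "")
    cat("selected features: ", length(x$selection$positions), " of ",
        x$selection$n_features, " at q = ", x$q, " (",
        sum(x$selection$direction == "over"), " over-, ",
        sum(x$selection$direction == "under"), " under-connectivity)\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.pcafs <- function(object, ...) {
  sig <- object$association[object$association$significant, ]
  structure(list(fit = object,
                 significant_pairs = sig[order(sig$factor,
                                               sig$component), ],
                 top_features = utils::head(
                   as.data.frame(object$selection)[
                     order(-abs(as.data.frame(object$selection)$z)), ], 10)),
            class = "summary.pcafs")
}

#' @export
print.summary.pcafs <- function(x, ...) {
  print(x$fit)
  cat("\nsignificant component-factor associations:\n")
  if (nrow(x$significant_pairs)) {
    print.data.frame(x$significant_pairs[, c("component", "factor", "test",
                                             "statistic", "q_value")],
                     row.names = FALSE, digits = 3)
  } else cat("(none)\n")
  if (nrow(x$top_features)) {
    cat("\ntop selected features by |z|:\n")
    print.data.frame(x$top_features, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.pcafs <- function(object, all = FALSE, ...) {
  if (is.null(object$component)) return(NULL)
  w <- object$pca$weights[object$component, ]
  if (all) w else w[object$selection$positions]
}

#' Project new subjects onto the fitted diagnosis component
#'
#' @param object a [pcafs()] fit with a non-null diagnosis component.
#' @param newdata subjects x features matrix (omit to return the training
#'   scores).
#' @param ... unused.
#' @return per-subject scores on the diagnosis component.
#' @export
predict.pcafs <- function(object, newdata = NULL, ...) {
  if (is.null(object$component)) {
    stop("null fit: no diagnosis component to project onto")
  }
  if (is.null(newdata)) {
    return(object$pca$scores[, object$component])
  }
  project_scores(object$pca, object$component, newdata)
}

#' @export
plot.pcafs <- function(x, n_components = 20, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  k <- min(n_components, length(x$pca$explained))
  dd <- x$association[x$association$factor == "diagnosis" &
                        x$association$component <= k, ]
  cols <- ifelse(dd$significant, "firebrick", "grey60")
  graphics::barplot(dd$statistic, names.arg = dd$component, col = cols,
                    border = NA, xlab = "component",
                    ylab = "diagnosis t-value",
                    main = "component screening")
  if (!is.null(x$component)) {
    w <- x$pca$weights[x$component, ]
    z <- (w - mean(w)) / stats::sd(w)
    graphics::hist(z, breaks = 60, col = "grey80", border = "white",
                   xlab = "standardized weight (z)",
                   main = paste0("PC", x$component, " weights"))
    graphics::abline(v = range(x$selection$z), col = "firebrick",
                     lty = 2)
  } else {
    graphics::plot.new()
    graphics::title(main = "null result: no diagnosis component")
  }
  invisible(x)
}
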