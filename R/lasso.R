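# Supervised baselines: subsampled LASSO feature selection and the
# subsampling ensemble-LASSO diagnostic classifier. Classification members
# are L1-penalized LOGISTIC regressions (diagnosis is binary), each fit on
# a balanced subsample with the penalty chosen by internal
# cross-validation. Any in-fold feature selection runs strictly inside the
# member's training rows: held-out subjects never touch selector or
# penalty-choice statistics.

balanced_subsample <- function(patient) {
  idx1 <- which(patient)
  idx0 <- which(!patient)
  m <- min(length(idx1), length(idx0))
  c(sample(idx1, m), sample(idx0, m))
}

fit_member_glmnet <- function(x, y, nfolds, lambda_choice, lambda = NULL) {
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda)
    return(list(beta = as.numeric(fit$beta), intercept = as.numeric(fit$a0),
                lambda = lambda))
  }
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", nfolds = nfolds)
  lam <- cv[[lambda_choice]]
  co <- stats::coef(cv, s = lam)
  list(beta = as.numeric(co)[-1], intercept = as.numeric(co)[1],
       lambda = lam)
}

#' LASSO feature selection with stability subsampling
#'
#' Repeats balanced subsampling of the two diagnosis groups; on each
#' subsample an L1-penalized logistic regression is fit with the penalty
#' chosen by internal cross-validation, and a feature is selected when the
#' number of subsamples in which its coefficient is nonzero reaches
#' `selection_count_threshold` (default: a majority).
#'
#' @param x subjects x features matrix.
#' @param labels binary diagnosis labels; both groups >= 10 when the
#'   penalty is cross-validated.
#' @param n_subsamples number of balanced subsamples.
#' @param selection_count_threshold minimum nonzero count for selection;
#'   defaults to `ceiling(n_subsamples / 2)`.
#' @param nfolds folds of the internal cross-validation.
#' @param lambda_choice `"lambda.1se"` (the sparser one-standard-error
#'   rule, default, as in `coef.cv.glmnet`) or `"lambda.min"`.
#' @param lambda optional fixed penalty, bypassing cross-validation.
#' @return an [fc_selection()]; `z` holds each selected feature's
#'   selection frequency across subsamples.
#' @export
lasso_select <- function(x, labels, n_subsamples = 100,
                         selection_count_threshold = NULL, nfolds = 10,
                         lambda_choice = c("lambda.1se", "lambda.min"),
                         lambda = NULL) {
  lambda_choice <- match.arg(lambda_choice)
  x <- as.matrix(x)
  y <- binary_labels(labels, nrow(x))
  if (length(unique(y$patient)) < 2) stop("labels are all identical")
  if (is.null(lambda) && (sum(y$patient) < 10 || sum(!y$patient) < 10)) {
    stop("both groups need >= 10 subjects for cross-validated penalties")
  }
  if (is.null(selection_count_threshold)) {
    selection_count_threshold <- ceiling(n_subsamples / 2)
  }
  counts <- integer(ncol(x))
  for (b in seq_len(n_subsamples)) {
    rows <- balanced_subsample(y$patient)
    fit <- fit_member_glmnet(x[rows, , drop = FALSE],
                             as.integer(y$patient[rows]), nfolds,
                             lambda_choice, lambda)
    counts <- counts + (fit$beta != 0)
  }
  keep <- which(counts >= selection_count_threshold)
  fc_selection(method = "lasso", positions = keep, n_features = ncol(x),
               z = counts[keep] / n_subsamples,
               q_level = NA_real_)
}

#' Fit a subsampling ensemble-LASSO classifier
#'
#' Trains `n_subsamples` L1-penalized logistic members, each on a balanced
#' subsample of the two groups. When `inner_selector` is supplied it is
#' called as `inner_selector(x_train, labels_train)` INSIDE each member's
#' training rows before the member fit, so feature computation and
#' extraction never see held-out subjects (the no-leakage contract). A
#' selector returning an empty set makes that member fall back to all
#' features (with a message). Member decision scores aggregate by
#' averaging predicted probabilities.
#'
#' @param x subjects x features matrix.
#' @param labels binary diagnosis labels.
#' @param n_subsamples ensemble size.
#' @param inner_selector optional `function(x, labels)` returning feature
#'   positions or an [fc_selection()].
#' @param nfolds,lambda_choice,lambda as in [lasso_select()].
#' @return an object of class `fc_ensemble`.
#' @export
ensemble_fit <- function(x, labels, n_subsamples = 100,
                         inner_selector = NULL, nfolds = 10,
                         lambda_choice = c("lambda.min", "lambda.1se"),
                         lambda = NULL) {
  # members are prediction-oriented, so the prediction-optimal penalty
  # (lambda.min) is the default here, unlike lasso_select
  lambda_choice <- match.arg(lambda_choice)
  x <- as.matrix(x)
  y <- binary_labels(labels, nrow(x))
  if (length(unique(y$patient)) < 2) stop("labels are all identical")
  if (is.null(lambda) && (sum(y$patient) < 10 || sum(!y$patient) < 10)) {
    stop("both groups need >= 10 subjects for cross-validated penalties")
  }
  members <- vector("list", n_subsamples)
  for (b in seq_len(n_subsamples)) {
    rows <- balanced_subsample(y$patient)
    feats <- seq_len(ncol(x))
    if (!is.null(inner_selector)) {
      sel <- inner_selector(x[rows, , drop = FALSE],
                            factor(ifelse(y$patient[rows], y$patient_level,
                                          y$control_level)))
      if (inherits(sel, "fc_selection")) sel <- sel$positions
      if (length(sel) == 0) {
        message("member ", b,
                ": selector returned no features; using all")
      } else feats <- sort(as.integer(sel))
    }
    fit <- fit_member_glmnet(x[rows, feats, drop = FALSE],
                             as.integer(y$patient[rows]), nfolds,
                             lambda_choice, lambda)
    beta <- numeric(ncol(x))
    beta[feats] <- fit$beta
    members[[b]] <- list(beta = beta, intercept = fit$intercept,
                         features = feats, lambda = fit$lambda,
                         n_train = length(rows))
  }
  structure(list(members = members, n_features = ncol(x),
                 control_level = y$control_level,
                 patient_level = y$patient_level),
            class = "fc_ensemble")
}

#' Predict with an ensemble classifier
#'
#' @param object an [ensemble_fit()] model.
#' @param newdata subjects x features matrix.
#' @param ... unused.
#' @return per-subject patient probabilities, averaged over members.
#' @export
predict.fc_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$n_features)
  }
  scores <- vapply(object$members, function(m) {
    stats::plogis(m$intercept + drop(newdata %*% m$beta))
  }, numeric(nrow(newdata)))
  rowMeans(matrix(scores, nrow = nrow(newdata)))
}

#' @export
print.fc_ensemble <- function(x, ...) {
  sizes <- vapply(x$members, function(m) sum(m$beta != 0), numeric(1))
  cat("<fc_ensemble> ", length(x$members), " LASSO members x ",
      x$n_features, " features; mean selected-set size ",
      round(mean(sizes), 1), "\n", sep = "")
  invisible(x)
}

#' Mean per-member selected-set size
#'
#' The "average number of FCs used for training": mean count of nonzero
#' member coefficients (fractional values are expected).
#'
#' @param model an [ensemble_fit()] model.
#' @return a single number.
#' @export
ensemble_mean_nfc <- function(model) {
  stopifnot(inherits(model, "fc_ensemble"))
  mean(vapply(model$members, function(m) sum(m$beta != 0), numeric(1)))
}

#' Classifier performance metrics
#'
#' AUC by the rank statistic over scores (the probability that a random
#' patient outscores a random control, ties counted half), plus accuracy,
#' sensitivity, specificity, and the Matthews correlation coefficient at
#' the decision threshold.
#'
#' @param model an [ensemble_fit()] model (or any object with a `predict`
#'   method returning scores).
#' @param x subjects x features matrix.
#' @param labels binary diagnosis labels with both classes present.
#' @param threshold decision threshold on the averaged probability.
#' @return an object of class `classifier_metrics`: `auc`, `accuracy`,
#'   `sensitivity`, `specificity`, `mcc`, and the confusion counts.
#' @export
evaluate_classifier <- function(model, x, labels, threshold = 0.5) {
  scores <- stats::predict(model, x)
  classifier_metrics(scores, labels, threshold = threshold)
}

#' @rdname evaluate_classifier
#' @param scores numeric decision scores (higher = more patient-like).
#' @export
classifier_metrics <- function(scores, labels, threshold = 0.5) {
  y <- binary_labels(labels, length(scores))
  pos <- y$patient
  if (all(pos) || !any(pos)) {
    stop("AUC undefined: test labels contain a single class")
  }
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(auc = auc, accuracy = (tp + tn) / length(scores),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp), mcc = mcc,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 threshold = threshold),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(paste0("AUC %.3f | accuracy %.3f | sensitivity %.3f | ",
                     "specificity %.3f | MCC %.3f\n"),
              x$auc, x$accuracy, x$sensitivity, x$specificity, x$mcc))
  invisible(x)
}

#' In-fold selector factories for the ensemble classifier
#'
#' `selector_pca(q, ...)` wraps the PCA-based selection pipeline
#' ([pcafs()] without the nuisance factors, which are unknown inside a
#' subsample) and `selector_ttest(...)` wraps [ttest_select()], each as a
#' `function(x, labels)` suitable for `inner_selector` in
#' [ensemble_fit()].
#'
#' @param q,mode,percentile passed to [select_features()].
#' @return a selector function.
#' @export
selector_pca <- function(q = 0.05, mode = "fdr", percentile = 0.98) {
  function(x, labels) {
    fit <- fit_pca(x)
    y <- binary_labels(labels, nrow(as.matrix(x)))
    tt <- vapply(seq_len(nrow(fit$weights)), function(i) {
      stats::t.test(fit$scores[, i] ~ y$patient, var.equal = TRUE)$p.value
    }, numeric(1))
    sig <- which(bh_fdr(tt, q)$reject)
    if (length(sig) == 0) return(integer(0))
    comp <- sig[which.max(fit$explained[sig])]
    select_features(fit, comp, q = q, mode = mode,
                    percentile = percentile)$positions
  }
}

#' @rdname selector_pca
#' @param correction,alpha passed to [ttest_select()].
#' @export
selector_ttest <- function(correction = "fdr_bh", alpha = 0.05) {
  function(x, labels) {
    ttest_select(x, labels, correction = correction,
                 alpha = alpha)$positions
  }
}
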