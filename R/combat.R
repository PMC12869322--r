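# ComBat harmonization of FC tables: the parametric empirical-Bayes
# location/scale batch model (Johnson, Li & Rabinovic 2007), with biological
# covariates (diagnosis, age, sex) protected via the regression design so
# only site differences are removed. Implemented with an explicit fit/apply
# split so a model fit on one table can harmonize another.

#' Fit a ComBat site-harmonization model
#'
#' Estimates feature-wise additive and multiplicative site effects in a
#' standardized space, with parametric empirical-Bayes shrinkage across
#' features (normal prior on locations, inverse-gamma on scales). Covariate
#' effects are estimated jointly and are NOT removed at apply time: only
#' the site location/scale adjustment is ever subtracted.
#'
#' @param x subjects x features numeric matrix (Fisher-z FC values).
#' @param site per-subject site labels (>= 2 sites, each with >= 2
#'   subjects).
#' @param covariates optional data frame of biological covariates to
#'   protect (e.g. diagnosis, age, sex); expanded via `model.matrix`.
#' @param eb use empirical-Bayes shrinkage (default). With `eb = FALSE`
#'   the raw per-site estimates are used, which on a covariate-free design
#'   reduces ComBat to exact per-site standardization.
#' @return an object of class `combat_model`.
#' @export
combat_fit <- function(x, site, covariates = NULL, eb = TRUE) {
  x <- as.matrix(x)
  site <- factor(site)
  if (nlevels(site) < 2) stop("ComBat needs >= 2 sites")
  if (length(site) != nrow(x)) stop("site length must match rows of x")
  tab <- table(site)
  if (any(tab < 2)) {
    stop("site(s) with < 2 subjects: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  batch <- stats::model.matrix(~ site - 1)
  cov_design <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_design <- stats::model.matrix(~ ., data = covariates)[, -1,
                                                              drop = FALSE]
  }
  design <- cbind(batch, cov_design)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[qd$pivot[(qd$rank + 1):ncol(design)]]
    stop("site/covariate design is rank deficient (confounded columns: ",
         paste(bad, collapse = ", "), ")")
  }
  beta <- solve(crossprod(design), crossprod(design, x))
  n <- nrow(x)
  grand_mean <- drop(crossprod(tab / n, beta[seq_len(nlevels(site)), ,
                                             drop = FALSE]))
  var_pooled <- colMeans((x - design %*% beta)^2)
  if (any(var_pooled <= 0)) {
    stop("feature(s) with zero residual variance: ",
         paste(utils::head(which(var_pooled <= 0)), collapse = ", "))
  }
  beta_cov <- if (!is.null(cov_design)) {
    beta[-seq_len(nlevels(site)), , drop = FALSE]
  }
  model <- structure(
    list(sites = levels(site), grand_mean = grand_mean,
         var_pooled = var_pooled, beta_cov = beta_cov,
         cov_names = colnames(cov_design), eb = isTRUE(eb),
         n_features = ncol(x)),
    class = "combat_model")
  # per-site parameters and EB priors, computed on the training table
  std <- combat_standardize(model, x, covariates)
  est <- combat_site_params(model, std, site, fit_priors = TRUE)
  model$priors <- est$priors
  model$gamma_star <- est$gamma_star
  model$delta_star <- est$delta_star
  model
}

# standardized residual space: (x - grand mean - protected covariates) / sd
combat_standardize <- function(model, x, covariates) {
  stand_mean <- matrix(model$grand_mean, nrow(x), length(model$grand_mean),
                       byrow = TRUE)
  if (!is.null(model$beta_cov)) {
    if (is.null(covariates)) {
      warning("model was fit with covariates but none supplied; ",
              "standardizing around the grand mean only")
    } else {
      cd <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                       drop = FALSE]
      if (!identical(colnames(cd), model$cov_names)) {
        stop("covariate columns do not match the fitted model (",
             paste(model$cov_names, collapse = ", "), ")")
      }
      stand_mean <- stand_mean + cd %*% model$beta_cov
    }
  }
  list(z = sweep(x - stand_mean, 2, sqrt(model$var_pooled), "/"),
       stand_mean = stand_mean)
}

# per-site location/scale in standardized space, optionally fitting EB
# priors across features and shrinking toward them
combat_site_params <- function(model, std, site, fit_priors = FALSE) {
  z <- std$z
  sites <- model$sites
  gamma_hat <- t(vapply(sites, function(s) colMeans(z[site == s, ,
                                                      drop = FALSE]),
                        numeric(ncol(z))))
  delta_hat <- t(vapply(sites, function(s) {
    apply(z[site == s, , drop = FALSE], 2, stats::var)
  }, numeric(ncol(z))))
  priors <- model$priors
  if (fit_priors) {
    priors <- lapply(seq_along(sites), function(k) {
      d <- delta_hat[k, ]
      m <- mean(d); s2 <- stats::var(d)
      list(gamma_bar = mean(gamma_hat[k, ]), tau2 = stats::var(gamma_hat[k, ]),
           a_prior = (2 * s2 + m^2) / s2, b_prior = (m * s2 + m^3) / s2)
    })
  }
  if (!model$eb) {
    return(list(gamma_star = gamma_hat, delta_star = delta_hat,
                priors = priors))
  }
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  counts <- table(factor(site, levels = sites))
  for (k in seq_along(sites)) {
    nk <- as.integer(counts[k])
    pr <- priors[[k]]
    sol <- combat_eb_solve(std$z[site == sites[k], , drop = FALSE],
                           gamma_hat[k, ], delta_hat[k, ], nk, pr)
    gamma_star[k, ] <- sol$gamma
    delta_star[k, ] <- sol$delta
  }
  list(gamma_star = gamma_star, delta_star = delta_star, priors = priors)
}

# iterative posterior-mean solution of the parametric EB model
combat_eb_solve <- function(z_site, g_hat, d_hat, n, pr, conv = 1e-4,
                            max_iter = 200) {
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (n * pr$tau2 * g_hat + d_old * pr$gamma_bar) /
      (n * pr$tau2 + d_old)
    sum2 <- colSums((z_site - matrix(g_new, n, length(g_new),
                                     byrow = TRUE))^2)
    d_new <- (0.5 * sum2 + pr$b_prior) / (n / 2 + pr$a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (is.finite(change) && change < conv) break
  }
  list(gamma = g_old, delta = d_old)
}

#' Apply a ComBat model to an FC table
#'
#' Harmonizes the supplied table with the model's standardization (grand
#' mean, pooled variance, protected covariate fit) and empirical-Bayes
#' priors. Site location/scale estimates are computed on the supplied data
#' and shrunk toward the model's priors, so applying a model to an already
#' harmonized table is (numerically) a no-op.
#'
#' @param model a [combat_fit()] result.
#' @param x subjects x features matrix; all `site` labels must be sites the
#'   model has seen.
#' @param site per-subject site labels.
#' @param covariates covariates matching the model's design (required when
#'   the model was fit with covariates, to reconstruct the protected
#'   means).
#' @return the harmonized matrix, same dimensions and dimnames as `x`.
#' @export
combat_apply <- function(model, x, site, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  x <- as.matrix(x)
  site <- factor(site)
  unseen <- setdiff(levels(site), model$sites)
  if (length(unseen)) {
    stop("site(s) not in the fitted model: ", paste(unseen, collapse = ", "))
  }
  if (ncol(x) != model$n_features) {
    stop("feature count mismatch: model has ", model$n_features)
  }
  std <- combat_standardize(model, x, covariates)
  est <- combat_site_params(model, std, site)
  z_adj <- std$z
  for (k in seq_along(model$sites)) {
    rows <- site == model$sites[k]
    if (!any(rows)) next
    z_adj[rows, ] <- sweep(
      sweep(z_adj[rows, , drop = FALSE], 2, est$gamma_star[k, ], "-"),
      2, sqrt(est$delta_star[k, ]), "/")
  }
  out <- sweep(z_adj, 2, sqrt(model$var_pooled), "*") + std$stand_mean
  dimnames(out) <- dimnames(x)
  out
}

#' One-shot ComBat harmonization
#'
#' Convenience wrapper fitting and applying the model on the same table --
#' the usual way a validation cohort is harmonized when no traveling-subject
#' data exist for it.
#'
#' @inheritParams combat_fit
#' @return the harmonized matrix.
#' @export
combat <- function(x, site, covariates = NULL, eb = TRUE) {
  model <- combat_fit(x, site, covariates, eb = eb)
  combat_apply(model, x, site, covariates)
}

#' @export
print.combat_model <- function(x, ...) {
  cat("<combat_model> ", length(x$sites), " sites x ", x$n_features,
      " features; covariates: ",
      if (is.null(x$cov_names)) "none" else paste(x$cov_names,
                                                  collapse = ", "),
      "; EB = ", x$eb, "\n", sep = "")
  invisible(x)
}
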