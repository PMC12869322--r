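# The core method: PCA, BH-FDR, component association screening,
# component choice, weight-based selection, direction labels, projection.

test_that("fit_pca matches an explicit covariance eigendecomposition", {
  set.seed(101)
  x <- matrix(rnorm(20 * 30), 20, 30)
  fit <- fit_pca(x)
  xc <- scale(x, scale = FALSE)
  ev <- eigen(crossprod(xc) / 1, symmetric = TRUE)  # scatter matrix
  k <- nrow(fit$weights)
  expect_equal(k, 19L)  # n - 1 after centering
  for (comp in 1:5) {
    w_ref <- ev$vectors[, comp]
    w_fit <- fit$weights[comp, ]
    expect_equal(abs(sum(w_ref * w_fit)), 1, tolerance = 1e-8)
  }
  expect_equal(fit$explained,
               (ev$values[seq_len(k)] / sum(pmax(ev$values, 0))),
               tolerance = 1e-8)
  # orthonormal rows, consistent scores, full reconstruction
  expect_equal(tcrossprod(fit$weights), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$scores, xc %*% t(fit$weights), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$scores %*% fit$weights, xc, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$explained) <= 1e-12))
})

test_that("fit_pca handles rank-1 data and fixes component signs", {
  set.seed(102)
  u <- rnorm(12)
  v <- rnorm(8)
  x <- outer(u, v)
  fit <- fit_pca(x)
  expect_equal(fit$explained[1], 1, tolerance = 1e-9)
  # sign convention: largest-|weight| entry is positive
  expect_gt(fit$weights[1, which.max(abs(fit$weights[1, ]))], 0)
  expect_error(fit_pca(x[1:2, ]), "at least 3")
})

test_that("BH-FDR equals brute-force step-up on random and fixed p-sets", {
  expect_equal(bh_fdr(c(0.2, 0.9))$reject, c(FALSE, FALSE))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5))$reject,
               c(TRUE, TRUE, TRUE, FALSE))  # 0.03 <= 3 * 0.05 / 4
  expect_true(bh_fdr(0.04)$reject)          # m = 1 reduces to p <= q
  expect_equal(bh_fdr(numeric(0))$reject, logical(0))
  set.seed(103)
  for (rep in 1:50) {
    p <- runif(8)^sample(c(1, 3), 1)  # mix of flat and signal-like sets
    q <- sample(c(0.01, 0.05, 0.2), 1)
    got <- bh_fdr(p, q)
    expect_equal(got$reject, bh_oracle(p, q))
    expect_true(all(got$q_value >= 0 & got$q_value <= 1))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_sim <- function(seed, effect = 1, n = 400) {
  gen_clinical_dataset(clinical_sim_config(
    n_control = n / 2, n_patient = n / 2, n_features = 500,
    n_disorder_fcs = 30, disorder_effect = effect, seed = seed))
}

test_that("associate flags the planted diagnosis component and only it", {
  hits <- 0
  for (seed in 1:15) {
    sim <- make_sim(seed)
    fit <- fit_pca(sim$fc)
    assoc <- associate(fit, sim$pheno, factors = "diagnosis")
    # the planted component is the one whose weights track the loadings
    truth_dir <- numeric(ncol(sim$fc))
    truth_dir[sim$truth$disorder_idx] <- sim$truth$loadings
    planted <- which.max(abs(fit$weights %*% truth_dir))
    sig <- assoc$component[assoc$significant]
    if (identical(sig, planted)) hits <- hits + 1
  }
  expect_gte(hits, 14)
})

test_that("associate applies the declared test per factor type", {
  sim <- make_sim(7)
  fit <- fit_pca(sim$fc)
  assoc <- associate(fit, sim$pheno)
  expect_setequal(unique(assoc$factor),
                  c("diagnosis", "symptom_score", "age", "sex", "mean_fd",
                    "site"))
  tests <- unique(assoc[, c("factor", "test")])
  expect_equal(tests$test[tests$factor == "diagnosis"], "two-sample t")
  expect_equal(tests$test[tests$factor == "site"], "one-way ANOVA")
  expect_equal(tests$test[tests$factor == "age"], "Pearson r")
  # a factor equal to a component's own scores correlates perfectly
  ph <- sim$pheno
  ph$age <- fit$scores[, 3]
  self <- associate(fit, ph, factors = "age")
  expect_equal(self$statistic[self$component == 3], 1, tolerance = 1e-12)
  expect_lt(self$p[self$component == 3], 1e-100)
  # degenerate inputs error informatively
  ph_bad <- sim$pheno
  ph_bad$site <- factor(c("solo", as.character(ph_bad$site[-1])))
  expect_error(associate(fit, ph_bad, factors = "site"), "solo")
  ph_const <- sim$pheno
  ph_const$age <- 40
  expect_error(associate(fit, ph_const, factors = "age"), "constant")
})

test_that("choose_diagnosis_pc follows the explained-variance rule", {
  sim <- make_sim(3)
  fit <- fit_pca(sim$fc)
  assoc <- associate(fit, sim$pheno, factors = "diagnosis")
  # exactly one significant component: that one is returned
  expect_equal(sum(assoc$significant), 1)
  expect_equal(choose_diagnosis_pc(assoc), assoc$component[assoc$significant])
  # two significant: the larger explained variance wins
  assoc2 <- assoc
  assoc2$significant[assoc2$component %in% c(3, 8)] <- TRUE
  assoc2$explained[3] <- 0.08
  assoc2$explained[8] <- 0.03
  assoc2$significant[assoc2$component == choose_diagnosis_pc(assoc)] <- FALSE
  expect_equal(choose_diagnosis_pc(assoc2), 3L)
  # none significant: null result
  assoc3 <- assoc
  assoc3$significant[] <- FALSE
  expect_null(choose_diagnosis_pc(assoc3))
})

test_that("select_features recovers a planted outlier and errors on
           degenerate components", {
  set.seed(104)
  # synthetic component: standard-normal weights with one planted outlier
  w <- rnorm(1000)
  w[123] <- 8
  w <- w / sqrt(sum(w^2))
  fake <- structure(list(weights = rbind(w), scores = matrix(0, 5, 1),
                         explained = 1, feature_means = numeric(1000),
                         n_subjects = 5),
                    class = "fc_pca")
  sel <- select_features(fake, 1)
  expect_true(123 %in% sel$positions)
  expect_lte(length(sel$positions), 5)  # null features essentially never in
  flat <- fake
  flat$weights[1, ] <- 1 / sqrt(1000)
  expect_error(select_features(flat, 1), "degenerate")
  # percentile mode keeps the stated share
  sel_p <- select_features(fake, 1, mode = "percentile", percentile = 0.98)
  expect_equal(length(sel_p$positions), 20)
  expect_true(123 %in% sel_p$positions)
})

test_that("planted-component recovery has high sensitivity and precision", {
  for (seed in c(2, 5, 9)) {
    sim <- make_sim(seed, effect = 0.8)
    fit <- pcafs(sim$fc, sim$pheno)
    expect_false(is.null(fit$component))
    sel <- fit$selection$positions
    expect_gte(mean(sim$truth$disorder_idx %in% sel), 0.9)  # sensitivity
    expect_gte(mean(sel %in% sim$truth$disorder_idx), 0.9)  # precision
  }
})

test_that("direction labels come from group means and flip with labels", {
  sim <- make_sim(5)
  fit <- pcafs(sim$fc, sim$pheno)
  sel <- fit$selection
  # positive loadings, positive effect: everything is over-connectivity
  expect_true(all(sel$direction == "over"))
  flipped <- factor(ifelse(sim$pheno$diagnosis == "patient", "control",
                           "patient"))
  sel_flip <- label_direction(sim$fc, flipped, sel)
  expect_true(all(sel_flip$direction == "under"))
  # explicit two-feature check
  x <- rbind(c(0.1, 0.5), c(0.1, 0.5), c(0.2, 0.3), c(0.2, 0.3))
  lab <- c("control", "control", "patient", "patient")
  s <- fc_selection("manual", 1:2, 2)
  out <- label_direction(x, lab, s)
  expect_equal(out$direction, c("over", "under"))
})

test_that("projection uses the model's centering and transfers the
           group difference to an independent cohort", {
  pair <- gen_discovery_validation_pair(clinical_sim_config(
    n_control = 200, n_patient = 200, n_features = 500,
    n_disorder_fcs = 30, disorder_effect = 0.5, seed = 11))
  fit <- pcafs(pair$discovery$fc, pair$discovery$pheno)
  expect_false(is.null(fit$component))
  # projecting the training data reproduces stored scores exactly
  expect_equal(unname(predict(fit)),
               unname(predict(fit, pair$discovery$fc)))
  proj <- predict(fit, pair$validation$fc)
  tt <- t.test(proj ~ pair$validation$pheno$diagnosis)
  expect_lt(tt$p.value, 0.01)
  # projecting pure noise: no group difference
  noise <- matrix(rnorm(length(pair$validation$fc)), nrow(pair$validation$fc))
  tt0 <- t.test(predict(fit, noise) ~ pair$validation$pheno$diagnosis)
  expect_gt(tt0$p.value, 0.01)
  expect_error(predict(fit, noise[, 1:10]), "features")
})

test_that("pcafs reports a null result on label-independent data", {
  sim <- gen_clinical_dataset(clinical_sim_config(
    n_control = 50, n_patient = 50, n_features = 300, n_disorder_fcs = 10,
    disorder_effect = 0, latent_sd = 0, site_bias_sd = 0,
    site_scale_sd = 0, age_effect = 0, sex_effect = 0, seed = 42))
  fit <- pcafs(sim$fc, sim$pheno, factors = "diagnosis")
  expect_null(fit$component)
  expect_length(fit$selection$positions, 0)
  expect_error(predict(fit, sim$fc), "null fit")
})
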