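# ComBat harmonization and traveling-subject site-bias correction.

two_site_data <- function(seed = 1, n_per = 100, p = 200, delta = 0.5,
                          effect = 0) {
  set.seed(seed)
  site <- rep(c("A", "B"), each = n_per)
  # diagnosis balanced WITHIN site, orthogonal to the site factor
  diagnosis <- factor(rep(rep(c("control", "patient"), each = n_per / 2), 2))
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  x[site == "A", ] <- x[site == "A", ] + delta
  x[site == "B", ] <- x[site == "B", ] - delta
  planted <- seq_len(min(20, p))
  x[, planted] <- x[, planted] + effect * (diagnosis == "patient")
  list(x = x, site = site, diagnosis = diagnosis, planted = planted)
}

test_that("ComBat without EB equalizes planted two-site means exactly and
           reduces to per-site standardization", {
  d <- two_site_data(delta = 0.5)
  harm <- combat(d$x, d$site, eb = FALSE)
  mA <- colMeans(harm[d$site == "A", ])
  mB <- colMeans(harm[d$site == "B", ])
  expect_lt(max(abs(mA - mB)), 1e-6)
  # closed form: per-site z-scoring (sample SD) mapped back to the pooled
  # location/scale
  model <- combat_fit(d$x, d$site, eb = FALSE)
  ref <- d$x
  for (s in c("A", "B")) {
    rows <- d$site == s
    ref[rows, ] <- sweep(sweep(scale(d$x[rows, ]), 2,
                               sqrt(model$var_pooled), "*"),
                         2, model$grand_mean, "+")
  }
  expect_equal(unname(harm), unname(ref), tolerance = 1e-8)
  # applying the fitted model twice is exactly idempotent without EB
  once <- combat_apply(model, d$x, d$site)
  twice <- combat_apply(model, once, d$site)
  expect_equal(twice, once, tolerance = 1e-8)
})

test_that("ComBat with zero site effect is close to the identity", {
  d <- two_site_data(seed = 3, delta = 0)
  harm <- combat(d$x, d$site)
  expect_lt(mean(abs(harm - d$x)), 0.05)
})

test_that("ComBat preserves a diagnosis effect orthogonal to site", {
  d <- two_site_data(seed = 5, delta = 0.5, effect = 0.6)
  g_before <- hedges_g(d$x, d$diagnosis)
  harm <- combat(d$x, d$site,
                 covariates = data.frame(diagnosis = d$diagnosis))
  g_after <- hedges_g(harm, d$diagnosis)
  # EB scale shrinkage rescales features by O(1/sqrt(n)) per site, so
  # per-feature g drifts a few percent; the planted effect itself survives
  expect_lt(max(abs(g_after[d$planted] - g_before[d$planted])), 0.15)
  expect_lt(mean(abs(g_after[d$planted] - g_before[d$planted])), 0.08)
  expect_equal(mean(g_after[d$planted]), 0.6, tolerance = 0.1)
})

test_that("harmonization shrinks per-feature site F-statistics", {
  d <- two_site_data(seed = 7, delta = 0.3)
  harm <- combat(d$x, d$site)
  f_stat <- function(x) {
    apply(x, 2, function(col) {
      stats::oneway.test(col ~ d$site, var.equal = TRUE)$statistic
    })
  }
  expect_gte(mean(f_stat(harm) < f_stat(d$x)), 0.95)
})

test_that("our ComBat matches sva::ComBat on the training table", {
  skip_if_not_installed("sva")
  d <- two_site_data(seed = 9, n_per = 40, p = 60, delta = 0.4,
                     effect = 0.5)
  mod <- stats::model.matrix(~ diagnosis, data = d["diagnosis"])
  ref <- t(suppressMessages(
    sva::ComBat(t(d$x), batch = d$site, mod = mod)))
  ours <- combat(d$x, d$site,
                 covariates = data.frame(diagnosis = d$diagnosis))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
  # and without covariates
  ref0 <- t(suppressMessages(sva::ComBat(t(d$x), batch = d$site)))
  ours0 <- combat(d$x, d$site)
  expect_equal(unname(ours0), unname(ref0), tolerance = 1e-6)
})

test_that("ComBat rejects degenerate designs and unseen sites", {
  d <- two_site_data(seed = 11, n_per = 20, p = 10)
  expect_error(combat_fit(d$x, rep("A", nrow(d$x))), ">= 2 sites")
  confounded <- data.frame(dup = factor(d$site))  # covariate == site
  expect_error(combat_fit(d$x, d$site, covariates = confounded),
               "rank deficient")
  model <- combat_fit(d$x, d$site)
  expect_error(combat_apply(model, d$x, rep("C", nrow(d$x))), "not in")
  # permutation equivariance: permuting subjects permutes output rows
  perm <- sample(nrow(d$x))
  harm <- combat_apply(model, d$x, d$site)
  harm_perm <- combat_apply(model, d$x[perm, ], d$site[perm])
  expect_equal(harm_perm, harm[perm, ], tolerance = 1e-10)
})

test_that("traveling-bias estimation solves the two-way least squares and
           recovers planted offsets", {
  # small instance against explicit lm() with the same constraint
  set.seed(21)
  labels <- expand.grid(participant = paste0("sub", 1:4),
                        site = paste0("site", 1:3))
  labels <- labels[rep(seq_len(nrow(labels)), 2), ]
  y <- rnorm(nrow(labels))
  ts <- list(values = cbind(y), labels = labels)
  est <- traveling_bias_estimate(ts)
  fit <- stats::lm(y ~ participant + site, data = cbind(labels, y = y))
  dc <- stats::dummy.coef(fit)$site
  counts <- table(labels$site)
  dc <- dc - sum(dc * counts) / sum(counts)
  expect_equal(unname(est$bias[, 1]), unname(dc), tolerance = 1e-10)

  # planted alternating +/-0.1 site offsets recovered within 0.01
  cfg <- traveling_sim_config(n_participants = 9, n_sites = 12,
                              runs_per_visit = 2, hub_and_spoke = FALSE,
                              sd_participant = 0.17, sd_scanner = 0,
                              sd_session = 0.01, sd_protocol = 0,
                              n_features = 100, seed = 22)
  ts2 <- gen_traveling_subject(cfg)
  offsets <- rep(c(0.1, -0.1), 6)
  site_num <- as.integer(sub("site", "", as.character(ts2$labels$site)))
  ts2$values <- ts2$values + offsets[site_num]
  est2 <- traveling_bias_estimate(ts2)
  got <- est2$bias[paste0("site", 1:12), ]
  expect_lt(max(abs(sweep(got, 1, offsets))), 0.01)

  # zero site effect: estimated biases ~ 0
  est0 <- traveling_bias_estimate(gen_traveling_subject(cfg))
  expect_lt(max(abs(est0$bias)), 0.01)
  # adding a constant to every run leaves site biases unchanged
  ts3 <- ts2
  ts3$values <- ts3$values + 5
  expect_equal(traveling_bias_estimate(ts3)$bias, est2$bias,
               tolerance = 1e-8)
})

test_that("bias subtraction is exact and invertible", {
  cfg <- traveling_sim_config(n_participants = 5, n_sites = 4,
                              hub_and_spoke = FALSE, n_features = 20,
                              seed = 30)
  ts <- gen_traveling_subject(cfg)
  bias <- traveling_bias_estimate(ts)
  x <- matrix(rnorm(6 * 20), 6, 20)
  site <- c("site1", "site2", "site3", "site1", "site4", "site2")
  sub <- traveling_bias_subtract(x, site, bias)
  expect_equal(unname(sub + bias$bias[site, ]), x)  # bit recovery
  zero <- bias
  zero$bias[] <- 0
  expect_equal(unname(traveling_bias_subtract(x, site, zero)), x)
  expect_error(traveling_bias_subtract(x, c(site[-1], "siteX"), bias),
               "siteX")
  # subtracting planted offsets restores site F-statistics to null levels
  d_site <- rep(c("site1", "site2"), each = 50)
  null_x <- matrix(rnorm(100 * 20), 100, 20)
  shifted <- null_x + 0.8 * (d_site == "site1")
  est <- traveling_bias_estimate(local({
    t2 <- ts
    t2$values <- t2$values +
      0.8 * (as.character(t2$labels$site) == "site1")
    t2
  }))
  fixed <- traveling_bias_subtract(shifted, d_site, est)
  f_null <- median(apply(null_x, 2, function(col) {
    stats::oneway.test(col ~ d_site, var.equal = TRUE)$statistic
  }))
  f_fixed <- median(apply(fixed, 2, function(col) {
    stats::oneway.test(col ~ d_site, var.equal = TRUE)$statistic
  }))
  expect_lt(f_fixed, f_null + 3)
})

test_that("disconnected or single-site designs are rejected", {
  labels <- data.frame(participant = c("a", "a", "b", "b"),
                       site = c("s1", "s1", "s2", "s2"))
  ts <- list(values = matrix(rnorm(4), 4, 1), labels = labels)
  expect_error(traveling_bias_estimate(ts), "< 2 sites")
  labels2 <- data.frame(participant = c("a", "a", "b", "b"),
                        site = c("s1", "s2", "s3", "s4"))
  ts2 <- list(values = matrix(rnorm(4), 4, 1), labels = labels2)
  expect_error(traveling_bias_estimate(ts2), "disconnected")
})
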