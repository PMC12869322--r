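# Synthetic clinical FC datasets with known planted structure.
#
# Generative model (directly on the Fisher-z scale):
#   x[s, f] = t[s] * load[f]                         (sparse disorder component)
#           + diffuse[f] * patient[s]                (weak diffuse disorder tail)
#           + age_effect  * z_age[s] * u_age[f]
#           + sex_effect  * c_sex[s] * u_sex[f]
#           + gamma[site[s], f]                      (additive site offset)
#           + delta[site[s], f] * eps[s, f]          (site-scaled noise)
# where t[s] = disorder_effect * patient[s] + latent_sd * N(0,1) is the
# subject's latent disorder factor (patients shift, everyone varies, e.g.
# with severity). Residual noise on the planted features is scaled down so
# their total within-group SD stays at noise_sd -- the empirical Hedge's g
# on planted features is therefore calibrated to disorder_effect whatever
# latent_sd is. Also, when `confounded_distractor` is on, a block of low-noise features
# carrying a site-1 offset while site 1 is assigned preferentially to
# patients: a high-SNR, site-driven signal that mimics diagnosis in one
# cohort but carries no disorder information.

#' Configuration for the clinical FC simulator
#'
#' Defaults describe the standard recovery regime used throughout the test
#' suite: 200 controls + 200 patients, 1,000 FC features, one sparse
#' disorder component loading on 50 features at a standardized effect of
#' 0.8, three sites with mild additive/scale biases, and unit noise.
#'
#' @param n_control,n_patient group sizes.
#' @param n_features number of FC features (ignored when `n_rois` given).
#' @param n_rois optional region count; implies
#'   `n_features = n_rois * (n_rois - 1) / 2` and ROI-pair feature names.
#' @param disorder_effect standardized patient-minus-control mean shift on
#'   the planted features (per unit loading).
#' @param n_disorder_fcs number of features carrying the disorder component.
#' @param latent_sd within-group SD of the latent disorder factor, as a
#'   fraction of the planted features' total SD (must satisfy
#'   `latent_sd < noise_sd`); gives the disorder component subject-level
#'   variance (severity variation) on top of the group shift.
#' @param diffuse_effect_sd SD of a weak diffuse disorder effect drawn
#'   independently for every feature (0 disables; used to emulate the broad
#'   tail of small true effects seen in real case-control FC data).
#' @param effect_consistency correlation (0..1) between the diffuse effect
#'   vectors of the two cohorts in [gen_discovery_validation_pair()].
#' @param n_sites number of imaging sites (round-robin assignment).
#' @param site_bias_sd SD of per-(site, feature) additive offsets.
#' @param site_scale_sd SD of log multiplicative per-(site, feature) noise
#'   scales.
#' @param age_effect,sex_effect loading magnitudes of the age and sex
#'   covariate components (unit-norm feature directions).
#' @param noise_sd residual noise SD.
#' @param confounded_distractor plant a high-SNR site-correlated distractor
#'   block (see Details).
#' @param n_distractor_fcs,distractor_amp,distractor_noise size, site-1
#'   offset, and relative noise scale of the distractor block.
#' @param confound_strength probability that a patient is assigned to site 1
#'   when the distractor is active (controls get `1 - confound_strength`).
#' @param seed RNG seed; identical config + seed gives bit-identical output.
#' @return a validated config object of class `clinical_sim_config`.
#' @export
clinical_sim_config <- function(n_control = 200, n_patient = 200,
                                n_features = 1000, n_rois = NULL,
                                disorder_effect = 0.8, n_disorder_fcs = 50,
                                latent_sd = 0.6,
                                diffuse_effect_sd = 0, effect_consistency = 1,
                                n_sites = 3, site_bias_sd = 0.1,
                                site_scale_sd = 0.05,
                                age_effect = 0.5, sex_effect = 0.5,
                                noise_sd = 1,
                                confounded_distractor = FALSE,
                                n_distractor_fcs = 50, distractor_amp = 0.5,
                                distractor_noise = 0.15,
                                confound_strength = 0.95, seed = 1) {
  if (!is.null(n_rois)) n_features <- n_fc_features(n_rois)
  cfg <- list(n_control = as.integer(n_control),
              n_patient = as.integer(n_patient),
              n_features = as.integer(n_features), n_rois = n_rois,
              disorder_effect = disorder_effect,
              n_disorder_fcs = as.integer(n_disorder_fcs),
              latent_sd = latent_sd,
              diffuse_effect_sd = diffuse_effect_sd,
              effect_consistency = effect_consistency,
              n_sites = as.integer(n_sites),
              site_bias_sd = site_bias_sd, site_scale_sd = site_scale_sd,
              age_effect = age_effect, sex_effect = sex_effect,
              noise_sd = noise_sd,
              confounded_distractor = isTRUE(confounded_distractor),
              n_distractor_fcs = as.integer(n_distractor_fcs),
              distractor_amp = distractor_amp,
              distractor_noise = distractor_noise,
              confound_strength = confound_strength,
              seed = as.integer(seed))
  validate_clinical_config(cfg)
  structure(cfg, class = "clinical_sim_config")
}

validate_clinical_config <- function(cfg) {
  counts <- c(cfg$n_control, cfg$n_patient, cfg$n_features,
              cfg$n_disorder_fcs, cfg$n_sites)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (cfg$n_control + cfg$n_patient < 4) {
    stop("need n_control + n_patient >= 4")
  }
  sds <- c(cfg$site_bias_sd, cfg$site_scale_sd, cfg$noise_sd,
           cfg$diffuse_effect_sd, cfg$latent_sd)
  if (any(sds < 0)) stop("SDs must be >= 0")
  if (cfg$latent_sd >= cfg$noise_sd && cfg$latent_sd > 0) {
    stop("latent_sd must be < noise_sd (it is a share of the planted ",
         "features' total SD)")
  }
  if (cfg$n_disorder_fcs > cfg$n_features) {
    stop("n_disorder_fcs exceeds n_features")
  }
  if (cfg$confounded_distractor &&
      cfg$n_disorder_fcs + cfg$n_distractor_fcs > cfg$n_features) {
    stop("disorder + distractor blocks exceed n_features")
  }
  if (cfg$effect_consistency < 0 || cfg$effect_consistency > 1) {
    stop("effect_consistency must be in [0, 1]")
  }
  invisible(cfg)
}

# Planted structure shared between cohorts of a discovery/validation pair.
sim_truth <- function(cfg) {
  set.seed(cfg$seed)
  p <- cfg$n_features
  disorder_idx <- sort(sample.int(p, cfg$n_disorder_fcs))
  loadings <- rep(1, cfg$n_disorder_fcs)
  distractor_idx <- integer(0)
  if (cfg$confounded_distractor) {
    distractor_idx <- sort(sample(setdiff(seq_len(p), disorder_idx),
                                  cfg$n_distractor_fcs))
  }
  u_age <- stats::rnorm(p); u_age <- u_age / sqrt(sum(u_age^2))
  u_sex <- stats::rnorm(p); u_sex <- u_sex / sqrt(sum(u_sex^2))
  diffuse <- stats::rnorm(p, 0, cfg$diffuse_effect_sd)
  cc <- cfg$effect_consistency
  diffuse_v <- cc * diffuse +
    sqrt(1 - cc^2) * stats::rnorm(p, 0, cfg$diffuse_effect_sd)
  list(disorder_idx = disorder_idx, loadings = loadings,
       distractor_idx = distractor_idx, u_age = u_age, u_sex = u_sex,
       diffuse = diffuse, diffuse_validation = diffuse_v)
}

# One cohort given a fixed planted truth. `diffuse` selects which diffuse
# effect vector applies (discovery vs validation cohort of a pair).
gen_clinical_cohort <- function(cfg, truth, seed, diffuse = truth$diffuse,
                                id_prefix = "S") {
  set.seed(seed)
  n <- cfg$n_control + cfg$n_patient
  p <- cfg$n_features
  patient <- rep(c(0, 1), c(cfg$n_control, cfg$n_patient))
  diagnosis <- factor(ifelse(patient == 1, "patient", "control"),
                      levels = c("control", "patient"))
  if (cfg$confounded_distractor) {
    p1 <- ifelse(patient == 1, cfg$confound_strength,
                 1 - cfg$confound_strength)
    at1 <- stats::runif(n) < p1
    site <- integer(n)
    site[at1] <- 1L
    if (cfg$n_sites > 1) {
      site[!at1] <- sample(2:cfg$n_sites, sum(!at1), replace = TRUE)
    } else site[!at1] <- 1L
  } else {
    site <- rep_len(seq_len(cfg$n_sites), n)
    site <- site[sample.int(n)]  # shuffle so site is label-independent
  }
  age <- stats::runif(n, 20, 70)
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  mean_fd <- stats::runif(n, 0.05, 0.35)
  latent <- cfg$disorder_effect * patient +
    cfg$latent_sd * stats::rnorm(n)
  symptom <- round(pmax(0, 8 + 12 * latent + stats::rnorm(n, 0, 4)))
  symptom[sample.int(n, ceiling(0.1 * n))] <- NA

  eps <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)
  # keep planted features at total within-group SD = noise_sd
  shrink <- sqrt(max(0, 1 - (cfg$latent_sd / cfg$noise_sd)^2))
  eps[, truth$disorder_idx] <- eps[, truth$disorder_idx] * shrink
  if (length(truth$distractor_idx)) {
    eps[, truth$distractor_idx] <- eps[, truth$distractor_idx] *
      cfg$distractor_noise
  }
  gamma <- matrix(stats::rnorm(cfg$n_sites * p, 0, cfg$site_bias_sd),
                  cfg$n_sites, p)
  delta <- exp(matrix(stats::rnorm(cfg$n_sites * p, 0, cfg$site_scale_sd),
                      cfg$n_sites, p))
  x <- eps * delta[site, , drop = FALSE] + gamma[site, , drop = FALSE]
  x[, truth$disorder_idx] <- x[, truth$disorder_idx] +
    tcrossprod(latent, truth$loadings)
  if (any(diffuse != 0)) x <- x + tcrossprod(patient, diffuse)
  x <- x + cfg$age_effect * tcrossprod(as.numeric(scale(age)), truth$u_age)
  x <- x + cfg$sex_effect *
    tcrossprod(as.numeric(sex == "M") - 0.5, truth$u_sex)
  if (length(truth$distractor_idx)) {
    x[, truth$distractor_idx] <- x[, truth$distractor_idx] +
      cfg$distractor_amp * (site == 1)
  }
  rownames(x) <- paste0(id_prefix, sprintf("%04d", seq_len(n)))
  colnames(x) <- if (!is.null(cfg$n_rois)) fc_pair_names(cfg$n_rois) else
    sprintf("FC%05d", seq_len(p))
  pheno <- data.frame(subject_id = rownames(x), diagnosis = diagnosis,
                      site = factor(paste0("site", site)), age = age,
                      sex = sex, symptom_score = symptom, mean_fd = mean_fd)
  list(fc = x, pheno = pheno)
}

#' Generate a synthetic clinical FC dataset
#'
#' @param cfg a [clinical_sim_config()].
#' @return a list of class `fc_sim` with `fc` (subjects x features Fisher-z
#'   matrix), `pheno` (phenotype table), and `truth` (planted feature
#'   indices, loadings, covariate directions, distractor indices).
#' @examples
#' sim <- gen_clinical_dataset(clinical_sim_config(seed = 7))
#' dim(sim$fc)
#' @export
gen_clinical_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "clinical_sim_config"))
  truth <- sim_truth(cfg)
  cohort <- gen_clinical_cohort(cfg, truth, seed = cfg$seed + 1L)
  structure(c(cohort, list(truth = truth, config = cfg)), class = "fc_sim")
}

#' Generate a matched discovery/validation cohort pair
#'
#' Both cohorts share the planted disorder component (identical feature
#' indices and loadings) but have independent subjects, independent site
#' bias realizations, and optionally different settings (e.g. the
#' site-confounded distractor active in discovery only).
#'
#' @param cfg a [clinical_sim_config()] describing the discovery cohort.
#' @param validation_overrides named list of config fields to override for
#'   the validation cohort. Overriding `n_features`, `n_disorder_fcs` or
#'   `seed` is an error (the planted truth must be shared).
#' @return list with `discovery`, `validation` (each `fc`/`pheno`) and the
#'   shared `truth`.
#' @export
gen_discovery_validation_pair <- function(cfg, validation_overrides = list()) {
  stopifnot(inherits(cfg, "clinical_sim_config"))
  frozen <- c("n_features", "n_rois", "n_disorder_fcs", "seed")
  bad <- intersect(names(validation_overrides), frozen)
  if (length(bad)) {
    stop("validation_overrides may not change: ", paste(bad, collapse = ", "))
  }
  vcfg <- utils::modifyList(unclass(cfg), validation_overrides)
  class(vcfg) <- "clinical_sim_config"
  validate_clinical_config(vcfg)
  truth <- sim_truth(cfg)
  vtruth <- truth
  if (!vcfg$confounded_distractor) vtruth$distractor_idx <- integer(0)
  disc <- gen_clinical_cohort(cfg, truth, seed = cfg$seed + 1L,
                              id_prefix = "D")
  val <- gen_clinical_cohort(vcfg, vtruth, seed = cfg$seed + 2L,
                             diffuse = truth$diffuse_validation,
                             id_prefix = "V")
  list(discovery = disc, validation = val, truth = truth)
}

#' The standard site-confounded robustness simulation
#'
#' The shipped configuration used to contrast unsupervised PCA-based
#' selection with supervised selectors: a discovery cohort carrying both a
#' true sparse disorder component (50 features, effect 0.8), a weak diffuse
#' disorder tail, and a high-SNR site-confounded distractor block, paired
#' with a validation cohort in which the distractor is absent and site
#' assignment is balanced. Supervised selectors chase the distractor block
#' in discovery and lose effect size in validation; the PCA route keys on
#' the dominant disorder component and generalizes.
#'
#' @param seed RNG seed.
#' @return as [gen_discovery_validation_pair()].
#' @export
sim_confounded_pair <- function(seed = 1) {
  cfg <- clinical_sim_config(n_control = 200, n_patient = 200,
                             n_features = 1000, disorder_effect = 0.8,
                             n_disorder_fcs = 50, diffuse_effect_sd = 0.18,
                             effect_consistency = 0.8,
                             confounded_distractor = TRUE,
                             n_distractor_fcs = 50, distractor_amp = 0.5,
                             distractor_noise = 0.15,
                             confound_strength = 0.95, seed = seed)
  gen_discovery_validation_pair(cfg,
                                list(confounded_distractor = FALSE))
}
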