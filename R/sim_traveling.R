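# Synthetic traveling-subject datasets: the same participants scanned at
# several sites, so that participant, scanner, protocol, and session
# contributions to FC variability can be separated.
#
# Generative model per run and feature:
#   value = participant effect + scanner effect + protocol effect
#         + session draw + residual,
# each effect vector drawn i.i.d. N(0, sd^2) per level and feature. There is
# no site term of its own: a site determines which scanner and protocol a
# run sees, mirroring real multi-site designs where "site" is shorthand for
# a scanner/protocol combination.

#' Configuration for the traveling-subject simulator
#'
#' Defaults emulate a hub-and-spoke traveling-subject campaign: 75
#' participants, 12 sites (5 scanner types, 3 protocols), each participant
#' visiting 3 sites (one of 3 hubs plus spokes) with 2 runs per visit, i.e.
#' 6 runs per participant. Factor SDs default to the magnitudes reported
#' for disorder-relevant FC in large traveling-subject studies
#' (participant 0.17, scanner 0.06, session 0.19, protocol 0.05).
#'
#' @param n_participants,n_sites,n_scanners,n_protocols design sizes.
#'   Scanner and protocol are assigned to sites cyclically with coprime
#'   periods so the two factors are not confounded.
#' @param runs_per_visit runs acquired per (participant, site) visit.
#' @param sites_per_participant sites each participant visits when
#'   `hub_and_spoke` is set (must be >= 2).
#' @param n_hubs number of hub sites.
#' @param sd_participant,sd_scanner,sd_session,sd_protocol,sd_noise
#'   per-factor SDs of the FC perturbations; `sd_session` is the per-run
#'   draw and `sd_noise` an optional extra residual (default 0).
#' @param n_features FC feature count.
#' @param hub_and_spoke if `FALSE`, every participant visits every site
#'   (complete crossed design).
#' @param seed RNG seed.
#' @return a config object of class `traveling_sim_config`.
#' @export
traveling_sim_config <- function(n_participants = 75, n_sites = 12,
                                 n_scanners = 5, n_protocols = 3,
                                 runs_per_visit = 2,
                                 sites_per_participant = 3, n_hubs = 3,
                                 sd_participant = 0.17, sd_scanner = 0.06,
                                 sd_session = 0.19, sd_protocol = 0.05,
                                 sd_noise = 0, n_features = 200,
                                 hub_and_spoke = TRUE, seed = 1) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_sites = as.integer(n_sites),
              n_scanners = as.integer(min(n_scanners, n_sites)),
              n_protocols = as.integer(min(n_protocols, n_sites)),
              runs_per_visit = as.integer(runs_per_visit),
              sites_per_participant = as.integer(sites_per_participant),
              n_hubs = as.integer(min(n_hubs, n_sites)),
              sd_participant = sd_participant, sd_scanner = sd_scanner,
              sd_session = sd_session, sd_protocol = sd_protocol,
              sd_noise = sd_noise, n_features = as.integer(n_features),
              hub_and_spoke = isTRUE(hub_and_spoke), seed = as.integer(seed))
  if (any(c(cfg$n_participants, cfg$n_sites, cfg$runs_per_visit,
            cfg$n_features) <= 0)) stop("all counts must be > 0")
  sds <- c(cfg$sd_participant, cfg$sd_scanner, cfg$sd_session,
           cfg$sd_protocol, cfg$sd_noise)
  if (any(sds < 0)) stop("SDs must be >= 0")
  if (cfg$hub_and_spoke) {
    if (cfg$n_sites < 2) stop("hub_and_spoke requires n_sites >= 2")
    if (cfg$sites_per_participant < 2) {
      stop("each participant must visit >= 2 sites under hub_and_spoke")
    }
    if (cfg$sites_per_participant > cfg$n_sites) {
      stop("sites_per_participant exceeds n_sites")
    }
  }
  structure(cfg, class = "traveling_sim_config")
}

#' Generate a synthetic traveling-subject dataset
#'
#' @param cfg a [traveling_sim_config()].
#' @return an object of class `traveling_set`: list with `values` (runs x
#'   features matrix), `labels` (data frame with `run_id`, `participant`,
#'   `site`, `scanner`, `protocol`, `session`), and `config`.
#' @export
gen_traveling_subject <- function(cfg) {
  stopifnot(inherits(cfg, "traveling_sim_config"))
  set.seed(cfg$seed)
  scanner_of_site <- (seq_len(cfg$n_sites) - 1L) %% cfg$n_scanners + 1L
  protocol_of_site <- (seq_len(cfg$n_sites) - 1L) %% cfg$n_protocols + 1L

  visits <- lapply(seq_len(cfg$n_participants), function(pt) {
    if (cfg$hub_and_spoke) {
      hub <- sample.int(cfg$n_hubs, 1)
      pool <- setdiff(seq_len(cfg$n_sites), hub)
      sites <- c(hub, sample(pool, cfg$sites_per_participant - 1L))
    } else {
      sites <- seq_len(cfg$n_sites)
    }
    data.frame(participant = pt, site = sites)
  })
  visits <- do.call(rbind, visits)
  labels <- visits[rep(seq_len(nrow(visits)), each = cfg$runs_per_visit), ]
  labels$run_in_visit <- rep(seq_len(cfg$runs_per_visit), nrow(visits))
  n_runs <- nrow(labels)
  labels$scanner <- scanner_of_site[labels$site]
  labels$protocol <- protocol_of_site[labels$site]
  labels$session <- paste0("p", labels$participant, "_s", labels$site,
                           "_r", labels$run_in_visit)
  labels$run_id <- sprintf("run%04d", seq_len(n_runs))
  labels <- labels[c("run_id", "participant", "site", "scanner",
                     "protocol", "session")]
  labels$participant <- factor(paste0("sub", labels$participant))
  labels$site <- factor(paste0("site", labels$site))
  labels$scanner <- factor(paste0("scanner", labels$scanner))
  labels$protocol <- factor(paste0("protocol", labels$protocol))

  p <- cfg$n_features
  eff_part <- matrix(stats::rnorm(cfg$n_participants * p, 0,
                                  cfg$sd_participant),
                     cfg$n_participants, p)
  eff_scan <- matrix(stats::rnorm(cfg$n_scanners * p, 0, cfg$sd_scanner),
                     cfg$n_scanners, p)
  eff_prot <- matrix(stats::rnorm(cfg$n_protocols * p, 0, cfg$sd_protocol),
                     cfg$n_protocols, p)
  values <- eff_part[as.integer(sub("sub", "", labels$participant)), ,
                     drop = FALSE] +
    eff_scan[as.integer(sub("scanner", "", labels$scanner)), ,
             drop = FALSE] +
    eff_prot[as.integer(sub("protocol", "", labels$protocol)), ,
             drop = FALSE] +
    matrix(stats::rnorm(n_runs * p, 0, cfg$sd_session), n_runs, p) +
    matrix(stats::rnorm(n_runs * p, 0, cfg$sd_noise), n_runs, p)
  rownames(values) <- labels$run_id
  colnames(values) <- sprintf("FC%05d", seq_len(p))
  structure(list(values = values, labels = labels, config = cfg,
                 truth = list(participant = eff_part, scanner = eff_scan,
                              protocol = eff_prot)),
            class = "traveling_set")
}

#' @export
print.traveling_set <- function(x, ...) {
  cat("<traveling_set> ", nrow(x$values), " runs x ", ncol(x$values),
      " features; ", nlevels(x$labels$participant), " participants, ",
      nlevels(x$labels$site), " sites, ",
      nlevels(x$labels$scanner), " scanners, ",
      nlevels(x$labels$protocol), " protocols\n", sep = "")
  invisible(x)
}
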