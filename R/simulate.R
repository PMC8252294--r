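#' Simulation configuration for synthetic bioassay and metabolite data
#'
#' Bundles every parameter of the synthetic-data generator into a validated
#' list. The defaults emulate the structure of a wild-tomato trichome
#' screening study: 19 accessions (8 of them truly resistant), sparse
#' replicate-level metabolite tables with log-normal nonzero abundances,
#' clip-cage whitefly survival counts (two cages of ~15 adults on each of
#' three plants), and daily-observed, right-censored thrips larva survival
#' over a 19-day follow-up.
#'
#' Planted (truly discriminative) features act through both a higher presence
#' probability in resistant accessions (`presence_resistant` vs
#' `presence_susceptible`) and a multiplicative abundance shift
#' (`planted_fold`), mirroring discriminant metabolites that differ in both
#' occurrence and level.
#'
#' @param n_accessions Number of accessions.
#' @param n_resistant Number of accessions whose true class is "resistant".
#' @param n_features Number of metabolite features per table.
#' @param n_planted Number of planted discriminative features (must not
#'   exceed `n_features`).
#' @param presence_resistant,presence_susceptible Presence probability of a
#'   planted feature in resistant / susceptible accessions; the former must
#'   exceed the latter.
#' @param presence_background Presence probability of a background (noise)
#'   feature in any accession. Low values reproduce the heavy sparsity of
#'   real trichome metabolomes, where many features occur in a single
#'   accession only.
#' @param lognormal_mu,lognormal_sigma Log-scale mean and SD of nonzero
#'   abundances (ion-count scale).
#' @param planted_fold Multiplicative abundance factor applied to planted
#'   features in resistant accessions.
#' @param n_replicates Biological replicates per accession (6 matches the
#'   acylsugar design, 4 the volatile design).
#' @param cage_size Adult whiteflies per clip cage.
#' @param cages_per_plant Clip cages per plant.
#' @param plants_per_accession Plants per accession in the whitefly assay.
#' @param surv_resistant,surv_susceptible Centre of the true whitefly
#'   5-day survival probability for resistant / susceptible accessions;
#'   per-accession values are spread deterministically around these so the
#'   panel spans the 0--88% range typical of such screens.
#' @param larvae_per_accession Thrips L1 larvae assayed per accession
#'   (one larva per leaf-disc well).
#' @param followup_days Follow-up horizon in days; larvae alive afterwards
#'   are censored.
#' @param baseline_daily_hazard Baseline (susceptible standard) daily death
#'   hazard for thrips larvae. Must be non-negative; zero yields a fully
#'   censored assay.
#' @param log_hr_resistant Centre of the true log hazard ratio of resistant
#'   accessions versus the baseline.
#' @param seed Integer seed; fixing it makes every generator reproducible.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_feature_table()], [simulate_whitefly_assay()],
#'   [simulate_thrips_assay()], [accession_truth()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 42)
#' ft <- simulate_feature_table(cfg)
#' ft$truth$planted_features
sim_config <- function(n_accessions = 19,
                       n_resistant = 8,
                       n_features = 80,
                       n_planted = 2,
                       presence_resistant = 0.9,
                       presence_susceptible = 0.1,
                       presence_background = 0.15,
                       lognormal_mu = 10,
                       lognormal_sigma = 1,
                       planted_fold = 8,
                       n_replicates = 6,
                       cage_size = 15,
                       cages_per_plant = 2,
                       plants_per_accession = 3,
                       surv_resistant = 0.2,
                       surv_susceptible = 0.75,
                       larvae_per_accession = 30,
                       followup_days = 19,
                       baseline_daily_hazard = 0.08,
                       log_hr_resistant = log(6),
                       seed = 1L) {
  probs <- c(presence_resistant = presence_resistant,
             presence_susceptible = presence_susceptible,
             presence_background = presence_background,
             surv_resistant = surv_resistant,
             surv_susceptible = surv_susceptible)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    abort(paste0("Probabilities must lie in [0, 1]: ",
                 paste(names(probs)[bad], collapse = ", ")))
  }
  if (presence_resistant <= presence_susceptible) {
    abort("`presence_resistant` must exceed `presence_susceptible` for planted features.")
  }
  if (n_planted > n_features) {
    abort("`n_planted` cannot exceed `n_features`.")
  }
  if (n_resistant < 1 || n_resistant >= n_accessions) {
    abort("`n_resistant` must be at least 1 and leave at least one susceptible accession.")
  }
  if (baseline_daily_hazard < 0) {
    abort("`baseline_daily_hazard` must be non-negative.")
  }
  counts <- c(n_accessions = n_accessions, n_features = n_features,
              n_replicates = n_replicates, cage_size = cage_size,
              cages_per_plant = cages_per_plant,
              plants_per_accession = plants_per_accession,
              larvae_per_accession = larvae_per_accession,
              followup_days = followup_days)
  if (any(counts < 1)) {
    abort("All design counts must be positive integers.")
  }
  cfg <- as.list(environment())
  cfg <- cfg[setdiff(names(cfg), c("probs", "bad", "counts"))]
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Ground-truth accession attributes implied by a simulation configuration
#'
#' Deterministic (seed-free) mapping from a [sim_config()] to each
#' accession's true class, whitefly survival probability and thrips log
#' hazard ratio. The first `n_resistant` accessions are resistant, with
#' survival probabilities spread evenly from 0 upward (so the panel always
#' contains a zero-survival accession, exercising the GLM exclusion rule)
#' and log hazard ratios spread around `log_hr_resistant`. The first
#' susceptible accession is the sensitive baseline standard: its log hazard
#' ratio is exactly 0 and its survival probability exactly
#' `surv_susceptible`.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `accession`, `class`, `surv_prob`,
#'   `log_hr`, plus an attribute `baseline` naming the baseline accession.
#' @export
accession_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_accessions
  nr <- config$n_resistant
  ns <- n - nr
  acc <- sprintf("acc%02d", seq_len(n))
  cls <- rep(c("resistant", "susceptible"), c(nr, ns))

  # susceptible accessions sit at or above the baseline survival (and at or
  # below its hazard): the labelling rules are one-sided, so true classes
  # stay consistent with what the generated assays imply under those rules
  sr <- if (nr == 1) 0 else seq(0, min(1, 2 * config$surv_resistant), length.out = nr)
  ss <- seq(config$surv_susceptible,
            min(1, config$surv_susceptible + 0.13), length.out = ns)

  hr_r <- if (nr == 1) config$log_hr_resistant else
    seq(0.75, 1.25, length.out = nr) * config$log_hr_resistant
  hr_s <- seq(0, -0.15, length.out = ns)

  out <- tibble(accession = acc, class = cls,
                surv_prob = c(sr, ss), log_hr = c(hr_r, hr_s))
  attr(out, "baseline") <- acc[nr + 1]
  out
}

#' Baseline (sensitive standard) accession of a simulated panel
#'
#' @param config A [sim_config()].
#' @return The accession identifier used as the susceptible reference level
#'   in the phenotyping models.
#' @export
baseline_accession <- function(config) {
  attr(accession_truth(config), "baseline")
}

# Deterministic sub-stream seeds so each generator can be re-run
# independently of the others under one global seed.
sub_seed <- function(config, stream) {
  offsets <- c(features = 11L, whitefly = 23L, thrips = 37L)
  (config$seed + offsets[[stream]]) %% .Machine$integer.max
}

#' Simulate a replicate-level metabolite feature table with known truth
#'
#' Generates a sparse accession x replicate x feature abundance table.
#' Presence is decided per accession x feature: planted features are present
#' with probability `presence_resistant` in resistant accessions and
#' `presence_susceptible` in susceptible ones; background features with
#' probability `presence_background` everywhere. When a feature is present
#' in an accession, every replicate draws a LogNormal(`lognormal_mu`,
#' `lognormal_sigma`) abundance, multiplied by `planted_fold` for planted
#' features in resistant accessions; absent features are exact zeros in all
#' replicates. Accession-level presence is what produces features detected
#' in a single accession only, a hallmark of real trichome metabolomes.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{table}{A `feature_table` (see [build_feature_table()]) with
#'       replicate-level long data and accession-mean wide data.}
#'     \item{truth}{A list with `planted_features` (character) and
#'       `accessions` (the [accession_truth()] tibble).}
#'   }
#' @export
simulate_feature_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth_acc <- accession_truth(config)
  feat <- sprintf("F%03d", seq_len(config$n_features))
  planted <- feat[seq_len(config$n_planted)]

  set.seed(sub_seed(config, "features"))
  n_acc <- config$n_accessions
  n_feat <- config$n_features

  pres_prob <- matrix(config$presence_background, n_acc, n_feat)
  if (config$n_planted > 0) {
    idx <- seq_len(config$n_planted)
    pres_prob[, idx] <- ifelse(truth_acc$class == "resistant",
                               config$presence_resistant,
                               config$presence_susceptible)
  }
  present <- matrix(runif(n_acc * n_feat) < pres_prob, n_acc, n_feat)

  grid <- tidyr::expand_grid(accession = truth_acc$accession,
                             replicate = seq_len(config$n_replicates),
                             feature_id = feat)
  pres_long <- present[cbind(match(grid$accession, truth_acc$accession),
                             match(grid$feature_id, feat))]
  ab <- numeric(nrow(grid))
  n_nz <- sum(pres_long)
  if (n_nz > 0) {
    ab[pres_long] <- rlnorm(n_nz, config$lognormal_mu, config$lognormal_sigma)
  }
  is_planted <- grid$feature_id %in% planted
  is_res <- truth_acc$class[match(grid$accession, truth_acc$accession)] == "resistant"
  ab[is_planted & is_res] <- ab[is_planted & is_res] * config$planted_fold

  long <- grid %>%
    mutate(class = truth_acc$class[match(.data$accession, truth_acc$accession)],
           abundance = ab)

  tab <- build_feature_table(long)
  list(table = tab,
       truth = list(planted_features = planted, accessions = truth_acc))
}

#' Simulate whitefly no-choice clip-cage survival records
#'
#' Each accession carries `plants_per_accession` plants with
#' `cages_per_plant` clip cages of `cage_size` adult whiteflies; the number
#' alive after the assay is Binomial(`cage_size`, p) with p the accession's
#' true survival probability from [accession_truth()].
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `accession`, `plant_id`, `cage_id`,
#'   `n_alive`, `n_dead`.
#' @export
simulate_whitefly_assay <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth_acc <- accession_truth(config)
  set.seed(sub_seed(config, "whitefly"))
  grid <- tidyr::expand_grid(accession = truth_acc$accession,
                             plant = seq_len(config$plants_per_accession),
                             cage = seq_len(config$cages_per_plant))
  p <- truth_acc$surv_prob[match(grid$accession, truth_acc$accession)]
  alive <- rbinom(nrow(grid), config$cage_size, p)
  grid %>%
    mutate(plant_id = paste0(.data$accession, "_p", .data$plant),
           cage_id = paste0(.data$plant_id, "_c", .data$cage),
           n_alive = alive,
           n_dead = config$cage_size - alive) %>%
    select("accession", "plant_id", "cage_id", "n_alive", "n_dead")
}

#' Simulate thrips larval time-to-event records
#'
#' Each larva draws a continuous exponential death time with daily rate
#' `baseline_daily_hazard * exp(log_hr)` for its accession; the time is
#' rounded up to the whole observation day (survival status was read once a
#' day). Larvae alive past `followup_days` are censored there with status 0.
#' A zero hazard yields a fully censored assay.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `accession`, `individual_id`, `day`
#'   (integer, in `[1, followup_days]`), `status` (1 = died, 0 = censored).
#' @export
simulate_thrips_assay <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth_acc <- accession_truth(config)
  set.seed(sub_seed(config, "thrips"))
  grid <- tidyr::expand_grid(accession = truth_acc$accession,
                             indiv = seq_len(config$larvae_per_accession))
  rate <- config$baseline_daily_hazard *
    exp(truth_acc$log_hr[match(grid$accession, truth_acc$accession)])
  t_cont <- ifelse(rate > 0, rexp(nrow(grid), pmax(rate, .Machine$double.xmin)), Inf)
  day <- ceiling(t_cont)
  status <- as.integer(day <= config$followup_days)
  day <- pmin(day, config$followup_days)
  grid %>%
    mutate(individual_id = paste0(.data$accession, "_i", .data$indiv),
           day = as.integer(day),
           status = status) %>%
    select("accession", "individual_id", "day", "status")
}
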