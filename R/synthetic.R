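## Synthetic-data generators for every input stream the pipeline consumes:
## area assessments with covariates, the older-people weighting survey, the
## resident validation survey, and a second rater's sheets. Areas carry a
## latent four-factor structure (each factor oriented so that higher = less
## desirable) coupled to a latent deprivation index, so parameter recovery
## can be scored against the ground truth.

local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  force(expr)
}

SETTLEMENT_TYPES <- c("city_and_town", "rural_town_fringe",
                      "village_dispersed")

#' Simulation configuration
#'
#' Defaults emulate the published study design: 405 purposively selected
#' areas with a 40/20/40 settlement mix, a resident validation survey with
#' 500 eligible returns (ineligible returns injected at the observed
#' 106/606 rate), a 545-respondent weighting survey, 10 re-rated areas with
#' a 5 per cent disagreement rate, factor-deprivation correlations signed
#' and sized as reported for the four domains against area deprivation
#' (+0.22, +0.25, -0.17, +0.67), and an inter-factor correlation of 0.2
#' (oblique structure).
#'
#' @param n_areas number of assessed areas.
#' @param n_residents target number of eligible resident returns.
#' @param prop_ineligible fraction of ineligible returns injected (too
#'   young, missing age, or unlinkable postcode).
#' @param settlement_mix named proportions over the three settlement types
#'   (must sum to 1).
#' @param inter_factor_corr common correlation among the four latent
#'   factors.
#' @param factor_deprivation_corr length-4 vector of target correlations
#'   between each (undesirability-oriented) factor and the deprivation
#'   index.
#' @param uniqueness optional named per-item residual variances; default
#'   `1 - loading^2`.
#' @param rater_disagreement_rate per-item probability that the second
#'   rater deviates (binary flip / ordinal +-1; proportions get Gaussian
#'   jitter with this standard deviation).
#' @param n_reliability_areas areas re-assessed by the second rater.
#' @param n_weighting_respondents weighting-survey sample size.
#' @param weighting_dispersion SD of respondent scatter around an item's
#'   planted position on the 9-point scale.
#' @param age_mean,age_sd,age_min resident age model (normal truncated at
#'   `age_min`).
#' @param perception_coupling named list: perception item -> named vector of
#'   factor couplings (positive = disagreement grows with the factor).
#' @param attachment_coupling named vector of factor couplings for the three
#'   attachment-importance items.
#' @param perception_noise_sd residual SD of the perception latents.
#' @return List of class `operat_sim_config`.
#' @export
simulation_config <- function(
    n_areas = 405,
    n_residents = 500,
    prop_ineligible = 106 / 606,
    settlement_mix = c(city_and_town = 0.40, rural_town_fringe = 0.20,
                       village_dispersed = 0.40),
    inter_factor_corr = 0.2,
    factor_deprivation_corr = c(natural_elements = 0.22,
                                incivilities_nuisance = 0.25,
                                navigation_mobility = -0.17,
                                territorial_functioning = 0.67),
    uniqueness = NULL,
    rater_disagreement_rate = 0.05,
    n_reliability_areas = 10,
    n_weighting_respondents = 545,
    weighting_dispersion = 1.5,
    age_mean = 74.07, age_sd = 7.79, age_min = 65,
    perception_coupling = list(
      enjoy_living = c(territorial_functioning = 0.30,
                       navigation_mobility = -0.25),
      desirable_place = c(territorial_functioning = 0.35,
                          navigation_mobility = -0.25),
      safe_day = c(incivilities_nuisance = 0.25),
      safe_night = c(incivilities_nuisance = 0.45)),
    attachment_coupling = c(natural_elements = -0.30),
    perception_noise_sd = 1) {
  if (abs(sum(settlement_mix) - 1) > 1e-8)
    config_error("settlement_mix proportions must sum to 1")
  if (!all(names(settlement_mix) %in% SETTLEMENT_TYPES))
    config_error("settlement_mix names must be the three settlement types")
  if (any(abs(factor_deprivation_corr) >= 1) ||
      abs(inter_factor_corr) >= 1)
    config_error("all correlation targets must lie strictly within (-1, 1)")
  if (prop_ineligible < 0 || prop_ineligible >= 1)
    config_error("prop_ineligible must be in [0, 1)")
  structure(list(
    n_areas = n_areas, n_residents = n_residents,
    prop_ineligible = prop_ineligible, settlement_mix = settlement_mix,
    inter_factor_corr = inter_factor_corr,
    factor_deprivation_corr = factor_deprivation_corr,
    uniqueness = uniqueness,
    rater_disagreement_rate = rater_disagreement_rate,
    n_reliability_areas = n_reliability_areas,
    n_weighting_respondents = n_weighting_respondents,
    weighting_dispersion = weighting_dispersion,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    perception_coupling = perception_coupling,
    attachment_coupling = attachment_coupling,
    perception_noise_sd = perception_noise_sd), class = "operat_sim_config")
}

#' Signed reference loading matrix of an instrument
#'
#' Items x domains matrix holding each item's reference loading on its own
#' domain (zero elsewhere), as used by the continuous factor-data generator.
#'
#' @param spec an [operat_instrument()].
#' @return Numeric matrix, `item_id` rows and `domain_id` columns.
#' @export
instrument_loading_matrix <- function(spec) {
  L <- matrix(0, nrow(spec$items), nrow(spec$domains),
              dimnames = list(spec$items$item_id, spec$domains$domain_id))
  for (i in seq_len(nrow(spec$items)))
    L[i, spec$items$domain_id[i]] <- spec$items$loading[i]
  L
}

#' Continuous data from a factor-loading pattern
#'
#' Draws `n` observations from the linear factor model `x = L f + e` with
#' correlated factors and item residual variances `uniqueness` (default
#' `1 - rowSums((L Phi) * L)`, giving unit-variance items). This is the
#' idealised, un-discretised version of the area generator, used to study
#' factor recovery directly.
#'
#' @param loadings items x factors matrix.
#' @param n observations.
#' @param Phi factor correlation matrix (default: constant 0.2 off-diagonal).
#' @param uniqueness per-item residual variance.
#' @param seed integer seed.
#' @return n x items numeric matrix.
#' @export
simulate_factor_data <- function(loadings, n, Phi = NULL, uniqueness = NULL,
                                 seed = NULL) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (is.null(Phi)) { Phi <- matrix(0.2, k, k); diag(Phi) <- 1 }
  comm <- rowSums((L %*% Phi) * L)
  if (is.null(uniqueness)) uniqueness <- pmax(1 - comm, 0.05)
  local_seed(seed, {
    f <- MASS::mvrnorm(n, rep(0, k), Phi)
    X <- f %*% t(L) +
      matrix(rnorm(n * nrow(L)), n) %*% diag(sqrt(uniqueness), nrow(L))
    colnames(X) <- rownames(L)
    X
  })
}

## joint draw of (deprivation, factors) with the configured correlations;
## errors when the implied correlation matrix is not positive definite
draw_latents <- function(n, config) {
  r <- unname(config$factor_deprivation_corr)
  k <- length(r)
  C <- matrix(config$inter_factor_corr, k + 1, k + 1)
  diag(C) <- 1
  C[1, 2:(k + 1)] <- r
  C[2:(k + 1), 1] <- r
  ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
  if (!ok)
    config_error("infeasible correlation targets: implied latent correlation matrix is not positive definite")
  Z <- MASS::mvrnorm(n, rep(0, k + 1), C)
  list(deprivation = Z[, 1], factors = Z[, -1, drop = FALSE])
}

#' Simulate area assessments with covariates and ground truth
#'
#' Latent four-factor scores (higher = less desirable) are drawn jointly
#' with a latent deprivation index under the configured correlations; each
#' item's undesirability is `|loading| * factor + residual` and is then
#' expressed on the item's observation scale (binary via a median threshold,
#' ordinal via equal-probability cut points, proportion via a clamped affine
#' map), with the direction set by the item's `desirable_direction`.
#' Settlement types are assigned by the configured mix and deprivation
#' quintiles by ranking the index.
#'
#' @param config an [simulation_config()].
#' @param spec an [operat_instrument()] (default: the shipped instrument).
#' @param seed integer seed.
#' @return List: `assessments` (tibble: `area_id`, one column per item),
#'   `covariates` (tibble: `area_id`, `deprivation_index`,
#'   `deprivation_quintile`, `settlement_type`), `ground_truth` (list:
#'   `factors`, `deprivation`, `loadings`, `multipliers`).
#' @export
simulate_areas <- function(config = simulation_config(),
                           spec = default_instrument(), seed = NULL) {
  local_seed(seed, {
    n <- config$n_areas
    lat <- draw_latents(n, config)
    f <- lat$factors
    colnames(f) <- spec$domains$domain_id
    settlement <- sample(names(config$settlement_mix), n, replace = TRUE,
                         prob = config$settlement_mix)
    area_id <- sprintf("AA%02d %dZZ", seq_len(n) %% 100,
                       seq_len(n) %% 10)
    area_id <- make.unique(area_id, sep = "_")
    obs <- list(area_id = area_id)
    for (i in seq_len(nrow(spec$items))) {
      it <- spec$items[i, ]
      l <- abs(it$loading)
      if (is.na(l)) l <- 0.6
      u2 <- if (!is.null(config$uniqueness)) config$uniqueness[[it$item_id]]
            else max(1 - l^2, 0.05)
      t_i <- l * f[, it$domain_id] + rnorm(n, 0, sqrt(u2))
      s <- if (it$desirable_direction == "presence_bad") 1 else -1
      a <- s * t_i  # latent amount of the named feature
      obs[[it$item_id]] <- switch(
        it$value_kind,
        binary = as.integer(a > 0),
        ordinal = {
          L <- it$ordinal_levels
          breaks <- qnorm(seq_len(L - 1) / L) * sqrt(l^2 + u2)
          findInterval(a, breaks) + 1L
        },
        proportion = pmin(pmax(0.5 + a / 4, 0), 1))
    }
    quintile <- as.integer(cut(rank(lat$deprivation, ties.method = "first"),
                               breaks = seq(0, n, length.out = 6),
                               labels = FALSE))
    list(
      assessments = tibble::as_tibble(obs),
      covariates = tibble::tibble(
        area_id = area_id,
        deprivation_index = lat$deprivation,
        deprivation_quintile = quintile,
        settlement_type = settlement),
      ground_truth = list(factors = f, deprivation = lat$deprivation,
                          loadings = instrument_loading_matrix(spec),
                          multipliers = setNames(spec$items$multiplier,
                                                 spec$items$item_id)))
  })
}

#' Simulate the older-people weighting survey
#'
#' Each respondent's rating of an item is a draw around the item's planted
#' position `5 + w` on the 9-point scale (normal scatter, rounded and
#' clamped to 1..9), reported as the (valence, magnitude) pair the
#' questionnaire collects. A planted weight of `NA` produces a no-consensus
#' item: a half-and-half mixture of strongly favourable and strongly
#' unfavourable respondents.
#'
#' @param planted_weights named integer vector of signed weights (-4..4,
#'   nonzero), `NA` for a planted no-consensus item.
#' @param config an [simulation_config()] (uses `n_weighting_respondents`
#'   and `weighting_dispersion`).
#' @param seed integer seed.
#' @return Tibble: `respondent_id`, `item_id`, `feature_present`,
#'   `valence`, `magnitude`.
#' @export
simulate_weighting_survey <- function(planted_weights,
                                      config = simulation_config(),
                                      seed = NULL) {
  w <- planted_weights
  if (is.null(names(w))) arg_error("planted_weights must be named by item_id")
  if (any(!is.na(w) & (abs(w) > 4 | w != round(w))))
    arg_error("planted weights must be integers in -4..4 (or NA)")
  n <- config$n_weighting_respondents
  local_seed(seed, {
    rows <- lapply(names(w), function(id) {
      if (is.na(w[[id]])) {
        half <- n %/% 2
        sc <- c(round(rnorm(half, 2, 1)), round(rnorm(n - half, 8, 1)))
      } else {
        sc <- round(rnorm(n, 5 + w[[id]], config$weighting_dispersion))
      }
      sc <- pmin(pmax(sc, 1), 9)
      vm <- from_nine_point(sc)
      tibble::tibble(respondent_id = sprintf("W%04d", seq_len(n)),
                     item_id = id,
                     feature_present = sample(c("yes", "no"), n,
                                              replace = TRUE),
                     valence = vm$valence, magnitude = vm$magnitude)
    })
    do.call(rbind, rows)
  })
}

#' Simulate the resident validation survey
#'
#' Ages are normal (`age_mean`, `age_sd`) truncated at `age_min`; each
#' perception item is an equal-probability six-level discretisation of a
#' latent that couples to the area's factors per
#' `config$perception_coupling` (1 = strongly agree .. 6 = strongly
#' disagree, so positive couplings make disagreement grow with the factor).
#' The three attachment-importance items couple via
#' `config$attachment_coupling`, reversed so higher importance aligns with
#' the more desirable state. Ineligible returns (underage, missing age, or
#' an unlinkable postcode) are injected at `prop_ineligible` to exercise
#' eligibility filtering.
#'
#' @param areas output of [simulate_areas()].
#' @param config an [simulation_config()].
#' @param seed integer seed.
#' @return Tibble: `respondent_id`, `area_id`, `age`, the four perception
#'   items, and `scenery_importance`, `space_importance`,
#'   `peacefulness_importance`.
#' @export
simulate_residents <- function(areas, config = simulation_config(),
                               seed = NULL) {
  local_seed(seed, {
    n_total <- round(config$n_residents / (1 - config$prop_ineligible))
    f <- areas$ground_truth$factors
    idx <- sample(nrow(f), n_total, replace = TRUE)
    ## truncated-normal ages by inverse-CDF
    p0 <- pnorm(config$age_min, config$age_mean, config$age_sd)
    age <- qnorm(runif(n_total, p0, 1), config$age_mean, config$age_sd)
    area_id <- areas$assessments$area_id[idx]

    n_bad <- round(config$prop_ineligible * n_total)
    if (n_bad > 0) {
      bad <- sample(n_total, n_bad)
      kind <- sample(c("young", "no_age", "bad_postcode"), n_bad,
                     replace = TRUE, prob = c(0.2, 0.1, 0.7))
      age[bad[kind == "young"]] <- runif(sum(kind == "young"), 40,
                                         config$age_min - 0.5)
      age[bad[kind == "no_age"]] <- NA_real_
      area_id[bad[kind == "bad_postcode"]] <-
        sprintf("XX%02d 9XX", seq_len(sum(kind == "bad_postcode")))
    }

    six_level <- function(latent, sd_lat) {
      breaks <- qnorm(seq_len(5) / 6) * sd_lat
      findInterval(latent, breaks) + 1L
    }
    out <- list(respondent_id = sprintf("R%04d", seq_len(n_total)),
                area_id = area_id, age = round(age, 1))
    for (item in names(config$perception_coupling)) {
      cp <- config$perception_coupling[[item]]
      lat <- as.vector(f[idx, names(cp), drop = FALSE] %*% cp) +
        rnorm(n_total, 0, config$perception_noise_sd)
      sd_lat <- sqrt(sum((cp %o% cp) *
                           stats::cor(f)[names(cp), names(cp)]) +
                       config$perception_noise_sd^2)
      out[[item]] <- six_level(lat, sd_lat)
    }
    cp <- config$attachment_coupling
    for (item in c("scenery_importance", "space_importance",
                   "peacefulness_importance")) {
      lat <- as.vector(f[idx, names(cp), drop = FALSE] %*% cp) +
        rnorm(n_total, 0, config$perception_noise_sd)
      sd_lat <- sqrt(sum((cp %o% cp) *
                           stats::cor(f)[names(cp), names(cp)]) +
                       config$perception_noise_sd^2)
      out[[item]] <- six_level(lat, sd_lat)
    }
    tibble::as_tibble(out)
  })
}

#' Eligibility filter for resident surveys
#'
#' Retains respondents aged `age_min` or over with an `area_id` present in
#' the assessed areas (mirroring the published exclusion of underage,
#' ageless and unlinkable returns).
#'
#' @param survey resident survey tibble.
#' @param assessments assessed areas (for the valid `area_id` set).
#' @param age_min minimum eligible age (default 65).
#' @return The eligible subset, with attribute `n_excluded`.
#' @export
filter_eligible_residents <- function(survey, assessments, age_min = 65) {
  ok <- !is.na(survey$age) & survey$age >= age_min &
    as.character(survey$area_id) %in%
      as.character(assessments$area_id)
  out <- survey[ok, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Simulate a second rater's assessment sheets
#'
#' Copies rater A's sheets for `n_areas` areas and perturbs each item
#' independently: binary items flip with probability `rate`; ordinal items
#' move one level up or down with probability `rate` (clamped to the
#' scale); proportion items receive Gaussian jitter with SD `rate`, clamped
#' to \[0, 1\].
#'
#' @param assessments rater A's sheets.
#' @param spec an [operat_instrument()].
#' @param rate disagreement rate (default from [simulation_config()]).
#' @param n_areas how many areas the second rater assesses (default 10;
#'   `Inf` for all).
#' @param seed integer seed.
#' @return List: `rater_a`, `rater_b` (tibbles over the selected areas).
#' @export
simulate_second_rater <- function(assessments, spec, rate = 0.05,
                                  n_areas = 10, seed = NULL) {
  local_seed(seed, {
    n_areas <- min(n_areas, nrow(assessments))
    pick <- sort(sample(nrow(assessments), n_areas))
    a <- assessments[pick, , drop = FALSE]
    b <- a
    for (i in seq_len(nrow(spec$items))) {
      it <- spec$items[i, ]
      v <- b[[it$item_id]]
      n <- length(v)
      if (it$value_kind == "binary") {
        hit <- runif(n) < rate
        v[hit] <- 1L - v[hit]
      } else if (it$value_kind == "ordinal") {
        hit <- runif(n) < rate
        v[hit] <- pmin(pmax(v[hit] + sample(c(-1L, 1L), sum(hit),
                                            replace = TRUE), 1L),
                       it$ordinal_levels)
      } else {
        v <- pmin(pmax(v + rnorm(n, 0, rate), 0), 1)
      }
      b[[it$item_id]] <- v
    }
    list(rater_a = a, rater_b = b)
  })
}

#' Simulate every data stream of a full study
#'
#' Convenience wrapper producing a coherent bundle: assessments with
#' covariates, the weighting survey (planted signed weights are the shipped
#' multipliers, signed by each item's desirable direction), the resident
#' survey, the second-rater sheets, and the generating ground truth.
#'
#' @param config an [simulation_config()].
#' @param spec an [operat_instrument()].
#' @param seed integer seed driving all four streams.
#' @return List: `assessments`, `covariates`, `weighting_survey`,
#'   `resident_survey`, `rater_b_assessments` (plus `rater_a_subset`),
#'   `ground_truth`.
#' @export
simulate_operat_bundle <- function(config = simulation_config(),
                                   spec = default_instrument(),
                                   seed = 1) {
  areas <- simulate_areas(config, spec, seed = seed)
  planted <- ifelse(spec$items$desirable_direction == "presence_good",
                    spec$items$multiplier, -spec$items$multiplier)
  names(planted) <- spec$items$item_id
  weighting <- simulate_weighting_survey(planted, config, seed = seed + 1)
  residents <- simulate_residents(areas, config, seed = seed + 2)
  raters <- simulate_second_rater(areas$assessments, spec,
                                  rate = config$rater_disagreement_rate,
                                  n_areas = config$n_reliability_areas,
                                  seed = seed + 3)
  gt <- areas$ground_truth
  gt$planted_signed_weights <- planted
  list(assessments = areas$assessments, covariates = areas$covariates,
       weighting_survey = weighting, resident_survey = residents,
       rater_a_subset = raters$rater_a, rater_b_assessments = raters$rater_b,
       ground_truth = gt)
}
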