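spec <- default_spec

test_that("simulated areas honour the schema and declared ranges", {
  cfg <- simulation_config()
  sim <- simulate_areas(cfg, spec, seed = 21)
  expect_equal(nrow(sim$assessments), 405)
  expect_setequal(names(sim$assessments), c("area_id", spec$items$item_id))
  for (i in seq_len(nrow(spec$items))) {
    it <- spec$items[i, ]
    v <- sim$assessments[[it$item_id]]
    switch(it$value_kind,
      binary = expect_true(all(v %in% c(0, 1)), label = it$item_id),
      ordinal = expect_true(all(v %in% seq_len(it$ordinal_levels)),
                            label = it$item_id),
      proportion = expect_true(all(v >= 0 & v <= 1), label = it$item_id))
  }
  ## covariates: quintiles consistent with the index ranking
  cv <- sim$covariates
  expect_true(all(sort(unique(cv$deprivation_quintile)) == 1:5))
  agg <- tapply(cv$deprivation_index, cv$deprivation_quintile, mean)
  expect_true(all(diff(agg) > 0))
  expect_true(all(cv$settlement_type %in%
                    c("city_and_town", "rural_town_fringe",
                      "village_dispersed")))
})

test_that("the same seed reproduces every stream exactly", {
  cfg <- simulation_config(n_areas = 60, n_residents = 80,
                           n_weighting_respondents = 50)
  b1 <- simulate_operat_bundle(cfg, spec, seed = 33)
  b2 <- simulate_operat_bundle(cfg, spec, seed = 33)
  expect_identical(b1$assessments, b2$assessments)
  expect_identical(b1$weighting_survey, b2$weighting_survey)
  expect_identical(b1$resident_survey, b2$resident_survey)
  expect_identical(b1$rater_b_assessments, b2$rater_b_assessments)
  b3 <- simulate_operat_bundle(cfg, spec, seed = 34)
  expect_false(identical(b1$assessments, b3$assessments))
})

test_that("infeasible latent correlation targets raise a config error", {
  cfg <- simulation_config(
    inter_factor_corr = -0.4,
    factor_deprivation_corr = c(natural_elements = 0.9,
                                incivilities_nuisance = 0.9,
                                navigation_mobility = 0.9,
                                territorial_functioning = 0.9))
  expect_error(simulate_areas(cfg, spec, seed = 1),
               class = "operat_config_error")
})

test_that("deprivation coupling is calibrated at the survey scale", {
  cfg <- simulation_config()
  target <- cfg$factor_deprivation_corr[["territorial_functioning"]]
  sims <- vapply(1:5, function(s) {
    sim <- simulate_areas(cfg, spec, seed = 100 + s)
    sc <- score_batch(spec, sim$assessments)$scores
    cor(sc$transformed_territorial_functioning,
        sim$covariates$deprivation_index, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(sims) - target), 0.15)
})

test_that("resident simulation injects the designed ineligible fraction", {
  cfg <- simulation_config()
  areas <- simulate_areas(cfg, spec, seed = 41)
  res <- simulate_residents(areas, cfg, seed = 42)
  expect_equal(nrow(res), 606)
  kept <- filter_eligible_residents(res, areas$assessments)
  expect_equal(nrow(kept) + attr(kept, "n_excluded"), 606)
  expect_gt(nrow(kept) / nrow(res), 0.75)
  expect_lt(nrow(kept) / nrow(res), 0.90)
  expect_true(all(kept$age >= 65))
  expect_true(all(kept$area_id %in% areas$assessments$area_id))
  ## age moments in the modelled vicinity
  expect_gt(mean(kept$age), 72); expect_lt(mean(kept$age), 78)
  for (col in c("enjoy_living", "desirable_place", "safe_day", "safe_night",
                "scenery_importance", "space_importance",
                "peacefulness_importance"))
    expect_true(all(res[[col]] %in% 1:6), label = col)
})

test_that("a zero-disagreement second rater copies rater A exactly", {
  sim <- simulate_areas(simulation_config(n_areas = 15), spec, seed = 51)
  dup <- simulate_second_rater(sim$assessments, spec, rate = 0,
                               n_areas = 10, seed = 52)
  expect_identical(dup$rater_a, dup$rater_b)
  expect_equal(nrow(dup$rater_a), 10)
})

test_that("planted no-consensus survey items are excluded downstream", {
  planted <- c(good = 3L, bad = -2L, split = NA)
  survey <- simulate_weighting_survey(planted, simulation_config(),
                                      seed = 61)
  tw <- thurstone_weights(survey)
  expect_true(tw$excluded[tw$item_id == "split"])
  expect_equal(tw$consensus[tw$item_id == "split"], "none")
  expect_false(any(tw$excluded[tw$item_id != "split"]))
})

test_that("weights, structure and coupling signs survive a full bundle", {
  ## end-to-end integration: every stream of one bundle feeds its stage
  cfg <- simulation_config()
  bundle <- simulate_operat_bundle(cfg, spec, seed = 71)
  ## (a) planted multipliers recovered from the weighting survey
  tw <- thurstone_weights(bundle$weighting_survey)
  w <- weight_table(tw, spec)
  expect_equal(setNames(w$multiplier, w$item_id),
               bundle$ground_truth$multipliers)
  ## (b) four-factor structure in the latent item space
  X <- simulate_factor_data(bundle$ground_truth$loadings, 405, seed = 72)
  expect_equal(sum(fit_efa(X, 4)$eigenvalues > 1), 4)
  ## (c) planted deprivation coupling signs at the score level
  batch <- score_batch(spec, bundle$assessments)
  cv <- convergent_validity(
    batch$scores,
    filter_eligible_residents(bundle$resident_survey, bundle$assessments),
    bundle$covariates)
  area_rows <- cv[cv$level == "area", ]
  got <- setNames(sign(area_rows$rho), area_rows$domain_id)
  expect_equal(got[names(cfg$factor_deprivation_corr)],
               sign(cfg$factor_deprivation_corr))
  ## (d) reliability on the bundled second rater
  rel <- reliability_report(bundle$rater_a_subset,
                            bundle$rater_b_assessments, spec)
  expect_gt(mean(rel$items$alpha), 0.8)
})
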