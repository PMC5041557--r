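spec <- default_spec

test_that("recoding puts 0 at the most desirable state", {
  litter <- spec$items[spec$items$item_id == "litter_fouling_glass", ]
  expect_equal(recode_item(litter, 1), 1)  # undesirable feature present
  expect_equal(recode_item(litter, 0), 0)
  gardens <- spec$items[spec$items$item_id == "garden_maintenance", ]
  expect_equal(recode_item(gardens, 1.0), 0)   # all gardens kept: best state
  expect_equal(recode_item(gardens, 0.25), 0.75)
  ## ordinal: equally spaced grid, direction-aware
  pave <- spec$items[spec$items$item_id == "pavement_maintenance", ]
  expect_equal(recode_item(pave, 4), 0)  # best maintenance level
  expect_equal(recode_item(pave, 1), 1)
  expect_equal(recode_item(pave, 2), 2 / 3)
  expect_error(recode_item(litter, 2), class = "operat_data_error")
  expect_error(recode_item(gardens, 1.2), class = "operat_data_error")
})

test_that("weighted item scores scale the recoded value by the multiplier", {
  it <- spec$items[spec$items$item_id == "litter_fouling_glass", ]  # x4
  expect_equal(weighted_item_score(it, 1), 4)
  it2 <- spec$items[spec$items$item_id == "public_grass_verges", ] # x3
  expect_equal(weighted_item_score(it2, 1), 0)  # desirable feature present
  gard <- spec$items[spec$items$item_id == "garden_maintenance", ] # x3
  expect_equal(weighted_item_score(gard, 0.5), 1.5)
})

test_that("chi is 100 over the sum of the domain weights", {
  expect_equal(compute_chi(c(1, 1, 2, 1)), 20)
  expect_equal(compute_chi(c(1, 1, 1, 1)), 25)
  expect_equal(compute_chi(c(2, 2, 2, 2)), 12.5)
  expect_error(compute_chi(numeric(0)), class = "operat_argument_error")
  expect_error(compute_chi(c(1, 0, 2)), class = "operat_argument_error")
})

test_that("the domain transform maps raw ranges onto weighted shares", {
  expect_equal(transform_domain(13, 0, 13, 20, 2), 40)
  expect_equal(transform_domain(0, 0, 13, 20, 2), 0)
  expect_equal(transform_domain(5, 0, 10, 20, 1), 10)
  expect_error(transform_domain(14, 0, 13, 20, 2),
               class = "operat_data_error")
  expect_error(transform_domain(5, 0, 0, 20, 2),
               class = "operat_argument_error")
})

test_that("extreme assessments hit the published maxima exactly", {
  worst <- score_area(spec, extreme_assessment(spec, "worst"))
  expect_equal(worst$total, 100)
  expect_equal(unlist(worst[paste0("raw_", spec$domains$domain_id)]),
               c(9, 10, 13, 14), ignore_attr = TRUE)
  expect_equal(unlist(worst[paste0("transformed_", spec$domains$domain_id)]),
               c(20, 20, 40, 20), ignore_attr = TRUE)
  best <- score_area(spec, extreme_assessment(spec, "best"))
  expect_equal(best$total, 0)
})

test_that("worsening one navigation item raises the total by m/13 * 40", {
  obs <- extreme_assessment(spec, "best")
  it <- spec$items[spec$items$item_id == "legible_road_signs", ]
  base <- score_area(spec, obs)$total
  obs$legible_road_signs <- 0  # signs absent: worst state for this item
  expect_equal(score_area(spec, obs)$total - base,
               it$multiplier / 13 * 40)
})

test_that("the total equals the brute-force per-item contribution sum", {
  set.seed(101)
  for (rep in 1:25) {
    obs <- random_assessment(spec)
    expect_equal(score_area(spec, obs)$total, oracle_total(spec, obs))
  }
})

test_that("scores are monotone in item undesirability and bounded", {
  set.seed(202)
  for (rep in 1:25) {
    obs <- random_assessment(spec)
    s0 <- score_area(spec, obs)
    expect_gte(s0$total, 0); expect_lte(s0$total, 100)
    i <- sample(nrow(spec$items), 1)
    it <- spec$items[i, ]
    v <- obs[[it$item_id]]
    ## move the item strictly toward its less desirable state if possible
    worse <- if (it$desirable_direction == "presence_good") {
      switch(it$value_kind, binary = 0, proportion = max(v - 0.3, 0),
             ordinal = max(v - 1, 1))
    } else {
      switch(it$value_kind, binary = 1, proportion = min(v + 0.3, 1),
             ordinal = min(v + 1, it$ordinal_levels))
    }
    obs[[it$item_id]] <- worse
    s1 <- score_area(spec, obs)
    expect_gte(s1$total, s0$total - 1e-12)
    for (d in spec$domains$domain_id)
      expect_gte(s1[[paste0("transformed_", d)]],
                 s0[[paste0("transformed_", d)]] - 1e-12)
  }
})

test_that("batch scoring summarises correctly and handles edge cases", {
  rows <- rbind(as.data.frame(extreme_assessment(spec, "best", "B")),
                as.data.frame(extreme_assessment(spec, "worst", "W")))
  batch <- score_batch(spec, rows)
  tot <- batch$summary[batch$summary$domain == "Total", ]
  expect_equal(tot$min, 0); expect_equal(tot$max, 100)
  expect_equal(tot$mean, 50)
  one <- score_batch(spec, rows[1, ])
  expect_equal(unique(one$summary$sd), 0)
  expect_error(score_batch(spec, rows[0, ]), class = "operat_argument_error")
})

test_that("missing items error by name unless prorating is requested", {
  obs <- extreme_assessment(spec, "worst")
  obs$sounds_of_nature <- NULL
  err <- tryCatch(score_area(spec, obs), error = identity)
  expect_s3_class(err, "operat_data_error")
  expect_match(conditionMessage(err), "sounds_of_nature")
  pro <- score_area(spec, obs, allow_missing = "prorate")
  ## every observed item is at its worst state, so prorating keeps the max
  expect_equal(pro$total, 100)
})
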