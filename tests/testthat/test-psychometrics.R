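test_that("Krippendorff alpha equals the brute-force pair oracle", {
  ## perfect agreement on varied values
  M <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(krippendorff_alpha(M, "nominal")$alpha, 1)
  expect_equal(krippendorff_alpha(M, "interval")$alpha, 1)
  ## the worked small-matrix cases, all metrics, with missing ratings
  set.seed(91)
  for (rep in 1:40) {
    n_u <- sample(3:6, 1); n_r <- 3
    M <- matrix(sample(1:4, n_u * n_r, replace = TRUE), n_u, n_r)
    M[runif(n_u * n_r) < 0.15] <- NA
    mu <- rowSums(!is.na(M))
    if (sum(mu >= 2) < 2) next
    vals <- M[!is.na(M)]
    if (length(unique(vals)) < 2) next
    for (metric in c("nominal", "ordinal", "interval")) {
      expect_equal(krippendorff_alpha(M, metric)$alpha,
                   oracle_krippendorff(M, metric), tolerance = 1e-10,
                   info = metric)
    }
  }
})

test_that("alpha is near zero for chance-level second raters", {
  set.seed(101)
  alphas <- replicate(40, {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(a)  # same margin, no alignment
    krippendorff_alpha(cbind(a, b), "nominal")$alpha
  })
  expect_lt(abs(mean(alphas)), 0.1)
})

test_that("degenerate identical ratings report alpha 1 with a note", {
  res <- krippendorff_alpha(cbind(rep(2, 4), rep(2, 4)), "nominal")
  expect_equal(res$alpha, 1)
  expect_true(res$degenerate)
  expect_error(krippendorff_alpha(matrix(1, 3, 1), "nominal"),
               class = "operat_argument_error")
})

test_that("reliability report chooses metrics by item kind", {
  spec <- default_spec
  sim <- simulate_areas(simulation_config(n_areas = 12), spec, seed = 3)
  dup <- simulate_second_rater(sim$assessments, spec, rate = 0,
                               n_areas = 10, seed = 4)
  rep0 <- reliability_report(dup$rater_a, dup$rater_b, spec)
  expect_equal(rep0$n_perfect, 16)
  expect_true(all(rep0$items$alpha == 1))
  expect_equal(sort(unique(rep0$items$metric)),
               c("interval", "nominal", "ordinal"))
  ## misaligned area sets error with the mismatch listed
  b2 <- dup$rater_b
  b2$area_id[1] <- "ZZ9 9ZZ"
  expect_error(reliability_report(dup$rater_a, b2, spec),
               class = "operat_data_error")
})

test_that("heavy disagreement fails the 0.8 criterion", {
  spec <- default_spec
  sim <- simulate_areas(simulation_config(n_areas = 30), spec, seed = 5)
  noisy <- simulate_second_rater(sim$assessments, spec, rate = 0.5,
                                 n_areas = 30, seed = 6)
  rep5 <- reliability_report(noisy$rater_a, noisy$rater_b, spec)
  binary <- rep5$items[rep5$items$metric == "nominal", ]
  expect_true(all(binary$alpha < 0.8))
  expect_lt(mean(binary$alpha), 0.3)
})

test_that("item-domain consistency flags noise items and constants", {
  spec <- default_spec
  sim <- simulate_areas(simulation_config(n_areas = 200), spec, seed = 7)
  res <- item_domain_consistency(spec, sim$assessments)
  expect_equal(nrow(res), 16)
  expect_true(all(res$pass))  # structured data: every item tracks its domain
  ## replace one item with pure noise
  broken <- sim$assessments
  set.seed(8)
  broken$sounds_of_nature <- sample(0:1, 200, replace = TRUE)
  res2 <- item_domain_consistency(spec, broken)
  expect_lt(res2$rho[res2$item_id == "sounds_of_nature"],
            res$rho[res$item_id == "sounds_of_nature"])
  ## constant item: undefined correlation reported as a failure
  broken$sounds_of_nature <- 1
  res3 <- item_domain_consistency(spec, broken)
  row <- res3[res3$item_id == "sounds_of_nature", ]
  expect_false(row$pass)
  expect_equal(row$reason, "constant_item")
  expect_error(item_domain_consistency(spec, sim$assessments[1:5, ]),
               class = "operat_argument_error")
})

test_that("a single-item domain correlates perfectly with its total", {
  domains <- data.frame(domain_id = c("d1", "d2"), name = c("One", "Two"),
                        eag_weight = c(1L, 1L))
  items <- data.frame(item_id = c("solo", "x1", "x2"),
                      domain_id = c("d1", "d2", "d2"),
                      value_kind = "proportion",
                      desirable_direction = "presence_bad",
                      multiplier = c(2L, 1L, 1L))
  spec <- operat_instrument(items, domains)
  set.seed(9)
  sheets <- data.frame(area_id = sprintf("a%02d", 1:20),
                       solo = runif(20), x1 = runif(20), x2 = runif(20))
  res <- item_domain_consistency(spec, sheets)
  expect_equal(res$rho[res$item_id == "solo"], 1)
})

test_that("aesthetic attachment anchors at 0, 50 and 100", {
  df <- data.frame(scenery_importance = c(6, 1, 3.5),
                   space_importance = c(6, 1, 3.5),
                   peacefulness_importance = c(6, 1, 3.5))
  expect_equal(aesthetic_attachment(df), c(100, 0, 50))
  df$space_importance[2] <- NA
  expect_error(aesthetic_attachment(df), class = "operat_data_error")
  expect_equal(length(aesthetic_attachment(df, na_drop = TRUE)), 2)
})

test_that("variance explained reproduces the rounding conventions", {
  expect_equal(variance_explained(0.67, "truncate"), 44L)
  expect_equal(variance_explained(0.22, "round"), 5L)
  expect_equal(variance_explained(1, "round"), 100L)
  expect_equal(variance_explained(-0.11, "round"), 1L)
  expect_error(variance_explained(1.2), class = "operat_argument_error")
  set.seed(10)
  r <- runif(20, -1, 1)
  expect_equal(variance_explained(r, "round"),
               variance_explained(-r, "round"))
  expect_equal(variance_explained(r, "truncate"),
               variance_explained(-r, "truncate"))
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  scores <- tibble::tibble(area_id = sprintf("a%02d", 1:9),
                           transformed_d1 = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                           total = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
  cov <- data.frame(area_id = scores$area_id,
                    grp = rep(c("g1", "g2", "g3"), each = 3))
  res <- utility_anova(scores, cov, "grp")
  ## brute-force SS decomposition: between = 3*((2-3)^2+(3-3)^2+(4-3)^2) = 6
  ## within = 6, df (2, 6) -> F = (6/2)/(6/6) = 3
  r1 <- res[res$domain_id == "d1", ]
  expect_equal(r1$F, 3)
  expect_equal(c(r1$df_between, r1$df_within), c(2, 6))
  expect_gt(r1$p_value, 0.05)
  ## SS conservation on arbitrary data
  set.seed(11)
  scores2 <- tibble::tibble(area_id = sprintf("b%02d", 1:40),
                            transformed_d1 = rnorm(40), total = rnorm(40))
  cov2 <- data.frame(area_id = scores2$area_id,
                     grp = sample(c("x", "y", "z"), 40, replace = TRUE))
  y <- scores2$transformed_d1
  g <- cov2$grp
  ss_tot <- sum((y - mean(y))^2)
  ss_b <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  ss_w <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  expect_equal(ss_tot, ss_b + ss_w)
  res2 <- utility_anova(scores2, cov2, "grp")
  expect_equal(res2$F[res2$domain_id == "d1"],
               (ss_b / 2) / (ss_w / (40 - 3)))
})

test_that("with two groups F equals the squared t statistic", {
  set.seed(12)
  scores <- tibble::tibble(area_id = sprintf("c%02d", 1:30),
                           transformed_d1 = rnorm(30), total = rnorm(30))
  cov <- data.frame(area_id = scores$area_id,
                    grp = rep(c("a", "b"), 15))
  res <- utility_anova(scores, cov, "grp")
  tt <- t.test(transformed_d1 ~ grp,
               data = cbind(scores, grp = cov$grp), var.equal = TRUE)
  expect_equal(res$F[res$domain_id == "d1"], unname(tt$statistic)^2)
  ## a group of one observation errors
  cov$grp[cov$grp == "b"][2:15] <- "a"
  expect_error(utility_anova(scores, cov, "grp"),
               class = "operat_data_error")
})

test_that("a planted mean shift isolates its group in the Tukey subsets", {
  set.seed(13)
  hits <- replicate(10, {
    n <- 120
    grp <- sample(c("city_and_town", "rural_town_fringe",
                    "village_dispersed"), n, replace = TRUE)
    y <- rnorm(n) + ifelse(grp == "village_dispersed", 2.5, 0)
    scores <- tibble::tibble(area_id = sprintf("d%03d", 1:n),
                             transformed_d1 = y, total = y)
    cov <- data.frame(area_id = scores$area_id, grp = grp)
    res <- utility_anova(scores, cov, "grp")
    subs <- res$tukey_subsets[res$domain_id == "d1"][[1]]
    any(vapply(subs, function(s) identical(s, "village_dispersed"),
               logical(1)))
  })
  expect_gte(mean(hits), 0.8)
})

test_that("convergent validity recovers planted coupling signs", {
  spec <- default_spec
  cfg <- simulation_config()
  areas <- simulate_areas(cfg, spec, seed = 14)
  batch <- score_batch(spec, areas$assessments)
  residents <- filter_eligible_residents(
    simulate_residents(areas, cfg, seed = 15), areas$assessments)
  cv <- convergent_validity(batch$scores, residents, areas$covariates)
  pick <- function(level, measure, domain)
    cv$rho[cv$level == level & cv$measure == measure &
             cv$domain_id == domain]
  ## safety disagreement grows with incivilities; attachment tracks
  ## natural elements negatively; deprivation couples positively to
  ## territorial functioning
  expect_gt(pick("individual", "safe_night", "incivilities_nuisance"), 0)
  expect_lt(pick("individual", "aesthetic_attachment", "natural_elements"), 0)
  expect_gt(pick("area", "deprivation_index", "territorial_functioning"), 0.3)
  expect_error(convergent_validity(batch$scores,
                                   within(residents,
                                          area_id <- "QQ1 1QQ"),
                                   areas$covariates),
               class = "operat_data_error")
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(16)
  x <- rnorm(40); y <- rnorm(40) + 0.5 * x
  k1 <- kendall_tau_b(x, y)$tau_b
  k2 <- kendall_tau_b(exp(x), y^3 + 5 * y)$tau_b
  expect_equal(k1, k2)
  s1 <- cor(x, y, method = "spearman")
  s2 <- cor(exp(x), y^3 + 5 * y, method = "spearman")
  expect_equal(s1, s2)
})
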