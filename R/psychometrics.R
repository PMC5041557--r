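## Validation statistics: internal consistency, convergent validity,
## utility (ANOVA + Tukey homogeneous subsets) and helpers.

#' Item-domain internal consistency
#'
#' Spearman rank correlation of each weighted item score with its domain
#' total. Following the published criterion the item is included in the
#' total it is correlated against (set `include_item = FALSE` for the
#' stricter item-rest convention); an item passes at `min_r` (default 0.2).
#' A constant item has no defined correlation and is reported as failing
#' with reason `"constant_item"`.
#'
#' @param spec an [operat_instrument()].
#' @param assessments data frame of raw assessments (>= 10 areas).
#' @param include_item include the item in its domain total (default TRUE).
#' @param min_r pass threshold (default 0.2).
#' @return Tibble: `item_id`, `domain_id`, `rho`, `pass`, `reason`.
#' @export
item_domain_consistency <- function(spec, assessments, include_item = TRUE,
                                    min_r = 0.2) {
  if (nrow(assessments) < 10L)
    arg_error("need at least 10 areas for item-domain consistency")
  W <- sapply(seq_len(nrow(spec$items)), function(i)
    weighted_item_score(spec$items[i, ], assessments[[spec$items$item_id[i]]]))
  colnames(W) <- spec$items$item_id
  rows <- lapply(seq_len(nrow(spec$items)), function(i) {
    it <- spec$items[i, ]
    members <- spec$items$item_id[spec$items$domain_id == it$domain_id]
    tot_members <- if (include_item) members else setdiff(members, it$item_id)
    total <- rowSums(W[, tot_members, drop = FALSE])
    x <- W[, it$item_id]
    if (sd(x) == 0 || sd(total) == 0)
      return(tibble::tibble(item_id = it$item_id, domain_id = it$domain_id,
                            rho = NA_real_, pass = FALSE,
                            reason = "constant_item"))
    rho <- cor(x, total, method = "spearman")
    tibble::tibble(item_id = it$item_id, domain_id = it$domain_id,
                   rho = rho, pass = rho >= min_r, reason = NA_character_)
  })
  do.call(rbind, rows)
}

#' Aesthetic attachment to place
#'
#' Composite of the importance ratings for scenery, space and peacefulness:
#' their sum, min-max transformed to 0--100 with higher = greater
#' attachment. Respondents missing any of the three items are excluded
#' (listwise) and raise an error unless `na_drop = TRUE`.
#'
#' @param survey data frame holding the three item columns.
#' @param items names of the three importance columns.
#' @param scale_min,scale_max anchors of each item's response scale
#'   (default 1 and 6, higher = more important).
#' @param na_drop drop incomplete respondents instead of erroring.
#' @return Numeric vector (0--100), one value per (complete) respondent.
#' @export
aesthetic_attachment <- function(survey,
                                 items = c("scenery_importance",
                                           "space_importance",
                                           "peacefulness_importance"),
                                 scale_min = 1, scale_max = 6,
                                 na_drop = FALSE) {
  miss <- setdiff(items, names(survey))
  if (length(miss))
    arg_error(paste0("missing attachment column(s): ",
                     paste(miss, collapse = ", ")))
  M <- as.matrix(survey[items])
  incomplete <- !stats::complete.cases(M)
  if (any(incomplete)) {
    if (!na_drop)
      data_error(paste0(sum(incomplete),
                        " respondent(s) missing an attachment item"))
    M <- M[!incomplete, , drop = FALSE]
  }
  if (any(M < scale_min | M > scale_max))
    data_error("attachment responses outside the declared scale")
  s <- rowSums(M)
  lo <- length(items) * scale_min
  hi <- length(items) * scale_max
  (s - lo) / (hi - lo) * 100
}

#' Convergent validity correlation table
#'
#' Spearman correlations (with p-values) between each transformed domain
#' score and (a) at the individual level, each resident perception item and
#' the aesthetic-attachment composite, each respondent paired with their
#' area's scores; (b) at the area level, the deprivation index.
#'
#' @param scores output of [score_batch()]`$scores` (or [score_area()] rows).
#' @param surveys resident survey data frame with `area_id` and perception
#'   columns.
#' @param covariates data frame with `area_id` and `deprivation_index`
#'   (optional; area-level rows are skipped when absent).
#' @param perception_items perception columns to correlate (default: the
#'   four standard items plus attachment when its inputs are present).
#' @param alpha significance level used for the `significant` flag.
#' @return Tibble: `level` (individual/area), `measure`, `domain_id`, `rho`,
#'   `p_value`, `n`, `significant`.
#' @export
convergent_validity <- function(scores, surveys, covariates = NULL,
                                perception_items = c("enjoy_living",
                                                     "desirable_place",
                                                     "safe_day",
                                                     "safe_night"),
                                alpha = 0.05) {
  dom_cols <- grep("^transformed_", names(scores), value = TRUE)
  link <- match(as.character(surveys$area_id), as.character(scores$area_id))
  if (all(is.na(link))) data_error("no respondents link to scored areas")
  surveys <- surveys[!is.na(link), , drop = FALSE]
  link <- link[!is.na(link)]
  measures <- list()
  for (it in intersect(perception_items, names(surveys)))
    measures[[it]] <- surveys[[it]]
  att_items <- c("scenery_importance", "space_importance",
                 "peacefulness_importance")
  if (all(att_items %in% names(surveys)))
    measures[["aesthetic_attachment"]] <-
      aesthetic_attachment(surveys, na_drop = FALSE)
  rows <- list()
  spearman_row <- function(level, measure, domain, x, y) {
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    tibble::tibble(level = level, measure = measure, domain_id = domain,
                   rho = unname(ct$estimate), p_value = ct$p.value, n = n,
                   significant = ct$p.value < alpha)
  }
  for (m in names(measures)) for (dc in dom_cols) {
    rows[[length(rows) + 1L]] <- spearman_row(
      "individual", m, sub("^transformed_", "", dc),
      scores[[dc]][link], measures[[m]])
  }
  if (!is.null(covariates) && "deprivation_index" %in% names(covariates)) {
    alink <- match(as.character(scores$area_id),
                   as.character(covariates$area_id))
    for (dc in dom_cols) {
      rows[[length(rows) + 1L]] <- spearman_row(
        "area", "deprivation_index", sub("^transformed_", "", dc),
        scores[[dc]], covariates$deprivation_index[alink])
    }
  }
  do.call(rbind, rows)
}

#' Percent of variance explained by a rank correlation
#'
#' \eqn{100 r_s^2} reported as an integer percent, either rounded (half away
#' from zero) or truncated. Symmetric in the sign of `r_s`.
#'
#' @param r_s Spearman correlation, |r_s| <= 1.
#' @param mode `"round"` or `"truncate"`.
#' @return Integer percent.
#' @examples
#' variance_explained(0.67, "truncate")  # 44
#' variance_explained(0.22, "round")     # 5
#' @export
variance_explained <- function(r_s, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (any(!is.finite(r_s)) || any(abs(r_s) > 1))
    arg_error("|r_s| must be <= 1")
  pct <- 100 * r_s^2
  out <- if (mode == "round") round_half_up(pct) else floor(pct)
  as.integer(out)
}

## SPSS-style homogeneous subsets: groups sorted by mean; greedy maximal
## runs in which every pairwise Tukey comparison is non-significant.
tukey_subsets <- function(means, p_matrix, alpha = 0.05) {
  g <- names(sort(means))
  subsets <- list()
  i <- 1L
  while (i <= length(g)) {
    j <- i
    while (j < length(g)) {
      cand <- g[i:(j + 1L)]
      ps <- outer(cand, cand, Vectorize(function(a, b)
        if (a == b) 1 else p_matrix[a, b]))
      if (min(ps) > alpha) j <- j + 1L else break
    }
    subsets[[length(subsets) + 1L]] <- g[i:j]
    i <- if (j < length(g)) j + 1L else j + 1L
  }
  ## drop subsets fully contained in another
  keep <- vapply(seq_along(subsets), function(a)
    !any(vapply(seq_along(subsets), function(b)
      a != b && all(subsets[[a]] %in% subsets[[b]]), logical(1))),
    logical(1))
  subsets[keep]
}

#' Utility of the instrument across area strata
#'
#' One-way ANOVA of each transformed domain score (and the total) across a
#' grouping of areas (deprivation quintile or settlement type), with Tukey
#' HSD post hoc tests aggregated into homogeneous subsets: groups whose
#' pairwise comparisons are all non-significant at `alpha` share a subset.
#'
#' @param scores scored areas ([score_batch()]`$scores`).
#' @param covariates data frame with `area_id` and the grouping column.
#' @param grouping name of the grouping column in `covariates` (e.g.
#'   `"deprivation_quintile"` or `"settlement_type"`).
#' @param alpha significance level for the subsets.
#' @return Tibble: `domain_id`, `F`, `df_between`, `df_within`, `p_value`,
#'   and list-columns `group_means`, `tukey_subsets`.
#' @export
utility_anova <- function(scores, covariates, grouping, alpha = 0.05) {
  if (!grouping %in% names(covariates))
    arg_error(paste0("grouping column not found: ", grouping))
  g <- factor(covariates[[grouping]][match(as.character(scores$area_id),
                                           as.character(covariates$area_id))])
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L))
    data_error("need >= 2 groups with >= 2 observations each")
  dom_cols <- c(grep("^transformed_", names(scores), value = TRUE), "total")
  rows <- lapply(dom_cols, function(dc) {
    y <- scores[[dc]]
    fit <- aov(y ~ g)
    an <- summary(fit)[[1]]
    tuk <- TukeyHSD(fit)$g
    lv <- levels(g)
    P <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
    for (r in rownames(tuk)) {
      ab <- strsplit(r, "-", fixed = TRUE)[[1]]
      P[ab[1], ab[2]] <- P[ab[2], ab[1]] <- tuk[r, "p adj"]
    }
    means <- tapply(y, g, mean)
    tibble::tibble(
      domain_id = sub("^transformed_", "", dc),
      F = an$`F value`[1],
      df_between = an$Df[1], df_within = an$Df[2],
      p_value = an$`Pr(>F)`[1],
      group_means = list(means),
      tukey_subsets = list(tukey_subsets(means, P, alpha)))
  })
  do.call(rbind, rows)
}
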