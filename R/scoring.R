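## Composite scoring: item recoding, weighting, domain aggregation and the
## chi-normalised 0-100 total. Higher scores always represent the less
## desirable state.

#' Normalising constant for domain weighting
#'
#' \eqn{\chi = 100 / \sum_d w_d}, where \eqn{w_d} are the positive integer
#' expert-panel weights of the domains. The maximum transformed score of
#' domain \eqn{d} is then \eqn{\chi w_d}, so the maxima always sum to 100.
#'
#' @param eag_weights vector of positive domain weights.
#' @return A positive scalar.
#' @examples
#' compute_chi(c(1, 1, 2, 1))  # 20
#' @export
compute_chi <- function(eag_weights) {
  if (!length(eag_weights) || !is.numeric(eag_weights))
    arg_error("eag_weights must be a nonempty numeric vector")
  if (any(!is.finite(eag_weights)) || any(eag_weights <= 0))
    arg_error("eag_weights must all be positive")
  100 / sum(eag_weights)
}

item_row <- function(spec, item) {
  if (is.character(item)) {
    j <- match(item, spec$items$item_id)
    if (is.na(j)) arg_error(paste0("unknown item_id: ", item))
    spec$items[j, ]
  } else item
}

## normalised "amount of feature present" in [0,1] on the item's scale
feature_amount <- function(item, raw_value) {
  v <- as.numeric(raw_value)
  kind <- item$value_kind
  if (kind == "binary") {
    if (any(!v %in% c(0, 1)))
      data_error(paste0("binary item '", item$item_id,
                        "' takes values in {0,1}"))
    v
  } else if (kind == "proportion") {
    if (any(v < 0 | v > 1 | !is.finite(v)))
      data_error(paste0("proportion item '", item$item_id,
                        "' takes values in [0,1]"))
    v
  } else {
    L <- item$ordinal_levels
    if (any(!is.finite(v) | v < 1 | v > L | v != round(v)))
      data_error(paste0("ordinal item '", item$item_id,
                        "' takes integer values in 1..", L))
    (v - 1) / (L - 1)
  }
}

#' Recode a raw observation onto the 0 = best, 1 = worst scale
#'
#' Every observation is mapped to \[0, 1\] with 0 the most desirable state
#' and 1 the least desirable. Binary and proportion items whose feature is
#' desirable return \eqn{1 - v}; undesirable features return \eqn{v}
#' unchanged. Ordinal items are first placed on an equally spaced \[0, 1\]
#' grid over their declared levels.
#'
#' @param item one row of an instrument's `items` table, or an `item_id`
#'   looked up in `spec`.
#' @param raw_value observation(s) on the item's declared scale.
#' @param spec instrument, required when `item` is an id string.
#' @return Numeric vector in \[0, 1\].
#' @export
recode_item <- function(item, raw_value, spec = NULL) {
  if (is.character(item)) item <- item_row(spec, item)
  u <- feature_amount(item, raw_value)
  if (item$desirable_direction == "presence_good") 1 - u else u
}

#' Weighted item contribution to the raw domain score
#'
#' The recoded 0--1 value multiplied by the item's Thurstone-derived integer
#' multiplier; ranges over \[0, multiplier\].
#'
#' @inheritParams recode_item
#' @return Numeric vector in \[0, multiplier\].
#' @export
weighted_item_score <- function(item, raw_value, spec = NULL) {
  if (is.character(item)) item <- item_row(spec, item)
  recode_item(item, raw_value) * item$multiplier
}

assessment_values <- function(assessment) {
  if (is.data.frame(assessment)) {
    stopifnot(nrow(assessment) == 1L)
    assessment <- as.list(assessment)
  }
  assessment
}

#' Raw score of one domain for one area
#'
#' Sum of the weighted item scores of the domain's member items. A missing
#' item is a hard error by default; with `allow_missing = "prorate"` the
#' domain score is scaled up from the observed items by
#' `raw_max / observed_max` so partial walks remain comparable (the result
#' carries a `prorated` attribute).
#'
#' @param spec an [operat_instrument()].
#' @param assessment named list or one-row data frame mapping `item_id` to
#'   the raw observation.
#' @param domain_id domain to score.
#' @param allow_missing `"error"` (default) or `"prorate"`.
#' @return Scalar in \[0, raw_max\].
#' @export
raw_domain_score <- function(spec, assessment, domain_id,
                             allow_missing = c("error", "prorate")) {
  allow_missing <- match.arg(allow_missing)
  obs <- assessment_values(assessment)
  items <- spec$items[spec$items$domain_id == domain_id, ]
  if (!nrow(items)) arg_error(paste0("unknown domain_id: ", domain_id))
  have <- vapply(items$item_id, function(id)
    !is.null(obs[[id]]) && !is.na(obs[[id]]), logical(1))
  if (!all(have)) {
    missing_ids <- items$item_id[!have]
    if (allow_missing == "error")
      data_error(paste0("incomplete assessment: missing item(s) ",
                        paste(missing_ids, collapse = ", ")))
    items <- items[have, ]
    if (!nrow(items))
      data_error(paste0("no observed items in domain ", domain_id))
  }
  total <- sum(vapply(seq_len(nrow(items)), function(i)
    weighted_item_score(items[i, ], obs[[items$item_id[i]]]), numeric(1)))
  full_max <- spec$domains$raw_max[spec$domains$domain_id == domain_id]
  obs_max <- sum(items$multiplier)
  if (obs_max < full_max) {
    total <- total * full_max / obs_max
    attr(total, "prorated") <- TRUE
  }
  total
}

#' Min-max transform of a raw domain score onto its weighted share of 100
#'
#' \deqn{T = \frac{raw - raw_{min}}{range} \times \chi w_d}
#' so the transformed score lies in \[0, chi * eag_weight\].
#'
#' @param raw raw domain score.
#' @param raw_min lowest possible raw score (0 for all shipped domains).
#' @param raw_range possible raw score range (> 0).
#' @param chi normalising constant from [compute_chi()].
#' @param eag_weight the domain's expert-panel weight.
#' @return Transformed score(s).
#' @export
transform_domain <- function(raw, raw_min, raw_range, chi, eag_weight) {
  if (!is_scalar_number(raw_range) || raw_range <= 0)
    arg_error("raw_range must be a positive scalar")
  if (any(raw < raw_min - 1e-9 | raw > raw_min + raw_range + 1e-9))
    data_error("raw score outside [raw_min, raw_min + raw_range]")
  (raw - raw_min) / raw_range * chi * eag_weight
}

#' Score a single area assessment
#'
#' Computes the four raw domain scores, the four transformed domain scores
#' and the composite total (sum of the transformed scores, in \[0, 100\],
#' higher = less desirable).
#'
#' @inheritParams raw_domain_score
#' @return One-row tibble: `area_id`, `raw_<domain>` and
#'   `transformed_<domain>` for each domain, and `total`.
#' @export
score_area <- function(spec, assessment,
                       allow_missing = c("error", "prorate")) {
  allow_missing <- match.arg(allow_missing)
  obs <- assessment_values(assessment)
  area_id <- obs$area_id %||% NA_character_
  out <- list(area_id = as.character(area_id))
  total <- 0
  for (i in seq_len(nrow(spec$domains))) {
    d <- spec$domains[i, ]
    raw <- raw_domain_score(spec, obs, d$domain_id, allow_missing)
    tr <- transform_domain(as.numeric(raw), d$raw_min, d$raw_max - d$raw_min,
                           spec$chi, d$eag_weight)
    out[[paste0("raw_", d$domain_id)]] <- as.numeric(raw)
    out[[paste0("transformed_", d$domain_id)]] <- tr
    total <- total + tr
  }
  out$total <- total
  tibble::as_tibble(out)
}

#' Score a batch of area assessments
#'
#' @param spec an [operat_instrument()].
#' @param assessments data frame, one row per area, with an `area_id` column
#'   and one column per item.
#' @inheritParams raw_domain_score
#' @return List with `scores` (tibble of per-area [score_area()] rows) and
#'   `summary` (per domain and total: maximum possible raw and transformed
#'   scores, observed min/max/mean/median/SD).
#' @export
score_batch <- function(spec, assessments,
                        allow_missing = c("error", "prorate")) {
  allow_missing <- match.arg(allow_missing)
  if (!is.data.frame(assessments) || !nrow(assessments))
    arg_error("assessments must be a data frame with at least one row")
  scores <- do.call(rbind, lapply(seq_len(nrow(assessments)), function(i)
    score_area(spec, assessments[i, ], allow_missing)))
  cols <- c(paste0("transformed_", spec$domains$domain_id), "total")
  labels <- c(spec$domains$name, "Total")
  max_raw <- c(spec$domains$raw_max, NA)
  max_tr <- c(spec$chi * spec$domains$eag_weight, 100)
  summary <- tibble::tibble(
    domain = labels,
    max_raw = max_raw,
    max_transformed = max_tr,
    min = vapply(cols, function(cn) min(scores[[cn]]), numeric(1),
                 USE.NAMES = FALSE),
    max = vapply(cols, function(cn) max(scores[[cn]]), numeric(1),
                 USE.NAMES = FALSE),
    mean = vapply(cols, function(cn) mean(scores[[cn]]), numeric(1),
                  USE.NAMES = FALSE),
    median = vapply(cols, function(cn) median(scores[[cn]]), numeric(1),
                    USE.NAMES = FALSE),
    sd = vapply(cols, function(cn)
      if (nrow(scores) < 2L) 0 else sd(scores[[cn]]), numeric(1),
      USE.NAMES = FALSE))
  list(scores = scores, summary = summary)
}
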