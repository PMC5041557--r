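## Thurstone-style item weighting from the older-people importance survey.
##
## Each respondent rates each candidate feature with a valence (good/bad
## feature) and a magnitude (how much it affects satisfaction). The pair is
## folded onto a 9-point favourability scale whose midpoint 5 is "not at
## all"; the item weight is the median of that distribution minus 5, and its
## absolute value (clamped to 1..4) becomes the item's scoring multiplier.

MAGNITUDE_LEVELS <- c("not_at_all", "very_little", "a_little",
                      "quite_a_lot", "a_great_deal")
VALENCE_LEVELS <- c("negative", "positive")

#' Fold a (valence, magnitude) rating onto the 9-point favourability scale
#'
#' The scale runs from 1 = "a great deal (unfavourably)" to 9 = "a great
#' deal (favourably)" with midpoint 5 = "not at all" (valence is ignored at
#' the midpoint). The map is a bijection between the valenced magnitude
#' ladder and 1..9.
#'
#' @param valence `"positive"`, `"negative"`, or `NA` (allowed only when
#'   `magnitude` is `"not_at_all"`).
#' @param magnitude one of `"not_at_all"`, `"very_little"`, `"a_little"`,
#'   `"quite_a_lot"`, `"a_great_deal"`.
#' @return Integer vector on 1..9; `NA` (with the record expected to be
#'   dropped upstream) where a non-midpoint magnitude has no valence.
#' @examples
#' to_nine_point("positive", "a_great_deal")  # 9
#' to_nine_point(NA, "not_at_all")            # 5
#' @export
to_nine_point <- function(valence, magnitude) {
  n <- max(length(valence), length(magnitude))
  valence <- rep_len(as.character(valence), n)
  magnitude <- rep_len(as.character(magnitude), n)
  bad <- !magnitude %in% MAGNITUDE_LEVELS
  if (any(bad))
    arg_error(paste0("invalid magnitude value(s): ",
                     paste(unique(magnitude[bad]), collapse = ", ")))
  bad <- !(is.na(valence) | valence %in% VALENCE_LEVELS)
  if (any(bad))
    arg_error(paste0("invalid valence value(s): ",
                     paste(unique(valence[bad]), collapse = ", ")))
  step <- match(magnitude, MAGNITUDE_LEVELS) - 1L  # 0..4
  out <- ifelse(step == 0L, 5L,
         ifelse(is.na(valence), NA_integer_,
         ifelse(valence == "positive", 5L + step, 5L - step)))
  as.integer(out)
}

## inverse of to_nine_point, used by the synthetic survey generator
from_nine_point <- function(score) {
  stopifnot(all(score %in% 1:9))
  step <- abs(score - 5L)
  list(valence = ifelse(step == 0L, NA_character_,
                        ifelse(score > 5L, "positive", "negative")),
       magnitude = MAGNITUDE_LEVELS[step + 1L])
}

## median on the 9-point grid; an even-count median falling between two scale
## points is rounded toward the midpoint 5 (conservative weighting).
nine_point_median <- function(scores) {
  s <- sort(scores)
  n <- length(s)
  if (n %% 2L == 1L) return(s[(n + 1L) / 2L])
  m <- (s[n / 2L] + s[n / 2L + 1L]) / 2
  if (m == round(m)) return(as.integer(m))
  as.integer(if (m > 5) floor(m) else ceiling(m))
}

#' Thurstone weight of a single item
#'
#' Builds the item's 9-point rating distribution, takes its median as the raw
#' weight, subtracts the midpoint 5 to give the signed weight in -4..4, and
#' derives the integer scoring multiplier `|signed weight|` (in 1..4).
#' Items without a clear valence consensus, or with signed weight 0, are
#' excluded (multiplier `NA`).
#'
#' Consensus is operationalised as: at least `consensus` (default 0.70) of
#' the non-midpoint responses share one valence. Respondents giving a
#' non-midpoint magnitude without a valence are dropped for this item and
#' counted in `n_dropped`.
#'
#' @param responses data frame for one item with columns `valence` and
#'   `magnitude` (and optionally `respondent_id`, `item_id`).
#' @param consensus minimum share of non-midpoint responses agreeing in
#'   valence for a clear consensus.
#' @return One-row tibble: `item_id`, `n_used`, `n_dropped`, `raw_weight`,
#'   `signed_weight`, `multiplier` (NA when excluded), `consensus`
#'   (`"clear"`/`"none"`), `excluded`, `exclusion_reason`, and a list-column
#'   `distribution` (counts over 1..9).
#' @export
item_weight <- function(responses, consensus = 0.7) {
  item_id <- if (!is.null(responses$item_id) && nrow(responses))
    as.character(responses$item_id[1]) else NA_character_
  scores <- to_nine_point(responses$valence, responses$magnitude)
  n_dropped <- sum(is.na(scores))
  scores <- scores[!is.na(scores)]
  if (!length(scores))
    data_error(paste0("no usable responses for item ",
                      item_id %||% "<unknown>"))
  dist <- tabulate(scores, nbins = 9L)
  raw <- nine_point_median(scores)
  signed <- raw - 5L
  n_neg <- sum(scores < 5L); n_pos <- sum(scores > 5L)
  share <- if (n_neg + n_pos == 0L) 1 else max(n_neg, n_pos) / (n_neg + n_pos)
  clear <- share >= consensus
  excluded <- !clear || signed == 0L
  reason <- if (!clear) "no_consensus"
            else if (signed == 0L) "zero_weight"
            else NA_character_
  tibble::tibble(
    item_id = item_id,
    n_used = length(scores), n_dropped = n_dropped,
    raw_weight = as.integer(raw), signed_weight = as.integer(signed),
    multiplier = if (excluded) NA_integer_
                 else as.integer(min(max(abs(signed), 1L), 4L)),
    consensus = if (clear) "clear" else "none",
    excluded = excluded, exclusion_reason = reason,
    distribution = list(dist))
}

#' Thurstone weights for every item in a weighting survey
#'
#' @param survey data frame with columns `respondent_id`, `item_id`,
#'   `valence`, `magnitude` (rows with `NA` magnitude are treated as the
#'   respondent skipping that item and dropped listwise per item).
#' @inheritParams item_weight
#' @return Tibble with one [item_weight()] row per item, ordered by
#'   `item_id`.
#' @export
thurstone_weights <- function(survey, consensus = 0.7) {
  if (!all(c("item_id", "valence", "magnitude") %in% names(survey)))
    arg_error("survey needs columns item_id, valence, magnitude")
  survey <- survey[!is.na(survey$magnitude), , drop = FALSE]
  ids <- sort(unique(as.character(survey$item_id)))
  do.call(rbind, lapply(ids, function(id)
    item_weight(survey[survey$item_id == id, , drop = FALSE], consensus)))
}

#' Rank items by mean importance
#'
#' Items are ranked by the mean of the magnitude responses (ignoring
#' valence), scored 1 = "not at all" .. 5 = "a great deal"; descending, with
#' ties broken lexicographically by `item_id` (stable).
#'
#' @param survey weighting-survey data frame (see [thurstone_weights()]).
#' @return Tibble `item_id`, `mean_importance`, `rank`.
#' @export
rank_items <- function(survey) {
  if (!nrow(survey)) arg_error("empty survey")
  survey <- survey[!is.na(survey$magnitude), , drop = FALSE]
  imp <- match(as.character(survey$magnitude), MAGNITUDE_LEVELS)
  means <- tapply(imp, as.character(survey$item_id), mean)
  ord <- order(-means, names(means), method = "radix")
  tibble::tibble(item_id = names(means)[ord],
                 mean_importance = as.numeric(means)[ord],
                 rank = seq_along(ord))
}

#' Build an instrument weight table from Thurstone results
#'
#' Joins derived multipliers onto an instrument's item table, flagging
#' excluded items; used to regenerate or audit the shipped multiplier table.
#'
#' @param weights output of [thurstone_weights()].
#' @param spec optional [operat_instrument()] whose items are to be matched.
#' @return Tibble `item_id`, `signed_weight`, `multiplier`, `excluded`,
#'   `exclusion_reason`.
#' @export
weight_table <- function(weights, spec = NULL) {
  out <- weights[, c("item_id", "signed_weight", "multiplier", "excluded",
                     "exclusion_reason")]
  if (!is.null(spec)) {
    miss <- setdiff(spec$items$item_id, out$item_id)
    if (length(miss))
      data_error(paste0("no survey responses for instrument item(s): ",
                        paste(miss, collapse = ", ")))
    out <- out[match(spec$items$item_id, out$item_id), ]
  }
  out
}
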