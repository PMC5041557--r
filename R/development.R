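## Structure-finding pipeline: validation screening of pilot items against
## resident perception questions, factor-count selection, and the iterative
## low-loading deletion loop that yields the final item set.

#' Screen pilot items against their paired validation questions
#'
#' Each pilot item is correlated (Kendall's tau-b) with its paired resident
#' perception question: each respondent is matched to their area's item
#' observation, so the test runs at the individual level. An item is retained
#' when the association is significant at `alpha`, or when an expert panel
#' lists it as an override; a collapsing map can then merge retained items
#' into composite items.
#'
#' @param assessments data frame, one row per area, with `area_id` and one
#'   column per pilot item.
#' @param validation data frame, one row per respondent, with `area_id` and
#'   one column per validation question.
#' @param pairing named character vector mapping item_id -> validation
#'   question column.
#' @param overrides character vector of item_ids to retain regardless of
#'   significance.
#' @param collapse named list mapping new composite item_id -> character
#'   vector of source item_ids; sources retained by screening are marked
#'   `collapsed_into:<new_id>`.
#' @param alpha significance level (default 0.05).
#' @return Tibble: `item_id`, `tau_b`, `p_value`, `n`, `retained`,
#'   `retained_reason` (`significant`, `expert_override`,
#'   `collapsed_into:<id>`, `dropped`).
#' @export
screen_items <- function(assessments, validation, pairing,
                         overrides = character(), collapse = list(),
                         alpha = 0.05) {
  if (!"area_id" %in% names(assessments) || !"area_id" %in% names(validation))
    arg_error("both tables need an area_id column")
  link <- match(as.character(validation$area_id),
                as.character(assessments$area_id))
  n_unlinked <- sum(is.na(link))
  if (n_unlinked == nrow(validation))
    data_error(paste0("no validation respondents link to assessed areas (",
                      n_unlinked, " unlinked of ", nrow(validation), ")"))
  rows <- lapply(names(pairing), function(id) {
    q <- pairing[[id]]
    if (!id %in% names(assessments))
      config_error(paste0("pilot item not in assessments: ", id))
    if (!q %in% names(validation))
      config_error(paste0("validation question not found: ", q))
    x <- assessments[[id]][link]
    y <- validation[[q]]
    res <- tryCatch(kendall_tau_b(x, y), operat_error = function(e)
      list(tau_b = NA_real_, p_value = NA_real_, n = sum(!is.na(x + y))))
    sig <- !is.na(res$p_value) && res$p_value < alpha
    reason <- if (sig) "significant"
              else if (id %in% overrides) "expert_override"
              else "dropped"
    tibble::tibble(item_id = id, tau_b = res$tau_b, p_value = res$p_value,
                   n = res$n, retained = reason != "dropped",
                   retained_reason = reason)
  })
  out <- do.call(rbind, rows)
  for (new_id in names(collapse)) {
    src <- collapse[[new_id]]
    hit <- out$item_id %in% src & out$retained
    out$retained_reason[hit] <- paste0("collapsed_into:", new_id)
  }
  attr(out, "n_unlinked") <- n_unlinked
  out
}

## factor-count selection: eigenvalue >= 1 rule, bounded by candidate range,
## then walked down while any factor holds fewer than two salient items
## (the interpretability guard against single-item factors).
select_n_factors <- function(data, candidate_factors, loading_threshold,
                             eps = 0.01, n_starts = 10, seed = 1) {
  R <- cor(as.matrix(data)[stats::complete.cases(data), , drop = FALSE])
  n_eig <- sum(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 1)
  k <- max(min(n_eig, max(candidate_factors)), min(candidate_factors))
  while (k > min(candidate_factors)) {
    m <- fit_efa(data, k, eps = eps, n_starts = n_starts, seed = seed)
    assign_f <- apply(abs(m$loadings), 1, which.max)
    salient <- abs(m$loadings)[cbind(seq_along(assign_f), assign_f)] >=
      loading_threshold
    per_factor <- tabulate(assign_f[salient], nbins = k)
    if (all(per_factor >= 2L)) break
    k <- k - 1L
  }
  k
}

#' Iterative EFA refinement by low-loading deletion
#'
#' Selects the number of factors (eigenvalue-greater-than-one rule within the
#' candidate range, with an interpretability guard rejecting solutions where
#' a factor holds fewer than two items loading at or above the threshold),
#' then repeatedly removes the single item whose largest absolute loading is
#' smallest and below `loading_threshold`, re-estimating the model after
#' each deletion until all retained items load at or above the threshold.
#' Ties are broken by item_id. Terminates in at most `length(start_items)`
#' iterations.
#'
#' @param data areas x items matrix/data frame.
#' @param start_items columns to start from (default: all).
#' @param candidate_factors integer range of factor counts to entertain.
#' @param loading_threshold salience threshold (default 0.4).
#' @param reselect_factors re-run factor-count selection after each deletion
#'   (default TRUE).
#' @inheritParams fit_efa
#' @return An object of class `operat_refinement`: `model` (final
#'   [fit_efa()] object), `n_factors`, `retained_items`, `dropped_items`
#'   (tibble `item_id`, `iteration`, `max_abs_loading`), `fit_grid`
#'   (fit indices for the candidate factor counts on the starting item set).
#' @export
refine_model <- function(data, start_items = colnames(data),
                         candidate_factors = 1:6, loading_threshold = 0.4,
                         reselect_factors = TRUE, eps = 0.01, n_starts = 10,
                         seed = 1) {
  X <- as.matrix(data)
  miss <- setdiff(start_items, colnames(X))
  if (length(miss))
    arg_error(paste0("start_items not in data: ", paste(miss, collapse = ", ")))
  items <- start_items
  dropped <- list()
  grid <- efa_fit_grid(X[, items, drop = FALSE],
                       candidate_factors[candidate_factors <
                                           length(items)],
                       eps = eps, n_starts = n_starts, seed = seed)
  k <- select_n_factors(X[, items, drop = FALSE], candidate_factors,
                        loading_threshold, eps, n_starts, seed)
  model <- NULL
  for (iteration in seq_along(start_items)) {
    if (length(items) <= k + 1L)
      operat_error("refinement removed too many items for the factor count",
                   "operat_degenerate_model_error")
    model <- fit_efa(X[, items, drop = FALSE], k, eps = eps,
                     n_starts = n_starts, seed = seed)
    max_abs <- apply(abs(model$loadings), 1, max)
    if (min(max_abs) >= loading_threshold) break
    worst_val <- min(max_abs)
    worst <- sort(names(max_abs)[max_abs == worst_val])[1]
    dropped[[length(dropped) + 1L]] <- tibble::tibble(
      item_id = worst, iteration = iteration, max_abs_loading = worst_val)
    items <- setdiff(items, worst)
    if (reselect_factors)
      k <- select_n_factors(X[, items, drop = FALSE], candidate_factors,
                            loading_threshold, eps, n_starts, seed)
  }
  ## guard: no factor may end up empty of salient items
  assign_f <- apply(abs(model$loadings), 1, which.max)
  salient <- abs(model$loadings)[cbind(seq_along(assign_f), assign_f)] >=
    loading_threshold
  if (any(tabulate(assign_f[salient], nbins = k) == 0L))
    operat_error("refinement emptied a factor of salient items",
                 "operat_degenerate_model_error")
  structure(list(
    model = model,
    n_factors = k,
    retained_items = items,
    dropped_items = if (length(dropped)) do.call(rbind, dropped)
                    else tibble::tibble(item_id = character(),
                                        iteration = integer(),
                                        max_abs_loading = numeric()),
    fit_grid = grid), class = "operat_refinement")
}

#' @export
print.operat_refinement <- function(x, ...) {
  cat("<operat_refinement> ", x$n_factors, " factors, ",
      length(x$retained_items), " items retained, ",
      nrow(x$dropped_items), " dropped\n", sep = "")
  if (nrow(x$dropped_items)) {
    cat("  dropped:\n")
    print(x$dropped_items)
  }
  invisible(x)
}
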