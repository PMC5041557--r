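## Krippendorff's alpha via the coincidence-matrix formulation, supporting
## any number of raters, missing ratings, and nominal / ordinal / interval
## difference metrics.

krippendorff_delta <- function(values, metric, nc) {
  k <- length(values)
  if (metric == "nominal") {
    D <- 1 - diag(k)
  } else if (metric == "interval") {
    D <- outer(values, values, function(a, b) (a - b)^2)
  } else { # ordinal: squared difference of cumulative marginal masses
    D <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- (sum(nc[i:j]) - (nc[i] + nc[j]) / 2)^2
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' Krippendorff's alpha inter-rater agreement
#'
#' \eqn{\alpha = 1 - D_o / D_e} computed from the coincidence matrix: within
#' each unit rated by \eqn{m_u \ge 2} raters, every ordered pair of ratings
#' contributes \eqn{1/(m_u - 1)} to the coincidence of its two values;
#' observed disagreement averages the difference metric over coincidences and
#' expected disagreement over the marginals. Missing ratings are allowed;
#' units with fewer than two ratings are ignored. Alpha is 1 for perfect
#' agreement and about 0 at chance level; it can be negative, which is
#' reported as computed. If every rating in the data is identical, expected
#' disagreement is zero and alpha is returned as 1 with a `degenerate` note.
#'
#' @param ratings units x raters matrix (NA = missing).
#' @param metric `"nominal"`, `"ordinal"` or `"interval"`.
#' @param threshold pass threshold on alpha (default 0.8).
#' @return List: `alpha`, `metric`, `n_units` (units with >= 2 ratings),
#'   `n_pairable` (total pairable ratings), `pass`, `degenerate`.
#' @export
krippendorff_alpha <- function(ratings,
                               metric = c("nominal", "ordinal", "interval"),
                               threshold = 0.8) {
  metric <- match.arg(metric)
  M <- as.matrix(ratings)
  if (ncol(M) < 2L) arg_error("need at least 2 raters")
  mu <- rowSums(!is.na(M))
  M <- M[mu >= 2L, , drop = FALSE]
  if (!nrow(M)) arg_error("need at least 1 unit rated by >= 2 raters")
  vals <- sort(unique(as.vector(M[!is.na(M)])))
  k <- length(vals)
  if (k == 1L)
    return(list(alpha = 1, metric = metric, n_units = nrow(M),
                n_pairable = sum(!is.na(M)), pass = TRUE, degenerate = TRUE))
  O <- matrix(0, k, k)
  for (u in seq_len(nrow(M))) {
    r <- M[u, ]; r <- r[!is.na(r)]
    m <- length(r)
    idx <- match(r, vals)
    for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
      O[idx[a], idx[b]] <- O[idx[a], idx[b]] + 1 / (m - 1)
  }
  nc <- rowSums(O)
  n <- sum(nc)
  D <- krippendorff_delta(vals, metric, nc)
  Do <- sum(O * D) / n
  De <- sum(outer(nc, nc) * D) / (n * (n - 1))
  alpha <- 1 - Do / De
  list(alpha = alpha, metric = metric, n_units = nrow(M),
       n_pairable = n, pass = alpha >= threshold, degenerate = FALSE)
}

#' Per-item inter-rater reliability report
#'
#' Computes Krippendorff's alpha for every instrument item from two (or
#' more) raters' assessment sheets of the same areas, with the difference
#' metric chosen by the item's value kind: nominal for binary items, ordinal
#' for ordinal items, interval for proportion items.
#'
#' @param rater_a,rater_b data frames with `area_id` plus one column per
#'   item (the same areas must appear in both).
#' @param spec an [operat_instrument()].
#' @param threshold pass threshold on alpha (default 0.8).
#' @return List: `items` (tibble `item_id`, `metric`, `alpha`, `n_units`,
#'   `pass`, `perfect`), `n_pass`, `n_perfect`.
#' @export
reliability_report <- function(rater_a, rater_b, spec, threshold = 0.8) {
  a_ids <- sort(as.character(rater_a$area_id))
  b_ids <- sort(as.character(rater_b$area_id))
  if (!identical(a_ids, b_ids)) {
    only_a <- setdiff(a_ids, b_ids); only_b <- setdiff(b_ids, a_ids)
    data_error(paste0(
      "raters assessed different areas; only rater A: ",
      paste(only_a, collapse = ", ") %||% "", "; only rater B: ",
      paste(only_b, collapse = ", ")))
  }
  rb <- rater_b[match(rater_a$area_id, rater_b$area_id), ]
  rows <- lapply(seq_len(nrow(spec$items)), function(i) {
    it <- spec$items[i, ]
    metric <- switch(it$value_kind, binary = "nominal", ordinal = "ordinal",
                     proportion = "interval")
    M <- cbind(rater_a[[it$item_id]], rb[[it$item_id]])
    res <- krippendorff_alpha(M, metric, threshold)
    tibble::tibble(item_id = it$item_id, metric = metric, alpha = res$alpha,
                   n_units = res$n_units, pass = res$pass,
                   perfect = isTRUE(all.equal(res$alpha, 1)) ||
                     res$degenerate)
  })
  items <- do.call(rbind, rows)
  list(items = items, n_pass = sum(items$pass),
       n_perfect = sum(items$perfect))
}
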