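## Instrument data model: items, domains, and the chi normalising constant.

VALID_VALUE_KINDS <- c("binary", "ordinal", "proportion")
VALID_DIRECTIONS  <- c("presence_good", "presence_bad")

#' Construct an OPERAT-style instrument
#'
#' An instrument bundles the item definitions (what is observed on the ground
#' and how it is weighted) with the domain definitions (how item scores are
#' aggregated and re-weighted into a 0--100 composite). The normalising
#' constant \eqn{\chi = 100 / \sum_d w_d} (where \eqn{w_d} are the expert-panel
#' domain weights) is computed on construction, so that the maximum
#' transformed score of domain \eqn{d} is \eqn{\chi w_d} and the maxima sum
#' to 100 for any valid instrument.
#'
#' @param items data frame with columns `item_id`, `label`, `domain_id`,
#'   `value_kind` (one of `"binary"`, `"ordinal"`, `"proportion"`),
#'   `desirable_direction` (`"presence_good"` or `"presence_bad"`),
#'   `multiplier` (integer 1--4), optional `loading` (reference factor
#'   loading) and `ordinal_levels` (required for ordinal items, >= 2).
#' @param domains data frame with columns `domain_id`, `name`, `eag_weight`
#'   (positive integer) and optional `raw_min` (default 0).
#' @param name instrument name.
#' @return An object of class `operat_instrument`: a list with tibbles
#'   `items` and `domains` (the latter gaining `raw_min`/`raw_max` columns,
#'   `raw_max` being the sum of member multipliers) and the scalar `chi`.
#' @examples
#' spec <- default_instrument()
#' spec$chi        # 20 for the shipped instrument
#' spec$domains$raw_max
#' @seealso [read_instrument()], [default_instrument()],
#'   [validate_default_instrument()]
#' @export
operat_instrument <- function(items, domains, name = "OPERAT") {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)

  need_item <- c("item_id", "domain_id", "value_kind", "desirable_direction",
                 "multiplier")
  miss <- setdiff(need_item, names(items))
  if (length(miss))
    config_error(paste0("items table is missing column(s): ",
                        paste(miss, collapse = ", ")))
  need_dom <- c("domain_id", "name", "eag_weight")
  miss <- setdiff(need_dom, names(domains))
  if (length(miss))
    config_error(paste0("domains table is missing column(s): ",
                        paste(miss, collapse = ", ")))

  if (!"label" %in% names(items)) items$label <- items$item_id
  if (!"loading" %in% names(items)) items$loading <- NA_real_
  if (!"ordinal_levels" %in% names(items)) items$ordinal_levels <- NA_integer_
  if (!"raw_min" %in% names(domains)) domains$raw_min <- 0

  if (anyDuplicated(items$item_id))
    config_error("duplicate item_id in items table")
  if (anyDuplicated(domains$domain_id))
    config_error("duplicate domain_id in domains table")

  bad <- !items$value_kind %in% VALID_VALUE_KINDS
  if (any(bad))
    config_error(paste0("invalid value_kind for item(s): ",
                        paste(items$item_id[bad], collapse = ", ")))
  bad <- !items$desirable_direction %in% VALID_DIRECTIONS
  if (any(bad))
    config_error(paste0("invalid desirable_direction for item(s): ",
                        paste(items$item_id[bad], collapse = ", ")))

  m <- items$multiplier
  if (!is.numeric(m) || any(is.na(m)) || any(m != as.integer(m)) ||
      any(m < 1) || any(m > 4))
    config_error(paste0(
      "multiplier must be an integer in 1..4; offending item(s): ",
      paste(items$item_id[is.na(m) | m < 1 | m > 4 | m != round(m)],
            collapse = ", ")))
  items$multiplier <- as.integer(m)

  ord <- items$value_kind == "ordinal"
  if (any(ord & (is.na(items$ordinal_levels) | items$ordinal_levels < 2)))
    config_error(paste0(
      "ordinal items need ordinal_levels >= 2; offending item(s): ",
      paste(items$item_id[ord & (is.na(items$ordinal_levels) |
                                 items$ordinal_levels < 2)], collapse = ", ")))
  items$ordinal_levels <- as.integer(items$ordinal_levels)

  bad <- !items$domain_id %in% domains$domain_id
  if (any(bad))
    config_error(paste0("item(s) reference unknown domain_id: ",
                        paste(items$item_id[bad], collapse = ", ")))
  empty <- setdiff(domains$domain_id, items$domain_id)
  if (length(empty))
    config_error(paste0("domain(s) have no items: ",
                        paste(empty, collapse = ", ")))

  w <- domains$eag_weight
  if (!is.numeric(w) || any(is.na(w)) || any(w <= 0) || any(w != round(w)))
    config_error("eag_weight must be a positive integer for every domain")
  domains$eag_weight <- as.integer(w)

  domains$raw_max <- vapply(domains$domain_id, function(d) {
    domains$raw_min[domains$domain_id == d] +
      sum(items$multiplier[items$domain_id == d])
  }, numeric(1))

  structure(
    list(name = name,
         items = tibble::as_tibble(items[c("item_id", "label", "domain_id",
                                           "value_kind", "desirable_direction",
                                           "multiplier", "loading",
                                           "ordinal_levels")]),
         domains = tibble::as_tibble(domains[c("domain_id", "name",
                                               "eag_weight", "raw_min",
                                               "raw_max")]),
         chi = compute_chi(domains$eag_weight)),
    class = "operat_instrument")
}

#' @export
print.operat_instrument <- function(x, ...) {
  cat("<operat_instrument> ", x$name, "\n", sep = "")
  cat("  ", nrow(x$items), " items in ", nrow(x$domains), " domains; chi = ",
      format(x$chi), "\n", sep = "")
  for (i in seq_len(nrow(x$domains))) {
    d <- x$domains[i, ]
    n <- sum(x$items$domain_id == d$domain_id)
    cat(sprintf("  %-26s %d items, eag_weight %d, raw 0..%g, transformed 0..%g\n",
                d$name, n, d$eag_weight, d$raw_max, x$chi * d$eag_weight))
  }
  invisible(x)
}

#' Parse an instrument configuration document
#'
#' Accepts the text of a YAML (or JSON, a YAML subset) configuration with
#' top-level keys `instrument_name`, `domains` and `items`, validates it and
#' returns the instrument object. Every structural constraint is checked:
#' multipliers in 1..4, ordinal scales declared, every item in exactly one
#' known domain, no empty domains.
#'
#' @param config_text character scalar (or vector of lines) holding the
#'   configuration document.
#' @return An [operat_instrument()] object.
#' @export
load_instrument <- function(config_text) {
  config_text <- paste(config_text, collapse = "\n")
  cfg <- tryCatch(yaml::yaml.load(config_text),
                  error = function(e)
                    config_error(paste0("configuration does not parse: ",
                                        conditionMessage(e))))
  for (key in c("domains", "items"))
    if (is.null(cfg[[key]]))
      config_error(paste0("configuration is missing top-level key: ", key))
  bind_rows_list <- function(lst, what) {
    if (!length(lst)) config_error(paste0("empty ", what, " list"))
    cols <- unique(unlist(lapply(lst, names)))
    out <- lapply(cols, function(cn)
      unlist(lapply(lst, function(e) e[[cn]] %||% NA)))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  operat_instrument(items = bind_rows_list(cfg$items, "items"),
                    domains = bind_rows_list(cfg$domains, "domains"),
                    name = cfg$instrument_name %||% "OPERAT")
}

#' Read an instrument configuration file
#'
#' @param path path to a YAML or JSON instrument configuration.
#' @return An [operat_instrument()] object.
#' @export
read_instrument <- function(path) {
  if (!file.exists(path)) config_error(paste0("no such file: ", path))
  load_instrument(readLines(path, warn = FALSE))
}

#' Serialise an instrument to YAML
#'
#' `write_instrument()` writes a configuration file that [read_instrument()]
#' parses back to an equal instrument (round-trip property).
#'
#' @param spec an [operat_instrument()] object.
#' @param path output file path; if `NULL` the YAML text is returned.
#' @return Invisibly, the YAML text.
#' @export
write_instrument <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "operat_instrument"))
  row_list <- function(df, cols) {
    lapply(seq_len(nrow(df)), function(i) {
      e <- as.list(df[i, cols, drop = FALSE])
      e[!vapply(e, function(v) is.na(v) %in% TRUE, logical(1))]
    })
  }
  doc <- list(
    instrument_name = spec$name,
    domains = row_list(spec$domains, c("domain_id", "name", "eag_weight")),
    items = row_list(spec$items, c("item_id", "label", "domain_id",
                                   "value_kind", "ordinal_levels",
                                   "desirable_direction", "multiplier",
                                   "loading")))
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' The shipped default OPERAT instrument
#'
#' Sixteen items in four domains (3, 3, 5 and 5 items) with raw maxima
#' 9, 10, 13 and 14, expert-panel domain weights 1, 1, 2 and 1, and
#' \eqn{\chi = 20}. The split of each domain maximum into per-item
#' multipliers is reconstructed (see the shipped configuration file) and can
#' be overridden via [read_instrument()].
#'
#' @return An [operat_instrument()] object.
#' @export
default_instrument <- function() {
  read_instrument(system.file("extdata", "operat_default.yaml",
                              package = "operat", mustWork = TRUE))
}

#' Check an instrument against the published OPERAT constants
#'
#' Produces a report asserting the printed structural constants of the final
#' published instrument: per-domain item counts (3, 3, 5, 5), raw maxima
#' (9, 10, 13, 14), expert-panel weights (1, 1, 2, 1), chi = 20, and that the
#' maximum transformed domain scores sum to 100. Failures are listed, not
#' raised.
#'
#' @param spec an [operat_instrument()] object.
#' @return A tibble with columns `check`, `domain_id`, `expected`, `observed`,
#'   `pass`.
#' @export
validate_default_instrument <- function(spec) {
  stopifnot(inherits(spec, "operat_instrument"))
  expected <- data.frame(
    domain_id = c("natural_elements", "incivilities_nuisance",
                  "navigation_mobility", "territorial_functioning"),
    n_items = c(3L, 3L, 5L, 5L),
    raw_max = c(9, 10, 13, 14),
    eag_weight = c(1L, 1L, 2L, 1L))
  rows <- list()
  add <- function(check, domain_id, exp, obs)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, domain_id = domain_id,
      expected = as.numeric(exp), observed = as.numeric(obs),
      pass = isTRUE(all.equal(as.numeric(exp), as.numeric(obs))))
  for (i in seq_len(nrow(expected))) {
    d <- expected$domain_id[i]
    j <- match(d, spec$domains$domain_id)
    if (is.na(j)) {
      add("domain_present", d, 1, 0)
      next
    }
    add("n_items", d, expected$n_items[i],
        sum(spec$items$domain_id == d))
    add("raw_max", d, expected$raw_max[i], spec$domains$raw_max[j])
    add("eag_weight", d, expected$eag_weight[i], spec$domains$eag_weight[j])
  }
  add("chi", NA_character_, 20, spec$chi)
  add("transformed_total_max", NA_character_, 100,
      sum(spec$chi * spec$domains$eag_weight))
  do.call(rbind, rows)
}
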