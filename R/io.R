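## File I/O: schema-validated CSV reading (with a rejects report rather than
## silent dropping), score/weight writers, and run manifests.

#' Column schema for a tabular input
#'
#' @param columns named list: column name -> list with `type`
#'   (`"character"`, `"numeric"`, `"integer"`), optional `min`, `max`,
#'   `choices`, and `required` (default TRUE).
#' @return Object of class `operat_schema`.
#' @export
table_schema <- function(columns) {
  structure(list(columns = columns), class = "operat_schema")
}

#' Schema of an assessment sheet for a given instrument
#'
#' `area_id` plus one column per item with the item's declared range;
#' covariate columns are permitted but not required.
#'
#' @param spec an [operat_instrument()].
#' @return An `operat_schema`.
#' @export
assessment_schema <- function(spec) {
  cols <- list(area_id = list(type = "character"))
  for (i in seq_len(nrow(spec$items))) {
    it <- spec$items[i, ]
    cols[[it$item_id]] <- switch(it$value_kind,
      binary = list(type = "numeric", min = 0, max = 1,
                    choices = c(0, 1)),
      ordinal = list(type = "numeric", min = 1, max = it$ordinal_levels),
      proportion = list(type = "numeric", min = 0, max = 1))
  }
  table_schema(cols)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c(",", ";", "\t"), function(d)
    lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
    integer(1))
  names(counts)[which.max(counts)]
}

#' Read and validate a CSV table against a schema
#'
#' Parses a delimited UTF-8 file (comma, semicolon or tab; auto-detected
#' from the header), checks required columns, coerces types, and collects
#' rows violating the schema into a rejects report attached as
#' `attr(x, "rejects")` (a tibble with `row`, `column`, `value`, `reason`)
#' instead of dropping them silently; offending rows are excluded from the
#' returned data.
#'
#' @param path file path.
#' @param schema an [table_schema()] (optional: when `NULL` the table is
#'   returned as read).
#' @return Tibble of valid rows with a `rejects` attribute.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) data_error(paste0("no such file: ", path))
  delim <- detect_delim(path)
  df <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                 check.names = FALSE, fileEncoding = "UTF-8")
  if (is.null(schema)) return(tibble::as_tibble(df))
  need <- names(schema$columns)[vapply(schema$columns, function(cs)
    cs$required %||% TRUE, logical(1))]
  miss <- setdiff(need, names(df))
  if (length(miss))
    data_error(paste0("missing required column(s): ",
                      paste(miss, collapse = ", ")))
  rejects <- list()
  bad_rows <- logical(nrow(df))
  for (cn in intersect(names(schema$columns), names(df))) {
    cs <- schema$columns[[cn]]
    v <- df[[cn]]
    if (cs$type %in% c("numeric", "integer")) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- (!is.na(v) & v != "" & is.na(vn))
      reason <- rep(NA_character_, length(v))
      reason[bad] <- "not numeric"
      out_of_range <- !is.na(vn) &
        ((!is.null(cs$min) & vn < (cs$min %||% -Inf)) |
         (!is.null(cs$max) & vn > (cs$max %||% Inf)) |
         (if (!is.null(cs$choices)) !vn %in% cs$choices else FALSE))
      reason[out_of_range & !bad] <- "out of range"
      bad <- bad | out_of_range
      df[[cn]] <- vn
    } else {
      df[[cn]] <- as.character(v)
      bad <- rep(FALSE, length(v))
      reason <- rep(NA_character_, length(v))
    }
    if (any(bad)) {
      rejects[[length(rejects) + 1L]] <- tibble::tibble(
        row = which(bad), column = cn, value = as.character(v[bad]),
        reason = reason[bad])
      bad_rows <- bad_rows | bad
    }
  }
  out <- tibble::as_tibble(df[!bad_rows, , drop = FALSE])
  attr(out, "rejects") <- if (length(rejects)) do.call(rbind, rejects)
    else tibble::tibble(row = integer(), column = character(),
                        value = character(), reason = character())
  out
}

#' Write per-area scores (and optionally a summary) as CSV
#'
#' Scores are written rounded to 2 decimals, the convention of printed score
#' tables; computations upstream are at full precision.
#'
#' @param batch result of [score_batch()].
#' @param path output CSV for the per-area scores.
#' @param summary_path optional CSV for the summary table.
#' @export
write_scores <- function(batch, path, summary_path = NULL) {
  sc <- batch$scores
  num <- vapply(sc, is.numeric, logical(1))
  sc[num] <- lapply(sc[num], round_half_up, digits = 2)
  write.csv(sc, path, row.names = FALSE)
  if (!is.null(summary_path)) {
    sm <- batch$summary
    num <- vapply(sm, is.numeric, logical(1))
    sm[num] <- lapply(sm[num], round_half_up, digits = 2)
    write.csv(sm, summary_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records the command, seed, input-file MD5 digests, package version and
#' timestamp next to a command's outputs, so a rerun can be checked for
#' input identity.
#'
#' @param dir output directory.
#' @param command subcommand name.
#' @param inputs character vector of input file paths.
#' @param seed seed used (or NA).
#' @export
write_manifest <- function(dir, command, inputs = character(),
                           seed = NA_integer_) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(command = command,
                   inputs = digests,
                   seed = seed,
                   version = as.character(utils::packageVersion("operat")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
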