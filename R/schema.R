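#' Load a relation schema
#'
#' A relation schema enumerates the relation types a corpus is annotated
#' with.  Each relation has a numeric id (contiguous from 1), a Chinese
#' name, an English name and a unique abbreviation.  The bundled default
#' schema describes the twelve food-health relation types used throughout
#' the package examples, with the residual "Other" relation (abbreviation
#' `"O"`) last; "Other" marks entity pairs that are not domain-relevant
#' and by default receives no object tagger in the cascade extractor.
#'
#' @param path path to a schema JSON file, or `NULL` for the bundled
#'   food-health schema.  The JSON holds a top-level `relations` array of
#'   objects with fields `id`, `name_zh`, `name_en`, `abbrev`.
#' @return a `relation_schema`: a data.frame with columns `id`, `name_zh`,
#'   `name_en`, `abbrev` and attribute `includes_other`.
#' @examples
#' sch <- load_schema()
#' nrow(sch)            # 12
#' relation_abbrevs(sch)
#' @export
load_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "schema_fh.json", package = "relcascade",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop_bad("schema file not found: %s", path)
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) stop_bad("failed to parse schema JSON: %s", conditionMessage(e))
  )
  if (is.null(parsed$relations)) stop_bad("schema JSON lacks a 'relations' array")
  rel <- as.data.frame(parsed$relations, stringsAsFactors = FALSE)
  needed <- c("id", "name_zh", "name_en", "abbrev")
  missing <- setdiff(needed, names(rel))
  if (length(missing) > 0) {
    stop_bad("schema relations lack fields: %s", paste(missing, collapse = ", "))
  }
  rel <- rel[needed]
  rel$id <- as.integer(rel$id)
  new_relation_schema(rel)
}

new_relation_schema <- function(rel) {
  if (nrow(rel) < 1) stop_bad("schema must contain at least one relation")
  if (anyDuplicated(rel$abbrev)) {
    stop_bad("duplicate relation abbreviations: %s",
             paste(unique(rel$abbrev[duplicated(rel$abbrev)]), collapse = ", "))
  }
  if (!identical(sort(rel$id), seq_len(nrow(rel)))) {
    stop_bad("relation ids must be unique and contiguous from 1")
  }
  rel <- rel[order(rel$id), , drop = FALSE]
  rownames(rel) <- NULL
  structure(rel,
            includes_other = "O" %in% rel$abbrev,
            class = c("relation_schema", "data.frame"))
}

#' Relation abbreviations of a schema
#'
#' @param schema a `relation_schema`.
#' @param include_other keep the residual `"O"` ("Other") relation?
#'   The cascade extractor trains object taggers only for the target
#'   relations, so it asks for `include_other = FALSE`.
#' @return character vector of abbreviations in id order.
#' @export
relation_abbrevs <- function(schema, include_other = TRUE) {
  stopifnot(inherits(schema, "relation_schema"))
  ab <- schema$abbrev
  if (!include_other) ab <- ab[ab != "O"]
  ab
}

#' @export
print.relation_schema <- function(x, ...) {
  cat(sprintf("<relation_schema> %d relations (includes_other = %s)\n",
              nrow(x), attr(x, "includes_other")))
  print.data.frame(x, ...)
  invisible(x)
}
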