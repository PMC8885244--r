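#' Entity span
#'
#' A contiguous character span of a sentence, 0-based and half-open:
#' `[start, end)`.  `relevance` records whether the entity is
#' domain-relevant (`"Food"`) or a distractor (`"Noise"`).
#'
#' @param start 0-based inclusive start index.
#' @param end 0-based exclusive end index (`end > start`).
#' @param relevance `"Food"` or `"Noise"`.
#' @param entity_type optional free-form type label.
#' @return an `entity_span` list.
#' @export
entity_span <- function(start, end, relevance = "Food", entity_type = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start) {
    stop_bad("invalid span [%s, %s): need 0 <= start < end", start, end)
  }
  if (!relevance %in% c("Food", "Noise")) {
    stop_bad("relevance must be 'Food' or 'Noise', got '%s'", relevance)
  }
  structure(list(start = start, end = end, relevance = relevance,
                 entity_type = entity_type),
            class = "entity_span")
}

#' Relational triple
#'
#' A (subject, relation, object) fact.  A triple is `useful` exactly when
#' both of its entity spans are domain-relevant (`"Food"`); a triple with
#' a `"Noise"` subject or object is a distractor that the noise filter is
#' meant to suppress.
#'
#' @param subj,obj `entity_span` objects (or `c(start, end)` pairs, taken
#'   as Food unless `subj_rel`/`obj_rel` say otherwise).
#' @param rel relation abbreviation (validated against a schema at corpus
#'   read/validation time).
#' @param subj_rel,obj_rel relevance flags used when `subj`/`obj` are bare
#'   index pairs.
#' @return a `triple` list with fields `subj`, `rel`, `obj`, `useful`.
#' @export
triple <- function(subj, rel, obj, subj_rel = "Food", obj_rel = "Food") {
  if (!inherits(subj, "entity_span")) subj <- entity_span(subj[1], subj[2], subj_rel)
  if (!inherits(obj, "entity_span"))  obj  <- entity_span(obj[1], obj[2], obj_rel)
  stopifnot(is.character(rel), length(rel) == 1L)
  structure(list(subj = subj, rel = rel, obj = obj,
                 useful = subj$relevance == "Food" && obj$relevance == "Food"),
            class = "triple")
}

#' Annotated sentence
#'
#' A character sequence plus its gold triples.  Text is NFC-normalised on
#' construction; all spans index characters of the normalised text.
#'
#' @param id sentence identifier.
#' @param text sentence text (length `M >= 1` after NFC normalisation).
#' @param triples list of [triple()] objects (possibly empty).
#' @return an `annotated_sentence`.
#' @export
annotated_sentence <- function(id, text, triples = list()) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(text), length(text) == 1L)
  text <- stringi::stri_trans_nfc(text)
  m <- nchar(text)
  if (m < 1L) stop_bad("sentence '%s': text must be non-empty", id)
  for (tr in triples) {
    if (!inherits(tr, "triple")) stop_bad("sentence '%s': triples must be triple objects", id)
    for (sp in list(tr$subj, tr$obj)) {
      if (sp$end > m) {
        stop_bad("sentence '%s': span [%d, %d) out of bounds for length %d",
                 id, sp$start, sp$end, m)
      }
    }
  }
  structure(list(id = id, text = text, triples = triples),
            class = "annotated_sentence")
}

span_text <- function(sentence, span) {
  substr(sentence$text, span$start + 1L, span$end)
}

validate_sentence <- function(sentence, schema) {
  for (tr in sentence$triples) {
    if (!tr$rel %in% schema$abbrev) {
      stop_bad("sentence '%s': unknown relation '%s'", sentence$id, tr$rel)
    }
  }
  invisible(sentence)
}

triple_from_record <- function(rec) {
  triple(subj = c(rec$subj[[1]], rec$subj[[2]]),
         rel = rec$rel,
         obj = c(rec$obj[[1]], rec$obj[[2]]),
         subj_rel = rec$subj_rel %||% "Food",
         obj_rel = rec$obj_rel %||% "Food")
}

#' Read an annotated corpus (JSON Lines)
#'
#' One sentence per line:
#' `{"id": ..., "text": ..., "triples": [{"subj": [s,e], "rel": ...,
#' "obj": [s,e], "subj_rel": "Food"|"Noise", "obj_rel": ...}, ...]}`.
#' Every record is validated against the schema and the span invariants;
#' errors name the offending line.
#'
#' @param path JSONL file path (UTF-8).
#' @param schema a `relation_schema` used to validate relation labels.
#' @return list of [annotated_sentence()] objects.
#' @export
read_corpus <- function(path, schema) {
  if (!file.exists(path)) stop_bad("corpus file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    sent <- tryCatch({
      rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
      s <- annotated_sentence(rec$id, rec$text,
                              lapply(rec$triples, triple_from_record))
      validate_sentence(s, schema)
    }, error = function(e) {
      stop_bad("corpus line %d: %s", i, conditionMessage(e))
    })
    out[[i]] <- sent
  }
  out
}

sentence_to_record <- function(sentence) {
  list(
    id = jsonlite::unbox(sentence$id),
    text = jsonlite::unbox(sentence$text),
    triples = lapply(sentence$triples, function(tr) {
      list(subj = c(tr$subj$start, tr$subj$end),
           rel = jsonlite::unbox(tr$rel),
           obj = c(tr$obj$start, tr$obj$end),
           subj_rel = jsonlite::unbox(tr$subj$relevance),
           obj_rel = jsonlite::unbox(tr$obj$relevance))
    })
  )
}

#' Write an annotated corpus (JSON Lines)
#'
#' Inverse of [read_corpus()]: one UTF-8 JSON object per sentence with a
#' fixed key order, so serialisation is deterministic and loss-free.
#'
#' @param sentences list of [annotated_sentence()] objects.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_corpus <- function(sentences, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in sentences) {
    line <- jsonlite::toJSON(sentence_to_record(s), auto_unbox = FALSE)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat(sprintf("<annotated_sentence> %s (%d chars, %d triples)\n",
              x$id, nchar(x$text), length(x$triples)))
  cat(" ", x$text, "\n")
  for (tr in x$triples) {
    cat(sprintf("  (%s[%d,%d) %s, %s, %s[%d,%d) %s)%s\n",
                span_text(x, tr$subj), tr$subj$start, tr$subj$end, tr$subj$relevance,
                tr$rel,
                span_text(x, tr$obj), tr$obj$start, tr$obj$end, tr$obj$relevance,
                if (tr$useful) "" else "  [noise]"))
  }
  invisible(x)
}
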