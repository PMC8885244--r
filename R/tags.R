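#' The modified BIO tag alphabet
#'
#' Plain BIO marks Begin/Inside/Outside of entity spans; the modified
#' scheme additionally prefixes entity tags with the relevance of the
#' entity, so a character is one of `O`, `Food-B`, `Food-I`, `Noise-B`,
#' `Noise-I`.  The `Food` prefix marks domain-relevant entities, `Noise`
#' marks distractors that downstream stages should suppress.
#'
#' @return character vector of the five tags, in fixed order (`O` first).
#' @export
tag_alphabet <- function() {
  c("O", "Food-B", "Food-I", "Noise-B", "Noise-I")
}

## Collect the distinct annotated spans of a sentence, resolving
## relevance conflicts (Food wins) and nesting (outermost span wins).
collect_spans <- function(sentence) {
  spans <- list()
  for (tr in sentence$triples) {
    for (sp in list(tr$subj, tr$obj)) {
      key <- sprintf("%d-%d", sp$start, sp$end)
      prev <- spans[[key]]
      if (is.null(prev)) {
        spans[[key]] <- sp
      } else if (prev$relevance != sp$relevance && prev$relevance == "Noise") {
        ## same span annotated both Noise and Food across triples:
        ## Food wins so the mask never zeroes a domain-relevant entity
        spans[[key]] <- sp
        message(sprintf("span [%d,%d): Food/Noise conflict resolved to Food",
                        sp$start, sp$end))
      }
    }
  }
  spans <- unname(spans)
  if (length(spans) == 0) return(spans)
  ord <- order(vapply(spans, `[[`, integer(1), "start"),
               -vapply(spans, `[[`, integer(1), "end"))
  spans <- spans[ord]
  kept <- list()
  last_end <- -1L
  for (sp in spans) {
    if (sp$start >= last_end) {
      kept[[length(kept) + 1L]] <- sp
      last_end <- sp$end
    } else if (sp$end <= last_end) {
      ## fully nested inside the previously kept (outermost) span
      message(sprintf("span [%d,%d): nested span dropped for BIO tagging",
                      sp$start, sp$end))
    } else {
      stop_bad("spans [%d,%d) and earlier span partially overlap: un-taggable",
               sp$start, sp$end)
    }
  }
  kept
}

#' Encode a sentence's entity spans as modified BIO tags
#'
#' The first character of every annotated span gets `<prefix>-B` and the
#' remaining characters `<prefix>-I`, where the prefix is the span's
#' relevance; all other positions are `O`.  A span annotated with both
#' relevances across triples is tagged `Food` (the mask must not zero a
#' domain-relevant entity); fully nested spans keep only the outermost
#' (with a message); partially overlapping spans cannot be expressed in a
#' linear tagging and raise an error.
#'
#' @param sentence an [annotated_sentence()].
#' @return a `tag_sequence`: character vector over [tag_alphabet()], one
#'   element per character of the sentence.
#' @export
encode_tags <- function(sentence) {
  m <- nchar(sentence$text)
  labels <- rep("O", m)
  for (sp in collect_spans(sentence)) {
    idx <- (sp$start + 1L):sp$end
    labels[idx] <- paste0(sp$relevance, "-I")
    labels[idx[1]] <- paste0(sp$relevance, "-B")
  }
  structure(labels, class = "tag_sequence")
}

#' Decode modified BIO tags into entity spans
#'
#' Maximal `B I I ...` runs of a common prefix become spans with that
#' relevance.  An orphan `I` (no preceding `B` or `I` of the same prefix)
#' is repaired by treating it as `B`, with a message.
#'
#' @param tags character vector over [tag_alphabet()].
#' @return list of [entity_span()] objects in text order.
#' @export
decode_tags <- function(tags) {
  unknown <- setdiff(unique(tags), tag_alphabet())
  if (length(unknown) > 0) {
    stop_bad("unknown tags: %s", paste(unknown, collapse = ", "))
  }
  spans <- list()
  cur_prefix <- NULL
  cur_start <- NA_integer_
  flush <- function(endpos) {
    if (!is.null(cur_prefix)) {
      spans[[length(spans) + 1L]] <<- entity_span(cur_start, endpos, cur_prefix)
    }
  }
  for (i in seq_along(tags)) {
    tag <- tags[[i]]
    if (tag == "O") {
      flush(i - 1L); cur_prefix <- NULL; next
    }
    parts <- strsplit(tag, "-", fixed = TRUE)[[1L]]
    prefix <- parts[1]; pos <- parts[2]
    if (pos == "B") {
      flush(i - 1L)
      cur_prefix <- prefix; cur_start <- i - 1L
    } else {
      if (is.null(cur_prefix) || cur_prefix != prefix) {
        message(sprintf("position %d: orphan %s-I repaired as %s-B", i - 1L, prefix, prefix))
        flush(i - 1L)
        cur_prefix <- prefix; cur_start <- i - 1L
      }
    }
  }
  flush(length(tags))
  spans
}

#' Binary position mask from modified BIO tags
#'
#' Converts a tag sequence into the 0/1 vector that gates the fused
#' representations: domain-relevant (`Food`-prefixed) positions are kept
#' (1) and distractor (`Noise`-prefixed) positions are zeroed (0).  Under
#' the default `"keep_outside"` policy non-entity (`O`) positions are also
#' kept, so sentence context survives; the `"literal"` policy zeroes them
#' too, retaining only marked relevant entities (useful for ablations).
#'
#' @param tags character vector over [tag_alphabet()].
#' @param policy `"keep_outside"` (default) or `"literal"`.
#' @return numeric 0/1 vector, one entry per position.
#' @export
position_mask <- function(tags, policy = c("keep_outside", "literal")) {
  policy <- match.arg(policy)
  unknown <- setdiff(unique(as.character(tags)), tag_alphabet())
  if (length(unknown) > 0) {
    stop_bad("unknown tags: %s", paste(unknown, collapse = ", "))
  }
  vapply(as.character(tags), function(tag) {
    if (startsWith(tag, "Food")) 1
    else if (startsWith(tag, "Noise")) 0
    else if (policy == "keep_outside") 1 else 0
  }, numeric(1), USE.NAMES = FALSE)
}
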