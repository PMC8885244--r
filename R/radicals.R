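# Character -> radical decomposition and the masked fusion of character
# and radical representations.  A radical is the structural/semantic
# component of a Chinese character (the smallest semantic unit handled
# here); mapping characters onto their radicals collapses a large
# character inventory onto a small radical alphabet.

#' Create a radical table
#'
#' @param mapping named character vector: `mapping[[char]] == radical`.
#' @return a `radical_table` with fields `mapping` and `radical_alphabet`.
#' @export
radical_table <- function(mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  structure(list(mapping = mapping,
                 radical_alphabet = sort(unique(unname(mapping)))),
            class = "radical_table")
}

#' Load a radical table from a TSV file
#'
#' Format: one `char<TAB>radical` pair per line, UTF-8.  With
#' `path = NULL` the bundled example table is loaded; it covers the
#' characters used in this package's worked examples, not the full
#' government radical inventory (a user-supplied table in the same
#' format drops in for real corpora).
#'
#' @param path TSV path or `NULL` for the bundled table.
#' @return a `radical_table`.
#' @export
load_radical_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "radicals_examples.tsv",
                        package = "relcascade", mustWork = TRUE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) stop_bad("radical table line %d is not 'char<TAB>radical'", bad[1])
  mapping <- vapply(parts, `[[`, character(1), 2L)
  names(mapping) <- vapply(parts, `[[`, character(1), 1L)
  radical_table(mapping)
}

#' Decompose text into its radical sequence
#'
#' Each character is replaced by its radical; characters absent from the
#' table (indivisible or unknown) pass through unchanged.  The output
#' always has exactly one token per input character.
#'
#' @param text a non-empty string.
#' @param table a [radical_table()].
#' @return character vector of radical tokens, length `nchar(text)`.
#' @export
decompose <- function(text, table) {
  stopifnot(inherits(table, "radical_table"))
  cs <- chars_of(text)
  if (length(cs) < 1) stop_bad("cannot decompose empty text")
  out <- unname(table$mapping[cs])
  out[is.na(out)] <- cs[is.na(out)]
  out
}

new_fused_sequence <- function(vectors, parts) {
  structure(list(vectors = vectors, parts = parts), class = "fused_sequence")
}

#' Fuse character and radical representations under the position mask
#'
#' Row `i` of the result is `concat(e_i * H_c[i, ], e_i * H_r[i, ])`:
#' both granularities are gated by the binary mask `E` (distractor
#' positions are zeroed) and concatenated, giving width `d_c + d_r`.
#'
#' @param H_c,H_r `encoded_sequence`s (or matrices) of equal length `M`.
#' @param E numeric 0/1 vector of length `M` (see [position_mask()]).
#' @return a `fused_sequence` of width `d_c + d_r`.
#' @export
fuse_radical <- function(H_c, H_r, E) {
  Xc <- if (inherits(H_c, "encoded_sequence")) H_c$vectors else H_c
  Xr <- if (inherits(H_r, "encoded_sequence")) H_r$vectors else H_r
  if (nrow(Xc) != nrow(Xr) || nrow(Xc) != length(E)) {
    stop_bad("fuse_radical: H_c (%d), H_r (%d) and E (%d) lengths differ",
             nrow(Xc), nrow(Xr), length(E))
  }
  fused <- cbind(Xc * E, Xr * E)
  new_fused_sequence(fused, parts = c(char = ncol(Xc), radical = ncol(Xr)))
}

#' Character- vs radical-level similarity diagnostic
#'
#' Encodes two texts at the chosen granularity, mean-pools the position
#' vectors, and returns their cosine similarity.  At the radical level
#' texts are first decomposed with the table.  The score is symmetric in
#' its arguments and lies in `[-1, 1]`.
#'
#' @param a,b non-empty strings.
#' @param level `"char"` or `"radical"`.
#' @param enc encoder (a `toy_encoder` or [encoder_config()]).
#' @param table a [radical_table()] (needed for `level = "radical"`).
#' @return cosine similarity scalar.
#' @export
similarity_diagnostic <- function(a, b, level = c("char", "radical"),
                                  enc, table = NULL) {
  level <- match.arg(level)
  if (nchar(a) < 1 || nchar(b) < 1) stop_bad("similarity needs non-empty texts")
  pool <- function(text) {
    h <- if (level == "char") {
      encode_chars(text, enc)
    } else {
      if (is.null(table)) stop_bad("radical-level similarity needs a radical table")
      encode_radicals(decompose(text, table), enc)
    }
    colMeans(h$vectors)
  }
  va <- pool(a); vb <- pool(b)
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}
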