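# Word segmentation and the character-word fusion stage.  Chinese text
# carries no whitespace; words are recovered by greedy longest match
# against an explicit lexicon, word vectors are broadcast back to
# character positions, gated by the noise mask, and concatenated with
# the character-radical fusion.

#' Segment text by greedy longest match
#'
#' Scans left to right; at each position the longest lexicon word
#' starting there is taken, and characters that start no lexicon word
#' become single-character tokens.  Deterministic, and the concatenation
#' of the tokens always reproduces the input text.
#'
#' @param text a non-empty string.
#' @param lexicon character vector of words.
#' @return a `segmentation`: list with `tokens` (N words) and
#'   `char_to_word` (length-M vector mapping each character position to
#'   its 1-based word index).
#' @export
segment <- function(text, lexicon) {
  cs <- chars_of(text)
  m <- length(cs)
  if (m < 1) stop_bad("cannot segment empty text")
  lexicon <- unique(lexicon[nchar(lexicon) > 0])
  by_first <- split(lexicon, substr(lexicon, 1, 1))
  tokens <- character(0)
  char_to_word <- integer(m)
  i <- 1L
  while (i <= m) {
    cands <- by_first[[cs[i]]]
    word <- cs[i]
    if (!is.null(cands)) {
      cands <- cands[order(-nchar(cands))]
      for (w in cands) {
        len <- nchar(w)
        if (i + len - 1L <= m && paste(cs[i:(i + len - 1L)], collapse = "") == w) {
          word <- w
          break
        }
      }
    }
    tokens <- c(tokens, word)
    char_to_word[i:(i + nchar(word) - 1L)] <- length(tokens)
    i <- i + nchar(word)
  }
  structure(list(tokens = tokens, char_to_word = char_to_word),
            class = "segmentation")
}

#' Broadcast word vectors to character positions
#'
#' Character `i` receives the vector of the word containing it, so a
#' two-character word contributes its vector to both of its characters.
#'
#' @param H_w an `encoded_sequence` (word granularity) or `N x d` matrix.
#' @param seg a [segment()] result whose `tokens` match `H_w`'s rows.
#' @return an `M x d` `encoded_sequence` at character granularity.
#' @export
broadcast_words <- function(H_w, seg) {
  X <- if (inherits(H_w, "encoded_sequence")) H_w$vectors else H_w
  if (nrow(X) != length(seg$tokens)) {
    stop_bad("broadcast_words: %d word vectors but %d tokens", nrow(X), length(seg$tokens))
  }
  new_encoded_sequence(X[seg$char_to_word, , drop = FALSE], "char")
}

#' Fuse character-radical and word representations
#'
#' Word vectors are broadcast to character positions, multiplied
#' elementwise by the binary mask `E`, and concatenated row-wise with the
#' character-radical fusion, giving width `(d_c + d_r) + d_w`.
#'
#' @param H_cr a `fused_sequence` from [fuse_radical()] (or a matrix).
#' @param H_w word-level `encoded_sequence` (N rows).
#' @param E numeric 0/1 mask of length `M`.
#' @param seg the [segment()] result aligning words to characters.
#' @return a `fused_sequence` of width `(d_c + d_r) + d_w`.
#' @export
fuse_char_word <- function(H_cr, H_w, E, seg) {
  Xcr <- if (inherits(H_cr, "fused_sequence")) H_cr$vectors else H_cr
  Hwe <- broadcast_words(H_w, seg)$vectors
  if (nrow(Xcr) != nrow(Hwe) || nrow(Xcr) != length(E)) {
    stop_bad("fuse_char_word: inconsistent lengths (H_cr %d, words %d, E %d)",
             nrow(Xcr), nrow(Hwe), length(E))
  }
  prev <- if (inherits(H_cr, "fused_sequence")) H_cr$parts else c(char = ncol(Xcr))
  new_fused_sequence(cbind(Xcr, Hwe * E), parts = c(prev, word = ncol(Hwe)))
}
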