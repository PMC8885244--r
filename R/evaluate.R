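# Triple matching and micro-averaged precision / recall / F1, with
# Student-t confidence intervals over independent runs.

triple_key <- function(tr) {
  sprintf("%d-%d|%s|%d-%d", tr$subj$start, tr$subj$end, tr$rel,
          tr$obj$start, tr$obj$end)
}

#' Match predicted against gold triples
#'
#' A predicted triple counts as a true positive iff its subject span,
#' relation, and object span all exactly equal those of a gold triple
#' (strict exact-boundary matching).  Counts satisfy
#' `tp + fn == |gold|` and `tp + fp == |pred|` (on distinct triples).
#'
#' @param pred,gold lists of [triple()] objects for one sentence.
#' @return list with integer `tp`, `fp`, `fn`.
#' @export
match_triples <- function(pred, gold) {
  pk <- unique(vapply(pred, triple_key, character(1)))
  gk <- unique(vapply(gold, triple_key, character(1)))
  tp <- length(intersect(pk, gk))
  list(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
}

#' Precision, recall, and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`.  A zero
#' denominator yields 0 with a warning.
#'
#' @param counts list with `tp`, `fp`, `fn` (e.g. from
#'   [match_triples()], possibly summed over sentences).
#' @return a `metrics_report` list with `precision`, `recall`, `f1` and
#'   the counts.
#' @export
prf <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  p <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no predictions: precision set to 0"); 0
  }
  r <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no gold triples: recall set to 0"); 0
  }
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, f1 = f1,
                 tp = tp, fp = fp, fn = fn),
            class = "metrics_report")
}

sum_counts <- function(counts_list) {
  list(tp = sum(vapply(counts_list, `[[`, numeric(1), "tp")),
       fp = sum(vapply(counts_list, `[[`, numeric(1), "fp")),
       fn = sum(vapply(counts_list, `[[`, numeric(1), "fn")))
}

#' Student-t confidence interval over repeated runs
#'
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)` for a vector of metric
#' values from independent (seeded) runs.
#'
#' @param values numeric vector, length >= 2.
#' @param level confidence level (default 0.95).
#' @return list with `mean` and `halfwidth`.
#' @export
confidence_interval <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop_bad("confidence interval needs at least 2 values")
  hw <- stats::qt((1 + level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  list(mean = mean(values), halfwidth = hw)
}

gold_useful_triples <- function(sentence) {
  Filter(function(tr) tr$useful, sentence$triples)
}

#' Evaluate predicted triples against a gold corpus
#'
#' Micro-averaged: TP/FP/FN are summed over sentences before computing
#' P/R/F1 (a per-sentence macro average is available via `macro`).  With
#' `by_n = TRUE` the report adds one row per stratum of sentences
#' grouped by their number of gold triples (1..5); empty strata are
#' omitted with a message.  Gold triples are the useful ones: distractor
#' (Noise) triples are not extraction targets.
#'
#' @param predictions named list (by sentence id) of triple lists, e.g.
#'   from [extract_corpus()].
#' @param gold list of annotated sentences.
#' @param by_n add per-stratum rows?
#' @param macro average per-sentence metrics instead of summing counts?
#' @return data.frame with columns `stratum`, `n_sentences`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_extraction <- function(predictions, gold, by_n = FALSE, macro = FALSE) {
  ids <- vapply(gold, `[[`, character(1), "id")
  if (!all(ids %in% names(predictions))) {
    stop_bad("missing predictions for sentences: %s",
             paste(utils::head(setdiff(ids, names(predictions)), 3), collapse = ", "))
  }
  counts <- lapply(gold, function(s) {
    match_triples(predictions[[s$id]], gold_useful_triples(s))
  })
  n_gold <- vapply(gold, function(s) length(gold_useful_triples(s)), integer(1))
  row_for <- function(stratum, idx) {
    if (macro) {
      ms <- lapply(counts[idx], function(ct) suppressWarnings(prf(ct)))
      data.frame(stratum = stratum, n_sentences = length(idx),
                 tp = sum_counts(counts[idx])$tp, fp = sum_counts(counts[idx])$fp,
                 fn = sum_counts(counts[idx])$fn,
                 precision = mean(vapply(ms, `[[`, numeric(1), "precision")),
                 recall = mean(vapply(ms, `[[`, numeric(1), "recall")),
                 f1 = mean(vapply(ms, `[[`, numeric(1), "f1")),
                 stringsAsFactors = FALSE)
    } else {
      m <- suppressWarnings(prf(sum_counts(counts[idx])))
      data.frame(stratum = stratum, n_sentences = length(idx),
                 tp = m$tp, fp = m$fp, fn = m$fn,
                 precision = m$precision, recall = m$recall, f1 = m$f1,
                 stringsAsFactors = FALSE)
    }
  }
  out <- row_for("overall", seq_along(gold))
  if (by_n) {
    for (k in 1:5) {
      idx <- which(n_gold == k)
      if (length(idx) == 0) {
        message(sprintf("stratum N=%d: no sentences, row omitted", k))
        next
      }
      out <- rbind(out, row_for(sprintf("N=%d", k), idx))
    }
  }
  out
}

#' Evaluate from corpus files
#'
#' Reads prediction and gold JSONL corpora (the prediction file stores
#' each sentence's extracted triples in the same record format), aligns
#' sentences by id, and delegates to [evaluate_extraction()].
#'
#' @param pred_file,gold_file JSONL corpus paths.
#' @param schema a `relation_schema` for validation.
#' @param by_n,macro see [evaluate_extraction()].
#' @return data.frame of metrics.
#' @export
evaluate_files <- function(pred_file, gold_file, schema, by_n = FALSE,
                           macro = FALSE) {
  pred <- read_corpus(pred_file, schema)
  gold <- read_corpus(gold_file, schema)
  pids <- vapply(pred, `[[`, character(1), "id")
  gids <- vapply(gold, `[[`, character(1), "id")
  if (!setequal(pids, gids)) stop_bad("prediction and gold sentence ids differ")
  predictions <- stats::setNames(lapply(pred, `[[`, "triples"), pids)
  evaluate_extraction(predictions, gold, by_n = by_n, macro = macro)
}
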