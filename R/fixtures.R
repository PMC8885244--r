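#' Bundled worked example: an annotated food-safety sentence
#'
#' A sentence about the veterinary drug enrofloxacin, typical of
#' food-safety monitoring text, carrying four annotated triples.  Two of
#' them describe the drug itself ("enrofloxacin belongs to the third
#' generation of quinolones", "enrofloxacin is a synthetic
#' broad-spectrum antibacterial") -- pharmacological facts that are
#' distractors for food-health extraction, so their entities are flagged
#' Noise.  The other two ("the skin and meat contain enrofloxacin",
#' "the maximum residue limit is 100 ug/kg") are the domain-relevant
#' facts the extractor should keep.  The span layout is computed from
#' the word pieces, so the annotation is correct by construction.
#'
#' @return an [annotated_sentence()] with four triples (two useful, two
#'   Noise).
#' @export
example_sentence_food_safety <- function() {
  pieces <- c(
    drug1 = "恩诺沙星",
    conn_be = "属于",
    quinolone = "第三代喹诺酮类",
    p1 = "，",
    conn_is1 = "是",
    drugclass = "合成广谱抗菌药物",
    p2 = "，",
    fish = "鱼的",
    skinmeat = "皮和肉",
    mid = "中",
    conn_co = "含有",
    drug2 = "恩诺沙星",
    p3 = "，",
    mrl = "最大残留限量",
    conn_is2 = "是",
    amount = "100μg/kg",
    p4 = "。"
  )
  ends <- cumsum(nchar(pieces))
  starts <- ends - nchar(pieces)
  span <- function(name) c(starts[[name]], ends[[name]])
  text <- paste(pieces, collapse = "")
  annotated_sentence(
    id = "enrofloxacin-example",
    text = text,
    triples = list(
      triple(span("drug1"), "BE", span("quinolone"),
             subj_rel = "Noise", obj_rel = "Noise"),
      triple(span("drug1"), "IS", span("drugclass"),
             subj_rel = "Noise", obj_rel = "Noise"),
      triple(span("skinmeat"), "CO", span("drug2"),
             subj_rel = "Food", obj_rel = "Food"),
      triple(span("mrl"), "IS", span("amount"),
             subj_rel = "Food", obj_rel = "Food")
    )
  )
}
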