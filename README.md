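# relcascade

Joint extraction of (subject, relation, object) triples from Chinese
domain text, designed for low-resource settings such as food-health and
food-safety monitoring, where sentences mix the facts you want with
well-formed but irrelevant ones.

The pipeline has three stages:

1. **Noise filtering.** A BiLSTM-CRF sequence labeler assigns every
   character a *modified BIO* tag — `O`, `Food-B/I` (domain-relevant
   entity), or `Noise-B/I` (distractor entity) — and a binary position
   mask `E` zeroes the distractor positions downstream.
2. **Semantic feature fusion.** Three small contextual encoders embed
   the sentence at three granularities: characters, their **radical**
   decomposition (the structural components of Chinese characters,
   e.g. 酉 in 酸), and its **word** segmentation (greedy longest match
   against a lexicon). The streams are gated by `E` and concatenated
   into a per-character matrix `H_cw`.
3. **Cascading pointer tagging.** The triple distribution is factorised
   as `p(s, r, o | x) = p(s | x) · p((r, o) | s, x)`: position-wise
   binary classifiers mark subject start/end positions (threshold τ,
   nearest-tail pairing); each decoded subject's mean representation is
   added to every position, and one start/end classifier pair *per
   relation* marks that subject's objects. Overlapping triples that
   share a subject fall out naturally.

Both trainable components (and their LSTM, attention, CRF and Adam
internals) are implemented in plain R with analytic gradients, small
enough to train on one CPU core in minutes and verified against finite
differences and exhaustive path enumeration in the test suite. A
synthetic toy-language generator with controllable noise makes the whole
pipeline testable end to end; real corpora in the documented JSONL
format drop into the same functions.

## Worked example

The bundled example sentence is a food-safety monitoring sentence about
the veterinary drug enrofloxacin, annotated with four triples — two
pharmacological distractors and two domain-relevant facts:

```r
library(relcascade)
s <- example_sentence_food_safety()
s
#> <annotated_sentence> enrofloxacin-example (53 chars, 4 triples)
#>   恩诺沙星属于第三代喹诺酮类，是合成广谱抗菌药物，鱼的皮和肉中含有恩诺沙星，最大残留限量是100μg/kg。
#>   (恩诺沙星[0,4) Noise, BE, 第三代喹诺酮类[6,13) Noise)  [noise]
#>   (恩诺沙星[0,4) Noise, IS, 合成广谱抗菌药物[15,23) Noise)  [noise]
#>   (皮和肉[26,29) Food, CO, 恩诺沙星[32,36) Food)
#>   (最大残留限量[37,43) Food, IS, 100μg/kg[44,52) Food)
```

With gold pointer scores, the cascade decoder recovers all four triples;
applying the noise filter's mask leaves the two relevant ones
(`CO` = Contains, `IS` = Is, from the bundled 12-relation schema):

```r
length(extract_triples(s, gold_score_model(load_schema())))
#> [1] 4
length(extract_triples(s, gold_score_model(load_schema(), extractor_config())))
#> [1] 2
```

Radical decomposition of "olive oil contains unsaturated fatty acids":

```r
paste(decompose("橄榄油含有不饱和脂肪酸", load_radical_table()), collapse = "")
#> [1] "木木水口月一食口月月酉"
```

End-to-end on the synthetic toy language — generate corpora, train the
denoiser and the extractor, evaluate held-out triple recovery stratified
by the number of relations per sentence:

```r
lang  <- make_toy_language(seed = 101)
train <- generate_corpus(lang, gen_config(150, noise_triple_prob = 0.3, seed = 1))
test  <- generate_corpus(lang, gen_config(50,  noise_triple_prob = 0.3, seed = 2))

den <- train_denoiser(train, seed = 1)
denoiser_accuracy(den, test)
#> [1] 0.9981533

mod <- train_extractor(train, lang$schema, extractor_config(seed = 1),
                       lang$radical_table, lang$lexicon$word, denoiser = den)
pred <- extract_corpus(test, mod)
evaluate_extraction(pred, test, by_n = TRUE)
#>   stratum n_sentences tp fp fn precision    recall        f1
#> 1 overall          50 68 20 21 0.7727273 0.7640449 0.7683616
#> 2     N=1          21 16  2  5 0.8888889 0.7619048 0.8205128
#> 3     N=2          19 29 11  9 0.7250000 0.7631579 0.7435897
#> 4     N=3          10 23  7  7 0.7666667 0.7666667 0.7666667
```

The denoiser tells relevant from distractor entities almost perfectly
on the toy language (relevance there is signalled by context, not by
the entity's characters), and this quick 150-sentence model already
recovers most triples. With the study-scale 500-sentence training
corpus used by the acceptance script, overall held-out F1 is around
0.9, decreasing as sentences carry more relations — the expected
difficulty gradient.

A thin command-line wrapper with `generate` / `denoise` / `train` /
`predict` / `evaluate` / `radsim` subcommands lives at
`inst/cli/relcascade.R`.

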