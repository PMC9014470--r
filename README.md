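# nergen — generalization analysis for biomedical NER

Biomedical named entity recognition (BioNER) benchmarks are dominated by
*memorizable* mentions: test mentions whose exact surface string was already
annotated in the training set.  A model can therefore post a high overall F1
while failing on the cases that matter most in a fast-moving literature —
new synonyms of known concepts and entirely new concepts (think of the name
"COVID-19" arriving in 2020).  `nergen` packages the analysis machinery
needed to quantify and probe this gap, exercisable entirely on synthetic
corpora so no external downloads or GPU models are required.

## What it does

**Partitioning.** Given a training corpus and a test corpus whose mentions
carry concept identifiers (CUIs, e.g. MeSH/OMIM IDs), every test mention
`(e, c)` is assigned by overlap with the training surface set
`E_train` and concept set `C_train`:

| surface `e` | concept `c` | split | recognition ability |
|---|---|---|---|
| `e ∈ E_train` | `c ∈ C_train` | **Mem** | memorization |
| `e ∉ E_train` | `c ∈ C_train` | **Syn** | synonym generalization |
| `e ∉ E_train` | `c ∉ C_train` | **Con** | concept generalization |
| `e ∈ E_train` | `c ∉ C_train` | Homonym | (reported separately) |

**Baselines.** `DICT_train` uses the training surfaces as a longest-match
dictionary; `DICT_syn` adds database synonyms of every training concept.
If candidate spans overlap, the longest is selected (leftmost on ties).

**Evaluation.** Entity-level precision/recall/F1 with exact span+type
matching; recall within each split (false positives cannot be attributed to
a split); *relaxed recall* for a target string (a prediction counts if its
span contains an occurrence of the target); abbreviation-subset recall on
the Con split.

**Debiasing.** A statistics-based bias product: the per-word tag-class
frequency table of the training set acts as a fixed "biased model" `b`, and
during training the tagger's distribution `p` is replaced by
`softmax(log p + log b)` inside the negative log-likelihood, so words with
skewed label statistics contribute little training signal.  Only the model
is updated; inference uses `p` alone.  A linear-softmax reference tagger
over sparse token features makes the effect measurable at desk scale.

**Synthetic benchmarks.** A seeded generator emits paired train/test
corpora (PubTator and CoNLL dialects), a concept-synonym map and a
ground-truth ledger, with exact control over split proportions, name
patterns (conventional "`X disease`" names, abbreviations, identifier-like
"`ABBREV-NUMBER`" names), annotation-inconsistency rate and per-word label
skew.

## Worked example

```r
library(nergen)

sim  <- generate_corpus(generator_config(seed = 42))
inv  <- build_inventory(sim$train)
part <- partition_corpus(sim$test, inv)
print(part)
#> <ner_partition>
#>   Mem          72  (60.0%)
#>   Syn          30  (25.0%)
#>   Con          18  (15.0%)
#>   Homonym       0  (0.0%)

pred <- dict_tag(sim$test, build_dict_train(sim$train))
entity_prf(sim$test$mentions, pred)
#> P=100.0% R=60.0% F1=75.0%  (tp=72 fp=0 fn=48)

split_recall(assign_split(sim$test$mentions, inv), pred)
#>     split  n hits recall
#> 1     Mem 72   72      1
#> 2     Syn 30    0      0
#> 3     Con 18    0      0
#> 4 Homonym  0    0     NA
```

The dictionary baseline recovers **every** memorizable mention and **none**
of the synonym/concept-generalization mentions — overall recall (60%) is
purely the Mem share.  That is the overestimation trap the partitioning
makes visible: a score computed over all mentions mostly measures
memorization.

The debiasing path:

```r
bt   <- compute_bias_table(corpus_to_conll(sim$train))
bias_rows(bt, "ripuemia")   # a word always tagged B in training
#>      B I O        (row is one-hot up to epsilon flooring)
m    <- train_tagger(sim$train, seed = 1, bias_table = bt)  # debiased
pred <- predict_tags(m, sim$test)                            # uses p only
```

## Command line

An `Rscript` front end mirrors the pipeline stages
(`inst/cli/nergen`): `convert`, `partition`, `tag`, `evaluate`,
`simulate`, `debias-train`.  For example:

```sh
nergen partition --train train.pubtator --test test.pubtator --out splits.tsv
nergen evaluate --gold test.pubtator --pred pred.pubtator --splits splits.tsv
```

## Scope

External neural taggers are supported through their outputs (prediction
files in PubTator/CoNLL form, or per-token probability matrices shaped like
`token_distributions()`); the package does not train or embed transformer
models.  Nested or discontinuous mentions and BioC XML are out of scope.
See `vignettes/generalization-analysis.Rmd` for the model, the generator's
assumptions, and known limitations.
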