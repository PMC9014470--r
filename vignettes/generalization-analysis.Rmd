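---
title: "Measuring and debiasing generalization in biomedical NER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and debiasing generalization in biomedical NER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nergen)
```

## The problem

A biomedical NER model is useful to the extent that it finds entity names
it has *not* seen annotated before: drug brand names coined after the
corpus was built, new synonyms of known diseases, and genuinely new
concepts.  Benchmark test sets, however, share most of their mention
surfaces with their training sets, so overall precision/recall/F1 mostly
measures memorization.  `nergen` operationalizes three recognition
abilities by partitioning test mentions on surface and concept-ID overlap
with training:

* **Mem** — surface seen, concept seen: memorization.
* **Syn** — surface unseen, concept seen: synonym generalization.
* **Con** — surface and concept unseen: concept generalization.

A fourth combination (surface seen, concept unseen) is logically possible —
the same string annotated under a new concept.  It is not part of the
three-way scheme; we report it as a separate *Homonym* bucket rather than
silently folding it into Mem, so the three splits keep their intended
semantics.  Only recall is reported per split: a false positive has no gold
split to be charged to.

### Normalization

Membership in `E_train` is string-level (synonyms such as Motrin/Ibuprofen
must count as different surfaces), so the only normalization applied is
case-folding and whitespace collapsing — an explicit, recorded policy
(`norm_policy()`), configurable because the reference corpora do not
document theirs.  Mentions with several concept IDs count as concept-seen
if *any* ID was seen (configurable to *all*); the `any` rule keeps Con
strictly "no known concept".  `UNKNOWN` IDs never match.

## Dictionary baselines

`DICT_train` matches the normalized training surfaces over
token-boundary-aligned spans (so "MI" cannot fire inside "MIld");
`DICT_syn` adds all database synonyms of concepts observed in training.
Overlapping candidates are resolved by character length, longest first,
leftmost on ties, greedily accepting spans disjoint from those already
accepted.  On a synthetic corpus with no annotation inconsistency this
yields exactly recall 1 on Mem and 0 on Syn/Con for `DICT_train` — the
formal statement of "memorization is easy".  When synonym-map surfaces
occur unannotated in the corpus (annotation inconsistency between corpus
and database), `DICT_syn` gains recall on Syn but loses precision relative
to `DICT_train`; the generator can inject this at a controlled rate.

## The bias product

Per-token, a tagger produces a distribution `p` over the `K` BIO classes.
The *biased model* is nothing but the training-set class frequency of the
current word (row `b` of the bias table): for word `w`,
`b_k(w) = count(w tagged k) / count(w)`.  Training minimizes
`-log p̂[gold]` with

```
p̂ = softmax(log p + log b)  =  (p * b) / Σ_j p_j b_j
```

where `b` is fixed and gradients flow only through `p`; at inference `p`
is used alone.  If the bias already concentrates on the gold class, `p̂`
is nearly right regardless of `p`, so the token contributes almost no
gradient: the model cannot earn training reward by memorizing per-word
label statistics, and must invest in context and shape features instead.

Numerical choices:

* **Zero handling.** Single-class words make `b` exactly zero elsewhere
  and `log b` undefined.  Rows are floored at `epsilon` and renormalized;
  the operation default is `1e-6`, which changes the frequencies by a
  negligible amount.
* **Epsilon in the desk-scale experiment.** The reference tagger is a
  linear model whose only parameter sharing is through feature overlap.
  With `epsilon = 1e-6`, every token whose word is single-class (most
  tokens: fillers are always O, most entity words always B or I) has a
  saturated `p̂` and contributes *no* gradient at all, so the debiased
  model learns almost nothing — a degenerate failure a BERT-scale model
  does not have, because its shared encoder receives gradient from every
  token.  The packaged debiasing experiment therefore builds its bias
  table with `epsilon = 0.1`, which caps the damping at roughly 8:1
  instead of ~10^6:1 while preserving the method's structure.  This is a
  property of the miniature model, not of the method, and the parameter is
  exposed.
* The loss shrinks relative to plain NLL exactly when `b[gold]` exceeds
  the `p`-weighted mean of `b` (direct algebra); `b[gold] > 1/K` alone is
  not sufficient, though the canonical skewed-word case (`b` one-hot on
  gold) always is.
* The bias is applied per token independently; no CRF/sequence coupling,
  matching the per-token formulation.  Word statistics use whole
  case-folded words, matching the reference tagger's vocabulary.

## The reference tagger

A multinomial logistic regression over sparse indicator features: word
identity, previous/next word, contains-digit, contains-hyphen, all-caps,
initial-cap, suffix bigram/trigram.  Full-batch gradient descent (default
400 epochs, learning rate 4, L2 `1e-4`), weights initialized `N(0, 0.01)`
under a fixed seed; training is bitwise reproducible.  It is deliberately
the simplest model that can both memorize word identities and exploit
context — the two behaviours whose balance the debiasing method shifts.
External taggers plug in through per-token probability matrices of the same
shape as `token_distributions()` or through prediction files; no neural
framework is embedded.

## The synthetic world

`generate_corpus()` emits a deterministic function of its config.  The
defaults describe a small benchmark-like world chosen once: 160 training
documents (two mentions each), 120 test documents (one mention each), 40
concepts with 3 held-out synonyms each, test split proportions
0.6/0.25/0.15/0 (real BioNER benchmarks are dominated by memorizable
mentions), and a name-pattern mix of 50% conventional two-word names
("`<stem> disease`", "`<stem> syndrome`"), 30% abbreviations, 20%
identifier-like `ABBREV-NUMBER` names.  Split proportions are realized
*exactly* (largest-remainder rounding), and a ledger records every test
mention's intended split, pattern class and abbreviation flag — the ground
truth the partitioner and metrics are tested against.

Structural features worth knowing:

* **Templates.** Sentences come from a small template family with single
  spaces and detached punctuation, so whitespace tokenization is exact and
  round-trips are byte-identical.  Entity slots appear either in *cued*
  contexts ("patients with …", "diagnosis of …") or *flat* ones ("The …
  episodes were frequent"), where only word identity identifies the
  entity.
* **Registry codes.** About 40% of context sentences mention an
  identifier-like trial/sample code (`ABC-12` shape) that is *not* an
  entity, teaching a disease tagger that such tokens are ordinarily O —
  the role chemical identifiers play for a disease tagger on real
  corpora.
* **Label-skew injection.** Six "biased head" words occur only as
  single-token B mentions in training (24 times each, mostly in flat
  contexts, so identity carries the load), while at test they appear
  inside two-token Con mentions where their gold tag is I.  Eight "mixed"
  scaffolding concepts keep modifier and head words with genuinely mixed
  tag statistics, so a debias-trained model still receives gradient and
  can learn the context features that resolve the test usage.
* **Inconsistency injection.** A configurable fraction of test documents
  contains an unannotated occurrence of a synonym-map surface.
* **COVID-19-style probe.** Optionally, a separate evaluation set built
  around one novel `ABBREV-NUMBER` concept, every document containing the
  surface in a disambiguating context ("… pandemic remains an ongoing
  global emergency"), scored by relaxed (containment) recall per
  occurrence.

What the generator does **not** emulate: real lexical variety, sentence
length and annotation noise distributions, nested or discontinuous
mentions, wordpiece effects, or the actual content of NCBI-disease/BC5CDR.
A green directional test therefore establishes that the *mechanisms*
(partition bookkeeping, dictionary behaviour, bias-product training
dynamics, shape-feature generalization) behave as the analysis predicts —
not that effect sizes transfer to real corpora.

## Design decisions on open points

* **Tokenization** splits on whitespace and detaches leading/trailing
  punctuation while keeping internal hyphens, so `COVID-19` and `MK-486`
  stay single tokens; it is a declared convention, not recovered from the
  reference corpora.
* **Misaligned mentions** expand to the smallest covering token span with
  a warning (no gold data discarded); **orphan `I` tags** start a new
  mention (deterministic lenient repair).
* **Abbreviation heuristic**: a single token, length ≥ 2, no lowercase
  letters, at least one uppercase (digits/hyphens allowed).  The reference
  analyses never define their criterion; ours is configurable and its
  flagged fraction is always reported alongside the recall.
* **Precision with no predictions** is reported as 0 with a
  `precision_defined = FALSE` flag rather than NaN.
* **Relaxed recall counts per occurrence**, so a document with two target
  occurrences contributes two units.
* **Pseudo entities** are `3–5` capital letters, a hyphen, and `1–3`
  digits, letter and digit counts uniform (the digit distribution is not
  documented anywhere; uniform without leading zeros is assumed).
* **Dictionary matching case**: case-insensitive after shared
  normalization; both this and token alignment are configuration-surfaced
  choices since the reference setup does not state them.

## Limitations

Exact benchmark split counts cannot be reproduced without the original
(undocumented) normalization; partitioning here is guaranteed only
self-consistent and oracle-consistent.  The reference tagger is a
desk-scale stand-in: directional conclusions (debiasing helps Con and not
Mem; name-pattern augmentation helps identifier-like novel names) are the
supported claims, not absolute scores.  The per-word bias table ignores
context entirely by construction; words whose entity status is genuinely
contextual are exactly where the bias product pays off, and words with
consistent, correct labels are where it costs a little memorization — the
trade-off the split metrics make visible.
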