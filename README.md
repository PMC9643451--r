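# metannot

Tissue and cell-type annotation of genomics samples from their
unstructured free-text metadata.

Public repositories hold millions of gene-expression samples whose
tissue of origin is described only in noisy, free-form submitter text.
`metannot` turns that text into calibrated per-tissue predictions: it
builds an ontology-aware gold standard from direct sample annotations,
embeds each sample's cleaned description as an IDF-weighted average of
word vectors, trains a one-vs-rest sparse logistic model per ontology
term, and evaluates everything with dataset-stratified cross-validation
so performance reflects unseen studies, not memorised batches. It is
aimed at curators and computational biologists who need machine-readable
anatomy/cell-type labels (UBERON/CL-style) at repository scale.

## The method

**Labels.** For a term *t*, a sample is *positive* if directly annotated
to *t* or any descendant of *t*; *ignored* if annotated to a strict
ancestor of *t* (ambiguous); otherwise *negative*. A dataset is positive
for *t* if a strict majority of its samples are, ignored if a strict
majority are ignored, else negative. Terms with positives from at least
3 datasets are trainable.

**Features.** Metadata text is cleaned (punctuation deleted, tokens with
digits/URL markers/fewer than 3 characters removed, lowercased,
optionally lemmatized) and pooled:

&nbsp;&nbsp;&nbsp;&nbsp;v = Σᵢ wᵢ e(tᵢ) / Σᵢ wᵢ,&nbsp;&nbsp;
w(t) = IDF(t, D) = log( N / |{d ∈ D : t ∈ d}| )

with the sum over the token multiset; words without a stored weight get
the mean weight of the rest of the bag. TF-IDF and uniform weighting are
also supported. Word vectors come from a pluggable backend; a seeded
hashed backend (deterministic unit-norm vector per word) is built in,
and any contextual-embedding model can be wrapped via `table_backend()`
or a custom `embed_word` function.

**Models.** Per term, L1-regularised logistic regression (inverse
regularisation C = 1) on positive vs negative entities; scores are
probabilities in (0, 1). Dataset descriptions are scored per sentence
and max-pooled. Predictions from several methods are combined by
F1-weighted averaging; sample and parent-dataset probabilities can be
added into a ranking score.

**Evaluation.** k-fold cross-validation stratified by *dataset* (3, 4 or
5 folds depending on the positive-dataset count), scored by average
precision (auPRC) and log2(auPRC / prior).

A dictionary NER baseline (exact word-boundary matching of term names
and synonyms) and an adapter for external binary annotators are
included, plus a seeded synthetic-corpus generator that produces a toy
ontology (OBO), sample/dataset metadata tables and annotations with
controllable tissue signal.

## Worked example

```r
library(metannot)

onto <- generate_toy_ontology(n_systems = 2, terms_per_system = 5,
                              depth = 1, seed = 1)
corp <- generate_corpus(corpus_spec(signal = 0.8, seed = 1), onto)
ann  <- annotation_table(corp$annotations, onto$dag, seed = 1)

texts <- setNames(corp$samples$text, corp$samples$sample_id)
feats <- embed_samples(texts, hashed_backend(128, seed = 1),
                       scheme = "uniform")

tm <- corp$terms[1]
sl <- propagate_sample_labels(onto$dag, ann, tm)
dl <- label_datasets(sl, ann)
plan <- plan_dataset_folds(dl, seed = 1, term = tm)
run_cv(lr_method(feats, sl, tm), plan, sl, ann$dataset_of)
#> eval_result [TS:0000003]: k=4 mean auPRC=0.919 prior=0.100 log2(auPRC/prior)=3.20
```

640 synthetic samples (10 leaf terms × 4 datasets × 16 samples) are
generated, embedded at dimension 128, and the first term's model is
evaluated by 4-fold dataset-stratified CV: it ranks held-out samples
from unseen datasets at auPRC 0.92 against a 0.10 prior — about
log2(0.92/0.10) ≈ 3.2 doublings over random.

Scoring arbitrary text against trained models:

```r
models <- lapply(corp$terms[1:3], function(t)
  train_term_model(feats, propagate_sample_labels(onto$dag, ann, t), t))
embed_and_predict_text("sample description text here", models,
                       hashed_backend(128, seed = 1), scheme = "uniform")
```

A command-line front end with subcommands `simulate`, `build-labels`,
`idf`, `embed`, `train`, `predict`, `evaluate`, `combine` is installed
at `inst/cli/metannot` (see `system.file("cli", "metannot",
package = "metannot")`).

## Vignette

`vignettes/annotating-sample-metadata.Rmd` documents the model,
its assumptions, all tunable parameters, the synthetic-data design and
the numerical choices in detail.
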