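# figword

Multimodal classification of biomedical documents for curation triage,
using the panel-type composition of their figures alongside caption and
title-and-abstract text.

## Why

Biological databases (gene-expression atlases, molecular-interaction
resources) employ curators who first *triage* the literature: decide which
publications are relevant to the database's scope. Text-only classifiers
miss a strong signal — the figures. Fluorescence micrographs of embryos
mark expression studies; gel/blot panels mark pull-down assays. `figword`
represents that signal explicitly and integrates it with text.

## The model

Each figure (possibly compound, i.e. made of several panels) is encoded as
a **Figure-word**: a binary vector `<c_1, …, c_K>` over a K-class
panel-type taxonomy (default K = 11), `c_i = 1` iff a panel of class *i*
is present. A document is then represented three ways:

* **d_IMG** — binary indicator over the `2^K = 2048` possible
  Figure-words: which panel-type combinations occur in the document;
* **d_CAP** — the mean of the word-embedding vectors of the *distinct*
  preprocessed tokens in the concatenated figure captions,
  `d_CAP = (w̄_1 + … + w̄_n) / n` with n the number of distinct
  in-vocabulary words (embedding dimension 200 by default);
* **d_TA** — the same embedding mean over the title-and-abstract.

Preprocessing = named-entity substitution (generic terms *gene*,
*disease*, *chemical*, *species*, *mutation*, *cell-line*) → lowercasing →
tokenization → Porter stemming → stop-word removal.

Two integration schemes combine the sources, both linear SVMs with
Platt-calibrated probabilities:

* **CombV** — one SVM on the standardized concatenation
  `d_ALL = [d_IMG | d_CAP | d_TA]` (2448 features by default; each feature
  rescaled to mean 0, sd 1 on the training folds);
* **CombC** — a stacked meta-classifier on the 6-vector
  `<L_IMG, P_IMG, L_CAP, P_CAP, L_TA, P_TA>` of base-classifier labels and
  relevant-class probabilities, with out-of-fold meta-features during
  training.

Evaluation uses five complete rounds of stratified 5-fold cross-validation
(precision / recall / F-score, Welch t-tests between systems,
complementarity analysis of which relevant documents each source catches).
Class-distinguishing Figure-words are ranked by the pooled two-proportion
z-score of their figure-level occurrence rates in relevant vs irrelevant
documents.

See `vignettes/figword-methods.Rmd` for assumptions, numerical choices and
limitations.

## Worked example

The package ships a seed-deterministic synthetic-corpus generator, so the
whole pipeline runs without downloads:

```r
library(figword)

# generate a 200-document synthetic triage corpus + embeddings
cfg  <- synth_config(n_docs = 200, seed = 7)
corp <- generate_corpus(cfg)
emb  <- generate_embeddings(cfg)

# build d_IMG, d_CAP, d_TA for every document
reps <- build_representations(corp$documents, emb)

# five rounds of 5-fold cross-validation for two schemes
plan  <- make_cv_plan(rounds = 5, folds = 5, seed = 1)
cap   <- run_cv(reps, "cap",   plan, fw_config(seed = 1))
combv <- run_cv(reps, "combv", plan, fw_config(seed = 1))
score_summary(rbind(cap, combv))

cmp <- compare_systems(combv, cap)
cat(sprintf("CombV vs C_CAP: t = %.2f, p = %.2g\n", cmp$t, cmp$p))

# most class-distinguishing Figure-words
rank_distinguishing(count_figure_words(corp$documents), top = 3)
```

Output:

```
  scheme precision_mean recall_mean f_score_mean f_score_sd
1    cap      0.8686030   0.8715789    0.8677757 0.03306175
2  combv      0.9609065   0.9200000    0.9382989 0.03396703
CombV vs C_CAP: t = 7.44, p = 1.6e-09
  index                       figure_word k_rel k_irr         z
1    32           Fluorescence microscopy   152    28 11.054665
2    64                          Gel/blot    46   153  -6.862812
3    33 Histogram+Fluorescence microscopy    46     9   5.734185
```

Reading this: the caption-only classifier reaches F ≈ 0.87 over the 25
(round, fold) evaluations; concatenating image, caption and abstract
features lifts F to ≈ 0.94, and the Welch test over the paired fold scores
confirms the gain. The ranking table mirrors how distinguishing
Figure-words are reported: the fluorescence-only composition occurs in 152
figures of relevant documents versus 28 of irrelevant ones (z ≈ 11,
enriched in relevant), while gel/blot-only panels are enriched on the
irrelevant side of this corpus.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/figword.R synth --n-docs 200 --seed 7 \
    --out corpus.json --embeddings emb.txt --out-dir run/
Rscript inst/cli/figword.R evaluate --corpus corpus.json \
    --embeddings emb.txt --scheme combv --out-dir run/
Rscript inst/cli/figword.R rank --corpus corpus.json --top 5 --out-dir run/
```

Every run writes a `manifest.json` (flags, seed, package version, input
digests) next to its outputs.

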