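# Shared in-code fixtures: tiny corpora and embedding tables built fresh at
# test time.

fix_tax <- default_taxonomy()

fix_doc <- function(id, label = "relevant", ta = "", figures = list()) {
  document_record(doc_id = id, title_abstract = ta, figures = figures,
                  label = label)
}

fix_fig <- function(labels, caption = "") {
  figure_record(caption = caption, panel_labels = labels)
}

# A three-document labeled corpus touching several panel types
fix_corpus3 <- function() {
  docs <- list(
    fix_doc("d1", "relevant", "Gene expression in mouse embryos",
            list(fix_fig(c("Histogram", "Fluorescence microscopy"),
                         "Expression levels quantified."),
                 fix_fig("Fluorescence microscopy",
                         "Whole embryo staining."))),
    fix_doc("d2", "irrelevant", "Protein folding dynamics",
            list(fix_fig(c("Gel/blot", "Histogram"),
                         "Pull-down assay blots."))),
    fix_doc("d3", NULL, "Unlabeled survey of imaging methods", list())
  )
  attr(docs, "taxonomy") <- fix_tax
  docs
}

# Deterministic small embedding table over an explicit token set
fix_embeddings <- function(tokens, dim = 8L, seed = 404L) {
  set.seed(seed)
  m <- matrix(rnorm(length(tokens) * dim), nrow = length(tokens))
  rownames(m) <- tokens
  embedding_table(m)
}

# A small separable representation set: class signal planted directly in
# all three blocks so every base classifier can reach perfect accuracy.
fix_separable_reps <- function(n = 30L, seed = 77L) {
  cfg <- synth_config(
    n_docs = n, seed = seed,
    caption_signal = 0.8, ta_signal = 0.8,
    panel_inclusion_probs = list(
      relevant = c(0.05, 0.02, 0.02, 0.02, 0.02, 0.95, 0.05, 0.02,
                   0.02, 0.02, 0.02),
      irrelevant = c(0.05, 0.02, 0.02, 0.02, 0.02, 0.02, 0.95, 0.02,
                     0.02, 0.02, 0.02)
    )
  )
  corp <- generate_corpus(cfg)
  emb <- generate_embeddings(cfg)
  build_representations(corp$documents, emb, warn = FALSE)
}
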