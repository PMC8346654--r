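#' Build all three document representations for a corpus
#'
#' Computes, for every document, the image vector d_IMG (binary, length
#' `2^K`), the caption vector d_CAP and the title-and-abstract vector d_TA
#' (embedding means, length `table$dim`). These are per-document encodings
#' with no fitted state, so they can be computed once per corpus without
#' train/test leakage; all fitting (standardization, classifiers) happens
#' later on training rows only.
#'
#' @param docs List of `fw_document` records.
#' @param table An `fw_embeddings` table.
#' @param taxonomy An `fw_taxonomy`.
#' @param ner Optional `fw_ner_map`.
#' @param mode Embedding-mean mode, see [mean_embedding()].
#' @param warn Warn on figures without classified panels?
#' @return An object of class `fw_reps`: list with `doc_ids`, `labels`
#'   (character, `NA` when unlabeled), sparse matrix `img`, dense matrices
#'   `cap` and `ta` (rows = documents), `taxonomy` and `dim`.
#' @export
build_representations <- function(docs, table, taxonomy = default_taxonomy(),
                                  ner = NULL, mode = "distinct",
                                  warn = TRUE) {
  assert_taxonomy(taxonomy)
  stopifnot(inherits(table, "fw_embeddings"))
  ids <- vapply(docs, function(d) d$doc_id, character(1L))
  img <- corpus_image_matrix(docs, taxonomy, warn = warn)
  cap <- t(vapply(docs, caption_vector, numeric(table$dim),
                  table = table, ner = ner, mode = mode))
  ta <- t(vapply(docs, ta_vector, numeric(table$dim),
                 table = table, ner = ner, mode = mode))
  rownames(cap) <- ids
  rownames(ta) <- ids
  structure(
    list(doc_ids = ids, labels = unname(corpus_labels(docs)),
         img = img, cap = cap, ta = ta,
         taxonomy = taxonomy, dim = table$dim),
    class = "fw_reps"
  )
}

#' @export
print.fw_reps <- function(x, ...) {
  cat("Document representations for", length(x$doc_ids), "documents\n")
  cat("  d_IMG:", ncol(x$img), "Figure-word slots (",
      sum(Matrix::colSums(x$img) > 0), "observed )\n")
  cat("  d_CAP / d_TA:", x$dim, "embedding dimensions\n")
  cat("  labeled:", sum(!is.na(x$labels)), "\n")
  invisible(x)
}

# Extract one representation block (dense, rownames = doc ids).
rep_block <- function(reps, block = c("img", "cap", "ta"), idx = NULL) {
  block <- match.arg(block)
  m <- reps[[block]]
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m <- as.matrix(m)
  colnames(m) <- paste0(toupper(block), "_", seq_len(ncol(m)))
  m
}

# Concatenated d_ALL = [d_IMG | d_CAP | d_TA]
rep_all <- function(reps, idx = NULL) {
  cbind(rep_block(reps, "img", idx),
        rep_block(reps, "cap", idx),
        rep_block(reps, "ta", idx))
}

# Numeric 0/1 gold labels (1 = relevant); errors on unlabeled documents.
rep_y <- function(reps, idx = NULL) {
  lab <- reps$labels
  if (!is.null(idx)) lab <- lab[idx]
  if (anyNA(lab))
    stop("corpus contains unlabeled documents; labels are required here",
         call. = FALSE)
  as.integer(lab == "relevant")
}
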