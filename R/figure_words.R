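#' Encode a figure as a Figure-word
#'
#' A Figure-word is the binary indicator vector `<c_1, ..., c_K>` over the
#' taxonomy's K panel-type classes (default K = 11), with `c_i = 1` when at
#' least one panel of class i is present in the figure. Duplicated panel
#' types collapse: the encoding records presence, not counts. A figure
#' containing only histogram and fluorescence-microscopy panels (classes 1
#' and 6 of the default taxonomy) therefore encodes as
#' `<1,0,0,0,0,1,0,0,0,0,0>`.
#'
#' @param panel_labels Non-empty character vector of taxonomy class names.
#' @param taxonomy An `fw_taxonomy`.
#' @return Integer 0/1 vector of length K, named by class.
#' @export
#' @examples
#' encode_figure(c("Histogram", "Fluorescence microscopy"), default_taxonomy())
encode_figure <- function(panel_labels, taxonomy = default_taxonomy()) {
  assert_taxonomy(taxonomy)
  if (length(panel_labels) == 0L)
    stop("cannot encode a figure with no panel labels", call. = FALSE)
  pos <- taxonomy$positions[panel_labels]
  if (anyNA(pos))
    stop("panel label '", panel_labels[is.na(pos)][1L],
         "' is not in the taxonomy", call. = FALSE)
  bits <- integer(length(taxonomy$classes))
  bits[unique(pos)] <- 1L
  names(bits) <- taxonomy$classes
  bits
}

#' Figure-word index
#'
#' Bijection between Figure-word bit vectors and integers in
#' `[0, 2^K - 1]`: class position 1 is the least-significant bit, so
#' `index = sum(c_i * 2^(i-1))`. For the default 11-class taxonomy the
#' vocabulary of possible Figure-words has exactly `2^11 = 2048` members.
#'
#' @param fw Integer 0/1 vector (a Figure-word).
#' @return Integer index in `[0, 2^K - 1]`.
#' @seealso [index_to_figure_word()]
#' @export
figure_word_index <- function(fw) {
  fw <- as.integer(fw)
  if (any(is.na(fw) | !(fw %in% c(0L, 1L))))
    stop("Figure-word entries must be 0/1", call. = FALSE)
  as.integer(sum(fw * 2^(seq_along(fw) - 1L)))
}

#' Inverse of [figure_word_index()]
#'
#' @param index Integer in `[0, 2^K - 1]`.
#' @param taxonomy Taxonomy defining K (and the bit names).
#' @return Integer 0/1 vector of length K, named by class.
#' @export
index_to_figure_word <- function(index, taxonomy = default_taxonomy()) {
  assert_taxonomy(taxonomy)
  k <- taxonomy_size(taxonomy)
  index <- as.integer(index)
  if (is.na(index) || index < 0L || index > 2^k - 1L)
    stop("Figure-word index must lie in [0, ", 2^k - 1L, "]", call. = FALSE)
  bits <- as.integer(bitwAnd(bitwShiftR(index, seq_len(k) - 1L), 1L))
  names(bits) <- taxonomy$classes
  bits
}

#' Human-readable Figure-word label
#'
#' @param index Figure-word index.
#' @param taxonomy Taxonomy defining the classes.
#' @return String joining the present classes with `"+"` (e.g.
#'   `"Histogram+Fluorescence microscopy"`).
#' @export
figure_word_label <- function(index, taxonomy = default_taxonomy()) {
  bits <- index_to_figure_word(index, taxonomy)
  paste(taxonomy$classes[bits == 1L], collapse = "+")
}

#' Size of the Figure-word vocabulary
#'
#' @param taxonomy An `fw_taxonomy`.
#' @return `2^K`, the number of possible Figure-words.
#' @export
figure_word_vocabulary_size <- function(taxonomy = default_taxonomy()) {
  2^taxonomy_size(taxonomy)
}

doc_figure_word_indices <- function(doc, taxonomy, warn = TRUE) {
  idx <- integer(0)
  for (f in doc$figures) {
    if (length(f$panel_labels) == 0L) {
      if (warn)
        warning("document '", doc$doc_id,
                "': skipping figure with no classified panels",
                call. = FALSE)
      next
    }
    idx <- c(idx, figure_word_index(encode_figure(f$panel_labels, taxonomy)))
  }
  idx
}

#' Image-based document vector d_IMG
#'
#' The document-level image representation: a binary vector of length `2^K`
#' (2048 for the default taxonomy) whose entry for Figure-word index i is 1
#' when that Figure-word occurs in at least one of the document's figures.
#' Figures without classified panels are skipped with a warning; a document
#' with no encodable figures yields the all-zero vector (missing-modality
#' documents are retained, not dropped).
#'
#' @param doc An `fw_document`.
#' @param taxonomy An `fw_taxonomy`.
#' @return Numeric 0/1 vector of length `2^K`; element `i` corresponds to
#'   Figure-word index `i - 1`.
#' @export
document_image_vector <- function(doc, taxonomy = default_taxonomy()) {
  v <- numeric(figure_word_vocabulary_size(taxonomy))
  idx <- doc_figure_word_indices(doc, taxonomy)
  v[unique(idx) + 1L] <- 1
  v
}

#' Sparse d_IMG matrix for a corpus
#'
#' Rows are documents (rownames = doc_id), columns the `2^K` Figure-word
#' vocabulary slots (column `i` is Figure-word index `i - 1`). Stored as a
#' sparse matrix since a document realizes at most as many Figure-words as it
#' has figures.
#'
#' @param docs List of `fw_document` records.
#' @param taxonomy An `fw_taxonomy`.
#' @param warn Warn on figures without classified panels?
#' @return A `dgCMatrix` of size n_docs x `2^K`.
#' @export
corpus_image_matrix <- function(docs, taxonomy = default_taxonomy(),
                                warn = TRUE) {
  n <- length(docs)
  ii <- integer(0); jj <- integer(0)
  for (d in seq_len(n)) {
    idx <- unique(doc_figure_word_indices(docs[[d]], taxonomy, warn = warn))
    ii <- c(ii, rep.int(d, length(idx)))
    jj <- c(jj, idx + 1L)
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = 1,
    dims = c(n, figure_word_vocabulary_size(taxonomy)),
    dimnames = list(vapply(docs, function(d) d$doc_id, character(1L)), NULL)
  )
}
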