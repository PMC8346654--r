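# package-level cache for the frozen stop-word list
.fw_env <- new.env(parent = emptyenv())

#' Frozen English stop-word list
#'
#' The standard English stop-word list shipped with the package (a frozen
#' copy under `inst/extdata/stopwords_en.txt`), so preprocessing is
#' reproducible and independent of any external toolkit version.
#'
#' @return Character vector of stop words.
#' @export
fw_stopwords <- function() {
  if (is.null(.fw_env$stopwords)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "figword",
                        mustWork = TRUE)
    .fw_env$stopwords <- readLines(path, warn = FALSE, encoding = "UTF-8")
  }
  .fw_env$stopwords
}

# Stop-word removal runs after stemming, so the removal set is the list
# plus its stemmed forms (Porter maps e.g. "was" -> "wa", "is" -> "i").
fw_stopword_set <- function(stopwords = fw_stopwords()) {
  if (!identical(.fw_env$stopset_src, stopwords)) {
    .fw_env$stopset_src <- stopwords
    .fw_env$stopset <- unique(c(stopwords, porter_stem(stopwords)))
  }
  .fw_env$stopset
}

#' Read a named-entity substitution map
#'
#' Two-column TSV (`surface_form<TAB>generic_term`) mapping entity surface
#' forms to one of the six generic concept terms `gene`, `disease`,
#' `chemical`, `species`, `mutation`, `cell-line`. Substituting mentions by
#' their generic term normalizes entity vocabulary before embedding lookup.
#'
#' @param path Path to the TSV file.
#' @return A named character vector (surface form -> generic term) of class
#'   `fw_ner_map`.
#' @export
read_ner_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 2L)
    stop("NER map '", path, "' must have exactly two tab-separated columns",
         call. = FALSE)
  ner_map(stats::setNames(tab[[2L]], tab[[1L]]))
}

#' Construct a named-entity substitution map
#'
#' @param map Named character vector: surface form -> generic term. Values
#'   must be among `gene`, `disease`, `chemical`, `species`, `mutation`,
#'   `cell-line`.
#' @return The validated map with class `fw_ner_map`.
#' @export
ner_map <- function(map) {
  generic <- c("gene", "disease", "chemical", "species", "mutation",
               "cell-line")
  if (length(map)) {
    stopifnot(is.character(map), !is.null(names(map)), all(nzchar(names(map))))
    bad <- setdiff(unique(unname(map)), generic)
    if (length(bad))
      stop("NER generic terms must be one of ",
           paste(generic, collapse = ", "), "; got '", bad[1L], "'",
           call. = FALSE)
  }
  structure(map, class = "fw_ner_map")
}

# Longest-match, case-insensitive, whole-word substitution of entity
# surface forms by their generic terms.
apply_ner <- function(text, ner = NULL) {
  if (is.null(ner) || length(ner) == 0L) return(text)
  forms <- names(ner)[order(-nchar(names(ner)))]
  for (f in forms) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", f), "\\b")
    text <- gsub(pat, ner[[f]], text, ignore.case = TRUE, perl = TRUE)
  }
  text
}

#' Preprocess text into tokens
#'
#' The text-normalization pipeline applied to captions and
#' titles-and-abstracts, in fixed order: named-entity substitution
#' (longest-match, case-insensitive, whole-word) -> lowercasing ->
#' tokenization on non-alphanumeric characters -> Porter stemming ->
#' stop-word removal. Deterministic; empty text yields an empty token list.
#'
#' @param text Raw text (single string).
#' @param ner Optional `fw_ner_map` of entity substitutions.
#' @param stopwords Stop-word list (default the frozen package list). Both
#'   the listed words and their stems are removed, since removal runs on
#'   stemmed tokens.
#' @return An object of class `fw_tokens`: list with `tokens` (ordered,
#'   preprocessed) and `distinct` (the set of distinct tokens).
#' @export
#' @examples
#' preprocess_text("Pax6 expression in mouse embryos",
#'                 ner = ner_map(c(Pax6 = "gene")))
preprocess_text <- function(text, ner = NULL, stopwords = fw_stopwords()) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(apply_ner(text, ner))
  toks <- strsplit(x, "[^a-z0-9]+")[[1L]]
  toks <- toks[nzchar(toks)]
  toks <- porter_stem(toks)
  toks <- toks[!(toks %in% fw_stopword_set(stopwords))]
  structure(list(tokens = toks, distinct = unique(toks)),
            class = "fw_tokens")
}

#' Concatenate a document's captions
#'
#' Joins the captions of a document's figures, in figure order, with single
#' spaces; empty captions are skipped. The concatenation is the document's
#' caption-based text.
#'
#' @param doc An `fw_document`.
#' @return A single string (possibly "").
#' @export
concat_captions <- function(doc) {
  caps <- vapply(doc$figures, function(f) f$caption, character(1L))
  paste(caps[nzchar(caps)], collapse = " ")
}

#' Embedding-mean document vector
#'
#' Maps a tokenized document to the mean of the embedding vectors of its
#' distinct in-vocabulary tokens: each distinct word contributes once,
#' regardless of how often it occurs, and the divisor n counts only distinct
#' tokens found in the table. Out-of-vocabulary tokens are skipped; a
#' document with no in-vocabulary token maps to the zero vector (keeping
#' downstream standardization well-defined). Set `mode = "tokens"` to
#' average over token occurrences instead.
#'
#' @param tdoc An `fw_tokens` object from [preprocess_text()].
#' @param table An `fw_embeddings` table.
#' @param mode `"distinct"` (default) or `"tokens"`.
#' @return Numeric vector of length `table$dim`.
#' @export
mean_embedding <- function(tdoc, table, mode = c("distinct", "tokens")) {
  stopifnot(inherits(tdoc, "fw_tokens"), inherits(table, "fw_embeddings"))
  mode <- match.arg(mode)
  toks <- if (mode == "distinct") tdoc$distinct else tdoc$tokens
  toks <- toks[toks %in% rownames(table$vectors)]
  if (length(toks) == 0L) return(numeric(table$dim))
  colMeans(table$vectors[toks, , drop = FALSE])
}

#' Caption-based document vector d_CAP
#'
#' Composition of [concat_captions()], [preprocess_text()] and
#' [mean_embedding()]: the document's concatenated captions are normalized
#' and averaged in embedding space. A document without captions yields the
#' zero vector.
#'
#' @inheritParams mean_embedding
#' @param doc An `fw_document`.
#' @param ner Optional `fw_ner_map`.
#' @return Numeric vector of length `table$dim` (default 200).
#' @export
caption_vector <- function(doc, table, ner = NULL,
                           mode = c("distinct", "tokens")) {
  mean_embedding(preprocess_text(concat_captions(doc), ner = ner), table,
                 mode = match.arg(mode))
}

#' Title-and-abstract document vector d_TA
#'
#' Same pipeline as [caption_vector()] applied to the document's
#' title-and-abstract text.
#'
#' @inheritParams caption_vector
#' @return Numeric vector of length `table$dim` (default 200).
#' @export
ta_vector <- function(doc, table, ner = NULL,
                      mode = c("distinct", "tokens")) {
  mean_embedding(preprocess_text(doc$title_abstract, ner = ner), table,
                 mode = match.arg(mode))
}
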