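#' Construct a figure record
#'
#' One (possibly compound) figure of a publication: its caption text and the
#' panel-type labels assigned to its constituent panels. The caption may be
#' empty (figure extraction yields more figures than captions) and the label
#' list may be empty when the figure was never segmented or classified.
#'
#' @param caption Caption text (single string, possibly "").
#' @param panel_labels Character vector of taxonomy class names (possibly
#'   empty). Duplicates are allowed; Figure-word encoding uses presence only.
#' @return An object of class `fw_figure`.
#' @export
figure_record <- function(caption = "", panel_labels = character()) {
  stopifnot(is.character(caption), length(caption) == 1L)
  structure(list(caption = caption,
                 panel_labels = as.character(panel_labels)),
            class = "fw_figure")
}

#' Construct a document record
#'
#' One publication: identifier, optional gold relevance label, the
#' title-and-abstract text, and its figures.
#'
#' @param doc_id Unique document identifier (string).
#' @param title_abstract Concatenated title-and-abstract text.
#' @param figures List of [figure_record()] objects (may be empty).
#' @param label `"relevant"`, `"irrelevant"`, or `NULL` for unlabeled.
#' @return An object of class `fw_document`.
#' @export
document_record <- function(doc_id, title_abstract = "", figures = list(),
                            label = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (!is.null(label)) {
    if (!(is.character(label) && length(label) == 1L &&
          label %in% c("relevant", "irrelevant")))
      stop("label must be \"relevant\", \"irrelevant\" or NULL (doc ",
           doc_id, ")", call. = FALSE)
  }
  if (!all(vapply(figures, inherits, logical(1L), "fw_figure")))
    stop("figures must be a list of figure_record objects (doc ", doc_id, ")",
         call. = FALSE)
  structure(list(doc_id = doc_id, label = label,
                 title_abstract = as.character(title_abstract),
                 figures = figures),
            class = "fw_document")
}

validate_docs <- function(docs, taxonomy) {
  assert_taxonomy(taxonomy)
  ids <- vapply(docs, function(d) d$doc_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate doc_id in corpus: '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  for (d in docs) {
    for (f in d$figures) {
      bad <- setdiff(f$panel_labels, taxonomy$classes)
      if (length(bad))
        stop("document '", d$doc_id, "': panel label '", bad[1L],
             "' is not in the taxonomy", call. = FALSE)
    }
  }
  invisible(docs)
}

#' Read a corpus interchange file
#'
#' Reads the JSON corpus format that stands in for upstream figure-extraction
#' output. The schema is
#' `{"taxonomy": [...], "documents": [{"doc_id", "label"?, "title_abstract",
#' "figures": [{"caption", "panel_labels": [...]}]}]}` with UTF-8 text and
#' label values `"relevant"` / `"irrelevant"` (absent for unlabeled
#' documents).
#'
#' @param path Path to a corpus JSON file.
#' @param taxonomy An `fw_taxonomy` to validate panel labels against, or
#'   `NULL` to use the taxonomy stored in the file (falling back to
#'   [default_taxonomy()] if the file carries none).
#' @return A list of `fw_document` records with the taxonomy attached as
#'   attribute `"taxonomy"`.
#' @export
read_corpus <- function(path, taxonomy = NULL) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || is.null(raw$documents))
    stop("corpus file '", path, "' has no 'documents' field", call. = FALSE)
  if (is.null(taxonomy)) {
    taxonomy <- if (!is.null(raw$taxonomy))
      fw_taxonomy(unlist(raw$taxonomy)) else default_taxonomy()
  }
  docs <- lapply(raw$documents, function(d) {
    if (is.null(d$doc_id))
      stop("corpus document without doc_id in '", path, "'", call. = FALSE)
    figs <- lapply(d$figures, function(f) {
      figure_record(
        caption = if (is.null(f$caption)) "" else as.character(f$caption),
        panel_labels = as.character(unlist(f$panel_labels))
      )
    })
    document_record(
      doc_id = as.character(d$doc_id),
      title_abstract = if (is.null(d$title_abstract)) ""
                       else as.character(d$title_abstract),
      figures = figs,
      label = if (is.null(d$label)) NULL else as.character(d$label)
    )
  })
  validate_docs(docs, taxonomy)
  attr(docs, "taxonomy") <- taxonomy
  docs
}

#' Write a corpus interchange file
#'
#' Inverse of [read_corpus()]: serializes document records (and the taxonomy)
#' to the JSON interchange format. `read_corpus(write_corpus(docs))` returns
#' records equal field-by-field to `docs`.
#'
#' @param docs List of `fw_document` records.
#' @param path Output path.
#' @param taxonomy Taxonomy to embed; defaults to the `"taxonomy"` attribute
#'   of `docs`, else [default_taxonomy()].
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path, taxonomy = NULL) {
  if (is.null(taxonomy)) taxonomy <- attr(docs, "taxonomy")
  if (is.null(taxonomy)) taxonomy <- default_taxonomy()
  validate_docs(docs, taxonomy)
  payload <- list(
    taxonomy = taxonomy$classes,
    documents = lapply(docs, function(d) {
      out <- list(doc_id = jsonlite::unbox(d$doc_id))
      if (!is.null(d$label)) out$label <- jsonlite::unbox(d$label)
      out$title_abstract <- jsonlite::unbox(d$title_abstract)
      out$figures <- lapply(d$figures, function(f) {
        list(caption = jsonlite::unbox(f$caption),
             # I() keeps single-label lists as JSON arrays
             panel_labels = I(as.list(f$panel_labels)))
      })
      out
    })
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, auto_unbox = FALSE, digits = NA,
                              pretty = TRUE),
             con, useBytes = TRUE)
  invisible(path)
}

#' Gold labels of a corpus
#'
#' @param docs List of `fw_document` records.
#' @return Character vector of `"relevant"`/`"irrelevant"`/`NA`, named by
#'   doc_id.
#' @export
corpus_labels <- function(docs) {
  stats::setNames(
    vapply(docs, function(d) if (is.null(d$label)) NA_character_ else d$label,
           character(1L)),
    vapply(docs, function(d) d$doc_id, character(1L))
  )
}
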