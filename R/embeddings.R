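#' Construct an embedding table
#'
#' @param vectors Numeric matrix, one row per token, with unique non-empty
#'   rownames (the tokens).
#' @return An object of class `fw_embeddings` with elements `dim` and
#'   `vectors`.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  tok <- rownames(vectors)
  if (is.null(tok) || any(!nzchar(tok)))
    stop("embedding matrix must have non-empty token rownames", call. = FALSE)
  if (anyDuplicated(tok))
    stop("duplicate token in embedding table: '", tok[duplicated(tok)][1L],
         "'", call. = FALSE)
  structure(list(dim = ncol(vectors), vectors = vectors),
            class = "fw_embeddings")
}

#' Read word embeddings in word2vec text format
#'
#' Expects the plain-text word2vec layout: a header line `"<count> <dim>"`
#' followed by one line per token, each holding the token and `dim`
#' whitespace-separated floats.
#'
#' @param path Path to the embedding file.
#' @return An `fw_embeddings` table.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 1L)
    stop("embedding file '", path, "' is empty", call. = FALSE)
  hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    stop("embedding file '", path, "': header must be '<count> <dim>'",
         call. = FALSE)
  count <- as.integer(hdr[1L]); dim <- as.integer(hdr[2L])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != count)
    stop("embedding file '", path, "': header declares ", count,
         " tokens but ", length(body), " rows found", call. = FALSE)
  parts <- strsplit(trimws(body), "[[:space:]]+")
  lens <- lengths(parts)
  if (any(lens != dim + 1L))
    stop("embedding file '", path, "': row ", which(lens != dim + 1L)[1L],
         " has ", lens[lens != dim + 1L][1L] - 1L,
         " values, expected ", dim, call. = FALSE)
  tokens <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(tokens))
    stop("embedding file '", path, "': duplicate token '",
         tokens[duplicated(tokens)][1L], "'", call. = FALSE)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim)))
  m <- if (dim == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(m))
    stop("embedding file '", path, "': non-numeric vector entry",
         call. = FALSE)
  rownames(m) <- tokens
  embedding_table(m)
}

#' Write word embeddings in word2vec text format
#'
#' @param table An `fw_embeddings` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  stopifnot(inherits(table, "fw_embeddings"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(table$vectors), table$dim), con,
             useBytes = TRUE)
  rows <- apply(table$vectors, 1L, function(v)
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " "))
  writeLines(paste(rownames(table$vectors), rows), con, useBytes = TRUE)
  invisible(path)
}
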