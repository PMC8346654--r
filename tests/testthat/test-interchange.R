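test_that("taxonomy validates names and exposes a bijective position map", {
  tax <- default_taxonomy()
  expect_length(tax$classes, 11L)
  expect_identical(tax$classes[1L], "Histogram")
  expect_identical(tax$classes[6L], "Fluorescence microscopy")
  expect_identical(tax$classes[11L], "Separation residual")
  # positions form a bijection onto 1..K
  expect_identical(sort(unname(tax$positions)), seq_along(tax$classes))
  expect_identical(tax$classes[tax$positions[tax$classes]], tax$classes)

  expect_error(fw_taxonomy(c("A", "A")), "unique")
  expect_error(fw_taxonomy(c("A", "")), "non-empty")
  expect_error(fw_taxonomy(character(0)), "at least one")
})

test_that("corpus JSON round-trips field-by-field", {
  docs <- fix_corpus3()
  path <- withr::local_tempfile(fileext = ".json")
  write_corpus(docs, path)
  back <- read_corpus(path)
  expect_length(back, 3L)
  for (i in seq_along(docs)) {
    expect_identical(back[[i]]$doc_id, docs[[i]]$doc_id)
    expect_identical(back[[i]]$label, docs[[i]]$label)
    expect_identical(back[[i]]$title_abstract, docs[[i]]$title_abstract)
    expect_identical(back[[i]]$figures, docs[[i]]$figures)
  }
  expect_identical(attr(back, "taxonomy")$classes, fix_tax$classes)

  # a second write is byte-identical (normalized serialization)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_corpus(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("unlabeled documents serialize without a label field", {
  path <- withr::local_tempfile(fileext = ".json")
  write_corpus(list(fix_doc("u1", label = NULL)), path, taxonomy = fix_tax)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_false("label" %in% names(raw$documents[[1L]]))
  expect_null(read_corpus(path)[[1L]]$label)
})

test_that("empty corpus and empty figure lists are valid", {
  path <- withr::local_tempfile(fileext = ".json")
  write_corpus(list(), path, taxonomy = fix_tax)
  expect_length(read_corpus(path), 0L)
})

test_that("unknown panel labels are rejected, naming doc and label", {
  docs <- list(fix_doc("dX", "relevant",
                       figures = list(fix_fig("Heatmap"))))
  path <- withr::local_tempfile(fileext = ".json")
  expect_error(write_corpus(docs, path, taxonomy = fix_tax), "Heatmap")
  # write under a wider taxonomy, then read under the default one
  wide <- fw_taxonomy(c(fix_tax$classes, "Heatmap"))
  write_corpus(docs, path, taxonomy = wide)
  err <- tryCatch(read_corpus(path, taxonomy = fix_tax),
                  error = conditionMessage)
  expect_match(err, "Heatmap")
  expect_match(err, "dX")
})

test_that("duplicate doc ids and bad labels are rejected", {
  expect_error(
    write_corpus(list(fix_doc("a"), fix_doc("a")),
                 withr::local_tempfile(), taxonomy = fix_tax),
    "duplicate doc_id")
  expect_error(document_record("d", label = "maybe"), "relevant")
})

test_that("a 100-document synthetic corpus round-trips equal", {
  cfg <- synth_config(n_docs = 100L, seed = 5L)
  corp <- generate_corpus(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_corpus(corp$documents, path)
  back <- read_corpus(path)
  expect_identical(lapply(back, unclass),
                   lapply(corp$documents, unclass))
})

test_that("embedding tables round-trip through word2vec text format", {
  toks <- sprintf("tok%02d", 1:50)
  tab <- fix_embeddings(toks, dim = 200L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(tab, path)
  hdr <- strsplit(readLines(path, n = 1L), " ")[[1L]]
  expect_identical(hdr, c("50", "200"))
  back <- read_embeddings(path)
  expect_identical(back$dim, 200L)
  expect_identical(rownames(back$vectors), toks)
  expect_equal(back$vectors, tab$vectors, tolerance = 1e-12)
})

test_that("malformed embedding files raise format errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 3", "a 1 2 3", "b 1 2 3 4"), path)
  expect_error(read_embeddings(path), "4 values")
  writeLines(c("2 3", "a 1 2 3", "a 4 5 6"), path)
  expect_error(read_embeddings(path), "duplicate token")
  writeLines(c("2 3", "a 1 2 3"), path)
  expect_error(read_embeddings(path), "declares 2")
  writeLines(c("2 3", "a 1 2 3", "b 1 x 3"), path)
  expect_error(read_embeddings(path), "non-numeric")
  expect_error(embedding_table(matrix(1, 1, 1)), "rownames")
})

test_that("a minimal word2vec header/body parses", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 3", "a 1 0 0", "b 0 1 0"), path)
  tab <- read_embeddings(path)
  expect_identical(nrow(tab$vectors), 2L)
  expect_identical(tab$dim, 3L)
  expect_equal(unname(tab$vectors["a", ]), c(1, 0, 0))
})
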