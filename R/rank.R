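#' Count Figure-word occurrences by document class
#'
#' Tallies, for every Figure-word realized in a labeled corpus, how many
#' figures of relevant and of irrelevant documents encode to it. Counting is
#' per figure: a Figure-word occurring in three figures of one document
#' contributes three, matching figure-level occurrence frequencies (and the
#' totals are figures, not documents). Figures without classified panels are
#' skipped.
#'
#' @param docs Labeled corpus (every document must carry a label).
#' @param taxonomy An `fw_taxonomy`.
#' @return An object of class `fw_figword_counts`: list with data.frame
#'   `counts` (`index`, `k_rel`, `k_irr` over observed Figure-words, ordered
#'   by index) and totals `n_rel`, `n_irr` (figures per class).
#' @export
count_figure_words <- function(docs, taxonomy = default_taxonomy()) {
  labels <- corpus_labels(docs)
  if (anyNA(labels))
    stop("count_figure_words requires a fully labeled corpus", call. = FALSE)
  tal <- list(relevant = integer(0), irrelevant = integer(0))
  for (d in docs) {
    idx <- doc_figure_word_indices(d, taxonomy, warn = FALSE)
    tal[[d$label]] <- c(tal[[d$label]], idx)
  }
  observed <- sort(unique(c(tal$relevant, tal$irrelevant)))
  counts <- data.frame(
    index = observed,
    k_rel = vapply(observed, function(i) sum(tal$relevant == i), integer(1L)),
    k_irr = vapply(observed, function(i) sum(tal$irrelevant == i),
                   integer(1L))
  )
  structure(list(counts = counts,
                 n_rel = length(tal$relevant), n_irr = length(tal$irrelevant),
                 taxonomy = taxonomy),
            class = "fw_figword_counts")
}

#' Two-proportion z statistic
#'
#' Pooled two-proportion z-score comparing an occurrence rate between two
#' groups: with `p1 = k1/n1`, `p2 = k2/n2` and pooled `p = (k1+k2)/(n1+n2)`,
#' `z = (p1 - p2) / sqrt(p (1-p) (1/n1 + 1/n2))`. The sign indicates the
#' direction of enrichment (positive = enriched in group 1). When the pooled
#' proportion is 0 or 1 the statistic is undefined and 0 is returned with a
#' warning.
#'
#' @param k1,n1 Successes and trials in group 1 (`n1 > 0`).
#' @param k2,n2 Successes and trials in group 2 (`n2 > 0`).
#' @return The z statistic (scalar).
#' @export
zscore <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  p <- (k1 + k2) / (n1 + n2)
  if (p <= 0 || p >= 1) {
    warning("pooled proportion is ", p, "; z undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}

#' Rank distinguishing Figure-words
#'
#' Ranks the observed Figure-words by the absolute two-proportion z-score of
#' their figure-level occurrence rates in relevant versus irrelevant
#' documents, returning the top-scoring words with both frequencies. Ties in
#' |z| are broken deterministically by total occurrence count (descending),
#' then by Figure-word index (ascending).
#'
#' @param counts An `fw_figword_counts` from [count_figure_words()].
#' @param top Number of rows to return (at most the number of observed
#'   Figure-words); must be positive.
#' @return Data frame with columns `index`, `figure_word` (readable label),
#'   `k_rel`, `k_irr`, `z`, ordered by decreasing |z|.
#' @export
rank_distinguishing <- function(counts, top = 5L) {
  stopifnot(inherits(counts, "fw_figword_counts"))
  if (!is.numeric(top) || length(top) != 1L || top <= 0)
    stop("'top' must be a positive integer", call. = FALSE)
  tab <- counts$counts
  if (nrow(tab) == 0L)
    return(data.frame(index = integer(0), figure_word = character(0),
                      k_rel = integer(0), k_irr = integer(0),
                      z = numeric(0)))
  tab$z <- suppressWarnings(vapply(seq_len(nrow(tab)), function(i)
    zscore(tab$k_rel[i], counts$n_rel, tab$k_irr[i], counts$n_irr),
    numeric(1L)))
  ord <- order(-abs(tab$z), -(tab$k_rel + tab$k_irr), tab$index)
  tab <- tab[ord, , drop = FALSE]
  tab <- utils::head(tab, as.integer(top))
  data.frame(
    index = tab$index,
    figure_word = vapply(tab$index, figure_word_label, character(1L),
                         taxonomy = counts$taxonomy),
    k_rel = tab$k_rel, k_irr = tab$k_irr, z = tab$z,
    row.names = NULL
  )
}
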