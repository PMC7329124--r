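#' TF-IDF cosine similarity over a report corpus
#'
#' Vectorises each report with word-level n-grams (default n = 1..10) on
#' lower-cased text (tokens are runs of two or more word characters),
#' weights raw counts with smoothed inverse document frequency
#' `log((1 + N) / (1 + df)) + 1`, L2-normalises each report vector, and
#' returns the matrix of pairwise cosine similarities (the normalised
#' TF-IDF matrix times its transpose).
#'
#' @param reports Data frame with columns `report_id` and `text` (or
#'   `full_text`).
#' @param ngram_min,ngram_max N-gram range.
#' @return A `tbi_similarity`: symmetric numeric matrix with unit
#'   diagonal, dimnames set to the report ids.
#' @export
tfidf_cosine <- function(reports, ngram_min = 1L, ngram_max = 10L) {
  col <- if ("text" %in% names(reports)) "text" else "full_text"
  stopifnot(all(c("report_id", col) %in% names(reports)),
            ngram_min >= 1, ngram_max >= ngram_min)
  if (nrow(reports) < 2) abort("Need at least two reports.")
  ids <- as.character(reports$report_id)
  docs <- lapply(reports[[col]], ngram_counts, ngram_min, ngram_max)
  vocab <- sort(unique(unlist(lapply(docs, names), use.names = FALSE)))
  trip <- lapply(seq_along(docs), function(i) {
    cnt <- docs[[i]]
    list(i = rep.int(i, length(cnt)), j = match(names(cnt), vocab),
         x = as.numeric(cnt))
  })
  tf <- Matrix::sparseMatrix(
    i = unlist(lapply(trip, `[[`, "i")),
    j = unlist(lapply(trip, `[[`, "j")),
    x = unlist(lapply(trip, `[[`, "x")),
    dims = c(length(docs), length(vocab)))
  n <- nrow(tf)
  df <- Matrix::colSums(tf > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  x <- tf %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(x^2))
  norms[norms == 0] <- 1
  x <- Matrix::Diagonal(x = 1 / norms) %*% x
  sim <- as.matrix(x %*% Matrix::t(x))
  sim <- pmin(pmax(sim, 0), 1)
  diag(sim) <- 1
  dimnames(sim) <- list(ids, ids)
  structure(sim, class = c("tbi_similarity", "matrix", "array"))
}

# Word n-gram counts for one document (named integer vector).
ngram_counts <- function(text, ngram_min, ngram_max) {
  words <- regmatches(tolower(text),
                      gregexpr("\\b\\w\\w+\\b", tolower(text),
                               perl = TRUE))[[1]]
  if (length(words) == 0) return(integer(0))
  grams <- unlist(lapply(seq.int(ngram_min, ngram_max), function(n) {
    if (length(words) < n) return(character(0))
    if (n == 1) return(words)
    vapply(seq_len(length(words) - n + 1), function(k)
      paste(words[k:(k + n - 1)], collapse = " "), character(1))
  }))
  table(grams)
}

#' @export
print.tbi_similarity <- function(x, ...) {
  cat("<tbi_similarity> ", nrow(x), " x ", ncol(x),
      " cosine similarity matrix (mean off-diagonal ",
      round(mean(x[upper.tri(x)]), 3), ")\n", sep = "")
  invisible(x)
}

#' Remove near-duplicate reports
#'
#' Greedy threshold-based deduplication: repeatedly draw a random
#' unprocessed report, collect every unprocessed report with cosine
#' similarity at or above the threshold to it (itself included), keep one
#' member of the set at random (the anchor is not privileged) and mark
#' the rest removed, until every report is processed. A report whose
#' similarity to every other report is below the threshold is always
#' kept.
#'
#' @param sim A `tbi_similarity` matrix.
#' @param threshold Similarity at or above which reports are considered
#'   duplicates (default 0.70). Must lie in (0, 1].
#' @param seed Integer seed driving the random draws.
#' @return Tibble with columns `report_id`, `status` (`"kept"` /
#'   `"removed"`) and `anchor_id` (the draw that processed the report).
#' @export
dedup_corpus <- function(sim, threshold = 0.70, seed = 1L) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must lie in (0, 1].")
  }
  ids <- rownames(sim)
  stopifnot(!is.null(ids), nrow(sim) == ncol(sim))
  status <- setNames(rep(NA_character_, length(ids)), ids)
  anchor_of <- setNames(rep(NA_character_, length(ids)), ids)
  withr::with_seed(seed, {
    repeat {
      open <- ids[is.na(status)]
      if (length(open) == 0) break
      anchor <- open[sample.int(length(open), 1)]
      set <- open[sim[anchor, open] >= threshold]
      keep <- set[sample.int(length(set), 1)]
      status[set] <- "removed"
      status[keep] <- "kept"
      anchor_of[set] <- anchor
    }
  })
  tibble(report_id = ids, status = unname(status[ids]),
         anchor_id = unname(anchor_of[ids]))
}

#' Similarity-aware dataset partitioning
#'
#' Builds a shuffled deck of dataset labels whose composition follows the
#' requested proportions (largest-remainder rounding), then repeatedly
#' draws a random unassigned report together with up to its three most
#' similar unassigned reports (ties broken by identifier order, no
#' similarity floor) and deals the group the next labels from the deck,
#' until every report is assigned.
#'
#' @param sim A `tbi_similarity` matrix covering at least the kept ids.
#' @param kept Character vector of report ids to partition (default: all
#'   rows of `sim`).
#' @param proportions Named numeric vector of dataset proportions summing
#'   to 1 (default `c(initialization = .1, training = .4,
#'   validation = .5)`).
#' @param seed Integer seed.
#' @param n_neighbors Neighbours drawn with each anchor (default 3).
#' @return Tibble with columns `report_id`, `dataset`.
#' @export
partition_corpus <- function(sim, kept = rownames(sim),
                             proportions = c(initialization = 0.10,
                                             training = 0.40,
                                             validation = 0.50),
                             seed = 1L, n_neighbors = 3L) {
  if (length(kept) == 0) abort("No reports to partition.")
  stopifnot(abs(sum(proportions) - 1) < 1e-8, !is.null(names(proportions)))
  kept <- as.character(kept)
  stopifnot(all(kept %in% rownames(sim)))
  counts <- largest_remainder(length(kept), proportions)
  assignment <- setNames(rep(NA_character_, length(kept)), kept)
  withr::with_seed(seed, {
    deck <- sample(rep(names(proportions), counts))
    pos <- 1L
    repeat {
      open <- kept[is.na(assignment)]
      if (length(open) == 0) break
      anchor <- open[sample.int(length(open), 1)]
      others <- setdiff(open, anchor)
      if (length(others) > 0) {
        ord <- others[order(-sim[anchor, others], match(others, kept))]
        group <- c(anchor, head(ord, n_neighbors))
      } else {
        group <- anchor
      }
      assignment[group] <- deck[pos:(pos + length(group) - 1L)]
      pos <- pos + length(group)
    }
  })
  tibble(report_id = kept, dataset = unname(assignment[kept]))
}

# Integer apportionment by the largest-remainder method.
largest_remainder <- function(n, proportions) {
  exact <- n * proportions
  counts <- floor(exact)
  left <- n - sum(counts)
  if (left > 0) {
    frac <- exact - counts
    bump <- order(-frac, seq_along(frac))[seq_len(left)]
    counts[bump] <- counts[bump] + 1
  }
  setNames(as.integer(counts), names(proportions))
}
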