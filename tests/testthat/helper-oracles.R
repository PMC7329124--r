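# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense vectors, explicit loops, direct formulas.

# Brute-force majority vote + ordered-list scan over a label multiset.
oracle_resolve <- function(labels, ordered) {
  best <- NULL; best_n <- -1
  for (l in unique(labels)) {
    n <- sum(labels == l)
    if (n > best_n) { best_n <- n; best <- l }
  }
  tied <- unique(labels)[vapply(unique(labels), function(l)
    sum(labels == l) == best_n, logical(1))]
  for (l in ordered) if (l %in% tied) return(l)
  best
}

# Brute-force nearest-edge gap between two character spans.
oracle_gap <- function(ms, me, ts, te) {
  if (me <= ts) ts - me else if (te <= ms) ms - te else 0L
}

# Dense brute-force TF-IDF cosine over explicitly materialised n-gram
# count vectors (smoothed idf, raw tf, L2 row norm).
oracle_tfidf_cosine <- function(texts, nmin = 1, nmax = 10) {
  tok <- lapply(texts, function(tx) {
    regmatches(tolower(tx), gregexpr("\\b\\w\\w+\\b", tolower(tx),
                                     perl = TRUE))[[1]]
  })
  grams <- lapply(tok, function(w) {
    out <- character(0)
    for (n in nmin:nmax) {
      if (length(w) < n) next
      for (k in seq_len(length(w) - n + 1)) {
        out <- c(out, paste(w[k:(k + n - 1)], collapse = " "))
      }
    }
    out
  })
  vocab <- sort(unique(unlist(grams)))
  counts <- t(vapply(grams, function(g)
    vapply(vocab, function(v) sum(g == v), numeric(1)),
    numeric(length(vocab))))
  n <- length(texts)
  df <- colSums(counts > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  x <- sweep(counts, 2, idf, `*`)
  x <- x / sqrt(rowSums(x^2))
  x %*% t(x)
}

# Direct p_o / p_e kappa over two label vectors.
oracle_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- 0
  for (l1 in lev) p_e <- p_e + mean(a == l1) * mean(b == l1)
  (p_o - p_e) / (1 - p_e)
}

# Small helper: annotation table from a named label matrix (reports x
# targets) given as a long data frame builder.
make_table <- function(report_id, target, annotation) {
  tibble::tibble(report_id = report_id, target = target,
                 annotation = annotation)
}

# A fully default annotation table for n reports (the empty-report
# surface).
default_table <- function(ids, catalog = tbicde::target_catalog()) {
  tidyr::crossing(report_id = ids, target = catalog$targets) |>
    dplyr::mutate(annotation = unname(catalog$default_label[target]))
}
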