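#' Mark a sentence with lexical targets and modifiers
#'
#' Scans one sentence with every compiled lexicon pattern and records all
#' matches as concept spans. Offsets follow the span contract used
#' throughout the package: `start` is 0-based inclusive, `end` exclusive,
#' and `matched_text` equals the sentence slice `[start, end)`. No
#' pruning or linking is performed here; see [prune_spans()],
#' [link_modifiers()] and [distance_prune()], or [markup_sentence()] for
#' the full chain.
#'
#' @param sentence Sentence text.
#' @param targets,modifiers `tbi_lexicon` tibbles (defaults: the shipped
#'   starter lexicons).
#' @param sentence_index Ordinal of the sentence within its report.
#' @return A `tbi_markup` object: list with `sentence`, `sentence_index`,
#'   `spans` (tibble: `span_id`, `concept_type`, `lex_id`, `literal`,
#'   `category`, `rule`, `start`, `end`, `matched_text`) and `links`
#'   (tibble: `target_id`, `modifier_id`, `distance`; empty until
#'   linking).
#' @export
#' @examples
#' mk <- mark_sentence("No subdural hemorrhage.")
#' mk$spans
mark_sentence <- function(sentence, targets = default_lexicon("target"),
                          modifiers = default_lexicon("modifier"),
                          sentence_index = 1L) {
  stopifnot(is.character(sentence), length(sentence) == 1)
  tg <- scan_lexicon(sentence, targets, "target")
  md <- scan_lexicon(sentence, modifiers, "modifier")
  spans <- fast_tibble(
    concept_type = c(tg$concept_type, md$concept_type),
    lex_id = c(tg$lex_id, md$lex_id),
    literal = c(tg$literal, md$literal),
    category = c(tg$category, md$category),
    rule = c(tg$rule, md$rule),
    start = c(tg$start, md$start),
    end = c(tg$end, md$end),
    matched_text = c(tg$matched_text, md$matched_text))
  ord <- order(spans$start, spans$end, spans$lex_id)
  spans <- spans[ord, ]
  spans$span_id <- seq_len(nrow(spans))
  spans <- spans[, c("span_id", "concept_type", "lex_id", "literal",
                     "category", "rule", "start", "end", "matched_text")]
  new_markup(sentence, sentence_index, spans, empty_links())
}

scan_lexicon <- function(sentence, lexicon, concept_type) {
  lex_id <- integer(0); start <- integer(0); end <- integer(0)
  for (i in seq_len(nrow(lexicon))) {
    m <- gregexpr(lexicon$regex[[i]], sentence, perl = TRUE,
                  ignore.case = TRUE)[[1]]
    if (m[1] == -1) next
    s <- as.integer(m) - 1L                # 0-based inclusive
    lex_id <- c(lex_id, rep.int(i, length(s)))
    start <- c(start, s)
    end <- c(end, s + attr(m, "match.length"))  # exclusive
  }
  list(concept_type = rep.int(concept_type, length(start)),
       lex_id = lex_id,
       literal = lexicon$literal[lex_id],
       category = lexicon$category[lex_id],
       rule = lexicon$rule[lex_id],
       start = start, end = end,
       matched_text = if (length(start) == 0) character(0) else
         substring(sentence, start + 1L, end))
}

# Minimal-validation tibble constructor for hot paths.
fast_tibble <- function(...) {
  l <- list(...)
  tibble::new_tibble(l, nrow = length(l[[1]]))
}

empty_spans <- function() {
  tibble(concept_type = character(), lex_id = integer(),
         literal = character(), category = character(),
         rule = character(), start = integer(), end = integer(),
         matched_text = character())
}

empty_links <- function() {
  tibble(target_id = integer(), modifier_id = integer(),
         distance = integer())
}

new_markup <- function(sentence, sentence_index, spans, links) {
  structure(list(sentence = sentence,
                 sentence_index = as.integer(sentence_index),
                 spans = spans, links = links),
            class = "tbi_markup")
}

#' @export
print.tbi_markup <- function(x, ...) {
  cat("<tbi_markup> sentence ", x$sentence_index, ": ",
      sum(x$spans$concept_type == "target"), " target span(s), ",
      sum(x$spans$concept_type == "modifier"), " modifier span(s), ",
      nrow(x$links), " link(s)\n", sep = "")
  invisible(x)
}

#' Span pruning: drop concepts contained in a larger concept
#'
#' A span strictly contained within another surviving span of the *same*
#' concept type is pruned (e.g. the modifier "not" disappears inside "do
#' not appear significantly changed"). Spans of identical extent and type
#' keep exactly one representative: the one earliest in lexicon order.
#'
#' @param markup A `tbi_markup`.
#' @return The markup with contained spans removed.
#' @export
prune_spans <- function(markup) {
  spans <- markup$spans
  n <- nrow(spans)
  if (n < 2) return(markup)
  type <- spans$concept_type; s <- spans$start; e <- spans$end
  lex <- spans$lex_id
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    same <- type == type[i]; same[i] <- FALSE
    contained <- same & s <= s[i] & e[i] <= e & (s < s[i] | e[i] < e)
    if (any(contained)) { keep[i] <- FALSE; next }
    twin <- same & s == s[i] & e == e[i] & lex < lex[i]
    if (any(twin)) keep[i] <- FALSE       # identical extent tie-break
  }
  markup$spans <- spans[keep, , drop = FALSE]
  markup
}

#' Link modifiers to the targets in their directional scope
#'
#' Each modifier is applied to every target within its scope: a `forward`
#' modifier reaches targets after it through the end of the sentence, a
#' `backward` modifier reaches targets before it from the sentence start,
#' and a `bidirectional` modifier reaches both. Scope never crosses the
#' sentence. Modifiers left with no linked target are dropped (modifier
#' pruning). The link distance is the character gap between the nearest
#' edges of the two spans (0 when they touch or overlap).
#'
#' @param markup A span-pruned `tbi_markup`.
#' @return The markup with `links` populated and unlinked modifiers
#'   removed.
#' @export
link_modifiers <- function(markup) {
  spans <- markup$spans
  tg <- spans[spans$concept_type == "target", , drop = FALSE]
  md <- spans[spans$concept_type == "modifier", , drop = FALSE]
  target_id <- integer(0); modifier_id <- integer(0)
  distance <- integer(0)
  if (nrow(tg) > 0 && nrow(md) > 0) {
    for (i in seq_len(nrow(md))) {
      after <- tg$start >= md$end[[i]]    # target follows the modifier
      before <- tg$end <= md$start[[i]]   # target precedes the modifier
      in_scope <- switch(md$rule[[i]],
        forward = after, backward = before, bidirectional = after | before)
      if (!any(in_scope)) next
      target_id <- c(target_id, tg$span_id[in_scope])
      modifier_id <- c(modifier_id,
                       rep.int(md$span_id[[i]], sum(in_scope)))
      distance <- c(distance, span_gap(md$start[[i]], md$end[[i]],
                                       tg$start[in_scope],
                                       tg$end[in_scope]))
    }
  }
  links <- fast_tibble(target_id = target_id, modifier_id = modifier_id,
                       distance = distance)
  linked_mods <- unique(links$modifier_id)
  drop <- spans$concept_type == "modifier" &
    !spans$span_id %in% linked_mods
  markup$spans <- spans[!drop, , drop = FALSE]
  markup$links <- links
  markup
}

# Nearest-edge character gap between two spans (0 if adjacent or
# overlapping). Vectorised over the second span.
span_gap <- function(ms, me, ts, te) {
  as.integer(pmax(0L, pmax(ts - me, ms - te)))
}

#' Distance pruning: one modifier per target
#'
#' When several modifiers link to the same target, only the nearest by
#' character distance survives. Ties prefer the modifier preceding the
#' target (clinical assertions usually lead the finding); any remaining
#' tie goes to the smaller start offset. Modifiers that lose all their
#' links are dropped.
#'
#' @param markup A linked `tbi_markup`.
#' @return The markup with at most one link per target span.
#' @export
distance_prune <- function(markup) {
  links <- markup$links
  if (nrow(links) > 1) {
    spans <- markup$spans
    pos <- function(id, col) spans[[col]][match(id, spans$span_id)]
    precedes <- pos(links$modifier_id, "end") <= pos(links$target_id,
                                                     "start")
    mstart <- pos(links$modifier_id, "start")
    ord <- order(links$target_id, links$distance, !precedes, mstart)
    links <- links[ord, ]
    links <- links[!duplicated(links$target_id), ]
  }
  markup$links <- links
  # modifier pruning again: drop modifiers that lost every link
  drop <- markup$spans$concept_type == "modifier" &
    !markup$spans$span_id %in% links$modifier_id
  markup$spans <- markup$spans[!drop, , drop = FALSE]
  markup
}

#' Full sentence markup chain
#'
#' Convenience composition of [mark_sentence()], [prune_spans()],
#' [link_modifiers()] and [distance_prune()], after which every surviving
#' target span carries at most one modifier.
#'
#' @inheritParams mark_sentence
#' @return A fully pruned `tbi_markup`.
#' @export
markup_sentence <- function(sentence, targets = default_lexicon("target"),
                            modifiers = default_lexicon("modifier"),
                            sentence_index = 1L) {
  mark_sentence(sentence, targets, modifiers, sentence_index) |>
    prune_spans() |> link_modifiers() |> distance_prune()
}

#' Sentence-level target assignments
#'
#' Extracts one `(target, label)` assignment per linked target span in a
#' fully pruned markup. Target spans without a linked modifier yield no
#' assignment (the report-level default will cover the target).
#'
#' @param markup A fully pruned `tbi_markup`.
#' @return Tibble with columns `target`, `label`, `sentence_index`,
#'   `source` (always `"matched"`).
#' @export
sentence_assignments <- function(markup) {
  if (nrow(markup$links) == 0) {
    return(tibble(target = character(), label = character(),
                  sentence_index = integer(), source = character()))
  }
  spans <- markup$spans
  n <- nrow(markup$links)
  fast_tibble(
    target = spans$category[match(markup$links$target_id, spans$span_id)],
    label = spans$category[match(markup$links$modifier_id, spans$span_id)],
    sentence_index = rep.int(markup$sentence_index, n),
    source = rep.int("matched", n))
}

#' Markup as a node/edge table for inspection
#'
#' Serialises a markup to a pair of tibbles (concept spans as nodes,
#' links as edges) suitable for writing to CSV or converting to a graph.
#'
#' @param markup A `tbi_markup`.
#' @return List with `nodes` and `edges` tibbles.
#' @export
markup_graph <- function(markup) {
  list(nodes = markup$spans,
       edges = markup$links)
}
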