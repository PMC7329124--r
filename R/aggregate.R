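#' Fill omitted targets with their default annotation
#'
#' Every catalog target a report never mentions receives one assignment
#' carrying the catalog default: NORMAL for gray-white differentiation and
#' cistern, ABSENT for the remaining 25 targets.
#'
#' @param assignments Tibble of sentence-level assignments (`target`,
#'   `label`, `sentence_index`, `source`), possibly empty.
#' @param catalog A [target_catalog()].
#' @return The assignments with defaults appended (`source = "default"`).
#' @export
fill_omitted <- function(assignments, catalog = target_catalog()) {
  missing <- setdiff(catalog$targets, unique(assignments$target))
  if (length(missing) == 0) return(assignments)
  bind_rows(assignments,
            tibble(target = missing,
                   label = unname(catalog$default_label[missing]),
                   sentence_index = NA_integer_,
                   source = "default"))
}

# Majority vote over one target's label multiset; ties broken by the
# first tied label in the ordered annotation list.
resolve_label <- function(labels, ordered) {
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) {
    list(label = top, tie = FALSE)
  } else {
    list(label = ordered[ordered %in% top][1], tie = TRUE)
  }
}

#' Resolve duplicate target mentions by majority vote
#'
#' A target mentioned in several sentences may carry conflicting
#' annotations. The majority label wins; when the maximal count is shared
#' the winner is the earliest of the tied labels in the target's ordered
#' annotation list (ABSENT-first for extraaxial fluid collection,
#' hemorrhage (NOS) and intracranial pathology; PRESENT-first otherwise).
#'
#' @param assignments Tibble of assignments covering every catalog target
#'   (see [fill_omitted()]).
#' @param catalog A [target_catalog()].
#' @return Tibble with one row per target: `target`, `label`,
#'   `provenance` (`"matched"`, `"default"` or `"tie_break"`).
#' @export
resolve_duplicates <- function(assignments, catalog = target_catalog()) {
  stopifnot(setequal(unique(assignments$target), catalog$targets))
  labs <- split(assignments$label, assignments$target)
  srcs <- split(assignments$source, assignments$target)
  t <- catalog$targets
  label <- character(length(t)); prov <- character(length(t))
  for (k in seq_along(t)) {
    res <- resolve_label(labs[[t[k]]], catalog$ordered_list[[t[k]]])
    label[k] <- res$label
    prov[k] <- if (res$tie) "tie_break"
               else if (all(srcs[[t[k]]] == "default")) "default"
               else "matched"
  }
  tibble(target = t, label = label, provenance = prov)
}

#' Replace annotations outside a target's allowed set
#'
#' Each target accepts only a subset of the annotation vocabulary
#' (gray-white differentiation and cistern are graded NORMAL/ABNORMAL,
#' the other 25 PRESENT/ABSENT). Labels outside the allowed set are
#' replaced by the predetermined counterpart (e.g. cistern ABSENT becomes
#' NORMAL). A label with no configured counterpart is a configuration
#' error.
#'
#' @param labels Tibble with one row per target (`target`, `label`, and
#'   optionally `provenance`).
#' @param catalog A [target_catalog()].
#' @return The tibble with all labels inside their allowed sets.
#' @export
replace_disallowed <- function(labels, catalog = target_catalog()) {
  for (i in seq_len(nrow(labels))) {
    t <- labels$target[[i]]; l <- labels$label[[i]]
    if (l %in% catalog$allowed_labels[[t]]) next
    repl <- unname(catalog$counterpart[[t]][l])
    if (is.na(repl)) {
      abort(paste0("No counterpart configured for (", t, ", ", l, ")"))
    }
    labels$label[[i]] <- repl
  }
  labels
}

#' Apply the derived-target decision rules
#'
#' Three targets are re-derived from the rest of the summary, in order:
#'
#' 1. if epidural, subdural or subarachnoid hemorrhage is PRESENT or
#'    SUSPECTED, hemorrhage (NOS) is set to ABSENT (the specific subtype
#'    supersedes the unspecified one);
#' 2. if any of those subtypes is PRESENT, extraaxial fluid collection is
#'    set to PRESENT; if instead one is SUSPECTED while extraaxial fluid
#'    collection still holds its ABSENT default, it is set to SUSPECTED;
#' 3. if any trigger target is PRESENT, SUSPECTED or ABNORMAL,
#'    intracranial pathology is set to PRESENT. Rule 3 sees rule 2's
#'    update, so a PRESENT subdural hemorrhage implies intracranial
#'    pathology through the extraaxial fluid collection it asserts.
#'
#' The operation is idempotent.
#'
#' @param labels Tibble with one row per target: `target`, `label`,
#'   `provenance`.
#' @param catalog A [target_catalog()].
#' @return The tibble with derived targets updated
#'   (`provenance = "derived"` where a rule fired).
#' @export
apply_derived_rules <- function(labels, catalog = target_catalog()) {
  if (!"provenance" %in% names(labels)) {
    labels$provenance <- ifelse(
      labels$label == catalog$default_label[labels$target],
      "default", "matched")
  }
  lab <- setNames(labels$label, labels$target)
  prov <- setNames(labels$provenance, labels$target)
  sub <- lab[catalog$hemorrhage_subtypes]

  set <- function(target, value) {
    lab[[target]] <<- value
    prov[[target]] <<- "derived"
  }
  # (a) a specific extraaxial hemorrhage suppresses hemorrhage (NOS)
  if (any(sub %in% c("PRESENT", "SUSPECTED"))) {
    set("hemorrhage", "ABSENT")
  }
  # (b) it also asserts (or hedges) an extraaxial fluid collection
  if (any(sub == "PRESENT")) {
    set("extraaxial fluid collection", "PRESENT")
  } else if (any(sub == "SUSPECTED") &&
             lab[["extraaxial fluid collection"]] == "ABSENT" &&
             prov[["extraaxial fluid collection"]] == "default") {
    set("extraaxial fluid collection", "SUSPECTED")
  }
  # (c) any positive trigger implies intracranial pathology
  if (any(lab[catalog$triggers] %in%
          c("PRESENT", "SUSPECTED", "ABNORMAL"))) {
    set("intracranial pathology", "PRESENT")
  }
  labels$label <- unname(lab[labels$target])
  labels$provenance <- unname(prov[labels$target])
  labels
}

#' Summarise one report into the 27-row structured summary
#'
#' Runs the full extraction pipeline on one report: section trimming (if
#' the text still carries its headers), cleaning and sentence splitting,
#' sentence markup with span/modifier/distance pruning, then the
#' report-level decision rules (omitted-target defaults, duplicate
#' majority vote, disallowed-label replacement, derived targets).
#'
#' @param text Report text. When it contains Findings/Impression headers
#'   the span between them is analysed; otherwise the whole text is.
#' @param report_id Identifier copied to the output.
#' @param targets,modifiers Lexicons (defaults: shipped starter lexicons).
#' @param catalog A [target_catalog()].
#' @param trim If `TRUE` (default), trim to the Findings span when the
#'   headers are found.
#' @return A `tbi_summary` tibble: 27 rows with columns `report_id`,
#'   `target`, `annotation`, `provenance`, in stable target order.
#' @export
#' @examples
#' summarize_report(
#'   "FINDINGS: No acute intracranial hemorrhage. IMPRESSION: Normal.")
summarize_report <- function(text, report_id = NA_character_,
                             targets = default_lexicon("target"),
                             modifiers = default_lexicon("modifier"),
                             catalog = target_catalog(),
                             trim = TRUE) {
  if (trim) {
    span <- extract_findings_span(text)
    if (!is.na(span)) text <- span
  }
  clean <- clean_report(text, report_id = report_id)
  assignments <- bind_rows(lapply(seq_along(clean$sentences), function(i) {
    markup_sentence(clean$sentences[[i]], targets, modifiers,
                    sentence_index = i) |>
      sentence_assignments()
  }))
  if (nrow(assignments) == 0) {
    assignments <- tibble(target = character(), label = character(),
                          sentence_index = integer(), source = character())
  }
  # mentions with annotations outside the seven-label vocabulary cannot
  # arise: lexicon loading already validated modifier categories
  summary <- assignments |>
    fill_omitted(catalog) |>
    resolve_duplicates(catalog) |>
    replace_disallowed(catalog) |>
    apply_derived_rules(catalog)
  out <- tibble(report_id = report_id,
                target = summary$target,
                annotation = summary$label,
                provenance = summary$provenance)
  out <- out[match(catalog$targets, out$target), ]
  structure(out, class = c("tbi_summary", class(tibble())))
}

#' Extract structured summaries for a corpus
#'
#' Maps [summarize_report()] over a corpus, returning one long tibble of
#' 27 rows per report (the structured-summary table written by the
#' command-line interface).
#'
#' @param reports Data frame with columns `report_id` and `text` (raw
#'   reports), or the `kept` tibble of [filter_corpus()] (its `full_text`
#'   column is used and trimming is skipped).
#' @inheritParams summarize_report
#' @return Tibble with columns `report_id`, `target`, `annotation`,
#'   `provenance`.
#' @export
extract_cde <- function(reports, targets = default_lexicon("target"),
                        modifiers = default_lexicon("modifier"),
                        catalog = target_catalog()) {
  is_clean <- "full_text" %in% names(reports)
  col <- if (is_clean) "full_text" else "text"
  stopifnot(all(c("report_id", col) %in% names(reports)))
  bind_rows(lapply(seq_len(nrow(reports)), function(i) {
    summarize_report(reports[[col]][[i]],
                     report_id = reports$report_id[[i]],
                     targets = targets, modifiers = modifiers,
                     catalog = catalog, trim = !is_clean)
  }))
}

#' @export
print.tbi_summary <- function(x, ...) {
  cat("<tbi_summary> structured summary, ",
      length(unique(x$report_id)), " report(s) x 27 targets\n", sep = "")
  NextMethod()
}
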