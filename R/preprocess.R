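#' Trim a report to its Findings--Impressions span
#'
#' Radiology reports carry administrative and history sections around the
#' diagnostic narrative. Only the span starting at the "Findings" header
#' and running through the "Impression(s)" section is analysed; headers
#' are matched case-insensitively with an optional colon. Reports missing
#' either header cannot be trimmed and return `NA` (such reports are
#' excluded from a corpus by [filter_corpus()]).
#'
#' The span runs from the Findings header to the end of the report text:
#' the impression is conventionally the closing section, so no attempt is
#' made to locate a terminator beyond it.
#'
#' @param text Full report text (single string).
#' @return The trimmed span, or `NA_character_` when either header is
#'   missing.
#' @export
#' @examples
#' extract_findings_span(
#'   "HISTORY: fall. FINDINGS: No acute hemorrhage. IMPRESSION: Normal.")
extract_findings_span <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  f <- regexpr("\\bfindings?\\b\\s*:?", text, perl = TRUE,
               ignore.case = TRUE)
  if (f == -1) return(NA_character_)
  rest <- substr(text, f, nchar(text))
  i <- regexpr("\\bimpressions?\\b\\s*:?", rest, perl = TRUE,
               ignore.case = TRUE)
  if (i == -1) return(NA_character_)
  rest
}

# Default retained character class: letters, digits, whitespace and a
# small set of clinically meaningful punctuation.
default_keep_class <- function() "[^A-Za-z0-9 \t.,;:?!%/()-]"

# Abbreviations (periods stripped) that never end a sentence.
default_abbreviations <- function() {
  c("dr", "mr", "mrs", "ms", "st", "vs", "cm", "mm", "ml", "cc",
    "e.g", "i.e", "approx", "fig")
}

#' Clean report text and split it into sentences
#'
#' Newlines are replaced with spaces, characters outside the retained set
#' are removed, whitespace is collapsed, and the text is split into
#' sentences on terminal punctuation. A small abbreviation guard list
#' (units such as "mm.", titles such as "Dr.") prevents spurious breaks; a
#' break additionally requires the next sentence to open with an upper
#' case letter, a digit or a parenthesis. The rule-based splitter is
#' deterministic, so repeated cleaning is a no-op.
#'
#' @param text Report text (already trimmed to the Findings span, if
#'   desired).
#' @param report_id Optional identifier carried through the pipeline.
#' @param keep_class Regex character class of characters to *remove*
#'   (everything else is retained).
#' @param abbreviations Lower-case abbreviation guard list (without the
#'   trailing period).
#' @return A `tbi_clean_report`: list with `report_id`, `sentences`
#'   (character vector) and `full_text` (sentences joined by single
#'   spaces).
#' @export
#' @examples
#' clean_report("No acute hemorrhage.\nNo midline shift.")$sentences
clean_report <- function(text, report_id = NA_character_,
                         keep_class = default_keep_class(),
                         abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  x <- gsub("[\r\n]+", " ", text)
  x <- gsub(keep_class, "", x, perl = TRUE)
  x <- str_squish(x)
  if (nchar(x) == 0) abort("Report text is empty after cleaning.")
  sentences <- split_sentences(x, abbreviations = abbreviations)
  structure(list(report_id = report_id,
                 sentences = sentences,
                 full_text = paste(sentences, collapse = " ")),
            class = "tbi_clean_report")
}

#' @export
print.tbi_clean_report <- function(x, ...) {
  cat("<tbi_clean_report> ", x$report_id, ": ", length(x$sentences),
      " sentences\n", sep = "")
  invisible(x)
}

# Deterministic rule-based sentence splitter.
split_sentences <- function(text, abbreviations = default_abbreviations()) {
  m <- gregexpr("[.?!]+(?=\\s)", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(str_trim(text))
  ends <- as.integer(m) + attr(m, "match.length") - 1L
  is_break <- vapply(seq_along(ends), function(k) {
    e <- ends[k]
    after <- sub("^\\s+", "", substr(text, e + 1L, nchar(text)))
    if (!grepl("^[A-Z0-9(]", after)) return(FALSE)
    punct <- substr(text, m[k], e)
    if (grepl("\\.", punct)) {
      before <- sub("[.?!]+$", "", substr(text, 1L, e))
      word <- tolower(sub("^.*?(\\S+)$", "\\1", before))
      if (word %in% abbreviations) return(FALSE)
    }
    TRUE
  }, logical(1))
  cut_at <- ends[is_break]
  starts <- c(1L, cut_at + 1L)
  stops <- c(cut_at, nchar(text))
  out <- str_trim(substring(text, starts, stops))
  out[nchar(out) > 0]
}

#' Detect scan types mentioned in a report
#'
#' Counts the distinct exam titles (e.g. "CT head", "CT cervical spine")
#' matched by a configurable pattern list. Reports naming more than one
#' scan type mix findings from several exams and are excluded from a
#' corpus.
#'
#' @param text Full (untrimmed) report text.
#' @param patterns Character vector of regexes whose first capture group
#'   is the scan-type name.
#' @return Character vector of distinct, lower-cased scan types.
#' @export
detect_scan_types <- function(text, patterns = default_scan_patterns()) {
  hits <- unlist(lapply(patterns, function(p) {
    m <- regmatches(text, gregexpr(p, text, perl = TRUE,
                                   ignore.case = TRUE))[[1]]
    if (length(m) == 0) return(character(0))
    sub(p, "\\1", m, perl = TRUE, ignore.case = TRUE)
  }))
  unique(str_squish(tolower(hits)))
}

#' @rdname detect_scan_types
#' @export
default_scan_patterns <- function() {
  paste0("\\bCT\\s+(?:scan\\s+)?(?:of\\s+the\\s+)?",
         "(head|brain|face|facial bones|orbits|temporal bones|",
         "cervical spine|c-spine|thoracic spine|lumbar spine|spine|",
         "chest|abdomen|pelvis)\\b")
}

#' Clean a corpus and apply exclusion rules
#'
#' Applies the two corpus exclusion rules -- a report must contain both a
#' Findings and an Impression(s) section (`missing_sections`), and must
#' describe a single scan type (`multiple_scan_types`) -- then trims and
#' cleans the surviving reports. Kept and excluded reports partition the
#' input.
#'
#' @param reports Data frame with columns `report_id` and `text`.
#' @param keep_class,abbreviations Passed to [clean_report()].
#' @param scan_patterns Passed to [detect_scan_types()].
#' @return List with `kept` (tibble: `report_id`, `full_text`, `sentences`
#'   list-column) and `excluded` (tibble: `report_id`, `reason`).
#' @export
filter_corpus <- function(reports, keep_class = default_keep_class(),
                          abbreviations = default_abbreviations(),
                          scan_patterns = default_scan_patterns()) {
  stopifnot(all(c("report_id", "text") %in% names(reports)))
  kept <- list(); excluded <- list()
  for (i in seq_len(nrow(reports))) {
    id <- reports$report_id[[i]]
    txt <- reports$text[[i]]
    span <- extract_findings_span(txt)
    if (is.na(span)) {
      excluded[[length(excluded) + 1L]] <-
        tibble(report_id = id, reason = "missing_sections")
      next
    }
    if (length(detect_scan_types(txt, scan_patterns)) > 1) {
      excluded[[length(excluded) + 1L]] <-
        tibble(report_id = id, reason = "multiple_scan_types")
      next
    }
    cr <- clean_report(span, report_id = id, keep_class = keep_class,
                       abbreviations = abbreviations)
    kept[[length(kept) + 1L]] <-
      tibble(report_id = id, full_text = cr$full_text,
             sentences = list(cr$sentences))
  }
  list(kept = if (length(kept)) bind_rows(kept) else
         tibble(report_id = character(), full_text = character(),
                sentences = list()),
       excluded = if (length(excluded)) bind_rows(excluded) else
         tibble(report_id = character(), reason = character()))
}

#' Read a corpus of reports
#'
#' Accepts either a directory of `.txt` files (one report each, file stem
#' used as the report id) or a CSV file with columns `report_id`, `text`.
#'
#' @param path Directory or CSV file path.
#' @return Tibble with columns `report_id`, `text`.
#' @export
read_reports <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0) abort(paste0("No .txt reports in ", path))
    return(tibble(
      report_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f)
        paste(readLines(f, warn = FALSE), collapse = "\n"), character(1),
        USE.NAMES = FALSE)))
  }
  if (!file.exists(path)) abort(paste0("Report source not found: ", path))
  out <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  stopifnot(all(c("report_id", "text") %in% names(out)))
  out[, c("report_id", "text")]
}
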