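#' Read a lexical-target or lexical-modifier lexicon
#'
#' Lexicons are UTF-8 tab-separated files with columns
#' `literal`, `category`, `pattern`, `rule` (no header row by default;
#' trailing columns may be empty or missing). Each row is one itemData
#' record: the `literal` is the canonical phrase, the `category` is either
#' an annotation label (modifier lexicons) or a target name (target
#' lexicons), the optional `pattern` is a regular expression matching
#' variant phrasings, and the `rule` gives the directional scope of a
#' modifier (`forward`, `backward` or `bidirectional`). Targets carry no
#' rule.
#'
#' When `pattern` is empty it is generated from the literal: regex
#' metacharacters are escaped and runs of whitespace become `\\s+`. All
#' patterns are matched case-insensitively and, unless a pattern already
#' anchors itself (starts with `\\b` or `^`), wrapped in word boundaries.
#'
#' @param path Path to the TSV file.
#' @param kind `"target"` or `"modifier"`.
#' @param header Whether the file has a header row naming the columns.
#' @return A `tbi_lexicon` tibble with columns `literal`, `category`,
#'   `pattern`, `rule`, and the compiled `regex` actually used for
#'   matching.
#' @seealso [default_lexicon()] for the lexicons shipped with the package,
#'   [write_lexicon()] for the inverse operation.
#' @export
read_lexicon <- function(path, kind = c("target", "modifier"),
                         header = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(paste0("Lexicon file not found: ", path))
  }
  raw <- readr::read_tsv(path,
    col_names = if (header) TRUE else c("literal", "category", "pattern",
                                        "rule"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (header) {
    missing_cols <- setdiff(c("literal", "category"), names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("Lexicon is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
  }
  for (col in c("pattern", "rule")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  raw <- raw[, c("literal", "category", "pattern", "rule")]
  as_tbi_lexicon(raw, kind = kind)
}

#' Build a lexicon from a data frame
#'
#' @param x Data frame with columns `literal`, `category`, and optionally
#'   `pattern` and `rule`.
#' @param kind `"target"` or `"modifier"`.
#' @return A validated, compiled `tbi_lexicon` tibble.
#' @export
as_tbi_lexicon <- function(x, kind = c("target", "modifier")) {
  kind <- match.arg(kind)
  x <- as_tibble(x)
  for (col in c("pattern", "rule")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  x$literal <- str_squish(x$literal)
  if (any(is.na(x$literal) | x$literal == "")) {
    abort("Every lexicon row needs a non-empty literal.")
  }
  if (kind == "modifier") {
    x$category <- vapply(seq_len(nrow(x)), function(i) {
      tryCatch(as_tbi_label(x$category[[i]], legacy = TRUE),
        error = function(e) {
          abort(paste0("Row ", i, ": unknown modifier category '",
                       x$category[[i]], "'"))
        })
    }, character(1))
    x$rule <- tolower(str_squish(x$rule))
    bad <- which(is.na(x$rule) | !x$rule %in% direction_rules())
    if (length(bad) > 0) {
      abort(paste0("Row ", bad[1], ": modifier rule must be one of ",
                   paste(direction_rules(), collapse = "/"),
                   ", got '", x$rule[bad[1]], "'"))
    }
  } else {
    x$category <- normalize_target(x$category)
    # targets carry no directionality rule
    x$rule <- NA_character_
  }
  x$pattern <- ifelse(is.na(x$pattern) | str_trim(x$pattern) == "",
                      literal_to_pattern(x$literal), x$pattern)
  x$regex <- vapply(seq_len(nrow(x)), function(i) {
    rx <- anchor_pattern(x$pattern[[i]])
    ok <- tryCatch({
      suppressWarnings(grepl(rx, "", perl = TRUE, ignore.case = TRUE))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      abort(paste0("Malformed regular expression for literal '",
                   x$literal[[i]], "': ", x$pattern[[i]]))
    }
    rx
  }, character(1))
  structure(x, class = c("tbi_lexicon", class(tibble())),
            kind = kind)
}

#' @export
print.tbi_lexicon <- function(x, ...) {
  cat("<tbi_lexicon> ", attr(x, "kind"), " lexicon, ", nrow(x),
      " entries\n", sep = "")
  NextMethod()
}

#' Write a lexicon back to a tab-separated file
#'
#' Writes the `literal`, `category`, `pattern`, `rule` columns (not the
#' compiled regex), so a written lexicon reloads to an equal one.
#'
#' @param lexicon A `tbi_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  readr::write_tsv(as_tibble(lexicon)[, c("literal", "category", "pattern",
                                          "rule")],
                   path, col_names = FALSE, na = "", progress = FALSE)
  invisible(path)
}

#' Starter lexicons shipped with the package
#'
#' Small target and modifier lexicons authored for this package. The target
#' lexicon covers the 27 TBI common data elements; the modifier lexicon
#' covers common negations ("no evidence of"), hedges ("possible",
#' "suspected"), multi-etiology phrasings ("was not excluded"),
#' affirmations ("there is", "is seen") and normal/abnormal assertions
#' ("are normal", "effacement of"). They are a synthetic starting point,
#' intended to be replaced or extended for any particular institution's
#' reporting style.
#'
#' @param kind `"target"` or `"modifier"`.
#' @return A `tbi_lexicon` tibble.
#' @export
#' @examples
#' default_lexicon("modifier")
default_lexicon <- function(kind = c("target", "modifier")) {
  kind <- match.arg(kind)
  fname <- if (kind == "target") "tbi_targets.tsv" else "tbi_modifiers.tsv"
  read_lexicon(system.file("extdata", fname, package = "tbicde",
                           mustWork = TRUE),
               kind = kind)
}

# Generate a regex from a literal: escape metacharacters, let any run of
# whitespace match flexible whitespace.
literal_to_pattern <- function(literal) {
  escaped <- gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", literal,
                  perl = TRUE)
  gsub("\\s+", "\\\\s+", escaped)
}

# Word-boundary anchoring unless the pattern takes over its own anchoring.
anchor_pattern <- function(pattern) {
  if (grepl("^(\\\\b|\\^)", pattern)) return(pattern)
  paste0("\\b(?:", pattern, ")\\b")
}
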