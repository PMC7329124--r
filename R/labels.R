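#' Annotation labels and directionality rules
#'
#' The seven annotation labels used to describe the status of a lexical
#' target on a head CT report. `NOT SPECIFIED` is a legacy label: it is
#' accepted when reading historical annotator tables but is never produced
#' by the extractor (it was retired as an annotation option because of its
#' overlap with ABSENT and INDETERMINATE).
#'
#' @param legacy If `TRUE`, include the legacy `"NOT SPECIFIED"` label.
#' @return Character vector of label names.
#' @export
#' @examples
#' tbi_labels()
tbi_labels <- function(legacy = FALSE) {
  out <- c("PRESENT", "SUSPECTED", "INDETERMINATE", "ABSENT", "NORMAL",
           "ABNORMAL")
  if (legacy) out <- append(out, "NOT SPECIFIED", after = 3L)
  out
}

#' @rdname tbi_labels
#' @export
direction_rules <- function() c("forward", "backward", "bidirectional")

#' Normalise and validate annotation labels
#'
#' Upper-cases, trims, and maps underscores to spaces so that
#' `"not_specified"`, `"Not Specified"` and `"NOT SPECIFIED"` are all read
#' as the same legacy label.
#'
#' @param x Character vector of labels.
#' @param legacy Whether the legacy `"NOT SPECIFIED"` label is acceptable.
#' @return Character vector of canonical labels.
#' @export
as_tbi_label <- function(x, legacy = TRUE) {
  out <- toupper(str_squish(gsub("_", " ", as.character(x))))
  bad <- setdiff(unique(out), tbi_labels(legacy = legacy))
  if (length(bad) > 0) {
    abort(paste0("Unknown annotation label(s): ",
                 paste(bad, collapse = ", ")))
  }
  out
}

# Internal: canonical target-name normalisation (lower case, squished).
normalize_target <- function(x) {
  str_squish(tolower(gsub("_", " ", as.character(x))))
}
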