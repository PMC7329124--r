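#' Tidy an agreement summary
#'
#' @param x A `tbi_agreement`.
#' @param ... Unused.
#' @return One row per agreement class with counts and proportions.
#' @export
tidy.tbi_agreement <- function(x, ...) {
  tibble(class = c("equivalent", "similar", "divergent", "other"),
         n = c(x$n_equivalent, x$n_similar, x$n_divergent, x$n_other),
         proportion = .data$n / x$n_total)
}

#' @rdname tidy.tbi_agreement
#' @export
glance.tbi_agreement <- function(x, ...) {
  tibble(n_cells = x$n_total, n_equivalent = x$n_equivalent,
         n_similar = x$n_similar, n_divergent = x$n_divergent,
         kappa = x$kappa)
}

#' Tidy confusion counts
#'
#' @param x A `tbi_confusion`.
#' @param ... Unused.
#' @return Long tibble of the four counts.
#' @export
tidy.tbi_confusion <- function(x, ...) {
  tibble(case = x$case,
         outcome = c("tp", "tn", "fp", "fn"),
         n = c(x$tp, x$tn, x$fp, x$fn))
}

#' @rdname tidy.tbi_confusion
#' @export
glance.tbi_confusion <- function(x, ...) {
  bind_cols(tibble(case = x$case, tp = x$tp, tn = x$tn, fp = x$fp,
                   fn = x$fn, n_excluded = x$n_excluded),
            as_tibble(classification_metrics(x)))
}

#' Tidy a sentence markup into a node table
#'
#' @param x A `tbi_markup`.
#' @param ... Unused.
#' @return The concept-span tibble, with a `linked_to` column naming the
#'   modifier chosen for each target span (NA when none).
#' @export
tidy.tbi_markup <- function(x, ...) {
  spans <- x$spans
  spans$linked_to <- NA_character_
  if (nrow(x$links) > 0) {
    idx <- match(x$links$target_id, spans$span_id)
    spans$linked_to[idx] <-
      spans$literal[match(x$links$modifier_id, spans$span_id)]
  }
  spans
}
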