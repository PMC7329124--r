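# Annotation tables are long tibbles with columns report_id, target,
# annotation (one row per cell). Validation joins two tables on identical
# (report_id, target) keys.
join_tables <- function(a, b, suffix = c("_a", "_b")) {
  need <- c("report_id", "target", "annotation")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  a <- a[, need]; b <- b[, need]
  ka <- paste(a$report_id, a$target, sep = "\r")
  kb <- paste(b$report_id, b$target, sep = "\r")
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    abort("Annotation tables must have one label per (report, target).")
  }
  miss_a <- setdiff(kb, ka); miss_b <- setdiff(ka, kb)
  if (length(miss_a) || length(miss_b)) {
    ex <- gsub("\r", " / ", head(c(miss_a, miss_b), 5))
    abort(paste0("Annotation tables do not share identical keys, e.g.: ",
                 paste(ex, collapse = "; ")))
  }
  out <- inner_join(a, b, by = c("report_id", "target"),
                    suffix = suffix)
  out[[paste0("annotation", suffix[1])]] <-
    as_tbi_label(out[[paste0("annotation", suffix[1])]])
  out[[paste0("annotation", suffix[2])]] <-
    as_tbi_label(out[[paste0("annotation", suffix[2])]])
  out
}

# Cell-wise agreement class per the published definitions.
agreement_class <- function(x, y) {
  neg <- c("ABSENT", "NORMAL"); pos <- c("PRESENT", "ABNORMAL")
  dplyr::case_when(
    x == y ~ "equivalent",
    (x == "PRESENT" & y == "SUSPECTED") |
      (x == "SUSPECTED" & y == "PRESENT") ~ "similar",
    (x %in% neg & y %in% pos) | (x %in% pos & y %in% neg) ~ "divergent",
    TRUE ~ "other")
}

#' Compare two annotation tables
#'
#' Classifies every (report, target) cell as *equivalent* (same label),
#' *similar* (one PRESENT, the other SUSPECTED), *divergent* (one ABSENT
#' or NORMAL, the other PRESENT or ABNORMAL) or *other*, and computes
#' Cohen's kappa over the full label confusion matrix.
#'
#' @param a,b Annotation tables: tibbles with columns `report_id`,
#'   `target`, `annotation` over identical keys.
#' @return A `tbi_agreement` object with counts, proportions, the cell
#'   classification and `kappa`.
#' @export
compare_annotations <- function(a, b) {
  j <- join_tables(a, b)
  j$class <- agreement_class(j$annotation_a, j$annotation_b)
  n <- nrow(j)
  counts <- table(factor(j$class, levels = c("equivalent", "similar",
                                             "divergent", "other")))
  structure(list(
    n_total = n,
    n_equivalent = unname(counts[["equivalent"]]),
    n_similar = unname(counts[["similar"]]),
    n_divergent = unname(counts[["divergent"]]),
    n_other = unname(counts[["other"]]),
    kappa = cohens_kappa(a, b),
    cells = j), class = "tbi_agreement")
}

#' @export
print.tbi_agreement <- function(x, ...) {
  cat("<tbi_agreement> ", x$n_total, " cells: ",
      x$n_equivalent, " equivalent (",
      sprintf("%.1f%%", 100 * x$n_equivalent / x$n_total), "), ",
      x$n_similar, " similar, ", x$n_divergent, " divergent, ",
      x$n_other, " other; kappa = ", sprintf("%.3f", x$kappa), "\n",
      sep = "")
  invisible(x)
}

#' Cohen's kappa between two annotation tables
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` computed over the
#' full multi-label confusion matrix of all shared cells. Identical
#' tables give kappa = 1, including the degenerate case where both raters
#' use a single label throughout (`p_e = 1`).
#'
#' @inheritParams compare_annotations
#' @return A single numeric value in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  j <- join_tables(a, b)
  if (nrow(j) == 0) abort("Cannot compute kappa on empty tables.")
  lev <- sort(union(j$annotation_a, j$annotation_b))
  tab <- table(factor(j$annotation_a, lev), factor(j$annotation_b, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(if (p_o == 1) 1 else NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Gold-standard cells from two annotators
#'
#' The gold standard is the subset of cells where the two annotators were
#' equivalent (gave the same label); other cells are not scored.
#'
#' @inheritParams compare_annotations
#' @return Annotation table restricted to the equivalent cells.
#' @export
gold_standard <- function(a, b) {
  j <- join_tables(a, b)
  eq <- j[j$annotation_a == j$annotation_b, ]
  tibble(report_id = eq$report_id, target = eq$target,
         annotation = eq$annotation_a)
}

# Positive label sets for the two scoring cases.
positive_set <- function(case) {
  switch(case,
         case1 = c("PRESENT", "ABNORMAL"),
         case2 = c("PRESENT", "SUSPECTED", "ABNORMAL"))
}
negative_set <- function() c("ABSENT", "NORMAL")

#' Confusion counts against a gold standard
#'
#' Scores predictions against gold labels under one of two positivity
#' cases: case 1 counts PRESENT and ABNORMAL as positive, case 2 adds
#' SUSPECTED to the positive group; ABSENT and NORMAL are negative in
#' both. TP/TN require prediction and gold on the same side; every other
#' scored cell is FP (positive prediction) or FN. Cells whose prediction
#' or gold label falls outside the positive and negative sets (e.g.
#' INDETERMINATE, or SUSPECTED under case 1) are excluded by default and
#' reported in `n_excluded`; with `unscored = "error"` such cells are
#' counted as FP/FN by the side of the prediction (a prediction outside
#' both sets counts FN).
#'
#' @param pred Predicted annotation table.
#' @param gold Gold-standard annotation table (see [gold_standard()]);
#'   `pred` is scored on the gold keys, which may be a subset of the
#'   prediction keys.
#' @param case `"case1"` or `"case2"`.
#' @param unscored `"exclude"` (default) or `"error"`.
#' @return A `tbi_confusion` object with fields `tp`, `tn`, `fp`, `fn`,
#'   `case`, `n_excluded`, `n_scored`.
#' @export
confusion_counts <- function(pred, gold, case = c("case1", "case2"),
                             unscored = c("exclude", "error")) {
  case <- match.arg(case); unscored <- match.arg(unscored)
  pred <- semi_join(pred, gold, by = c("report_id", "target"))
  j <- join_tables(pred, gold, suffix = c("_pred", "_gold"))
  pos <- positive_set(case); neg <- negative_set()
  p <- j$annotation_pred; g <- j$annotation_gold
  side <- function(x) ifelse(x %in% pos, "pos",
                             ifelse(x %in% neg, "neg", "out"))
  sp <- side(p); sg <- side(g)
  scored <- sp != "out" & sg != "out"
  n_excluded <- sum(!scored)
  if (unscored == "error") {
    scored <- rep(TRUE, length(sp))
    n_excluded <- 0L
  }
  sp <- sp[scored]; sg <- sg[scored]
  structure(list(
    tp = sum(sp == "pos" & sg == "pos"),
    tn = sum(sp == "neg" & sg == "neg"),
    fp = sum(sp == "pos" & sg != "pos"),
    fn = sum(sp != "pos" & !(sp == "neg" & sg == "neg")),
    case = case, n_excluded = n_excluded, n_scored = sum(scored)),
    class = "tbi_confusion")
}

#' @export
print.tbi_confusion <- function(x, ...) {
  cat("<tbi_confusion> [", x$case, "] TP=", x$tp, " TN=", x$tn,
      " FP=", x$fp, " FN=", x$fn,
      if (x$n_excluded > 0) paste0(" (", x$n_excluded, " excluded)"),
      "\n", sep = "")
  invisible(x)
}

#' The six classification performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive value, accuracy, and the F1 score
#' `2*PPV*Sens/(PPV+Sens)`. A metric whose denominator is zero is
#' undefined and reported as `NA` (never as 0).
#'
#' @param counts A `tbi_confusion`, or a list/vector with elements `tp`,
#'   `tn`, `fp`, `fn`.
#' @return A `tbi_metrics` tibble with one row and columns `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, `f1`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  total <- tp + tn + fp + fn
  if (total == 0) abort("All confusion counts are zero.")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  ppv <- ratio(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  out <- tibble(sensitivity = sens,
                specificity = ratio(tn, tn + fp),
                ppv = ppv,
                npv = ratio(tn, tn + fn),
                accuracy = (tp + tn) / total,
                f1 = f1)
  structure(out, class = c("tbi_metrics", class(tibble())))
}

#' Per-target error tabulation
#'
#' For each of the 27 targets: the number of gold-positive occurrences,
#' false negatives, false positives, and the target's F1 score (NA when
#' undefined, e.g. a target never positive and never predicted positive).
#' Rows follow the stable catalog order.
#'
#' @inheritParams confusion_counts
#' @param catalog A [target_catalog()] fixing the target roster/order.
#' @return Tibble with columns `target`, `occurrences`, `fn`, `fp`, `f1`,
#'   of class `tbi_target_errors`.
#' @export
per_target_errors <- function(pred, gold, case = c("case1", "case2"),
                              unscored = c("exclude", "error"),
                              catalog = target_catalog()) {
  case <- match.arg(case); unscored <- match.arg(unscored)
  pos <- positive_set(case)
  rows <- lapply(catalog$targets, function(t) {
    g <- gold[gold$target == t, ]
    if (nrow(g) == 0) {
      return(tibble(target = t, occurrences = 0L, fn = 0L, fp = 0L,
                    f1 = NA_real_))
    }
    cc <- confusion_counts(pred[pred$target == t, ], g, case = case,
                           unscored = unscored)
    f1 <- if (cc$tp + cc$fp + cc$fn > 0) {
      classification_metrics(cc)$f1
    } else NA_real_
    tibble(target = t,
           occurrences = sum(as_tbi_label(g$annotation) %in% pos),
           fn = cc$fn, fp = cc$fp, f1 = f1)
  })
  structure(bind_rows(rows),
            class = c("tbi_target_errors", class(tibble())),
    case = case)
}
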