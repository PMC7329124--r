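#' The 27 TBI common data element targets
#'
#' Canonical names of the 27 lexical targets, in the stable order used for
#' all structured-summary output and per-target error tables.
#'
#' @return Character vector of length 27.
#' @export
#' @examples
#' cde_targets()
cde_targets <- function() {
  c("intraparenchymal hemorrhage", "facial fracture",
    "extraaxial fluid collection", "hypodensities", "skull fracture",
    "intraventricular hemorrhage", "herniation", "mass effect",
    "subarachnoid hemorrhage", "subdural hemorrhage", "hyperdensities",
    "atrophy", "contusion", "hemorrhage", "swelling", "pneumocephalus",
    "ischemia", "epidural hemorrhage", "anoxic", "aneurysm",
    "hydrocephalus", "intracranial pathology", "gray-white differentiation",
    "cistern", "midline shift", "diffuse axonal injury", "microhemorrhage")
}

# Targets whose status is graded normal/abnormal rather than
# present/absent.
graded_targets <- function() c("gray-white differentiation", "cistern")

# Targets resolved with the ABSENT-first ordered annotation list.
absent_first_targets <- function() {
  c("extraaxial fluid collection", "hemorrhage", "intracranial pathology")
}

# The specific extraaxial hemorrhage subtypes driving the derived rules.
hemorrhage_subtypes <- function() {
  c("epidural hemorrhage", "subdural hemorrhage", "subarachnoid hemorrhage")
}

# Default trigger set for the intracranial-pathology derived rule: the
# published list (with its duplicated intraventricular-hemorrhage entry
# read once) plus intraparenchymal hemorrhage, which the duplication
# appears to stand in for.
default_triggers <- function() {
  c("gray-white differentiation", "cistern", "hydrocephalus",
    "pneumocephalus", "extraaxial fluid collection", "midline shift",
    "mass effect", "diffuse axonal injury", "anoxic", "herniation",
    "aneurysm", "contusion", "swelling", "ischemia", "hemorrhage",
    "intraventricular hemorrhage", "intraparenchymal hemorrhage")
}

#' Build the target catalog
#'
#' The catalog holds the report-level decision constants for the 27
#' targets: the default annotation used when a target is never mentioned
#' (NORMAL for gray-white differentiation and cistern, ABSENT for the
#' other 25), the ordered annotation list used to break majority-vote ties
#' (ABSENT-first for extraaxial fluid collection, hemorrhage (NOS) and
#' intracranial pathology; PRESENT-first for all others), the set of
#' annotations allowed for each target together with the counterpart used
#' to replace a disallowed one (e.g. cistern ABSENT is replaced with
#' NORMAL), and the trigger set of the intracranial-pathology derived
#' rule.
#'
#' @param config Optional overrides: a named list (or path to a YAML file)
#'   with any of `triggers` (character vector), `allowed_labels` (named
#'   list target -> label set), `counterpart` (named list target -> named
#'   map label -> replacement), `ordered_list` (named list target ->
#'   ordered labels), `default_label` (named map target -> label).
#' @return A `tbi_catalog` object.
#' @export
#' @examples
#' cat27 <- target_catalog()
#' cat27$default_label[["cistern"]]
#' cat27$counterpart[["cistern"]][["ABSENT"]]
target_catalog <- function(config = NULL) {
  targets <- cde_targets()
  graded <- graded_targets()

  default_label <- setNames(
    ifelse(targets %in% graded, "NORMAL", "ABSENT"), targets)

  present_first <- c("PRESENT", "SUSPECTED", "INDETERMINATE", "ABSENT",
                     "ABNORMAL", "NORMAL")
  absent_first <- c("ABSENT", "INDETERMINATE", "SUSPECTED", "PRESENT",
                    "NORMAL", "ABNORMAL")
  ordered_list <- setNames(lapply(targets, function(t) {
    if (t %in% absent_first_targets()) absent_first else present_first
  }), targets)

  allowed_labels <- setNames(lapply(targets, function(t) {
    if (t %in% graded) {
      c("NORMAL", "ABNORMAL", "SUSPECTED", "INDETERMINATE")
    } else {
      c("PRESENT", "SUSPECTED", "INDETERMINATE", "ABSENT")
    }
  }), targets)

  counterpart <- setNames(lapply(targets, function(t) {
    if (t %in% graded) {
      c(ABSENT = "NORMAL", PRESENT = "ABNORMAL",
        "NOT SPECIFIED" = "NORMAL")
    } else {
      c(NORMAL = "ABSENT", ABNORMAL = "PRESENT",
        "NOT SPECIFIED" = "ABSENT")
    }
  }), targets)

  cat <- structure(
    list(targets = targets,
         default_label = default_label,
         allowed_labels = allowed_labels,
         ordered_list = ordered_list,
         counterpart = counterpart,
         triggers = default_triggers(),
         hemorrhage_subtypes = hemorrhage_subtypes()),
    class = "tbi_catalog")

  if (!is.null(config)) cat <- apply_catalog_config(cat, config)
  validate_catalog(cat)
  cat
}

#' Build a catalog from a target lexicon
#'
#' Validates that the lexicon covers exactly the 27 catalog targets and
#' returns the catalog parameterising the report-level decision rules.
#'
#' @param target_lexicon A `tbi_lexicon` of kind `"target"`.
#' @inheritParams target_catalog
#' @return A `tbi_catalog`.
#' @export
build_catalog <- function(target_lexicon, config = NULL) {
  found <- unique(target_lexicon$category)
  missing <- setdiff(cde_targets(), found)
  extra <- setdiff(found, cde_targets())
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "Target lexicon must cover exactly the 27 catalog targets.",
      if (length(missing) > 0)
        paste0(" Missing: ", paste(missing, collapse = ", "), "."),
      if (length(extra) > 0)
        paste0(" Unknown: ", paste(extra, collapse = ", "), ".")))
  }
  target_catalog(config = config)
}

apply_catalog_config <- function(cat, config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("triggers", "allowed_labels", "counterpart", "ordered_list",
             "default_label")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown catalog config key(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(config$triggers)) {
    cat$triggers <- normalize_target(unlist(config$triggers))
  }
  for (key in c("allowed_labels", "ordered_list")) {
    for (t in names(config[[key]])) {
      cat[[key]][[normalize_target(t)]] <-
        as_tbi_label(unlist(config[[key]][[t]]))
    }
  }
  for (t in names(config$counterpart)) {
    ov <- unlist(config$counterpart[[t]])
    names(ov) <- as_tbi_label(names(ov))
    tt <- normalize_target(t)
    cat$counterpart[[tt]][names(ov)] <- as_tbi_label(ov)
  }
  for (t in names(config$default_label)) {
    cat$default_label[[normalize_target(t)]] <-
      as_tbi_label(config$default_label[[t]], legacy = FALSE)
  }
  cat
}

validate_catalog <- function(cat) {
  stopifnot(length(cat$targets) == 27,
            identical(sort(names(cat$default_label)), sort(cat$targets)))
  bad <- setdiff(cat$triggers, cat$targets)
  if (length(bad) > 0) {
    abort(paste0("Trigger set names unknown target(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(cat)
}

#' @export
print.tbi_catalog <- function(x, ...) {
  cat("<tbi_catalog> 27 TBI common data elements\n")
  cat("  NORMAL-by-default:", paste(names(which(x$default_label ==
      "NORMAL")), collapse = ", "), "\n")
  cat("  ABSENT-first tie-break:",
      paste(names(which(vapply(x$ordered_list, function(o) o[1] == "ABSENT",
                               logical(1)))), collapse = ", "), "\n")
  cat("  intracranial-pathology triggers:", length(x$triggers),
      "targets\n")
  invisible(x)
}
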