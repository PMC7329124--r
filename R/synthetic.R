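#' Configuration for the synthetic report generator
#'
#' Defines the study conditions emulated by the generator: short head-CT
#' narratives of 9--15 sentences with Findings/Impression section
#' headers, seeded mentions of the 27 lexical targets rendered through a
#' template bank of assertion phrases (negations for ABSENT, hedges for
#' SUSPECTED, multi-etiology phrasing for INDETERMINATE), optional
#' "smart-phrase" boilerplate, and optional contradictory duplicate
#' mentions. In adversarial mode the generator additionally injects the
#' two failure modes seen with real reports: a *stale* smart-phrase
#' contradicted later in the body, and bare mentions that carry no
#' lexical modifier (or fall outside the starter lexicon's coverage).
#'
#' @param n_reports Number of reports.
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the configuration.
#' @param sentence_count_range Min/max sentences per report.
#' @param target_prevalence Named probability per target of being
#'   mentioned in a report (defaults loosely follow the relative
#'   frequencies of findings on trauma head CT: hemorrhage subtypes
#'   common, axonal/anoxic injury rare).
#' @param label_mix Two named probability vectors: `standard` over
#'   PRESENT/SUSPECTED/INDETERMINATE/ABSENT for the 25 present/absent
#'   targets, `graded` over NORMAL/ABNORMAL/SUSPECTED for gray-white
#'   differentiation and cistern.
#' @param smartphrase_rate Probability of opening the findings with the
#'   blanket-negation smart-phrase (only when consistent with the seeded
#'   labels).
#' @param conflict_rate Probability, per seeded target, of injecting a
#'   second, contradictory mention; ground truth then follows the
#'   majority/ordered-list resolution.
#' @param adversarial Enable the adversarial constructs.
#' @param stale_smartphrase_rate,bare_mention_rate Rates of the two
#'   adversarial constructs (used only when `adversarial = TRUE`).
#' @return A `tbi_synth_config` list.
#' @export
synth_config <- function(n_reports = 100L, seed = 1L,
                         sentence_count_range = c(9L, 15L),
                         target_prevalence = default_prevalence(),
                         label_mix = default_label_mix(),
                         smartphrase_rate = 0.3,
                         conflict_rate = 0.1,
                         adversarial = FALSE,
                         stale_smartphrase_rate = 0.25,
                         bare_mention_rate = 0.25) {
  stopifnot(n_reports >= 0,
            length(sentence_count_range) == 2,
            sentence_count_range[1] <= sentence_count_range[2])
  bad <- setdiff(names(target_prevalence), cde_targets())
  if (length(bad) > 0) {
    abort(paste0("Prevalence keyed by unknown target(s): ",
                 paste(bad, collapse = ", ")))
  }
  probs <- c(target_prevalence, smartphrase_rate, conflict_rate,
             unlist(label_mix), stale_smartphrase_rate, bare_mention_rate)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    sentence_count_range = as.integer(sentence_count_range),
    target_prevalence = target_prevalence, label_mix = label_mix,
    smartphrase_rate = smartphrase_rate, conflict_rate = conflict_rate,
    adversarial = isTRUE(adversarial),
    stale_smartphrase_rate = if (isTRUE(adversarial))
      stale_smartphrase_rate else 0,
    bare_mention_rate = if (isTRUE(adversarial)) bare_mention_rate else 0),
    class = "tbi_synth_config")
}

#' @rdname synth_config
#' @export
default_prevalence <- function() {
  c("intraparenchymal hemorrhage" = 0.15, "facial fracture" = 0.15,
    "extraaxial fluid collection" = 0.10, "hypodensities" = 0.20,
    "skull fracture" = 0.15, "intraventricular hemorrhage" = 0.10,
    "herniation" = 0.08, "mass effect" = 0.20,
    "subarachnoid hemorrhage" = 0.30, "subdural hemorrhage" = 0.25,
    "hyperdensities" = 0.15, "atrophy" = 0.15, "contusion" = 0.10,
    "hemorrhage" = 0.10, "swelling" = 0.10, "pneumocephalus" = 0.10,
    "ischemia" = 0.05, "epidural hemorrhage" = 0.08, "anoxic" = 0.03,
    "aneurysm" = 0.03, "hydrocephalus" = 0.05,
    "intracranial pathology" = 0.10, "gray-white differentiation" = 0.15,
    "cistern" = 0.20, "midline shift" = 0.20,
    "diffuse axonal injury" = 0.03, "microhemorrhage" = 0.03)
}

#' @rdname synth_config
#' @export
default_label_mix <- function() {
  list(standard = c(PRESENT = 0.30, SUSPECTED = 0.15,
                    INDETERMINATE = 0.10, ABSENT = 0.45),
       graded = c(NORMAL = 0.55, ABNORMAL = 0.30, SUSPECTED = 0.15))
}

# Noun phrases rendering each target inside the template bank.
# plural switches verb agreement.
synth_phrase_bank <- function() {
  tribble(
    ~target, ~np, ~np_indef, ~plural,
    "intraparenchymal hemorrhage", "intraparenchymal hemorrhage",
      "an intraparenchymal hemorrhage", FALSE,
    "facial fracture", "facial fracture", "a facial fracture", FALSE,
    "extraaxial fluid collection", "extraaxial fluid collection",
      "an extraaxial fluid collection", FALSE,
    "hypodensities", "hypodensity", "a hypodensity", FALSE,
    "skull fracture", "skull fracture", "a skull fracture", FALSE,
    "intraventricular hemorrhage", "intraventricular hemorrhage",
      "intraventricular hemorrhage", FALSE,
    "herniation", "herniation", "uncal herniation", FALSE,
    "mass effect", "mass effect", "mass effect", FALSE,
    "subarachnoid hemorrhage", "subarachnoid hemorrhage",
      "a small subarachnoid hemorrhage", FALSE,
    "subdural hemorrhage", "subdural hematoma", "a subdural hematoma",
      FALSE,
    "hyperdensities", "hyperdensity", "a hyperdensity", FALSE,
    "atrophy", "atrophy", "generalized atrophy", FALSE,
    "contusion", "contusion", "a contusion", FALSE,
    "hemorrhage", "intracranial hemorrhage",
      "an intracranial hemorrhage", FALSE,
    "swelling", "brain swelling", "brain swelling", FALSE,
    "pneumocephalus", "pneumocephalus", "pneumocephalus", FALSE,
    "ischemia", "ischemia", "ischemia", FALSE,
    "epidural hemorrhage", "epidural hematoma", "an epidural hematoma",
      FALSE,
    "anoxic", "anoxic brain injury", "anoxic brain injury", FALSE,
    "aneurysm", "aneurysm", "an aneurysm", FALSE,
    "hydrocephalus", "hydrocephalus", "hydrocephalus", FALSE,
    "intracranial pathology", "acute intracranial abnormality",
      "an acute intracranial abnormality", FALSE,
    "midline shift", "midline shift", "midline shift", FALSE,
    "diffuse axonal injury", "diffuse axonal injury",
      "diffuse axonal injury", FALSE,
    "microhemorrhage", "microhemorrhages", "scattered microhemorrhages",
      TRUE)
}

# Graded-target templates (gray-white differentiation, cistern).
graded_templates <- function() {
  list(
    "gray-white differentiation" = list(
      NORMAL = c("Gray-white differentiation is preserved.",
                 "Normal gray-white differentiation."),
      ABNORMAL = c("There is loss of gray-white differentiation.",
                   "Blurring of gray-white differentiation."),
      SUSPECTED = "Gray-white differentiation is suspected to be abnormal.",
      INDETERMINATE = "Gray-white differentiation was not excluded."),
    "cistern" = list(
      NORMAL = c("The basal cisterns are normal.",
                 "Normal basal cisterns."),
      ABNORMAL = c("There is effacement of the basal cisterns.",
                   "The basal cisterns are effaced."),
      SUSPECTED = "The basal cisterns are suspected to be effaced.",
      INDETERMINATE = "The basal cisterns were not excluded."))
}

#' Render one seeded mention as a sentence
#'
#' Looks up the template bank for the `(target, label)` pair and returns
#' one assertion sentence; used by the generator and by template-coverage
#' tests. Missing pairs are a configuration error.
#'
#' @param target Target name.
#' @param label Annotation label the sentence should assert.
#' @param variant Which template variant to use (wraps around).
#' @return A single sentence.
#' @export
render_mention <- function(target, label, variant = 1L) {
  label <- as_tbi_label(label, legacy = FALSE)
  if (target %in% graded_targets()) {
    bank <- graded_templates()[[target]][[label]]
    if (is.null(bank)) {
      abort(paste0("Template bank has no rendering for (", target, ", ",
                   label, ")"))
    }
    return(bank[(variant - 1L) %% length(bank) + 1L])
  }
  bank <- synth_phrase_bank()
  row <- bank[bank$target == target, ]
  if (nrow(row) == 0 || label %in% c("NORMAL", "ABNORMAL")) {
    abort(paste0("Template bank has no rendering for (", target, ", ",
                 label, ")"))
  }
  np <- row$np; cap_np <- cap_first(np)
  be <- if (row$plural) "are" else "is"
  there <- if (row$plural) "There are" else "There is"
  was <- if (row$plural) "were" else "was"
  tpl <- switch(label,
    PRESENT = c(paste0(there, " ", row$np_indef, "."),
                paste0(cap_np, " ", be, " seen."),
                paste0(cap_np, " ", be, " present.")),
    ABSENT = c(paste0("No ", np, "."),
               paste0("No evidence of ", np, "."),
               paste0(there, " no ", np, ".")),
    SUSPECTED = c(paste0("Possible ", np, "."),
                  paste0(cap_np, " ", be, " suspected.")),
    INDETERMINATE = c(paste0(cap_np, " ", was, " not excluded."),
                      paste0("Differential includes ", np, ".")))
  tpl[(variant - 1L) %% length(tpl) + 1L]
}

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# The blanket-negation smart-phrase and the targets it asserts ABSENT.
smartphrase_sentence <- function() {
  paste0("There is no evidence of intracranial hemorrhage, mass effect, ",
         "midline shift or abnormal extraaxial fluid collection.")
}
smartphrase_targets <- function() {
  c("hemorrhage", "mass effect", "midline shift",
    "extraaxial fluid collection")
}

# Adversarial bare-mention bank: sentences whose finding a radiologist
# would read as PRESENT but that carry no lexical modifier (or escape the
# starter lexicon), so the extractor falls back to the default.
bare_mention_bank <- function() {
  tribble(
    ~target, ~label, ~sentence, ~construct,
    "atrophy", "PRESENT", "There has been cerebellar volume loss.",
      "bare_mention",
    "intraventricular hemorrhage", "PRESENT",
      "Hemorrhagic extension into the lateral ventricles.", "lexicon_gap")
}

# Filler sentences free of lexicon targets.
filler_bank <- function() {
  c("The paranasal sinuses are clear.",
    "The mastoid air cells are clear.",
    "The visualized orbits are unremarkable.",
    "The ventricles are stable in size and configuration.",
    "The sella is preserved.",
    "Surrounding soft tissues are within normal limits.",
    "Examination was performed without intravenous contrast.",
    "Patient motion mildly limits evaluation.",
    "Comparison was made with the prior examination.",
    "Bone windows were reviewed.")
}

empty_mentions <- function() {
  tibble(target = character(), label = character(),
         construct = character(), in_truth = logical(),
         visible = logical(), sentence = character())
}

history_bank <- function() {
  c("Fall from standing", "Motor vehicle collision", "Assault",
    "Found down", "Ground level fall", "Bicycle accident")
}

#' Generate one synthetic report with known ground truth
#'
#' Draws the report's seeded targets and labels from the configuration,
#' renders each mention through the template bank, assembles a report
#' with section headers and filler sentences, and derives the ground
#' truth by pushing the seeded mention multiset through the same
#' report-level decision rules the extractor applies (defaults, majority
#' vote, counterpart replacement, derived targets). Adversarial
#' constructs add sentences whose true reading the extractor cannot
#' recover; they are recorded so failures can be attributed.
#'
#' @param config A [synth_config()].
#' @param index Report ordinal (drives the per-report random stream).
#' @param catalog A [target_catalog()].
#' @return List with `report_id`, `text`, `truth` (27-row `tbi_summary`),
#'   `mentions` (tibble `target`, `label`, `construct`, `in_truth`,
#'   `visible`), `constructs` (character).
#' @export
synth_report <- function(config, index, catalog = target_catalog()) {
  report_id <- sprintf("synthetic-%04d", index)
  seed_i <- (config$seed %% 1000003L) * 2011L + index * 7919L
  withr::with_seed(seed_i, {
    mix <- config$label_mix
    prev <- config$target_prevalence
    seeded <- names(prev)[runif(length(prev)) < prev]
    mentions <- list()
    add_mention <- function(target, label, construct, in_truth = TRUE,
                            visible = TRUE, sentence = NA_character_) {
      if (is.na(sentence)) {
        sentence <- render_mention(target, label,
                                   variant = sample.int(3L, 1))
      }
      mentions[[length(mentions) + 1L]] <<-
        tibble(target = target, label = label, construct = construct,
               in_truth = in_truth, visible = visible,
               sentence = sentence)
    }
    for (t in seeded) {
      m <- if (t %in% graded_targets()) mix$graded else mix$standard
      lab <- sample(names(m), 1, prob = m)
      add_mention(t, lab, "covered")
      if (runif(1) < config$conflict_rate) {
        pool <- setdiff(names(m), lab)
        add_mention(t, sample(pool, 1), "conflict")
      }
    }
    # adversarial bare mentions: asserted findings the lexicon cannot link
    if (runif(1) < config$bare_mention_rate) {
      bm <- bare_mention_bank()
      bm <- bm[sample.int(nrow(bm), 1), ]
      add_mention(bm$target, bm$label, bm$construct, in_truth = TRUE,
                  visible = FALSE, sentence = bm$sentence)
    }
    # smart-phrase boilerplate
    mention_tbl <- bind_rows(empty_mentions(), mentions)
    sp_conflicting <- nrow(mention_tbl) > 0 && any(
      mention_tbl$in_truth &
        mention_tbl$target %in% smartphrase_targets() &
        mention_tbl$label != "ABSENT")
    smartphrase <- FALSE; stale <- FALSE
    if (runif(1) < config$stale_smartphrase_rate) {
      # stale: the boilerplate contradicts the body
      smartphrase <- TRUE; stale <- TRUE
      if (!any(mention_tbl$target == "extraaxial fluid collection" &
               mention_tbl$label == "PRESENT")) {
        add_mention("extraaxial fluid collection", "PRESENT", "covered")
      }
      for (t in smartphrase_targets()) {
        add_mention(t, "ABSENT", "stale_smartphrase", in_truth = FALSE,
                    sentence = NA_character_)
      }
      # stale boilerplate mentions are rendered jointly, not per target
    } else if (runif(1) < config$smartphrase_rate && !sp_conflicting) {
      smartphrase <- TRUE
      for (t in smartphrase_targets()) {
        add_mention(t, "ABSENT", "smartphrase", sentence = NA_character_)
      }
    }
    mention_tbl <- bind_rows(empty_mentions(), mentions)

    # body sentences: smart-phrase first, then shuffled mentions+fillers
    body_tbl <- mention_tbl[!mention_tbl$construct %in%
                              c("smartphrase", "stale_smartphrase"), ]
    body <- body_tbl$sentence
    n_sent <- sample(seq(config$sentence_count_range[1],
                         config$sentence_count_range[2]), 1)
    n_fill <- max(0L, n_sent - length(body) - as.integer(smartphrase))
    fillers <- sample(filler_bank(), min(n_fill, length(filler_bank())))
    body <- sample(c(body, fillers))
    if (smartphrase) body <- c(smartphrase_sentence(), body)

    text <- paste0(
      "EXAM: CT head without contrast.\n",
      "HISTORY: ", sample(history_bank(), 1), ".\n\n",
      "FINDINGS: ", paste(body, collapse = " "), "\n\n",
      "IMPRESSION: Findings as described above.\n")

    truth_assign <- mention_tbl[mention_tbl$in_truth, c("target", "label")]
    truth <- tibble(target = truth_assign$target,
                    label = truth_assign$label,
                    sentence_index = NA_integer_, source = "matched") |>
      fill_omitted(catalog) |>
      resolve_duplicates(catalog) |>
      replace_disallowed(catalog) |>
      apply_derived_rules(catalog)
    truth <- tibble(report_id = report_id, target = truth$target,
                    annotation = truth$label,
                    provenance = truth$provenance)
    truth <- truth[match(catalog$targets, truth$target), ]

    constructs <- unique(c(mention_tbl$construct,
                           if (stale) "stale_smartphrase"))
    list(report_id = report_id, text = text,
         truth = structure(truth, class = c("tbi_summary",
                                            class(tibble()))),
         mentions = mutate(mention_tbl, report_id = report_id,
                           .before = 1),
         constructs = setdiff(constructs, c("covered", "conflict",
                                            "smartphrase")))
  })
}

#' Generate a synthetic corpus
#'
#' @param config A [synth_config()].
#' @param catalog A [target_catalog()].
#' @return A `tbi_synth` list with `reports` (tibble `report_id`,
#'   `text`), `truth` (long annotation table with provenance),
#'   `mentions` (seeded mention log) and `config`.
#' @export
#' @examples
#' synth <- synth_corpus(synth_config(n_reports = 2, seed = 42))
#' synth$reports$report_id
synth_corpus <- function(config, catalog = target_catalog()) {
  reps <- lapply(seq_len(config$n_reports), function(i)
    synth_report(config, i, catalog))
  out <- list(
    reports = tibble(report_id = map_chr(reps, "report_id"),
                     text = map_chr(reps, "text")),
    truth = bind_rows(lapply(reps, `[[`, "truth")),
    mentions = bind_rows(lapply(reps, `[[`, "mentions")),
    config = config)
  structure(out, class = "tbi_synth")
}

#' @export
print.tbi_synth <- function(x, ...) {
  cat("<tbi_synth> ", nrow(x$reports), " synthetic report(s), seed ",
      x$config$seed,
      if (x$config$adversarial) ", adversarial constructs on", "\n",
      sep = "")
  invisible(x)
}

#' Targets a construct can corrupt
#'
#' Maps each adversarial construct to the set of summary targets whose
#' extracted label it can change, including knock-on effects through the
#' derived rules; used to attribute end-to-end mismatches.
#'
#' @param construct One of `"stale_smartphrase"`, `"bare_mention"`,
#'   `"lexicon_gap"`.
#' @param target The mention's target (for bare mentions).
#' @return Character vector of target names.
#' @export
construct_scope <- function(construct, target = NULL) {
  derived <- c("extraaxial fluid collection", "hemorrhage",
               "intracranial pathology")
  switch(construct,
    stale_smartphrase = union(smartphrase_targets(), derived),
    bare_mention = , lexicon_gap = union(target, derived),
    abort(paste0("Unknown construct: ", construct)))
}
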