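empty_assignments <- function() {
  tibble::tibble(target = character(), label = character(),
                 sentence_index = integer(), source = character())
}

assign_rows <- function(target, labels) {
  tibble::tibble(target = target, label = labels,
                 sentence_index = seq_along(labels), source = "matched")
}

test_that("omitted targets receive the published defaults", {
  cat27 <- target_catalog()
  filled <- fill_omitted(empty_assignments(), cat27)
  expect_equal(nrow(filled), 27)
  expect_equal(sum(filled$label == "ABSENT"), 25)
  expect_equal(sort(filled$target[filled$label == "NORMAL"]),
               sort(c("gray-white differentiation", "cistern")))
  expect_true(all(filled$source == "default"))
  # covering input is untouched; 26-target input gains exactly one row
  full <- assign_rows(cat27$targets, rep("ABSENT", 27))
  expect_identical(fill_omitted(full, cat27), full)
  partial <- full[full$target != "cistern", ]
  added <- fill_omitted(partial, cat27)
  expect_equal(nrow(added), 27)
  expect_equal(added$label[added$target == "cistern"], "NORMAL")
})

test_that("duplicate resolution follows majority vote with ordered tie-break", {
  cat27 <- target_catalog()
  res <- function(target, labels) {
    a <- fill_omitted(assign_rows(rep(target, length(labels)), labels),
                      cat27)
    out <- resolve_duplicates(a, cat27)
    out$label[out$target == target]
  }
  expect_equal(res("subdural hemorrhage",
                   c("ABSENT", "ABSENT", "PRESENT")), "ABSENT")
  expect_equal(res("subdural hemorrhage",
                   c("PRESENT", "PRESENT", "ABSENT", "ABSENT",
                     "SUSPECTED")), "PRESENT")
  expect_equal(res("extraaxial fluid collection",
                   c("PRESENT", "ABSENT")), "ABSENT")
  # >2-way ties still scan the ordered list
  expect_equal(res("contusion",
                   c("ABSENT", "SUSPECTED", "INDETERMINATE")),
               "SUSPECTED")
})

test_that("duplicate resolution matches the count-and-scan oracle", {
  cat27 <- target_catalog()
  set.seed(42)
  pool <- tbi_labels()
  for (i in 1:300) {
    t <- sample(cat27$targets, 1)
    labels <- sample(pool, sample.int(7, 1), replace = TRUE)
    a <- fill_omitted(assign_rows(rep(t, length(labels)), labels), cat27)
    got <- resolve_duplicates(a, cat27)
    expect_equal(got$label[got$target == t],
                 oracle_resolve(labels, cat27$ordered_list[[t]]),
                 info = paste(t, paste(labels, collapse = ",")))
  }
})

test_that("adding a copy of the majority label never changes the outcome", {
  cat27 <- target_catalog()
  set.seed(43)
  for (i in 1:60) {
    t <- sample(cat27$targets, 1)
    labels <- sample(tbi_labels(), sample.int(5, 1), replace = TRUE)
    a <- fill_omitted(assign_rows(rep(t, length(labels)), labels), cat27)
    won <- resolve_duplicates(a, cat27)$label[
      resolve_duplicates(a, cat27)$target == t]
    a2 <- fill_omitted(assign_rows(rep(t, length(labels) + 1),
                                   c(labels, won)), cat27)
    won2 <- resolve_duplicates(a2, cat27)
    expect_equal(won2$label[won2$target == t], won)
  }
})

test_that("disallowed annotations are replaced by their counterparts", {
  cat27 <- target_catalog()
  base <- resolve_duplicates(fill_omitted(empty_assignments(), cat27),
                             cat27)
  set_lab <- function(df, t, l) { df$label[df$target == t] <- l; df }
  out <- replace_disallowed(set_lab(base, "cistern", "ABSENT"), cat27)
  expect_equal(out$label[out$target == "cistern"], "NORMAL")
  out <- replace_disallowed(
    set_lab(base, "gray-white differentiation", "PRESENT"), cat27)
  expect_equal(out$label[out$target == "gray-white differentiation"],
               "ABNORMAL")
  out <- replace_disallowed(set_lab(base, "subdural hemorrhage",
                                    "PRESENT"), cat27)
  expect_equal(out$label[out$target == "subdural hemorrhage"], "PRESENT")
  # a pair with no counterpart is a configuration error
  broken <- target_catalog()
  broken$counterpart[["cistern"]] <- character(0)
  expect_error(replace_disallowed(set_lab(base, "cistern", "ABSENT"),
                                  broken), "No counterpart")
})

derived_from <- function(labels_by_target, cat27 = target_catalog()) {
  base <- resolve_duplicates(fill_omitted(empty_assignments(), cat27),
                             cat27)
  for (t in names(labels_by_target)) {
    base$label[base$target == t] <- labels_by_target[[t]]
    base$provenance[base$target == t] <- "matched"
  }
  apply_derived_rules(base, cat27)
}

test_that("a present subdural hemorrhage cascades through the derived rules", {
  out <- derived_from(c("subdural hemorrhage" = "PRESENT"))
  lab <- setNames(out$label, out$target)
  expect_equal(lab[["extraaxial fluid collection"]], "PRESENT")
  expect_equal(lab[["hemorrhage"]], "ABSENT")
  expect_equal(lab[["intracranial pathology"]], "PRESENT")
  expect_equal(out$provenance[out$target == "hemorrhage"], "derived")
})

test_that("a suspected subtype upgrades a default extraaxial collection", {
  out <- derived_from(c("subarachnoid hemorrhage" = "SUSPECTED"))
  lab <- setNames(out$label, out$target)
  expect_equal(lab[["extraaxial fluid collection"]], "SUSPECTED")
  expect_equal(lab[["hemorrhage"]], "ABSENT")
  expect_equal(lab[["intracranial pathology"]], "PRESENT")
  # but an explicitly matched ABSENT collection is left alone
  cat27 <- target_catalog()
  base <- resolve_duplicates(fill_omitted(empty_assignments(), cat27),
                             cat27)
  base$label[base$target == "subarachnoid hemorrhage"] <- "SUSPECTED"
  base$provenance[base$target == "subarachnoid hemorrhage"] <- "matched"
  base$provenance[base$target == "extraaxial fluid collection"] <-
    "matched"
  out2 <- apply_derived_rules(base, cat27)
  expect_equal(out2$label[out2$target == "extraaxial fluid collection"],
               "ABSENT")
})

test_that("derived rules are idempotent and inert on an all-default summary", {
  out0 <- derived_from(c())
  expect_equal(out0$label[out0$target == "intracranial pathology"],
               "ABSENT")
  expect_true(all(out0$provenance == "default"))
  for (combo in list(c("subdural hemorrhage" = "PRESENT"),
                     c("epidural hemorrhage" = "SUSPECTED",
                       "cistern" = "ABNORMAL"),
                     c("midline shift" = "PRESENT",
                       "hemorrhage" = "PRESENT"))) {
    once <- derived_from(combo)
    twice <- apply_derived_rules(once)
    expect_identical(twice, once, info = paste(names(combo),
                                               collapse = "+"))
  }
})

test_that("summarize_report produces a well-formed 27-row summary", {
  s <- summarize_report(
    "FINDINGS: No acute intracranial hemorrhage. IMPRESSION: Normal.",
    report_id = "r1")
  expect_equal(nrow(s), 27)
  expect_equal(s$target, cde_targets())
  expect_false(any(s$annotation == "NOT SPECIFIED"))
  expect_equal(s$annotation[s$target == "hemorrhage"], "ABSENT")
  expect_equal(s$provenance[s$target == "hemorrhage"], "matched")
  expect_equal(s$annotation[s$target == "cistern"], "NORMAL")
  # labels always inside the allowed set
  cat27 <- target_catalog()
  ok <- vapply(seq_len(nrow(s)), function(i)
    s$annotation[i] %in% cat27$allowed_labels[[s$target[i]]], logical(1))
  expect_true(all(ok))
})

test_that("an empty findings body yields the pure default surface", {
  s <- summarize_report("FINDINGS: IMPRESSION:")
  expect_equal(sum(s$annotation == "ABSENT"), 25)
  expect_equal(sort(s$target[s$annotation == "NORMAL"]),
               sort(c("gray-white differentiation", "cistern")))
})

test_that("an asserted subdural hematoma carries its derived consequences", {
  s <- summarize_report(paste(
    "FINDINGS: A subdural hematoma is present along the convexity.",
    "IMPRESSION: Acute subdural hematoma."))
  lab <- setNames(s$annotation, s$target)
  expect_equal(lab[["subdural hemorrhage"]], "PRESENT")
  expect_equal(lab[["extraaxial fluid collection"]], "PRESENT")
  expect_equal(lab[["hemorrhage"]], "ABSENT")
  expect_equal(lab[["intracranial pathology"]], "PRESENT")
})

test_that("extract_cde maps a corpus to one long summary table", {
  reps <- tibble::tibble(
    report_id = c("a", "b"),
    text = c("FINDINGS: No subdural hematoma. IMPRESSION: Normal.",
             "FINDINGS: Possible contusion. IMPRESSION: See above."))
  out <- extract_cde(reps)
  expect_equal(nrow(out), 54)
  expect_equal(out$annotation[out$report_id == "b" &
                                out$target == "contusion"], "SUSPECTED")
})
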