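---
title: "Extracting TBI common data elements from head CT reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting TBI common data elements from head CT reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbicde)
library(dplyr)
```

## The problem and the model

Radiology reports for non-contrast head CT scans are unstructured
narrative text, yet they carry the most important early prognostic
information about a traumatic brain injury (TBI): whether there is a
subdural or subarachnoid hemorrhage, midline shift, cisternal
effacement, and so on. Research and trial stratification need this
information as *common data elements* — standardized variables with a
controlled vocabulary — rather than prose.

`tbicde` converts one report into a structured summary of 27 such
elements, each annotated with exactly one of six labels:

* **PRESENT** — the report explicitly asserts the finding;
* **SUSPECTED** — the report hedges ("possible", "suspected");
* **INDETERMINATE** — the finding is one of several offered etiologies
  ("was not excluded", "differential includes");
* **ABSENT** — the report explicitly denies the finding, or never
  mentions it;
* **NORMAL / ABNORMAL** — the graded status of the two structural
  elements (gray-white differentiation and the basal cisterns).

A seventh legacy label, `NOT SPECIFIED`, is accepted when reading
historical annotator tables but is never produced by the extractor; its
meaning overlapped ABSENT and INDETERMINATE and it was retired as an
annotation option.

The extraction model is a lexicon-driven contextual-assertion algorithm
in the NegEx/ConText family. It is deliberately *not* a statistical
model: every decision is a deterministic rule over regular-expression
matches, which makes its behaviour auditable clause by clause — the
property that matters most when the output feeds clinical research.

### Sentence-level markup

Each sentence is scanned with two lexicons of *itemData* records
(literal, category, pattern, directionality rule):

* **lexical targets** — the 27 findings, e.g. literal
  `microhemorrhage` with pattern `microhemorrhage(s)?`;
* **lexical modifiers** — contextual phrases that assign a label, e.g.
  `no evidence of` (ABSENT, forward), `was not excluded`
  (INDETERMINATE, backward).

Matches become concept spans with character offsets (0-based start,
exclusive end). Three pruning passes then enforce "one modifier per
target":

1. **span pruning** — a span strictly contained in another span of the
   same concept type is dropped; in
   "findings do not appear significantly changed" the modifier *not*
   disappears inside *do not appear significantly changed*;
2. **modifier linking and pruning** — every modifier is applied to the
   targets inside its directional scope (*forward*: to the end of the
   sentence; *backward*: to its start; *bidirectional*: both), and
   modifiers linked to no target are dropped;
3. **distance pruning** — when several modifiers reach one target, the
   nearest by character distance wins; in "multifocal subarachnoid
   hemorrhage … most notably in the right sylvian fissure" the label
   comes from *multifocal*, not *in the*.

### Report-level decision rules

Sentence assignments are collapsed into the 27-row summary in four
steps:

1. **omitted targets** — unmentioned targets receive their default:
   NORMAL for gray-white differentiation and the cisterns, ABSENT for
   the other 25;
2. **duplicate targets** — a target mentioned in several sentences is
   resolved by majority vote; when the maximal count is tied the
   winner is the earliest tied label in the target's *ordered
   annotation list* (ABSENT-first for extraaxial fluid collection,
   hemorrhage (NOS) and intracranial pathology; PRESENT-first for all
   others);
3. **counterpart replacement** — a label outside the target's allowed
   set is replaced by its predetermined counterpart (cisterns ABSENT
   becomes NORMAL, gray-white differentiation PRESENT becomes
   ABNORMAL);
4. **derived targets** — cross-target logic: a PRESENT or SUSPECTED
   extraaxial hemorrhage subtype suppresses hemorrhage (NOS) to
   ABSENT; a PRESENT subtype asserts extraaxial fluid collection
   (a SUSPECTED subtype upgrades a *default* ABSENT collection to
   SUSPECTED); and any positive trigger target implies intracranial
   pathology PRESENT.

```{r}
summarize_report(
  "FINDINGS: There is a subdural hematoma. No midline shift.
   IMPRESSION: Acute subdural hematoma.") |>
  filter(provenance != "default")
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| lexicons | shipped starter TSVs | replaceable per institution |
| `threshold` (dedup) | 0.70 | cosine similarity at/above which reports are near-duplicates |
| `ngram_min`/`ngram_max` | 1 / 10 | word n-gram range of the TF-IDF vectorizer |
| `proportions` (split) | 0.10/0.40/0.50 | initialization/training/validation deck |
| `case` (evaluation) | case1 | positive set {PRESENT, ABNORMAL}; case2 adds SUSPECTED |
| `unscored` (evaluation) | exclude | how cells outside both label sides are scored |
| catalog `triggers` | 17 targets | the intracranial-pathology derived rule |

All units are characters (distances), probabilities (rates), or labels.

## Design choices where the design was open

Several details of this family of algorithms are conventionally left to
the implementation. The choices here, and why:

* **Distance metric.** "Nearest by character length" is implemented as
  the gap between the *nearest edges* of the modifier and target spans
  (0 when they touch or overlap). Measuring from span starts or ends
  instead would make the result depend on the lengths of the phrases,
  which has no clinical meaning.
* **Distance ties.** Prefer the modifier preceding the target, then
  the smaller start offset. Clinical assertions usually lead the
  finding ("no evidence of X"), so the preceding phrase is the safer
  reading; the second key makes the whole chain a total order, so the
  pipeline is deterministic for any input.
* **Scope of the "in the" modifier.** A locative phrase that follows a
  finding asserts it about that preceding finding, so the entry ships
  with a *backward* rule — with a forward rule it could never compete
  for the finding before it and the distance-pruning behaviour above
  could not arise.
* **Identical-extent span ties.** Keep the entry earliest in lexicon
  order, making lexicon order the single, explicit tie authority.
* **Derived-rule ordering.** The rules run hemorrhage-NOS →
  extraaxial-fluid-collection → intracranial-pathology, and the last
  rule sees the collection update. This ordering makes a PRESENT
  subdural hematoma imply intracranial pathology through either route,
  which is clearly the intended clinical semantics.
* **The trigger set.** The published enumeration of the
  intracranial-pathology rule names sixteen distinct targets and
  repeats intraventricular hemorrhage; we read the duplicate as the
  near-namesake intraparenchymal hemorrhage (a specific hemorrhage
  that surely implies intracranial pathology), giving 17 triggers.
  The set is configurable for users who prefer the literal reading.
* **Counterpart generalisation.** Only cisterns-ABSENT→NORMAL is fixed
  by the decision rules; we generalise symmetrically
  (ABSENT↔NORMAL, PRESENT↔ABNORMAL per target family, legacy
  NOT SPECIFIED→the target's default) and expose the full map in the
  catalog configuration rather than guessing silently elsewhere.
* **Majority ties among more than two labels** use the same
  ordered-list scan as two-way ties.
* **Section headers.** The Findings/Impression header tokens are kept
  inside the cleaned text (they never match a lexicon entry); the
  Findings span runs to the end of the report, since the impression is
  conventionally the closing section.
* **"Symbols removed"** is realised as a retained character class —
  letters, digits, whitespace and `. , ; : ? ! % / ( ) -` — so that
  measurements ("5 mm"), ratios and hyphenated terms ("gray-white")
  survive cleaning. The class is configurable.
* **Sentence splitting** is a deterministic rule on terminal
  punctuation with a clinical abbreviation guard ("mm.", "Dr.",
  "vs."), rather than a learned sentencizer, so the same input always
  yields the same markup.

## The synthetic corpus: what it emulates and what it does not

Real institutional report corpora cannot be redistributed, so the
package ships a seeded generator whose output carries known ground
truth (`synth_corpus()`). It emulates the observable structure of
short trauma head-CT reports: 9–15 sentences, EXAM/HISTORY headers, a
Findings–Impression span, per-target mention prevalences loosely
following the relative frequency of findings on trauma CT (hemorrhage
subtypes common; axonal and anoxic injury rare), assertion phrasing per
label (negations, hedges, multi-etiology constructions), optional
blanket-negation "smart-phrase" boilerplate, and contradictory
duplicate mentions whose truth follows the majority/ordered-list
resolution. Ground truth is defined *after* the derived rules, because
that is the only observable the extractor emits.

In adversarial mode the generator injects the failure modes reported
for real corpora, each logged so that tests can attribute every
end-to-end mismatch to its construct:

* a *stale smart-phrase* — the opening boilerplate denies findings the
  body later asserts, so the ABSENT-first tie-break buries a true
  extraaxial fluid collection;
* *bare mentions / lexicon gaps* — sentences such as "There has been
  cerebellar volume loss." carry no modifier the lexicon can link, so
  the target silently falls back to its default.

What the generator does **not** emulate: institution-specific style,
typographical noise, compound sentences whose syntax defeats regular
expressions, genuinely ambiguous wording, and findings phrased outside
the starter lexicon's coverage. Exact recovery on the non-adversarial
corpus therefore demonstrates the internal consistency of the pipeline
(markup, pruning, voting, derivation) — not expected field accuracy on
real reports, which depends on lexicon curation.

On the shipped templates the adversarial corpus degrades the cell-level
case-2 F1 to roughly 0.90; the test suite asserts it never falls below
a floor of 0.80, and that every mismatching cell lies in the scope of
an injected construct.

## Numerical and degenerate-input choices

* Empty sentences, sentences with no lexicon hits, and reports with an
  empty findings body are all valid inputs; the last yields the pure
  default summary (25 ABSENT + 2 NORMAL).
* Cohen's kappa is computed over the full multi-label confusion
  matrix, not a binarised one; identical single-label tables (chance
  agreement 1) return kappa 1 rather than 0/0.
* Metrics with zero denominators are reported `NA`, never 0, so
  averages cannot be silently inflated; evaluation cells whose label
  falls outside both the positive and negative sets (INDETERMINATE
  always; SUSPECTED under case 1) are excluded and counted, with a
  flag for the literal "all other cases are errors" reading.
* TF-IDF uses lower-cased word tokens of length ≥ 2, raw counts,
  smoothed idf `log((1+N)/(1+df)) + 1` and L2 row normalisation;
  similarities are clipped to [0, 1] and the diagonal is exact.
* Dataset-deck rounding uses the largest-remainder method, which
  reproduces the reference 311 → 31/124/156 split exactly.
* All stochastic operations (dedup draws, deck shuffling, corpus
  generation) consume a caller-supplied seed through an isolated RNG
  scope, so results are reproducible and the caller's RNG state is
  untouched.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the
statistical checks meaningful while keeping a full run comfortable on
one CPU: 200-report corpora for end-to-end recovery, 120 reports for
the adversarial attribution study, 10,000 random label multisets for
the majority-vote oracle, the full 7⁴ enumeration of hemorrhage-state
combinations for the derived rules, and 10⁵ cells for the
independence limit of kappa.

## Known limitations

* Regular expressions cannot resolve long-range syntax; compound
  sentences ("fracture of the left orbital floor extending …") can
  escape both the target patterns and span pruning.
* No termination clues: a modifier's scope runs to the sentence
  boundary, so "however"-style clause breaks are not modelled unless
  encoded as lexicon entries.
* No laterality, size, count or longitudinal comparison is extracted —
  one label per element per report.
* The starter lexicons are a small synthetic starting point;
  production use requires curating them against the local reporting
  style, and the evaluation module exists precisely to support that
  loop.
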