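# tbicde

Structured extraction of traumatic brain injury (TBI) common data
elements from free-text non-contrast head CT radiology reports.

## What problem this solves, and for whom

Head CT reports are the most information-dense early record of a TBI,
but they are written as prose. Research groups, registries and trial
teams need the same information as standardized variables: is there a
*subdural hemorrhage*? is *midline shift* present? are the *basal
cisterns* effaced? Manual annotation is slow and inconsistent;
`tbicde` automates it with an auditable, rule-based pipeline so that
subjects can be stratified by visible damage directly from the report
text.

The package is for clinical NLP researchers and TBI study teams who
need (a) the extractor itself, (b) the corpus-preparation tools around
it (section trimming, sentence splitting, TF-IDF near-duplicate
removal, similarity-aware dataset partitioning), (c) the evaluation
machinery to validate it against human annotators, and (d) a seeded
synthetic-report generator so everything is testable without access to
protected health information.

## The algorithm

`tbicde` is a lexicon-driven contextual-assertion algorithm in the
NegEx/ConText family. Two tab-separated lexicons define *itemData*
records — literal, category, regular expression, directionality rule:

* **lexical targets**: the 27 TBI common data elements
  (`microhemorrhage(s)?`, `subdural (hemorrhage|hematoma)`, …);
* **lexical modifiers**: contextual phrases carrying an annotation —
  negations (`no evidence of` → ABSENT, forward scope), hedges
  (`possible` → SUSPECTED), multi-etiology markers
  (`(was|were)\snot\sexcluded` → INDETERMINATE, backward scope),
  affirmations, and normal/abnormal assertions.

Per sentence: mark all target and modifier spans; prune spans nested in
larger same-type spans; link each modifier to the targets in its
directional scope and drop unlinked modifiers; keep only the nearest
modifier per target by character distance. Per report: fill omitted
targets with defaults (NORMAL for gray-white differentiation and
cistern, ABSENT for the other 25), resolve duplicate mentions by
majority vote with an ordered tie-break list, replace disallowed
annotations with predetermined counterparts, and apply derived rules
(a specific extraaxial hemorrhage suppresses hemorrhage-NOS, asserts
extraaxial fluid collection, and — like any positive trigger finding —
implies intracranial pathology). The output is always exactly 27 rows,
one annotation each, from {PRESENT, SUSPECTED, INDETERMINATE, ABSENT,
NORMAL, ABNORMAL}.

Evaluation utilities compute annotator agreement classes
(equivalent / similar / divergent), Cohen's kappa over the full label
confusion matrix, confusion counts under two positivity cases
(case 1: {PRESENT, ABNORMAL}; case 2: + SUSPECTED), the six standard
classification metrics, and per-target error tables.

## Worked example

```r
library(tbicde)
library(dplyr)

report <- "EXAM: CT head without contrast.
HISTORY: Fall from standing.

FINDINGS: There is a subdural hematoma along the left convexity.
No midline shift. The basal cisterns are patent.
Gray-white differentiation is preserved.

IMPRESSION: Acute subdural hematoma."

summarize_report(report, report_id = "example-1") |>
  filter(provenance != "default")
#> # A tibble: 7 × 4
#>   report_id target                      annotation provenance
#>   <chr>     <chr>                       <chr>      <chr>
#> 1 example-1 extraaxial fluid collection PRESENT    derived
#> 2 example-1 subdural hemorrhage         PRESENT    matched
#> 3 example-1 hemorrhage                  ABSENT     derived
#> 4 example-1 intracranial pathology      PRESENT    derived
#> 5 example-1 gray-white differentiation  NORMAL     matched
#> 6 example-1 cistern                     NORMAL     matched
#> 7 example-1 midline shift               ABSENT     matched
```

Reading the output: the asserted subdural hematoma is `matched` from
the text; the derived rules then assert the extraaxial fluid
collection and intracranial pathology it implies and suppress the
unspecified "hemorrhage (NOS)" element to ABSENT, because a specific
subtype supersedes it. The explicit negation and the two normal
structural statements are matched directly; the remaining 20 elements
(not shown) hold their defaults.

Validating the extractor against a corpus with known ground truth:

```r
syn  <- synth_corpus(synth_config(n_reports = 50, seed = 7))
pred <- extract_cde(syn$reports)
compare_annotations(pred, syn$truth)
#> <tbi_agreement> 1350 cells: 1350 equivalent (100.0%), 0 similar,
#>   0 divergent, 0 other; kappa = 1.000

glance(confusion_counts(pred, syn$truth, case = "case2"))
#> # A tibble: 1 × 12
#>   case     tp    tn    fp    fn n_excluded sensitivity specificity   ppv ...
#> 1 case2   123  1207     0     0         20           1           1     1 ...
```

(The 20 excluded cells are INDETERMINATE, which belongs to neither the
positive nor the negative group.)

A thin command-line interface wraps the same functions:

```sh
exec/tbicde synth   --n 200 --seed 7 --out reports/ --truth truth.csv
exec/tbicde extract --reports reports/ --out summary.csv
exec/tbicde dedup   --reports reports/ --threshold 0.70 --seed 1 --out dedup.csv
exec/tbicde split   --reports reports/ --proportions 0.1,0.4,0.5 --seed 1 --out split.csv
exec/tbicde eval    --pred summary.csv --gold truth.csv --case case2 --out metrics.csv
```

See `vignettes/extracting-tbi-cde.Rmd` for the full account of the
model, its parameters, and the design decisions.

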