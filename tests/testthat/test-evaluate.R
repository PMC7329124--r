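two_tables <- function(labels_a, labels_b, targets = NULL) {
  n <- length(labels_a)
  targets <- targets %||% rep_len(cde_targets(), n)
  ids <- sprintf("r%03d", ceiling(seq_len(n) / 27))
  list(a = make_table(ids, targets, labels_a),
       b = make_table(ids, targets, labels_b))
}

test_that("agreement classes follow the published definitions", {
  tt <- two_tables(c("PRESENT", "PRESENT", "ABSENT", "INDETERMINATE"),
                   c("PRESENT", "SUSPECTED", "PRESENT", "SUSPECTED"),
                   targets = cde_targets()[1:4])
  ag <- compare_annotations(tt$a, tt$b)
  expect_equal(ag$n_equivalent, 1)
  expect_equal(ag$n_similar, 1)
  expect_equal(ag$n_divergent, 1)
  expect_equal(ag$n_other, 1)
  expect_equal(ag$n_total, 4)
  td <- tidy(ag)
  expect_equal(sum(td$n), 4)
  # identical tables: all equivalent, kappa 1
  same <- default_table(c("r1", "r2"))
  ag2 <- compare_annotations(same, same)
  expect_equal(ag2$n_equivalent, ag2$n_total)
  expect_equal(ag2$kappa, 1)
})

test_that("tables with mismatched keys are rejected", {
  a <- default_table("r1")
  b <- a[-1, ]
  expect_error(compare_annotations(a, b), "identical keys")
  dup <- rbind(a, a[1, ])
  expect_error(compare_annotations(dup, dup), "one label per")
})

test_that("kappa matches the confusion-matrix oracle on a toy table", {
  la <- c("ABSENT", "ABSENT", "PRESENT", "PRESENT", "ABSENT", "NORMAL",
          "NORMAL", "PRESENT", "ABSENT", "ABSENT", "NORMAL", "PRESENT")
  lb <- c("ABSENT", "PRESENT", "PRESENT", "ABSENT", "ABSENT", "NORMAL",
          "ABSENT", "PRESENT", "ABSENT", "NORMAL", "NORMAL", "PRESENT")
  tt <- two_tables(la, lb, targets = cde_targets()[1:12])
  k <- cohens_kappa(tt$a, tt$b)
  expect_equal(k, oracle_kappa(la, lb), tolerance = 1e-12)
  # independent cross-check against e1071's implementation
  skip_if_not_installed("e1071")
  tab <- table(la, lb)
  expect_equal(k, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
})

test_that("kappa is symmetric and tends to zero for independent labels", {
  set.seed(77)
  n <- 5400
  la <- sample(c("ABSENT", "PRESENT"), n, replace = TRUE)
  lb <- sample(c("ABSENT", "PRESENT"), n, replace = TRUE)
  tt <- two_tables(la, lb,
                   targets = rep_len(cde_targets(), n))
  k <- cohens_kappa(tt$a, tt$b)
  expect_lt(abs(k), 0.05)
  expect_equal(cohens_kappa(tt$b, tt$a), k)
})

test_that("the gold standard is the equivalent-cell subset", {
  tt <- two_tables(c("PRESENT", "ABSENT", "SUSPECTED"),
                   c("PRESENT", "PRESENT", "SUSPECTED"),
                   targets = cde_targets()[1:3])
  g <- gold_standard(tt$a, tt$b)
  expect_equal(nrow(g), 2)
  expect_setequal(g$annotation, c("PRESENT", "SUSPECTED"))
})

test_that("confusion counts respect the two positivity cases", {
  gold <- make_table(rep("r1", 4), cde_targets()[1:4],
                     c("PRESENT", "ABSENT", "SUSPECTED", "ABNORMAL"))
  pred <- make_table(rep("r1", 4), cde_targets()[1:4],
                     c("PRESENT", "ABSENT", "ABSENT", "ABSENT"))
  c1 <- confusion_counts(pred, gold, "case1")
  # SUSPECTED gold cell is unscored under case1
  expect_equal(c(c1$tp, c1$tn, c1$fp, c1$fn), c(1, 1, 0, 1))
  expect_equal(c1$n_excluded, 1)
  c2 <- confusion_counts(pred, gold, "case2")
  expect_equal(c(c2$tp, c2$tn, c2$fp, c2$fn), c(1, 1, 0, 2))
  expect_equal(c2$n_excluded, 0)
  # the literal reading scores unscored cells as errors
  c1e <- confusion_counts(pred, gold, "case1", unscored = "error")
  expect_equal(c1e$fn, 2)
  expect_equal(c1e$n_scored, 4)
})

test_that("case2 true positives always dominate case1", {
  set.seed(5)
  pool <- tbi_labels()
  for (i in 1:20) {
    n <- 54
    gold <- make_table(rep(sprintf("g%d-%d", i, 1:2), each = 27),
                       rep_len(cde_targets(), n),
                       sample(pool, n, replace = TRUE))
    pred <- make_table(gold$report_id, gold$target,
                       sample(pool, n, replace = TRUE))
    c1 <- confusion_counts(pred, gold, "case1")
    c2 <- confusion_counts(pred, gold, "case2")
    expect_gte(c2$tp, c1$tp)
  }
})

test_that("classification metrics evaluate the published formulas", {
  m <- classification_metrics(list(tp = 75, fn = 3, fp = 0, tn = 922))
  expect_equal(m$sensitivity, 75 / 78)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 922 / 925)
  expect_equal(m$accuracy, 997 / 1000)
  expect_equal(m$f1, 2 * 1 * (75 / 78) / (1 + 75 / 78))
  all_right <- classification_metrics(list(tp = 1, tn = 1, fp = 0,
                                           fn = 0))
  expect_true(all(unlist(all_right) == 1))
  degenerate <- classification_metrics(list(tp = 0, fp = 0, tn = 5,
                                            fn = 5))
  expect_equal(degenerate$sensitivity, 0)
  expect_true(is.na(degenerate$ppv))
  expect_error(classification_metrics(list(tp = 0, tn = 0, fp = 0,
                                           fn = 0)), "zero")
})

test_that("metric formulas hold on random confusion tuples", {
  set.seed(6)
  for (i in 1:200) {
    cc <- as.list(setNames(sample(0:50, 4, replace = TRUE),
                           c("tp", "tn", "fp", "fn")))
    if (sum(unlist(cc)) == 0) next
    m <- classification_metrics(cc)
    with(cc, {
      if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
      if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
      if (!is.na(m$f1)) {
        expect_equal(m$f1, 2 * m$ppv * m$sensitivity /
                       (m$ppv + m$sensitivity))
      }
      expect_equal(m$accuracy, (tp + tn) / (tp + tn + fp + fn))
    })
  }
})

test_that("per-target errors localise injected mistakes and sum globally", {
  set.seed(8)
  ids <- sprintf("r%02d", 1:20)
  gold <- default_table(ids)
  flip <- sample(nrow(gold), 40)
  gold$annotation[flip] <- sample(c("PRESENT", "SUSPECTED", "ABNORMAL"),
                                  40, replace = TRUE)
  gold$annotation <- ifelse(
    gold$target %in% c("gray-white differentiation", "cistern") &
      gold$annotation == "PRESENT", "ABNORMAL", gold$annotation)
  # perfect prediction: zero errors everywhere, F1 = 1 where occurring
  pt <- per_target_errors(gold, gold, "case2")
  expect_equal(pt$target, cde_targets())
  expect_true(all(pt$fn == 0 & pt$fp == 0))
  expect_true(all(pt$f1[pt$occurrences > 0] == 1))
  # one injected miss moves exactly one row
  pred <- gold
  pos <- which(pred$annotation == "PRESENT")[1]
  pred$annotation[pos] <- "ABSENT"
  pt2 <- per_target_errors(pred, gold, "case2")
  hit <- gold$target[pos]
  expect_equal(pt2$fn[pt2$target == hit], 1)
  expect_equal(pt2$fn[pt2$target != hit], pt$fn[pt$target != hit])
  # per-target counts sum to the global confusion counts
  cc <- confusion_counts(pred, gold, "case2")
  expect_equal(sum(pt2$fn), cc$fn)
  expect_equal(sum(pt2$fp), cc$fp)
})

test_that("per-target errors equal a brute-force per-target recomputation", {
  set.seed(9)
  ids <- sprintf("r%02d", 1:20)
  pool <- c("PRESENT", "SUSPECTED", "ABSENT", "NORMAL", "ABNORMAL",
            "INDETERMINATE")
  gold <- default_table(ids)
  gold$annotation <- sample(pool, nrow(gold), replace = TRUE)
  pred <- gold
  pred$annotation <- ifelse(runif(nrow(pred)) < 0.2,
                            sample(pool, nrow(pred), replace = TRUE),
                            pred$annotation)
  pt <- per_target_errors(pred, gold, "case1")
  pos <- c("PRESENT", "ABNORMAL"); neg <- c("ABSENT", "NORMAL")
  for (t in unique(pt$target)) {
    g <- gold[gold$target == t, ]; p <- pred[pred$target == t, ]
    scored <- g$annotation %in% c(pos, neg) & p$annotation %in% c(pos, neg)
    gp <- g$annotation[scored] %in% pos; pp <- p$annotation[scored] %in% pos
    expect_equal(pt$fn[pt$target == t], sum(!pp & gp))
    expect_equal(pt$fp[pt$target == t], sum(pp & !gp))
    expect_equal(pt$occurrences[pt$target == t],
                 sum(g$annotation %in% pos))
  }
})
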