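test_that("grade binarization follows the referable-DR cutoff", {
  expect_equal(binarize_grade(c("R2", "R3s", "R3a")), rep("positive", 3))
  expect_equal(binarize_grade(c("R0", "R1")), rep("negative", 2))
  expect_true(is.na(binarize_grade(NA_character_)))
  expect_error(binarize_grade("R4"), "R4")
  expect_error(binarize_grade(c("R0", "referable")), "referable")
})

test_that("participant aggregation is an OR over gradable images", {
  rec <- toy_records()
  rec$classifier_label <- ifelse(rec$classifier_score >= 0.5, "positive", "negative")
  agg <- suppressMessages(aggregate_participants(rec))
  # A: one positive image among three -> positive
  expect_equal(agg$human_label[agg$participant_id == "A"], "positive")
  # B: all images negative -> negative
  expect_equal(agg$human_label[agg$participant_id == "B"], "negative")
  # C: 1 gradable positive + 2 ungradable (classifier positive) -> human
  # positive, classifier negative: ungradable images are ignored
  expect_equal(agg$human_label[agg$participant_id == "C"], "positive")
  expect_equal(agg$classifier_label[agg$participant_id == "C"], "negative")
  # D: only ungradable images -> excluded and counted
  expect_false("D" %in% agg$participant_id)
  expect_equal(attr(agg, "n_excluded"), 1L)
  expect_equal(agg$n_gradable[agg$participant_id == "A"], 3L)
})

test_that("aggregation of empty input returns empty output with a warning", {
  empty <- toy_records()[0, ]
  empty$classifier_label <- character(0)
  expect_warning(out <- aggregate_participants(empty), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("adding a positive gradable image never flips a participant negative", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    rec <- data.frame(
      image_id = as.character(seq_len(n + 1)),
      participant_id = "X",
      gradable = c(sample(c(TRUE, FALSE), n, replace = TRUE), TRUE),
      human_label = c(sample(c("positive", "negative"), n, replace = TRUE), "positive"),
      classifier_label = sample(c("positive", "negative"), n + 1, replace = TRUE),
      stringsAsFactors = FALSE
    )
    base <- rec[seq_len(n), ]
    if (any(base$gradable)) {
      before <- suppressMessages(aggregate_participants(base))$human_label
      after <- suppressMessages(aggregate_participants(rec))$human_label
      if (identical(before, "positive")) expect_equal(after, "positive")
    }
    expect_equal(suppressMessages(aggregate_participants(rec))$human_label, "positive")
  }
})

test_that("confusion tallies match an independent double-loop count", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    cls <- sample(c("positive", "negative"), n, replace = TRUE)
    hum <- sample(c("positive", "negative"), n, replace = TRUE, prob = c(0.3, 0.7))
    cm <- build_confusion(cls, hum)
    ref <- brute_confusion(cls, hum)
    expect_equal(cm$tp, ref$tp)
    expect_equal(cm$fp, ref$fp)
    expect_equal(cm$tn, ref$tn)
    expect_equal(cm$fn, ref$fn)
    # cell conservation and derived totals
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, n)
    expect_equal(cm$label_positive, sum(hum == "positive"))
    expect_equal(cm$pred_positive, sum(cls == "positive"))
  }
})

test_that("confusion handles degenerate and invalid input", {
  cm <- build_confusion(rep("positive", 5), rep("positive", 5))
  expect_equal(cm$tp, 5)
  expect_equal(cm$fp + cm$tn + cm$fn, 0)
  expect_error(build_confusion(c("positive", NA), c("positive", "positive"),
                               unit_id = c("u1", "u2")), "u2")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("diagnostic metrics reproduce the published confusion matrices", {
  ic <- image_counts()
  m <- compute_metrics(confusion_counts(ic$tp, ic$fp, ic$tn, ic$fn))
  expect_equal(round_half_up(100 * m$sensitivity, 1), 79.6)
  expect_equal(round_half_up(100 * m$specificity, 1), 91.6)
  expect_equal(round_half_up(100 * m$accuracy, 1), 90.9)
  expect_equal(round_half_up(100 * m$precision, 1), 38.6)
  expect_equal(round_half_up(100 * m$f1, 1), 52.0)

  pc <- participant_counts()
  mp <- compute_metrics(confusion_counts(pc$tp, pc$fp, pc$tn, pc$fn,
                                         level = "participant"))
  expect_equal(round_half_up(100 * mp$sensitivity, 1), 88.1)
  expect_equal(round_half_up(100 * mp$specificity, 1), 84.6)
  expect_equal(round_half_up(100 * mp$accuracy, 1), 84.9)
  expect_equal(round_half_up(100 * mp$precision, 1), 31.0)
  expect_equal(round_half_up(100 * mp$f1, 1), 45.9)
})

test_that("metric identities hold on random confusion counts", {
  set.seed(11)
  for (i in 1:20) {
    cm <- confusion_counts(sample(1:500, 1), sample(1:500, 1),
                           sample(1:500, 1), sample(1:500, 1))
    m <- compute_metrics(cm)
    P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
    expect_equal(m$f1, 2 * m$precision * m$sensitivity / (m$precision + m$sensitivity))
    expect_true(all(unlist(m[c("accuracy", "precision", "sensitivity",
                               "specificity", "f1")]) >= 0))
    expect_true(all(unlist(m[c("accuracy", "precision", "sensitivity",
                               "specificity", "f1")]) <= 1))
  }
})

test_that("perfect classification gives all-1 metrics; zero denominators give NA", {
  perfect <- compute_metrics(confusion_counts(10, 0, 90, 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                "specificity", "f1")]),
               c(accuracy = 1, precision = 1, sensitivity = 1,
                 specificity = 1, f1 = 1))
  expect_warning(m <- compute_metrics(confusion_counts(0, 5, 50, 0)),
                 "sensitivity undefined")
  expect_true(is.na(m$sensitivity))
  expect_false(isTRUE(m$sensitivity == 0))
  m2 <- suppressWarnings(compute_metrics(confusion_counts(0, 0, 50, 0)))
  expect_true(is.na(m2$precision) && is.na(m2$sensitivity) && is.na(m2$f1))
  expect_equal(m2$specificity, 1)
})

test_that("AUROC equals brute-force pair enumeration, with tie handling", {
  expect_equal(compute_auroc(rep(0.4, 8), c(rep("positive", 3), rep("negative", 5))),
               0.5)
  expect_equal(compute_auroc(c(0.9, 0.8, 0.1, 0.2),
                             c("positive", "positive", "negative", "negative")), 1)
  # 6-point toy set with one tied pair, frozen from the enumeration oracle
  s <- c(0.9, 0.5, 0.3, 0.5, 0.2, 0.1)
  l <- c("positive", "positive", "positive", "negative", "negative", "negative")
  # pairs: 0.9 beats all three (3); 0.5 ties 0.5, beats 0.2 and 0.1 (2.5);
  # 0.3 loses to 0.5, beats 0.2 and 0.1 (2) -> 7.5 of 9
  expect_equal(brute_auroc(s, l), 7.5 / 9)
  expect_equal(compute_auroc(s, l), 7.5 / 9)
  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # frequent ties
    l <- c("positive", "negative",
           sample(c("positive", "negative"), n - 2, replace = TRUE))
    expect_equal(compute_auroc(s, l), brute_auroc(s, l))
  }
  expect_error(compute_auroc(c(0.1, 0.9), c("positive", "positive")),
               "at least one positive and one negative")
})
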