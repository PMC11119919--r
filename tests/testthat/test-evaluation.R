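test_that("classification metrics follow their definitions", {
  m <- classification_metrics(confusion_counts(TP = 50, FP = 5, TN = 40, FN = 5))
  expect_equal(unname(m["ACC"]), 0.90, tolerance = 1e-12)
  expect_equal(unname(m["PRE"]), 50 / 55, tolerance = 1e-12)
  expect_equal(unname(m["SEN"]), 50 / 55, tolerance = 1e-12)
  expect_equal(unname(m["SPE"]), 40 / 45, tolerance = 1e-12)
  expect_equal(unname(m["F1"]), 50 / 55, tolerance = 1e-12)
  # perfect classifier
  perfect <- classification_metrics(confusion_counts(10, 0, 10, 0))
  expect_true(all(perfect == 1))
  # undefined sensitivity marker when no positives exist
  none <- classification_metrics(confusion_counts(0, 3, 7, 0))
  expect_true(is.na(none["SEN"]))
})

test_that("duplicate detection flags later-indexed near-identical prototypes", {
  set.seed(8)
  V <- matrix(runif(6 * 5), 6)
  V[4, ] <- V[2, ]                       # same class duplicate pair (2,4)
  V[5, ] <- V[1, ] * 1.0000001           # near-identical cross: (1 A, 5 B)
  fps <- feature_patterns(V, c("A", "A", "A", "A", "B", "B"))
  dup <- detect_duplicates(fps)
  expect_true(dup[4])
  expect_false(dup[2])
  expect_false(dup[5])                   # cross-class pairs are not duplicates
  # orthogonal vectors are never flagged
  fps2 <- feature_patterns(diag(4), rep("A", 4))
  expect_false(any(detect_duplicates(fps2)))
  # permutation invariance of the kept-set size
  perm <- c(3, 1, 4, 2, 6, 5)
  fps3 <- feature_patterns(V[perm, ], fps$class_id[perm])
  expect_equal(sum(detect_duplicates(fps3)), sum(dup))
})

make_verdict <- function(id, truth, pred, mismatch, bg_image, bg_brain,
                         crit2 = TRUE) {
  structure(list(id = id, truth_label = truth, prediction = pred,
                 prediction_correct = truth == pred,
                 criterion1_all_top10_same_class = mismatch == 0,
                 criterion2_all_top10_concept_consistent = crit2,
                 reliable = (truth == pred) && mismatch == 0 && crit2,
                 mismatch_count = mismatch,
                 background_hits = c(image = bg_image, brain = bg_brain)),
            class = "reliability_verdict")
}

test_that("reliability verdicts combine the two criteria with correctness", {
  fps <- fixture_patterns(matrix(0.5, 4, 2), rep(c("A", "B"), each = 2))
  rows <- data.frame(rank = 1:4, class_id = c("A", "A", "B", "A"),
                     peak_row = c(5, 5, 6, 30), peak_col = c(5, 6, 5, 30))
  ex <- structure(list(id = "t", prediction = "A", rows = rows),
                  class = "local_explanation")
  lesion <- matrix(0, 32, 32); lesion[1:10, 1:10] <- 1
  brain <- matrix(1, 32, 32)
  v <- assess_reliability(ex, "A", lesion, brain)
  expect_false(v$criterion1_all_top10_same_class)   # one B row
  expect_equal(v$mismatch_count, 1)
  expect_false(v$criterion2_all_top10_concept_consistent) # peak at (30,30)
  expect_identical(v$reliable, FALSE)
  expect_equal(unname(v$background_hits["brain"]), 1)
  # all same-class rows with in-lesion peaks are reliable
  rows2 <- rows; rows2$class_id <- "A"; rows2$peak_row[4] <- 7; rows2$peak_col[4] <- 7
  ex2 <- structure(list(id = "t2", prediction = "A", rows = rows2),
                   class = "local_explanation")
  expect_true(assess_reliability(ex2, "A", lesion, brain)$reliable)
  # missing masks leave criterion 2 unevaluable
  v3 <- assess_reliability(ex2, "A", NULL, NULL)
  expect_true(is.na(v3$criterion2_all_top10_concept_consistent))
  expect_true(is.na(v3$reliable))
})

test_that("reliability summaries report mean and sample SD per group", {
  vs <- list(make_verdict("a", "A", "A", 0, 0, 0),
             make_verdict("b", "A", "A", 2, 1, 0),
             make_verdict("c", "A", "A", 4, 0, 2),
             make_verdict("d", "B", "A", 8, 1, 1))
  sm <- reliability_summary(vs, top_k = 10)
  allA <- sm[sm$group == "all" & sm$class == "A", ]
  expect_equal(allA$mismatched_mean, 2)
  expect_equal(allA$mismatched_sd, 2)          # sample SD of (0, 2, 4)
  expect_equal(allA$matched_mean + allA$mismatched_mean, 10)
  wrongB <- sm[sm$group == "wrong" & sm$class == "B", ]
  expect_equal(wrongB$n, 1)
  # two-verdict hand case: mismatches {2, 4} -> mean 3, sample SD sqrt(2)
  sm2 <- reliability_summary(vs[2:3], top_k = 10)
  expect_equal(sm2$mismatched_mean[1], 3)
  expect_equal(sm2$mismatched_sd[1], sqrt(2), tolerance = 1e-12)
})

test_that("background-source test matches the signed-rank conventions", {
  # all-tied pairs are undefined
  vs <- replicate(8, make_verdict("x", "A", "A", 0, 1, 1), simplify = FALSE)
  expect_true(is.na(background_source_test(vs)$statistic))
  # pairs (0, 2) x 8: every difference negative, W (positive-rank sum) = 0
  vs2 <- replicate(8, make_verdict("x", "A", "A", 0, 0, 2), simplify = FALSE)
  bt <- background_source_test(vs2)
  expect_equal(unname(bt$statistic), 0)
  expect_equal(bt$n_pairs, 8L)
  # order invariance
  set.seed(2)
  vs3 <- lapply(1:12, function(i)
    make_verdict(paste0("v", i), "A", "A", 0, rpois(1, 1), rpois(1, 2)))
  expect_equal(background_source_test(vs3)$statistic,
               background_source_test(rev(vs3))$statistic)
})
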