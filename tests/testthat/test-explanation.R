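test_that("bounding boxes are tight, inside bounds, and contain the argmax", {
  rr <- matrix(1:64, 64, 64); cc <- t(rr)
  m <- exp(-((rr - 24)^2 + (cc - 44)^2) / (2 * 5^2))   # smooth single bump
  box <- bounding_box_from_map(m, 0.95)
  expect_gte(box[1], 24 - 12); expect_lte(box[3], 24 + 12)
  expect_gte(box[2], 44 - 12); expect_lte(box[4], 44 + 12)
  am <- protopart:::argmax_rowmajor(m)
  expect_true(box[1] <= am[1] && am[1] <= box[3])
  expect_true(box[2] <= am[2] && am[2] <= box[4])
  # constant map falls back to the full image with a warning
  expect_warning(full <- bounding_box_from_map(matrix(1, 8, 8)), "constant")
  expect_equal(full, c(1L, 1L, 8L, 8L))
})

test_that("global explanation reproduces the projection invariant", {
  fx <- fixture_training_data()
  model <- fixture_trained_model()
  ge <- explain_global(model, fx$push)
  expect_length(ge$entries, sum(!model$patterns$flags$pruned))
  for (e in ge$entries) {
    expect_equal(e$pooled_score, log(1 / model$cfg$epsilon), tolerance = 1e-6)
    side <- nrow(e$source_record$pixels)
    expect_true(all(e$box >= 1) && all(e$box <= side))
  }
  # pruned prototypes are absent
  m2 <- model
  m2$patterns$flags$pruned[1] <- TRUE
  ge2 <- explain_global(m2, fx$push)
  expect_length(ge2$entries, length(ge$entries) - 1L)
  # an unprojected model must push first
  expect_error(explain_global(fixture_model_spec(), fx$push), "push")
})

test_that("local explanations reproduce the logits and the prediction", {
  fx <- fixture_training_data()
  model <- fixture_trained_model()
  for (rec in fx$test[1:4]) {
    ex <- explain_local(model, rec)
    # per-class sums of top-k weighted scores equal the head logits
    for (cl in model$classes) {
      rows_cl <- ex$rows[ex$rows$class_id == cl, ]
      k <- min(model$cfg$top_k, nrow(rows_cl))
      manual <- sum(sort(rows_cl$weighted_score, decreasing = TRUE))
      # cross-check against logits recomputed from the full score vector
      expect_equal(unname(ex$logits[cl]),
                   unname(class_logits(ex$full_scores, model$conn,
                                       model$patterns, model$cfg)[cl]),
                   tolerance = 1e-9)
    }
    # the prediction maximizes the reported logits
    expect_equal(ex$prediction,
                 names(ex$logits)[which.max(ex$logits)])
    # rows sorted by similarity, boxes legal and containing the peak
    expect_true(all(diff(ex$rows$similarity) <= 1e-12))
    expect_true(all(ex$rows$row0 <= ex$rows$peak_row &
                    ex$rows$peak_row <= ex$rows$row1))
    expect_true(all(ex$rows$weighted_score ==
                    ex$rows$similarity * ex$rows$weight))
  }
  # determinism including tie order
  e1 <- explain_local(model, fx$test[[1]])
  e2 <- explain_local(model, fx$test[[1]])
  expect_identical(e1$rows, e2$rows)
})

test_that("per-class sums of top-k weighted scores reproduce the logits", {
  fx <- fixture_training_data()
  model <- fixture_trained_model()
  # the fixture has 2 prototypes/class and top_k = 2, so the local top-k
  # rows per class are exactly the logit contributors (cross-class weights
  # are zero after the convex stage)
  expect_true(all(model$conn[cbind(seq_len(4),
    3 - match(model$patterns$class_id, model$classes))] == 0))
  for (rec in fx$test[1:4]) {
    ex <- explain_local(model, rec)
    sa <- score_all(extract_features(model$backbone, rec), model$patterns,
                    model$cfg)
    full <- rep(NA_real_, 4); full[sa$proto_idx] <- sa$scores
    for (cl in model$classes) {
      idx <- which(model$patterns$class_id == cl)
      manual <- sum(sort(full[idx] * model$conn[idx, cl],
                         decreasing = TRUE)[1:model$cfg$top_k])
      expect_equal(unname(ex$logits[cl]), manual, tolerance = 1e-9)
    }
  }
})
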