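test_that("warm-up trains only add-on layers and prototypes", {
  fx <- fixture_training_data()
  model <- fixture_model_spec()
  sch <- fixture_schedule(warmup = 2L, total = 2L, push = integer(0))
  before <- model
  set.seed(sch$seed)
  after <- warmup_stage(model, fx$train, sch)
  for (li in seq_along(before$backbone$layers)) {
    ly <- before$backbone$layers[[li]]
    if (is.null(ly$W)) next
    if (ly$group == "base") {
      expect_identical(after$backbone$layers[[li]]$W, ly$W)
      expect_identical(after$backbone$layers[[li]]$b, ly$b)
    } else {
      expect_false(identical(after$backbone$layers[[li]]$W, ly$W))
    }
  }
  # class connections frozen throughout SGD
  expect_identical(after$conn, before$conn)
  # prototypes moved
  expect_false(identical(after$patterns$vectors, before$patterns$vectors))
  # one log row per epoch
  expect_equal(nrow(after$log), 2L)
})

test_that("joint epochs unfreeze the base stack, deterministically", {
  fx <- fixture_training_data()
  sch <- fixture_schedule()
  model <- fixture_model_spec()
  set.seed(sch$seed)
  m1 <- warmup_stage(model, fx$train, sch)
  base_before <- m1$backbone$layers[[1]]$W
  m2 <- joint_stage_epoch(m1, fx$train, sch)
  expect_false(identical(m2$backbone$layers[[1]]$W, base_before))
  expect_identical(m2$conn, m1$conn)
  # identical seed and data reproduce the same state (up to BLAS
  # reduction-order noise on multithreaded builds)
  set.seed(sch$seed)
  m1b <- warmup_stage(fixture_model_spec(), fx$train, sch)
  m2b <- joint_stage_epoch(m1b, fx$train, sch)
  expect_equal(m2$backbone$layers[[1]]$W, m2b$backbone$layers[[1]]$W,
               tolerance = 1e-4)
  # prototype updates amplify reduction-order noise through the similarity
  # gradient, so the reproducibility band is wider
  expect_equal(m2$patterns$vectors, m2b$patterns$vectors, tolerance = 1e-2)
})

test_that("projection makes prototypes bit-equal nearest same-class patches", {
  fx <- fixture_training_data()
  model <- fixture_trained_model()
  expect_true(model$projected)
  side <- model$backbone$latent_side
  stride <- model$backbone$spatial_stride
  rf <- model$backbone$receptive_field
  ids <- vapply(fx$push, `[[`, "", "id")
  labs <- vapply(fx$push, `[[`, "", "label")
  # independent exhaustive-search oracle over brain-area interior patches
  for (p in seq_len(nrow(model$patterns$vectors))) {
    fp <- model$patterns$vectors[p, ]
    src <- model$patterns$source_image_id[p]
    expect_false(is.na(src))
    rec <- fx$push[[match(src, ids)]]
    expect_equal(rec$label, model$patterns$class_id[p])
    lat <- extract_features(model$backbone, rec)
    pm <- protopart:::latent_patches(lat)
    loc <- model$patterns$source_location[p, ]
    j <- (loc[1] - 1) * side + loc[2]
    # bit-equal to the cited latent patch
    expect_identical(unname(fp), unname(pm[j, ]))
    # pooled self-activation equals the zero-distance similarity
    am <- activation_map(lat, fp, model$cfg)
    expect_equal(am$pooled_score, log(1 / model$cfg$epsilon),
                 tolerance = 1e-9)
  }
  # small-instance assignment matches a brute-force search for one prototype
  p <- 1L
  fp_pre <- model$patterns$vectors[p, ]
  best <- list(d2 = Inf)
  for (i in which(labs == model$patterns$class_id[p])) {
    pm <- protopart:::latent_patches(extract_features(model$backbone,
                                                      fx$push[[i]]))
    ok <- protopart:::brain_patch_mask(fx$push[[i]], side, stride, rf)
    for (j in which(ok)) {
      d2 <- sum((pm[j, ] - fp_pre)^2)
      if (d2 < best$d2) best <- list(d2 = d2, img = i, patch = j)
    }
  }
  # re-projecting an already-projected prototype is idempotent (d2 = 0 at
  # its own recorded patch)
  expect_equal(best$d2, 0, tolerance = 1e-12)
  expect_equal(ids[best$img], model$patterns$source_image_id[p])
})

test_that("convex stage zeroes cross-class weights without touching features", {
  fx <- fixture_training_data()
  model <- fixture_trained_model()
  sch <- fixture_schedule()
  # perturb with harmful positive cross-class connections so the stage has
  # work to do (an A prototype boosting the B logit adds class-blind noise)
  model$conn[1, 2] <- 0.5
  model$conn[3, 1] <- 0.4
  before_layers <- model$backbone$layers
  before_proto <- model$patterns$vectors
  same <- outer(model$patterns$class_id, colnames(model$conn), "==")
  # CE on cached scores before
  S <- protopart:::model_score_batch(model, fx$train)$scores
  labs <- vapply(fx$train, `[[`, "", "label")
  ce_of <- function(m) cross_entropy_term(protopart:::model_logits(m, S), labs)
  ce_before <- ce_of(model)
  m2 <- convex_last_layer(model, fx$train, sch)
  expect_true(all(m2$conn[!same] == 0))
  expect_true(all(m2$conn[same] >= 0))
  expect_identical(m2$backbone$layers, before_layers)
  expect_identical(m2$patterns$vectors, before_proto)
  # the convex fit plus clamping does not make training CE worse here
  expect_lte(ce_of(m2), ce_before + 1e-8)
})

test_that("fit orchestrates stages, pushes, and is seed-reproducible", {
  fx <- fixture_training_data()
  model <- fit(fixture_model_spec(), fx$train, fx$push,
               fixture_schedule(total = 4L, push = c(3L, 4L)))
  expect_true(model$projected)
  expect_equal(nrow(model$log), 4L)
  expect_true(all(!is.na(model$patterns$source_image_id)))
  pred1 <- predict_dataset(model, fx$test)
  model2 <- fit(fixture_model_spec(), fx$train, fx$push,
                fixture_schedule(total = 4L, push = c(3L, 4L)))
  pred2 <- predict_dataset(model2, fx$test)
  expect_identical(pred1$predicted, pred2$predicted)
  expect_equal(pred1$A, pred2$A, tolerance = 1e-3)
  expect_equal(pred1$B, pred2$B, tolerance = 1e-3)
})

test_that("schedule validation rejects pushes inside the warm-up", {
  expect_error(training_schedule(warmup_epochs = 5, total_epochs = 10,
                                 push_epochs = 4), "push_epochs")
})
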