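test_that("z-score normalization standardizes brain pixels and zeroes background", {
  rec <- fixture_phantom("A", seed = 4)
  z <- zscore_normalize(rec)
  v <- z$pixels[z$brain_mask > 0]
  expect_lt(abs(mean(v)), 1e-6)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
  expect_true(all(z$pixels[z$brain_mask == 0] == 0))
  # idempotence up to tolerance
  z2 <- zscore_normalize(z)
  expect_lt(max(abs(z2$pixels - z$pixels)), 1e-6)
  # two-point symmetry on a minimal record
  tiny <- image_record(matrix(c(2, 4, 0, 0), 2), "A",
                       brain_mask = matrix(c(1, 1, 0, 0), 2))
  zt <- zscore_normalize(tiny)
  expect_equal(zt$pixels[1:2], c(-1, 1))
  # constant brain region errors
  const <- image_record(matrix(1, 4, 4), "A", brain_mask = matrix(1, 4, 4))
  expect_error(zscore_normalize(const), "degenerate")
})

test_that("background cropping returns the tight brain bounding box", {
  px <- matrix(0, 30, 30)
  px[10:20, 5:15] <- 1
  rec <- image_record(px, "A")
  cr <- crop_background(rec)
  expect_identical(dim(cr$pixels), c(11L, 11L))
  # fully nonzero image is unchanged
  full <- image_record(matrix(1:16 / 16, 4), "A")
  expect_identical(crop_background(full)$pixels, full$pixels)
  # every nonzero input pixel survives the crop
  ph <- fixture_phantom("B", seed = 9)
  crp <- crop_background(ph)
  expect_equal(sort(crp$pixels[crp$pixels != 0]),
               sort(ph$pixels[ph$pixels != 0]))
  expect_error(crop_background(image_record(matrix(0, 4, 4), "A")), "empty")
})

test_that("resizing yields the requested side and binary masks", {
  rec <- fixture_phantom("A", seed = 2)
  rs <- resize_image(crop_background(rec), 224)
  expect_identical(dim(rs$pixels), c(224L, 224L))
  expect_true(all(rs$lesion_mask %in% c(0, 1)))
  expect_true(all(rs$brain_mask %in% c(0, 1)))
  # identity when already at the requested side
  expect_identical(resize_image(rec, 64)$pixels, rec$pixels)
})

test_that("six-fold augmentation emits six seeded copies per record within limits", {
  recs <- generate_dataset(5, 64, seed = 3)   # 10 records
  aug <- augment_six_fold(recs, augment_spec(seed = 31))
  expect_length(aug, 60)                      # six augmented per original
  # angles encoded in the transform strings stay within the limits
  rots <- grep("^rot", vapply(aug, `[[`, "", "transform"), value = TRUE)
  angles <- as.numeric(sub("rot", "", rots))
  expect_true(all(abs(angles) <= 20))
  shears <- as.numeric(sub("shear", "",
    grep("^shear", vapply(aug, `[[`, "", "transform"), value = TRUE)))
  expect_true(all(abs(shears) <= 10))
  # determinism
  aug2 <- augment_six_fold(recs, augment_spec(seed = 31))
  expect_identical(lapply(aug, `[[`, "pixels"), lapply(aug2, `[[`, "pixels"))
  # labels and lineage preserved; masks stay binary under the same map
  for (a in aug[1:6]) {
    expect_equal(a$label, recs[[1]]$label)
    expect_equal(a$source_id, recs[[1]]$id)
    expect_true(all(a$lesion_mask %in% c(0, 1)))
  }
})

test_that("rotation by 0 degrees is the identity and masks follow pixels", {
  rec <- fixture_phantom("A", seed = 6)
  same <- protopart:::warp_record(rec, diag(2), "identity", "_id")
  expect_lt(max(abs(same$pixels - rec$pixels)), 1e-12)
  expect_identical(same$lesion_mask, rec$lesion_mask)
})

test_that("split respects fractions, disjointness, and the push quota", {
  recs <- generate_dataset(50, 64, seed = 13)   # 100 records
  sp <- split_dataset(recs, split_spec(0.70, push_per_class = 30, seed = 5))
  expect_length(sp$train, 70)
  expect_length(sp$test, 30)
  expect_length(sp$push, 60)
  ids_train <- vapply(sp$train, `[[`, "", "id")
  ids_test <- vapply(sp$test, `[[`, "", "id")
  expect_length(intersect(ids_train, ids_test), 0)
  # push is drawn from the training set, 30 per class
  ids_push <- vapply(sp$push, `[[`, "", "id")
  expect_true(all(ids_push %in% ids_train))
  expect_equal(as.integer(table(vapply(sp$push, `[[`, "", "label"))),
               c(30L, 30L))
  # too-small training class errors
  expect_error(split_dataset(recs[1:10], split_spec(0.5, push_per_class = 30)),
               "configuration error")
})
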