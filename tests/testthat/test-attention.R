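test_that("patch distances match hand values and the loop oracle", {
  # D=2: patch (1,2) vs prototype (0,0) -> squared distance 5
  lat <- structure(list(values = array(c(1, 2), c(2, 1, 1)),
                        latent_side = 1L, spatial_stride = 1),
                   class = "latent_grid")
  expect_equal(patch_distances(lat, c(0, 0))[1, 1], 5)
  # zero distance at the matching location
  lat2 <- fixture_latent(D = 4, side = 3, seed = 2)
  fp <- lat2$values[, 2, 3]
  d2 <- patch_distances(lat2, fp)
  expect_equal(d2[2, 3], 0)
  expect_gte(min(d2), 0)
  # random instances against the brute-force loop oracle
  for (seed in 1:5) {
    lt <- fixture_latent(D = 8, side = 5, seed = seed)
    fpv <- runif(8)
    got <- patch_distances(lt, fpv)
    ref <- matrix(0, 5, 5)
    for (r in 1:5) for (c in 1:5)
      ref[r, c] <- sum((lt$values[, r, c] - fpv)^2)
    expect_lt(max(abs(got - ref)), 1e-10)
  }
  expect_error(patch_distances(lat2, c(1, 2)), "depth mismatch")
})

test_that("similarity transform has its closed form, limit, and monotonicity", {
  cfg <- attention_config(epsilon = 1e-4)
  expect_equal(similarity_from_distance(0, cfg), log(1e4), tolerance = 1e-12)
  # decreasing toward 0 from above
  expect_gt(similarity_from_distance(1e6, cfg), 0)
  expect_lt(similarity_from_distance(1e6, cfg), 1e-5)
  set.seed(9)
  a <- runif(1000, 0, 50); b <- a + runif(1000, 1e-6, 10)
  expect_true(all(similarity_from_distance(a, cfg) >
                  similarity_from_distance(b, cfg)))
})

test_that("activation maps pool their maximum with a deterministic tie-break", {
  lat <- fixture_latent(D = 6, side = 4, seed = 3)
  cfg <- attention_config()
  fp <- lat$values[, 3, 2]
  am <- activation_map(lat, fp, cfg)
  expect_equal(am$argmax_latent, c(3L, 2L))
  expect_equal(am$pooled_score, log(1 / cfg$epsilon), tolerance = 1e-9)
  expect_equal(am$pooled_score, max(am$similarity))
  # constant latent -> constant similarity grid
  clat <- structure(list(values = array(0.4, c(3, 4, 4)), latent_side = 4L,
                         spatial_stride = 8), class = "latent_grid")
  amc <- activation_map(clat, rep(0.1, 3), cfg)
  expect_equal(max(amc$similarity), min(amc$similarity))
  expect_equal(amc$argmax_latent, c(1L, 1L))  # row-major first tie
  # full oracle equivalence on random instances
  for (seed in 6:10) {
    lt <- fixture_latent(D = 8, side = 5, seed = seed)
    fpv <- runif(8)
    am2 <- activation_map(lt, fpv, cfg)
    orc <- oracle_attention(lt$values, fpv, cfg$epsilon)
    expect_lt(max(abs(am2$similarity - orc$sim)), 1e-10)
    expect_equal(am2$pooled_score, orc$pooled, tolerance = 1e-10)
  }
})

test_that("upsampling preserves constants, bounds, and peak location", {
  cfg <- attention_config()
  clat <- structure(list(values = array(0.4, c(3, 7, 7)), latent_side = 7L,
                         spatial_stride = 32), class = "latent_grid")
  amc <- upsample_map(activation_map(clat, rep(0.3, 3), cfg), 224)
  expect_identical(dim(amc$upsampled), c(224L, 224L))
  expect_lt(diff(range(amc$upsampled)), 1e-12)
  # single-peak map: upsampled argmax within one latent cell of the peak
  lat <- fixture_latent(D = 4, side = 4, seed = 12, stride = 16)
  fp <- lat$values[, 2, 3]
  am <- upsample_map(activation_map(lat, fp), 64)
  mapped <- (c(2, 3) - 0.5) * 16 + 0.5
  expect_lt(max(abs(am$argmax_pixel - mapped)), 16)
  # no overshoot beyond the input range
  expect_gte(min(am$upsampled), min(am$similarity) - 1e-12)
  expect_lte(max(am$upsampled), max(am$similarity) + 1e-12)
})

test_that("score_all covers unpruned prototypes in stable order", {
  lat <- fixture_latent(D = 4, side = 3, seed = 5)
  set.seed(44)
  fps <- feature_patterns(matrix(runif(10 * 4), 10), rep(c("A", "B"), each = 5))
  sa <- score_all(lat, fps)
  expect_length(sa$scores, 10)
  # pruned prototypes are skipped
  fps$flags$pruned[c(2, 7, 9)] <- TRUE
  sa2 <- score_all(lat, fps)
  expect_length(sa2$scores, 7)
  expect_false(any(c(2, 7, 9) %in% sa2$proto_idx))
  # permuting prototype order leaves the score multiset unchanged
  perm <- sample(10)
  fps3 <- feature_patterns(fps$vectors[perm, ], fps$class_id[perm])
  sa3 <- score_all(lat, fps3)
  expect_equal(unname(sort(sa3$scores)), unname(sort(sa$scores)))
  fps$flags$pruned <- rep(TRUE, 10)
  expect_error(score_all(lat, fps), "empty model")
})
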