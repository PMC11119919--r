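test_that("cross-entropy matches the direct softmax formula", {
  # equal two-class logits cost ln 2 per image
  lg <- matrix(c(1, 1), 1, dimnames = list(NULL, c("A", "B")))
  expect_equal(cross_entropy_term(lg, "A"), log(2), tolerance = 1e-12)
  # overwhelming correct logit drives the loss toward zero
  expect_lt(cross_entropy_term(matrix(c(50, 0), 1,
            dimnames = list(NULL, c("A", "B"))), "A"), 1e-12)
  # random batch vs hand-computed -log softmax
  set.seed(5)
  lg <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("A", "B")))
  labs <- sample(c("A", "B"), 10, TRUE)
  ref <- mean(vapply(1:10, function(i)
    -log(exp(lg[i, labs[i]]) / sum(exp(lg[i, ]))), 0))
  expect_equal(cross_entropy_term(lg, labs), ref, tolerance = 1e-6)
  expect_error(cross_entropy_term(lg, rep("C", 10)), "label")
})

test_that("cluster and separation losses equal the brute-force min-of-min", {
  for (seed in 1:4) {
    fx <- make_loss_fixture(seed)
    ref_min <- function(i, same) {
      keep <- if (same) fx$fps$class_id == fx$labels[i] else
        fx$fps$class_id != fx$labels[i]
      best <- Inf
      for (p in which(keep)) for (j in seq_len(nrow(fx$latents[[i]])))
        best <- min(best, sum((fx$latents[[i]][j, ] - fx$fps$vectors[p, ])^2))
      best
    }
    clst <- cluster_loss(fx$latents, fx$labels, fx$fps)
    sep <- separation_loss(fx$latents, fx$labels, fx$fps)
    expect_equal(clst, mean(vapply(seq_along(fx$latents),
                                   ref_min, 0, same = TRUE)),
                 tolerance = 1e-10)
    expect_equal(sep, -mean(vapply(seq_along(fx$latents),
                                   ref_min, 0, same = FALSE)),
                 tolerance = 1e-10)
    expect_gte(clst, 0)
    expect_lte(sep, 0)
  }
})

test_that("a prototype equal to a patch of every image zeroes the cluster loss", {
  fx <- make_loss_fixture(7, n = 2)
  fx$fps$vectors[1, ] <- fx$latents[[1]][4, ]
  fx$fps$vectors[4, ] <- fx$latents[[2]][4, ]   # class B prototype
  fx$latents[[2]][7, ] <- fx$fps$vectors[4, ]
  fx$latents[[1]][2, ] <- fx$fps$vectors[1, ]
  expect_equal(cluster_loss(fx$latents, fx$labels, fx$fps), 0)
})

test_that("single-image cluster min and separation sign follow hand values", {
  D <- 3
  lat <- matrix(0, 2, D)                      # two zero patches
  fpv <- rbind(rep(2 / sqrt(3), D),           # d2 = 4
               rep(3 / sqrt(3), D),           # d2 = 9
               rep(3 / sqrt(3), D))           # other class, d2 = 9
  fps <- feature_patterns(fpv, c("A", "A", "B"))
  expect_equal(cluster_loss(list(lat), "A", fps), 4, tolerance = 1e-12)
  expect_equal(separation_loss(list(lat), "A", fps), -9, tolerance = 1e-12)
})

test_that("total loss composes the weighted terms", {
  bl <- total_loss(1, 2, -3, loss_weights(0.8, 0.08))
  expect_equal(bl$total, 2.36, tolerance = 1e-12)
  expect_equal(total_loss(5, 2, -3, loss_weights(0, 0))$total, 5)
})

test_that("moving a prototype toward its closest patch lowers the cluster loss", {
  fx <- make_loss_fixture(9, n = 1)
  base <- cluster_loss(fx$latents, fx$labels, fx$fps)
  # find the argmin (prototype, patch) pair and step the prototype toward it
  keep <- which(fx$fps$class_id == fx$labels[1])
  best <- c(Inf, NA, NA)
  for (p in keep) for (j in seq_len(nrow(fx$latents[[1]]))) {
    d2 <- sum((fx$latents[[1]][j, ] - fx$fps$vectors[p, ])^2)
    if (d2 < best[1]) best <- c(d2, p, j)
  }
  fx$fps$vectors[best[2], ] <- fx$fps$vectors[best[2], ] +
    0.01 * (fx$latents[[1]][best[3], ] - fx$fps$vectors[best[2], ])
  expect_lt(cluster_loss(fx$latents, fx$labels, fx$fps), base)
})
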