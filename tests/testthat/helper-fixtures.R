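# Shared test fixtures, built in code.

fixture_phantom <- function(class_label = "A", seed = 7L, size = 64L) {
  generate_phantom(phantom_spec(image_size = size, class_label = class_label,
                                lesion_radius = 10, ring_width = 3,
                                haze_radius = 16, seed = seed))
}

# A small latent grid filled with reproducible uniform values.
fixture_latent <- function(D = 4L, side = 3L, seed = 1L, stride = 8) {
  set.seed(seed)
  structure(list(values = array(runif(D * side * side), c(D, side, side)),
                 latent_side = side, spatial_stride = stride),
            class = "latent_grid")
}

# Brute-force similarity oracle: triple loop over grid cells and depth,
# independent of the package's vectorized path.
oracle_attention <- function(latent_arr, fp, eps) {
  D <- dim(latent_arr)[1]; H <- dim(latent_arr)[2]; W <- dim(latent_arr)[3]
  sim <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    d2 <- 0
    for (k in seq_len(D)) d2 <- d2 + (latent_arr[k, r, c] - fp[k])^2
    sim[r, c] <- log((d2 + 1) / (d2 + eps))
  }
  list(sim = sim, pooled = max(sim))
}

# Direct 3x3 same-padding convolution + activation, by explicit loops.
oracle_conv3 <- function(img_arr, Wm, b, act = "relu") {
  H <- dim(img_arr)[1]; W <- dim(img_arr)[2]; Cin <- dim(img_arr)[3]
  Cout <- length(b)
  out <- array(0, c(H, W, Cout))
  for (r in seq_len(H)) for (c in seq_len(W)) for (co in seq_len(Cout)) {
    acc <- b[co]
    for (dr in -1:1) for (dc in -1:1) for (ch in seq_len(Cin)) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
        k <- (dc + 1) * 3 + (dr + 1) + 1       # package weight-row layout
        acc <- acc + img_arr[rr, cc, ch] * Wm[(k - 1) * Cin + ch, co]
      }
    }
    out[r, c, co] <- if (act == "relu") max(acc, 0) else acc
  }
  out
}

# Tiny trained-free model with injected prototypes for head/logit tests.
fixture_patterns <- function(vectors, class_id) feature_patterns(vectors, class_id)

# Random latents + prototypes for loss-contract tests.
make_loss_fixture <- function(seed = 1, n = 4, D = 5, side = 3, per = 3) {
  set.seed(seed)
  latents <- lapply(seq_len(n), function(i)
    matrix(runif(side * side * D), side * side, D))
  labels <- rep(c("A", "B"), length.out = n)
  fps <- feature_patterns(matrix(runif(2 * per * D), ncol = D),
                          rep(c("A", "B"), each = per))
  list(latents = latents, labels = labels, fps = fps)
}
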