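# Minimal convolutional network engine on BLAS matrix ops.
#
# Feature maps are stored as dense matrices of shape (B*H*W) x C with pixels
# in row-major order within each image: row((i,r,c)) = (i-1)*H*W + (r-1)*W + c.
# 3x3 convolutions use im2col (9 indexed copies) followed by one GEMM; their
# backward pass is the transposed GEMM plus 9 indexed accumulations (col2im).
# All layers are deterministic; max-pool ties break at the first (row-major)
# maximum.

# Index of every interior pixel inside the zero-padded (pad=1) layout, plus
# the 9 neighbour offsets.  Cached per (B, H, W) in the calling layer.
nn_pad_index <- function(B, H, W) {
  Hp <- H + 2L; Wp <- W + 2L
  r <- rep(rep(seq_len(H), each = W), times = B)
  c <- rep(rep(seq_len(W), times = H), times = B)
  i <- rep(seq_len(B), each = H * W)
  idx0 <- (i - 1L) * (Hp * Wp) + r * Wp + c + 1L
  offs <- as.integer(outer((-1:1) * Wp, -1:1, "+"))  # column-major: (dr,dc)
  list(idx0 = idx0, offs = offs, Hp = Hp, Wp = Wp)
}

nn_im2col <- function(X, B, H, W, pi) {
  C <- ncol(X)
  Xp <- matrix(0, B * pi$Hp * pi$Wp, C)
  Xp[pi$idx0, ] <- X
  cols <- matrix(0, B * H * W, 9L * C)
  for (k in 1:9)
    cols[, ((k - 1L) * C + 1L):(k * C)] <- Xp[pi$idx0 + pi$offs[k], ]
  cols
}

# 3x3 same-padding convolution + ReLU. W is (9*Cin) x Cout, b length Cout.
nn_conv3_fwd <- function(X, B, H, W, Wm, b, train = FALSE) {
  pi <- nn_pad_index(B, H, W)
  cols <- nn_im2col(X, B, H, W, pi)
  Y <- cols %*% Wm
  for (j in seq_along(b)) Y[, j] <- Y[, j] + b[j]
  mask <- Y > 0
  Y[!mask] <- 0
  cache <- if (train) list(cols = cols, mask = mask, pi = pi,
                           B = B, H = H, W = W, Cin = ncol(X)) else NULL
  list(Y = Y, cache = cache)
}

nn_conv3_bwd <- function(dY, Wm, cache) {
  dY[!cache$mask] <- 0
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  dcols <- tcrossprod(dY, Wm)                      # (B*H*W) x (9*Cin)
  C <- cache$Cin
  pi <- cache$pi
  dXp <- matrix(0, cache$B * pi$Hp * pi$Wp, C)
  for (k in 1:9) {
    tgt <- pi$idx0 + pi$offs[k]
    dXp[tgt, ] <- dXp[tgt, ] + dcols[, ((k - 1L) * C + 1L):(k * C)]
  }
  list(dX = dXp[pi$idx0, , drop = FALSE], dW = dW, db = db)
}

# 1x1 convolution: a per-pixel linear map with ReLU or sigmoid activation.
# The sigmoid variant bounds the latent space in (0,1) so prototypes and
# latent patches live in the same box.
nn_conv1_fwd <- function(X, Wm, b, act = "relu", train = FALSE) {
  Y <- X %*% Wm
  for (j in seq_along(b)) Y[, j] <- Y[, j] + b[j]
  if (act == "sigmoid") {
    Y <- 1 / (1 + exp(-Y))
    cache <- if (train) list(X = X, Y = Y, act = act) else NULL
  } else {
    mask <- Y > 0
    Y[!mask] <- 0
    cache <- if (train) list(X = X, mask = mask, act = act) else NULL
  }
  list(Y = Y, cache = cache)
}

nn_conv1_bwd <- function(dY, Wm, cache) {
  if (cache$act == "sigmoid") {
    dY <- dY * cache$Y * (1 - cache$Y)
  } else {
    dY[!cache$mask] <- 0
  }
  list(dX = tcrossprod(dY, Wm), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# Indices of the 4 children of each 2x2 pooling window.
nn_pool_index <- function(B, H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  r2 <- rep(rep(seq_len(H2), each = W2), times = B)
  c2 <- rep(rep(seq_len(W2), times = H2), times = B)
  i <- rep(seq_len(B), each = H2 * W2)
  base <- (i - 1L) * (H * W)
  tl <- base + (2L * r2 - 2L) * W + (2L * c2 - 1L)
  list(tl, tl + 1L, tl + W, tl + W + 1L)
}

nn_pool_fwd <- function(X, B, H, W, train = FALSE) {
  ix <- nn_pool_index(B, H, W)
  Y <- X[ix[[1]], , drop = FALSE]
  which <- matrix(1L, nrow(Y), ncol(Y))
  for (k in 2:4) {
    Xk <- X[ix[[k]], , drop = FALSE]
    sel <- Xk > Y                 # strict: ties keep the earliest child
    Y[sel] <- Xk[sel]
    which[sel] <- k
  }
  list(Y = Y, cache = if (train) list(ix = ix, which = which,
                                      nX = B * H * W) else NULL)
}

nn_pool_bwd <- function(dY, cache, C) {
  dX <- matrix(0, cache$nX, C)
  nOut <- nrow(dY)
  for (k in 1:4) {
    sel <- which(cache$which == k)
    if (!length(sel)) next
    jrow <- ((sel - 1L) %% nOut) + 1L
    jcol <- ((sel - 1L) %/% nOut) + 1L
    dX[(jcol - 1L) * cache$nX + cache$ix[[k]][jrow]] <- dY[sel]
  }
  dX
}

# Kaiming-uniform initialization for a fan_in x fan_out weight matrix.
nn_init_kaiming <- function(fan_in, fan_out) {
  bound <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -bound, bound), fan_in, fan_out)
}
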