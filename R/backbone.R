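#' Convolutional feature extractor
#'
#' Builds the feature extractor that maps a grayscale input image to a
#' non-negative latent grid of depth `D`: a base convolutional stack (a
#' VGG16-style 13-layer stack or a small 4-block `tiny` network) followed by
#' two additional 1x1 convolutional layers, with a ReLU after every
#' convolution.  The base stack and the two add-on layers form separate
#' trainable parameter groups so the training schedule can warm up the add-on
#' layers while the base is frozen.
#'
#' The first add-on layer uses a ReLU; the second uses a sigmoid, which
#' bounds every latent entry in (0, 1) so that latent patches and the
#' prototype vectors (initialized uniformly in the unit box) share one
#' bounded space — squared patch-prototype distances are then at most `D`
#' and the cluster/separation losses operate on a well-conditioned scale.
#'
#' Bases:
#' * `vgg16_random`: the VGG16 convolutional stack (64-64 / 128-128 /
#'   256-256-256 / 512-512-512 / 512-512-512 with five 2x2 max-pools) at
#'   random initialization; input 224 gives a 7x7 latent grid.  Grayscale
#'   inputs are replicated to three channels.  Add-on layers map 512 -> 256 ->
#'   `D`.
#' * `vgg16_pretrained`: same architecture with ImageNet weights; raises an
#'   error when no checkpoint is available (no download is attempted).
#' * `tiny`: two 3x3 conv blocks (16, 32 channels), each followed by a 2x2
#'   max-pool, for 64x64 inputs -> 16x16 latent grid (4-pixel stride,
#'   10-pixel receptive field).  The small receptive field keeps part-level
#'   attention spatially honest: a latent cell represents one local texture
#'   (a lesion core, an enhancing rim segment, halo tissue), so individual
#'   lesion parts are resolvable as distinct prototype targets.  Add-on
#'   layers map 32 -> 128 -> `D`.  Small enough to train on a desktop CPU.
#'
#' @param spec A [backbone_spec()].
#' @return A `pp_backbone` handle with elements `layers` (weights, each
#'   tagged with its parameter group `base` or `addon`), `latent_dim`,
#'   `latent_side` and `spatial_stride`.
#' @export
build_backbone <- function(spec = backbone_spec()) {
  base_defs <- list(
    tiny = list(in_channels = 1L, convs = c(16, 32),
                pool_after = c(TRUE, TRUE), addon_mid = 128L),
    vgg16_random = list(in_channels = 3L,
                        convs = c(64, 64, 128, 128, 256, 256, 256,
                                  512, 512, 512, 512, 512, 512),
                        pool_after = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE,
                                       TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                                       TRUE),
                        addon_mid = 256L)
  )
  if (spec$base == "vgg16_pretrained")
    stop("pretrained VGG16 weights are not available offline; ",
         "use base = \"vgg16_random\" or \"tiny\"")
  def <- base_defs[[spec$base]]
  if (is.null(def)) stop("unknown backbone base: ", spec$base)

  layers <- list()
  cin <- def$in_channels
  side <- spec$input_side
  rf <- 1; jump <- 1                  # receptive-field bookkeeping
  for (i in seq_along(def$convs)) {
    cout <- def$convs[i]
    layers[[length(layers) + 1L]] <- list(
      kind = "conv3", group = "base",
      W = nn_init_kaiming(9L * cin, cout), b = numeric(cout))
    cin <- cout
    rf <- rf + 2 * jump
    if (def$pool_after[i]) {
      layers[[length(layers) + 1L]] <- list(kind = "pool")
      side <- side %/% 2L
      rf <- rf + jump
      jump <- 2 * jump
    }
  }
  mid <- if (!is.null(spec$addon_mid)) spec$addon_mid else def$addon_mid
  layers[[length(layers) + 1L]] <- list(
    kind = "conv1", group = "addon", act = "relu",
    W = nn_init_kaiming(cin, mid), b = numeric(mid))
  layers[[length(layers) + 1L]] <- list(
    kind = "conv1", group = "addon", act = "sigmoid",
    W = nn_init_kaiming(mid, spec$out_channels), b = numeric(spec$out_channels))

  structure(list(spec = spec, layers = layers,
                 in_channels = def$in_channels,
                 latent_dim = as.integer(spec$out_channels),
                 latent_side = as.integer(side),
                 spatial_stride = spec$input_side / side,
                 receptive_field = rf),
            class = "pp_backbone")
}

#' Backbone specification
#'
#' @param base One of `"tiny"`, `"vgg16_random"`, `"vgg16_pretrained"`.
#' @param out_channels Latent depth `D` produced by the add-on layers.
#' @param input_side Expected input side in pixels (224 for VGG16 bases, 64
#'   for `tiny`).
#' @param addon_mid Width of the intermediate add-on 1x1 layer; `NULL` uses
#'   the base default (256 for VGG16, 128 for tiny).
#' @export
backbone_spec <- function(base = c("tiny", "vgg16_random", "vgg16_pretrained"),
                          out_channels = 128L,
                          input_side = if (match.arg(base) == "tiny") 64L else 224L,
                          addon_mid = NULL) {
  base <- match.arg(base)
  stopifnot(out_channels >= 1)
  structure(list(base = base, out_channels = as.integer(out_channels),
                 input_side = as.integer(input_side), addon_mid = addon_mid),
            class = "backbone_spec")
}

#' @export
print.pp_backbone <- function(x, ...) {
  cat(sprintf("<pp_backbone %s> input %dx%d -> latent %dx%dx%d (stride %g)\n",
              x$spec$base, x$spec$input_side, x$spec$input_side,
              x$latent_dim, x$latent_side, x$latent_side, x$spatial_stride))
  invisible(x)
}

# Forward pass over a batch.  X is (B * side^2) x in_channels, row-major
# pixels within each image.  Returns the latent matrix (B * Hl * Wl) x D and,
# when train = TRUE, the per-layer caches for backprop.
backbone_forward <- function(handle, X, B, train = FALSE) {
  H <- handle$spec$input_side; W <- H
  caches <- if (train) vector("list", length(handle$layers)) else NULL
  for (li in seq_along(handle$layers)) {
    ly <- handle$layers[[li]]
    if (ly$kind == "conv3") {
      r <- nn_conv3_fwd(X, B, H, W, ly$W, ly$b, train)
    } else if (ly$kind == "conv1") {
      r <- nn_conv1_fwd(X, ly$W, ly$b, ly$act, train)
    } else {
      r <- nn_pool_fwd(X, B, H, W, train)
      r$cache <- c(r$cache, list(C = ncol(X)))
      H <- H %/% 2L; W <- W %/% 2L
    }
    X <- r$Y
    if (train) caches[[li]] <- r$cache
  }
  list(latent = X, caches = caches, Hl = H, Wl = W)
}

# Backward pass: dLatent is the gradient at the latent output; returns a list
# of per-layer gradients (dW, db) aligned with handle$layers.
backbone_backward <- function(handle, caches, dLatent) {
  grads <- vector("list", length(handle$layers))
  dY <- dLatent
  for (li in rev(seq_along(handle$layers))) {
    ly <- handle$layers[[li]]
    if (ly$kind == "conv3") {
      r <- nn_conv3_bwd(dY, ly$W, caches[[li]])
      grads[[li]] <- list(dW = r$dW, db = r$db)
      dY <- r$dX
    } else if (ly$kind == "conv1") {
      r <- nn_conv1_bwd(dY, ly$W, caches[[li]])
      grads[[li]] <- list(dW = r$dW, db = r$db)
      dY <- r$dX
    } else {
      dY <- nn_pool_bwd(dY, caches[[li]], caches[[li]]$C)
    }
  }
  grads
}

# Stack image records into the (B * side^2) x C input matrix the backbone
# consumes, replicating grayscale to the channel count the base expects.
records_to_input <- function(handle, records) {
  side <- handle$spec$input_side
  B <- length(records)
  X <- matrix(0, B * side * side, handle$in_channels)
  for (i in seq_len(B)) {
    px <- records[[i]]$pixels
    if (!all(dim(px) == c(side, side)))
      stop(sprintf("input error: image %s is %dx%d, backbone expects %dx%d",
                   records[[i]]$id, nrow(px), ncol(px), side, side))
    v <- as.numeric(t(px))                 # row-major vector
    rows <- ((i - 1L) * side * side + 1L):(i * side * side)
    for (ch in seq_len(handle$in_channels)) X[rows, ch] <- v
  }
  X
}

#' Extract the latent grid for one image
#'
#' Runs the backbone on a single image and returns the latent feature grid.
#'
#' @param handle A `pp_backbone` from [build_backbone()].
#' @param image A 2-D numeric matrix (side x side) or an [image_record()].
#' @return A `latent_grid`: list with `values` (array `D x Hl x Wl`, all
#'   entries >= 0), `latent_side` and `spatial_stride`.
#' @export
extract_features <- function(handle, image) {
  rec <- if (inherits(image, "image_record")) image else
    image_record(image, label = "?", id = "adhoc")
  X <- records_to_input(handle, list(rec))
  fw <- backbone_forward(handle, X, 1L)
  latent_grid_from_matrix(fw$latent, handle)
}

# Convert one image's latent rows ((Hl*Wl) x D, row-major pixels) to the
# D x Hl x Wl array exposed to users.
latent_grid_from_matrix <- function(lat, handle) {
  Hl <- handle$latent_side; Wl <- Hl; D <- handle$latent_dim
  arr <- array(0, c(D, Hl, Wl))
  for (r in seq_len(Hl))
    arr[, r, ] <- t(lat[((r - 1L) * Wl + 1L):(r * Wl), , drop = FALSE])
  structure(list(values = arr, latent_side = Hl,
                 spatial_stride = handle$spatial_stride),
            class = "latent_grid")
}

# Flatten a latent_grid (or keep a patch matrix as-is) into (Hl*Wl) x D
# row-major patch rows.
latent_patches <- function(latent) {
  if (is.matrix(latent)) return(latent)
  stopifnot(inherits(latent, "latent_grid"))
  arr <- latent$values
  D <- dim(arr)[1]; Hl <- dim(arr)[2]; Wl <- dim(arr)[3]
  out <- matrix(0, Hl * Wl, D)
  for (r in seq_len(Hl))
    out[((r - 1L) * Wl + 1L):(r * Wl), ] <- t(arr[, r, ])
  out
}
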