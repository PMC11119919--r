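#' Multi-part attention: prototype similarity maps and pooled scores
#'
#' Each feature pattern (prototype) is a depth-`D` latent vector compared
#' against every spatial patch of an image's latent grid.  The squared L2
#' distance `d2` between a patch and a prototype is mapped to a similarity
#' `log((d2 + 1) / (d2 + epsilon))`, a strictly decreasing transform that is
#' large when the patch nearly coincides with the prototype and tends to 0 as
#' the distance grows.  The spatial grid of similarities is the prototype's
#' activation map; its global maximum is the prototype's pooled similarity
#' score for the image, and the upsampled map localizes the most similar
#' image part.
#'
#' @name attention
NULL

#' Attention configuration
#'
#' @param epsilon Small positive stabilizer in the similarity transform; the
#'   similarity at distance zero is `log(1/epsilon)`.
#' @param prototypes_per_class Number of feature patterns learned per class.
#' @param top_k Number of top-ranked similarity scores used by the classifier
#'   head and shown in local explanations.
#' @export
attention_config <- function(epsilon = 1e-4, prototypes_per_class = 50L,
                             top_k = 10L) {
  stopifnot(epsilon > 0, prototypes_per_class >= 1, top_k >= 1)
  structure(list(epsilon = epsilon,
                 prototypes_per_class = as.integer(prototypes_per_class),
                 top_k = as.integer(top_k)),
            class = "attention_config")
}

#' Create a set of feature patterns
#'
#' Prototypes are held together as a set: a `P x D` matrix of latent vectors
#' plus per-prototype class identity, within-class index, projection
#' provenance (source push image and latent location, `NA` until the first
#' projection) and QC flags.
#'
#' @param vectors `P x D` numeric matrix, one prototype per row.
#' @param class_id Character vector of length `P`.
#' @return A `feature_patterns` object.
#' @export
feature_patterns <- function(vectors, class_id) {
  stopifnot(is.matrix(vectors), nrow(vectors) == length(class_id))
  P <- nrow(vectors)
  index <- stats::ave(seq_len(P), class_id, FUN = seq_along)
  structure(list(
    vectors = vectors, class_id = as.character(class_id),
    index = as.integer(index),
    source_image_id = rep(NA_character_, P),
    source_location = matrix(NA_integer_, P, 2,
                             dimnames = list(NULL, c("row", "col"))),
    flags = data.frame(background_invalid = rep(FALSE, P),
                       duplicate = rep(FALSE, P),
                       manually_flagged = rep(FALSE, P),
                       pruned = rep(FALSE, P))
  ), class = "feature_patterns")
}

#' @export
print.feature_patterns <- function(x, ...) {
  cat(sprintf("<feature_patterns> %d prototypes (D=%d), classes: %s; %d pruned\n",
              nrow(x$vectors), ncol(x$vectors),
              paste(names(table(x$class_id)), table(x$class_id),
                    sep = ":", collapse = " "),
              sum(x$flags$pruned)))
  invisible(x)
}

# Random initialization of prototypes in the non-negative latent space.
init_feature_patterns <- function(D, classes, per_class) {
  vec <- matrix(stats::runif(length(classes) * per_class * D), ncol = D)
  feature_patterns(vec, rep(classes, each = per_class))
}

#' Squared distances between latent patches and one prototype
#'
#' Entry `(r, c)` is the squared Euclidean distance between the prototype
#' vector and the latent patch at grid position `(r, c)`.
#'
#' @param latent A `latent_grid` from [extract_features()].
#' @param fp Numeric prototype vector of length `D` (or a 1-row matrix).
#' @return `Hl x Wl` matrix of squared distances (all >= 0).
#' @export
patch_distances <- function(latent, fp) {
  fp <- as.numeric(fp)
  pm <- latent_patches(latent)
  if (ncol(pm) != length(fp))
    stop(sprintf("depth mismatch: latent depth %d, prototype depth %d",
                 ncol(pm), length(fp)))
  d2 <- rowSums(pm * pm) - 2 * drop(pm %*% fp) + sum(fp * fp)
  d2 <- pmax(d2, 0)                        # guard tiny negative round-off
  side <- as.integer(sqrt(length(d2)))
  matrix(d2, side, side, byrow = TRUE)     # rows of pm are row-major patches
}

#' Similarity from squared distance
#'
#' `log((d2 + 1) / (d2 + epsilon))`: strictly decreasing in `d2`, equal to
#' `log(1/epsilon)` at zero distance and approaching 0 from above as the
#' distance grows.
#'
#' @param d2 Squared distance(s), >= 0 (vectorized).
#' @param cfg An [attention_config()] (only `epsilon` is used).
#' @export
similarity_from_distance <- function(d2, cfg = attention_config()) {
  stopifnot(all(d2 >= 0))
  log((d2 + 1) / (d2 + cfg$epsilon))
}

# First-occurrence argmax in row-major order; returns c(row, col).
argmax_rowmajor <- function(m) {
  j <- which.max(t(m))
  c(((j - 1L) %/% ncol(m)) + 1L, ((j - 1L) %% ncol(m)) + 1L)
}

#' Activation map of one prototype on one image
#'
#' Applies the similarity transform elementwise to the patch distances and
#' max-pools the resulting grid into the prototype's pooled similarity score.
#' The location of the maximum is recorded with a deterministic row-major
#' first-occurrence tie-break; `argmax_pixel` maps the latent argmax to the
#' center of its receptive cell at input resolution (replaced by the true
#' upsampled argmax after [upsample_map()]).
#'
#' @param latent A `latent_grid`.
#' @param fp Prototype vector of length `D`.
#' @param cfg An [attention_config()].
#' @return An `activation_map`: `similarity` grid, `pooled_score`,
#'   `argmax_latent`, `argmax_pixel`, `upsampled` (`NULL` until upsampled).
#' @export
activation_map <- function(latent, fp, cfg = attention_config()) {
  d2 <- patch_distances(latent, fp)
  sim <- similarity_from_distance(d2, cfg)
  am <- argmax_rowmajor(sim)
  stride <- if (inherits(latent, "latent_grid")) latent$spatial_stride else 1
  structure(list(similarity = sim,
                 pooled_score = sim[am[1], am[2]],
                 argmax_latent = am,
                 argmax_pixel = round((am - 0.5) * stride + 0.5),
                 spatial_stride = stride,
                 upsampled = NULL),
            class = "activation_map")
}

#' Upsample an activation map to input resolution
#'
#' Bilinear interpolation of the similarity grid to `target_side` pixels;
#' interpolation cannot overshoot the grid's value range.  Updates
#' `argmax_pixel` to the upsampled argmax (row-major first occurrence).
#'
#' @param map An `activation_map`.
#' @param target_side Target side in pixels (>= latent side).
#' @export
upsample_map <- function(map, target_side) {
  stopifnot(inherits(map, "activation_map"),
            target_side >= nrow(map$similarity))
  up <- ebi_resize(map$similarity, target_side, "bilinear")
  map$upsampled <- up
  map$argmax_pixel <- argmax_rowmajor(up)
  map
}

# EBImage resize that always returns a plain matrix.
ebi_resize <- function(m, side, filter) {
  out <- EBImage::resize(m, w = side, h = side, filter = filter)
  matrix(as.numeric(EBImage::imageData(out)), side, side)
}

#' Score all prototypes on one image
#'
#' Computes one activation map per unpruned prototype, in stable
#' (class, index) order.
#'
#' @param latent A `latent_grid`.
#' @param patterns A [feature_patterns()] set.
#' @param cfg An [attention_config()].
#' @return List with `scores` (named numeric, pooled score per unpruned
#'   prototype), `maps` (list of `activation_map`s), and `proto_idx` (their
#'   row indices in `patterns$vectors`).
#' @export
score_all <- function(latent, patterns, cfg = attention_config()) {
  keep <- which(!patterns$flags$pruned)
  if (!length(keep)) stop("empty model: all feature patterns are pruned")
  ord <- keep[order(patterns$class_id[keep], patterns$index[keep])]
  maps <- lapply(ord, function(p)
    activation_map(latent, patterns$vectors[p, ], cfg))
  scores <- vapply(maps, `[[`, 0, "pooled_score")
  names(scores) <- paste0(patterns$class_id[ord], patterns$index[ord])
  list(scores = scores, maps = maps, proto_idx = ord)
}
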