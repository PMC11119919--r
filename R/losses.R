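#' Training objective: cross-entropy + cluster + separation
#'
#' The total loss is `CE + r1 * Clst + r2 * Sep`.  The cluster term is the
#' batch mean of each image's smallest squared distance between any latent
#' patch and any *same-class* prototype — minimizing it pulls some part of
#' every training image close to a prototype of its own class.  The
#' separation term is minus the batch mean of the smallest squared distance
#' to any *other-class* prototype — it is never positive, and minimizing it
#' (making it more negative) pushes every image's patches away from
#' wrong-class prototypes.
#'
#' @name losses
NULL

#' Loss weights
#'
#' @param r1 Coefficient of the cluster term (>= 0).
#' @param r2 Coefficient of the separation term (>= 0).
#' @export
loss_weights <- function(r1 = 0.8, r2 = 0.08) {
  stopifnot(r1 >= 0, r2 >= 0)
  structure(list(r1 = r1, r2 = r2), class = "loss_weights")
}

#' Mean categorical cross-entropy
#'
#' Softmax cross-entropy of per-image logits against labels, averaged over
#' the batch.
#'
#' @param logits Numeric matrix `n x n_classes`, columns named by class (a
#'   single named vector is treated as one image).
#' @param labels Character vector of length `n`.
#' @export
cross_entropy_term <- function(logits, labels) {
  if (is.null(dim(logits))) logits <- matrix(logits, 1,
                                             dimnames = list(NULL, names(logits)))
  stopifnot(nrow(logits) == length(labels))
  if (!all(labels %in% colnames(logits)))
    stop("input error: label outside the class set")
  lse <- apply(logits, 1, function(z) { m <- max(z); m + log(sum(exp(z - m))) })
  mean(lse - logits[cbind(seq_along(labels), match(labels, colnames(logits)))])
}

# Smallest squared patch-prototype distance per image, restricted to
# same-class (cluster) or other-class (separation) prototypes, and
# optionally to a subset of patches (e.g. brain-area patches).
min_proto_dist <- function(latents, labels, patterns, same_class,
                           patch_masks = NULL) {
  vapply(seq_along(latents), function(i) {
    keep <- !patterns$flags$pruned &
      (if (same_class) patterns$class_id == labels[i]
       else patterns$class_id != labels[i])
    if (!any(keep))
      stop("empty-class error: no ", if (same_class) "same" else "other",
           "-class prototypes for label ", labels[i])
    pm <- latent_patches(latents[[i]])
    if (!is.null(patch_masks) && any(patch_masks[[i]]))
      pm <- pm[patch_masks[[i]], , drop = FALSE]
    fp <- patterns$vectors[keep, , drop = FALSE]
    d2 <- outer(rowSums(pm^2), rep(1, nrow(fp))) +
      outer(rep(1, nrow(pm)), rowSums(fp^2)) - 2 * tcrossprod(pm, fp)
    max(min(d2), 0)
  }, 0)
}

#' Cluster loss
#'
#' @param latents List of `latent_grid`s (or patch matrices), one per image.
#' @param labels Character labels, one per image.
#' @param patterns A [feature_patterns()] set.
#' @param patch_masks Optional list of logical vectors (one per image,
#'   length = patches) restricting the patch minimum, e.g. to patches whose
#'   receptive cell lies on brain tissue; `NULL` uses all patches.
#' @return Batch mean of min-over-same-class-prototypes, min-over-patches
#'   squared distance; always >= 0.
#' @export
cluster_loss <- function(latents, labels, patterns, patch_masks = NULL) {
  mean(min_proto_dist(latents, labels, patterns, same_class = TRUE,
                      patch_masks = patch_masks))
}

#' Separation loss
#'
#' @inheritParams cluster_loss
#' @return Minus the batch mean of min-over-other-class-prototypes,
#'   min-over-patches squared distance; always <= 0.
#' @export
separation_loss <- function(latents, labels, patterns, patch_masks = NULL) {
  -mean(min_proto_dist(latents, labels, patterns, same_class = FALSE,
                       patch_masks = patch_masks))
}

#' Compose the total loss
#'
#' @param ce,clst,sep Finite loss components.
#' @param w A [loss_weights()].
#' @param n Batch size (bookkeeping only).
#' @return A `batch_loss` list with `total = ce + r1*clst + r2*sep` and the
#'   components.
#' @export
total_loss <- function(ce, clst, sep, w = loss_weights(), n = NA_integer_) {
  stopifnot(is.finite(ce), is.finite(clst), is.finite(sep))
  structure(list(total = ce + w$r1 * clst + w$r2 * sep,
                 ce = ce, clst = clst, sep = sep, n = n),
            class = "batch_loss")
}
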