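#' Global and local explanations
#'
#' After projection every prototype is a real latent patch of a push image,
#' so the model's reasoning can be shown in image space.  The *global*
#' explanation is the full set of learned feature patterns: for each
#' prototype, its source push image, its self-activation map and bounding
#' box, its class and class-connection weight, and its QC flags.  The *local*
#' explanation of one test image ranks all unpruned prototypes by pooled
#' similarity score (globally, across classes), keeps the top `top_k` rows,
#' and reports for each row the activated image part (bounding box), the
#' similarity score, the class-connection weight and the weighted score; the
#' per-class sums of weighted scores over each class's top-`top_k` prototypes
#' reproduce the classifier logits exactly.
#'
#' @name explanation
NULL

#' Bounding box of the hot region of an activation map
#'
#' Tight box around all pixels at or above the `threshold_quantile` quantile
#' of the upsampled map.  The box always contains the map argmax.  A constant
#' map yields the full-image box with a warning.
#'
#' @param map An upsampled activation-map matrix (or an `activation_map`
#'   whose `upsampled` field is set).
#' @param threshold_quantile Quantile defining "hot" (default 0.95).
#' @return Integer vector `(row0, col0, row1, col1)`.
#' @export
bounding_box_from_map <- function(map, threshold_quantile = 0.95) {
  m <- if (inherits(map, "activation_map")) map$upsampled else map
  stopifnot(is.matrix(m))
  if (max(m) == min(m)) {
    warning("constant activation map: returning full-image box")
    return(c(1L, 1L, nrow(m), ncol(m)))
  }
  thr <- stats::quantile(m, threshold_quantile, names = FALSE)
  hot <- m >= thr
  rows <- range(which(rowSums(hot) > 0))
  cols <- range(which(colSums(hot) > 0))
  c(rows[1], cols[1], rows[2], cols[2])
}

# Activation map of prototype p on an arbitrary record, upsampled.
proto_map_on_record <- function(model, p, record) {
  latent <- extract_features(model$backbone, record)
  m <- activation_map(latent, model$patterns$vectors[p, ], model$cfg)
  upsample_map(m, nrow(record$pixels))
}

#' Global explanation of a trained, projected model
#'
#' Recomputes each unpruned prototype's activation on its own source push
#' image.  Because the prototype is bit-equal to a latent patch of that
#' image, the pooled self-activation score equals `log(1/epsilon)`.
#'
#' @param model A trained, projected `pp_model`.
#' @param push_data The push set used at the last projection (defaults to
#'   the one recorded on the model).
#' @return A `global_explanation`: list with `entries` (one per unpruned
#'   prototype: prototype index, class, source image id, box, weight, pooled
#'   score, map) and `threshold_quantile`.
#' @export
explain_global <- function(model, push_data = model$push_records,
                           threshold_quantile = 0.95) {
  if (!isTRUE(model$projected))
    stop("must-push-first error: prototypes have not been projected")
  stopifnot(!is.null(push_data))
  ids <- vapply(push_data, `[[`, "", "id")
  keep <- which(!model$patterns$flags$pruned)
  entries <- lapply(keep, function(p) {
    src <- match(model$patterns$source_image_id[p], ids)
    if (is.na(src))
      stop("push image ", model$patterns$source_image_id[p],
           " not found in push_data")
    m <- proto_map_on_record(model, p, push_data[[src]])
    cl <- model$patterns$class_id[p]
    list(prototype = p, class_id = cl,
         index = model$patterns$index[p],
         source_image_id = ids[src],
         source_record = push_data[[src]],
         weight = model$conn[p, cl],
         pooled_score = m$pooled_score,
         argmax_pixel = m$argmax_pixel,
         box = bounding_box_from_map(m, threshold_quantile),
         map = m)
  })
  structure(list(entries = entries,
                 threshold_quantile = threshold_quantile),
            class = "global_explanation")
}

#' Local explanation of one prediction
#'
#' Scores all unpruned prototypes on the image, ranks them globally by
#' pooled similarity, and reports the top `top_k` reasoning rows together
#' with the prediction.  Deterministic given model and image (score ties
#' break by class then within-class index).
#'
#' @param model A trained, projected `pp_model`.
#' @param record An [image_record()].
#' @param threshold_quantile Quantile for the bounding boxes.
#' @return A `local_explanation`: `id`, `prediction`, `logits`, and `rows`
#'   (data frame: rank, prototype, class, similarity, weight,
#'   weighted_score, box coordinates, peak pixel) plus the per-row maps.
#' @export
explain_local <- function(model, record, threshold_quantile = 0.95) {
  if (!isTRUE(model$projected))
    stop("must-push-first error: prototypes have not been projected")
  latent <- extract_features(model$backbone, record)
  sa <- score_all(latent, model$patterns, model$cfg)
  full_scores <- rep(NA_real_, nrow(model$patterns$vectors))
  full_scores[sa$proto_idx] <- sa$scores
  logits <- class_logits(full_scores, model$conn, model$patterns, model$cfg)
  prediction <- predict_class(logits)

  k <- min(model$cfg$top_k, length(sa$proto_idx))
  ord <- order(-sa$scores)[seq_len(k)]      # global ranking, stable ties
  side <- nrow(record$pixels)
  rows <- lapply(seq_along(ord), function(r) {
    p <- sa$proto_idx[ord[r]]
    m <- upsample_map(sa$maps[[ord[r]]], side)
    cl <- model$patterns$class_id[p]
    box <- bounding_box_from_map(m, threshold_quantile)
    data.frame(rank = r, prototype = p, class_id = cl,
               proto_index = model$patterns$index[p],
               similarity = m$pooled_score,
               weight = model$conn[p, cl],
               weighted_score = m$pooled_score * model$conn[p, cl],
               row0 = box[1], col0 = box[2], row1 = box[3], col1 = box[4],
               peak_row = m$argmax_pixel[1], peak_col = m$argmax_pixel[2])
  })
  maps <- lapply(seq_along(ord), function(r)
    upsample_map(sa$maps[[ord[r]]], side))
  structure(list(id = record$id, label = record$label,
                 prediction = prediction, logits = logits,
                 rows = do.call(rbind, rows), maps = maps,
                 full_scores = full_scores),
            class = "local_explanation")
}

#' @export
print.local_explanation <- function(x, ...) {
  cat(sprintf("<local_explanation %s> predicted %s (logits %s)\n", x$id,
              x$prediction,
              paste(sprintf("%s=%.3f", names(x$logits), x$logits),
                    collapse = " ")))
  print(x$rows[, c("rank", "class_id", "proto_index", "similarity",
                   "weight", "weighted_score")], row.names = FALSE)
  invisible(x)
}

# Render an activation overlay (grayscale image + warm colormap at 0.5
# opacity) as an H x W x 3 array for PNG export.
overlay_rgb <- function(pixels, upsampled, alpha = 0.5) {
  g <- pixels - min(pixels)
  if (max(g) > 0) g <- g / max(g)
  u <- upsampled - min(upsampled)
  if (max(u) > 0) u <- u / max(u)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "Inferno")) / 255
  idx <- pmin(255L, pmax(0L, round(u * 255))) + 1L
  out <- array(0, c(nrow(pixels), ncol(pixels), 3))
  for (ch in 1:3) {
    heat <- matrix(pal[ch, idx], nrow(pixels), ncol(pixels))
    out[, , ch] <- (1 - alpha) * g + alpha * heat
  }
  out
}
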