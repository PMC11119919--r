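#' Prototype-part attention model
#'
#' Bundles the backbone, the feature-pattern set, the class-connection
#' weights and the configuration into one trainable state.
#'
#' @param backbone A `pp_backbone` from [build_backbone()] (or a
#'   [backbone_spec()], which is built).
#' @param classes Character vector of class labels in configured order (the
#'   first class wins exact logit ties).
#' @param cfg An [attention_config()].
#' @param lw A [loss_weights()].
#' @param seed Integer seed used for prototype initialization.
#' @return A `pp_model`.
#' @export
pp_model <- function(backbone, classes = c("A", "B"),
                     cfg = attention_config(), lw = loss_weights(),
                     seed = 1L) {
  if (inherits(backbone, "backbone_spec")) {
    set.seed(seed)
    backbone <- build_backbone(backbone)
  }
  set.seed(seed + 1L)
  patterns <- init_feature_patterns(backbone$latent_dim, classes,
                                    cfg$prototypes_per_class)
  structure(list(
    backbone = backbone, patterns = patterns,
    conn = init_class_connections(patterns, classes),
    classes = classes, cfg = cfg, lw = lw,
    projected = FALSE, epoch = 0L,
    log = NULL, opt = NULL
  ), class = "pp_model")
}

#' @export
print.pp_model <- function(x, ...) {
  cat(sprintf("<pp_model> %s backbone, %d prototypes (%d pruned), classes %s, epoch %d%s\n",
              x$backbone$spec$base, nrow(x$patterns$vectors),
              sum(x$patterns$flags$pruned), paste(x$classes, collapse = "/"),
              x$epoch, if (x$projected) ", projected" else ""))
  invisible(x)
}

# Pooled similarity scores for a batch.  Returns per-image score matrix
# (n x P, NA at pruned columns), the argmax patch index (row-major, n x P),
# the full distance matrix at the argmax, and optionally the raw latent and
# caches for backprop.
model_score_batch <- function(model, records, train = FALSE) {
  B <- length(records)
  X <- records_to_input(model$backbone, records)
  fw <- backbone_forward(model$backbone, X, B, train = train)
  Np <- fw$Hl * fw$Wl
  FP <- model$patterns$vectors
  P <- nrow(FP)
  eps <- model$cfg$epsilon
  # (B*Np) x P squared distances
  d2 <- outer(rowSums(fw$latent^2), rep(1, P)) +
    outer(rep(1, B * Np), rowSums(FP^2)) - 2 * tcrossprod(fw$latent, FP)
  d2 <- pmax(d2, 0)
  sim <- log((d2 + 1) / (d2 + eps))
  scores <- matrix(NA_real_, B, P)
  argpatch <- matrix(NA_integer_, B, P)
  pruned <- model$patterns$flags$pruned
  for (i in seq_len(B)) {
    rows <- ((i - 1L) * Np + 1L):(i * Np)
    block <- sim[rows, , drop = FALSE]
    aj <- max.col(t(block), ties.method = "first")   # argmax patch per proto
    argpatch[i, ] <- aj
    scores[i, ] <- block[cbind(aj, seq_len(P))]
  }
  scores[, pruned] <- NA_real_
  list(scores = scores, argpatch = argpatch, d2 = d2, sim = sim,
       latent = fw$latent, caches = fw$caches, Np = Np, B = B)
}

# Logits for a batch of score rows (n x P) -> n x n_classes matrix.
model_logits <- function(model, scores) {
  n <- nrow(scores)
  out <- matrix(0, n, length(model$classes),
                dimnames = list(NULL, model$classes))
  for (i in seq_len(n))
    out[i, ] <- class_logits(scores[i, ], model$conn, model$patterns,
                             model$cfg)
  out
}

#' Predict classes for a list of records
#'
#' @param model A trained `pp_model`.
#' @param records List of [image_record()]s.
#' @param batch_size Forward-pass batch size.
#' @return Data frame with `id`, `label`, `predicted` and one logit column
#'   per class.
#' @export
predict_dataset <- function(model, records, batch_size = 32L) {
  n <- length(records)
  res <- vector("list", 0)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    sb <- model_score_batch(model, records[idx])
    lg <- model_logits(model, sb$scores)
    res[[length(res) + 1L]] <- data.frame(
      id = vapply(records[idx], `[[`, "", "id"),
      label = vapply(records[idx], `[[`, "", "label"),
      predicted = apply(lg, 1, function(z)
        predict_class(stats::setNames(z, colnames(lg)))),
      lg, check.names = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the full model state (backbone weights,
#' prototype vectors and provenance, class connections, configuration).
#'
#' @param model A `pp_model`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "pp_model"))
  m
}
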