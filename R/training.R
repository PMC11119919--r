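#' Three-stage training
#'
#' Training alternates three stages:
#' 1. *Warm-up*: SGD on the add-on 1x1 layers and the prototype vectors with
#'    the base convolutional stack and the class connections frozen.
#' 2. *Joint*: SGD on all convolutional layers and the prototypes, the class
#'    connections still frozen; at each scheduled push epoch the prototypes
#'    are projected onto their nearest same-class latent patch of the push
#'    set, and the class connections are then re-fit by a convex
#'    L1-penalized optimization followed by clamping (cross-class weights to
#'    exactly 0, same-class weights to >= 0).
#'
#' The SGD optimizer is plain momentum SGD (momentum 0.9) with separate
#' learning rates for the base stack and for add-on layers + prototypes.
#'
#' @name training
NULL

#' Training schedule
#'
#' @param warmup_epochs Epochs of warm-up (add-on layers + prototypes only).
#' @param total_epochs Total epochs including warm-up.
#' @param push_epochs Integer vector of epochs after which prototypes are
#'   projected (each followed by the convex last-layer stage); must lie in
#'   `(warmup_epochs, total_epochs]`.
#' @param last_layer_iters Full-batch iterations of the convex stage.
#' @param lr_addon_and_prototypes Learning rate for add-on layers and
#'   prototype vectors.
#' @param lr_pretrained Learning rate for the base convolutional stack.
#' @param lr_last_layer Learning rate of the convex stage.
#' @param lambda L1 coefficient on cross-class connection weights in the
#'   convex stage.
#' @param batch_size Mini-batch size.
#' @param clip_grad_norm Global gradient-norm ceiling for SGD stability.
#' @param seed Integer seed governing the whole run.
#' @export
training_schedule <- function(warmup_epochs = 5L, total_epochs = 100L,
                              push_epochs = c(20L, 40L, 60L, 80L, 100L),
                              last_layer_iters = 20L,
                              lr_addon_and_prototypes = 3e-3,
                              lr_pretrained = 1e-4,
                              lr_last_layer = 1e-4,
                              lambda = 1e-4,
                              batch_size = 32L,
                              clip_grad_norm = 5,
                              seed = 1L) {
  stopifnot(warmup_epochs >= 0, total_epochs >= warmup_epochs,
            all(push_epochs > warmup_epochs), all(push_epochs <= total_epochs),
            lr_addon_and_prototypes > 0, lr_pretrained > 0, lr_last_layer > 0,
            lambda >= 0, batch_size >= 1)
  structure(list(warmup_epochs = as.integer(warmup_epochs),
                 total_epochs = as.integer(total_epochs),
                 push_epochs = as.integer(sort(push_epochs)),
                 last_layer_iters = as.integer(last_layer_iters),
                 lr_addon_and_prototypes = lr_addon_and_prototypes,
                 lr_pretrained = lr_pretrained,
                 lr_last_layer = lr_last_layer,
                 lambda = lambda, batch_size = as.integer(batch_size),
                 clip_grad_norm = clip_grad_norm,
                 seed = as.integer(seed)),
            class = "training_schedule")
}

# Logical mask over the row-major latent patches of one record: TRUE where
# the receptive cell's center pixel lies on brain tissue and the cell's
# receptive field stays inside the image frame (cells that see the
# zero-padding boundary carry frame artifacts, not anatomy).  Focuses the
# cluster/separation minima and the projection search on brain-area patches
# (the stated purpose of background cropping); brain condition is skipped
# when the record has no brain mask.
brain_patch_mask <- function(record, latent_side, stride, rf = 0) {
  side_px <- nrow(record$pixels)
  r <- rep(seq_len(latent_side), each = latent_side)
  c <- rep(seq_len(latent_side), times = latent_side)
  pr <- pmin(pmax(round((r - 0.5) * stride + 0.5), 1), side_px)
  pc <- pmin(pmax(round((c - 0.5) * stride + 0.5), 1), ncol(record$pixels))
  ok <- pr > rf / 2 & pr <= side_px - rf / 2 &
        pc > rf / 2 & pc <= ncol(record$pixels) - rf / 2
  if (!is.null(record$brain_mask))
    ok <- ok & record$brain_mask[cbind(pr, pc)] > 0
  ok
}

# One SGD mini-batch step on CE + r1*Clst + r2*Sep.  `groups` names the
# trainable parameter groups ("base", "addon"); prototypes always train in
# SGD stages.  Returns the updated model plus the batch loss and predictions.
sgd_batch_step <- function(model, records, schedule, groups) {
  labels <- vapply(records, `[[`, "", "label")
  sb <- model_score_batch(model, records, train = TRUE)
  B <- sb$B; Np <- sb$Np
  FP <- model$patterns$vectors
  P <- nrow(FP)
  eps <- model$cfg$epsilon

  logits <- model_logits(model, sb$scores)
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)
  onehot <- outer(labels, model$classes, "==") + 0
  dlogit <- (probs - onehot) / B
  ce <- cross_entropy_term(logits, labels)

  # triplets (image, prototype, patch) receiving gradient on d2
  t_img <- integer(0); t_pro <- integer(0); t_pat <- integer(0)
  t_coef <- numeric(0)
  sel_all <- lapply(seq_len(B), function(i)
    sort(unique(unlist(topk_per_class(sb$scores[i, ], model$patterns,
                                      model$classes, model$cfg$top_k)))))
  for (i in seq_len(B)) {
    for (p in sel_all[[i]]) {
      coef <- sum(dlogit[i, ] * model$conn[p, ])
      if (coef == 0) next
      j <- sb$argpatch[i, p]
      d2v <- sb$d2[(i - 1L) * Np + j, p]
      simprime <- 1 / (d2v + 1) - 1 / (d2v + eps)
      t_img <- c(t_img, i); t_pro <- c(t_pro, p); t_pat <- c(t_pat, j)
      t_coef <- c(t_coef, coef * simprime)
    }
  }
  # cluster / separation terms: min-of-min over d2, restricted to
  # brain-area patches when masks are available
  side <- model$backbone$latent_side
  stride <- model$backbone$spatial_stride
  clst_v <- numeric(B); sep_v <- numeric(B)
  rf <- model$backbone$receptive_field
  for (i in seq_len(B)) {
    pidx <- which(brain_patch_mask(records[[i]], side, stride, rf))
    if (!length(pidx)) pidx <- seq_len(Np)
    rows <- (i - 1L) * Np + pidx
    same <- which(model$patterns$class_id == labels[i] &
                    !model$patterns$flags$pruned)
    diff <- which(model$patterns$class_id != labels[i] &
                    !model$patterns$flags$pruned)
    dsub <- sb$d2[rows, same, drop = FALSE]
    k <- arrayInd(which.min(dsub), dim(dsub))
    clst_v[i] <- dsub[k]
    t_img <- c(t_img, i); t_pro <- c(t_pro, same[k[2]])
    t_pat <- c(t_pat, pidx[k[1]])
    t_coef <- c(t_coef, model$lw$r1 / B)
    dsub <- sb$d2[rows, diff, drop = FALSE]
    k <- arrayInd(which.min(dsub), dim(dsub))
    sep_v[i] <- dsub[k]
    t_img <- c(t_img, i); t_pro <- c(t_pro, diff[k[2]])
    t_pat <- c(t_pat, pidx[k[1]])
    t_coef <- c(t_coef, -model$lw$r2 / B)
  }
  loss <- total_loss(ce, mean(clst_v), -mean(sep_v), model$lw, n = B)

  # d2 gradients -> latent patches and prototypes
  rows_g <- (t_img - 1L) * Np + t_pat
  M <- sb$latent[rows_g, , drop = FALSE] - FP[t_pro, , drop = FALSE]
  contrib <- 2 * t_coef * M
  dLatent <- matrix(0, B * Np, ncol(FP))
  agg <- rowsum(contrib, group = rows_g)
  dLatent[as.integer(rownames(agg)), ] <- agg
  dFP <- matrix(0, P, ncol(FP))
  aggp <- rowsum(-contrib, group = t_pro)
  dFP[as.integer(rownames(aggp)), ] <- aggp

  grads <- backbone_backward(model$backbone, sb$caches, dLatent)

  # gradient-norm clipping per parameter group, so an exploding similarity
  # gradient (the near-saturation 1/epsilon regime of a prototype) cannot
  # throttle the convolutional layers' learning signal
  gsq <- c(base = 0, addon = 0, proto = sum(dFP^2))
  for (li in seq_along(grads)) {
    g <- grads[[li]]
    if (!is.null(g) && model$backbone$layers[[li]]$group %in% groups) {
      grp <- model$backbone$layers[[li]]$group
      gsq[grp] <- gsq[grp] + sum(g$dW^2) + sum(g$db^2)
    }
  }
  scale <- pmin(schedule$clip_grad_norm / pmax(sqrt(gsq), 1e-12), 1)

  # momentum SGD update
  if (is.null(model$opt))
    model$opt <- list(layers = vector("list", length(grads)), vFP = 0 * dFP)
  mu <- 0.9
  for (li in seq_along(grads)) {
    g <- grads[[li]]
    if (is.null(g)) next
    ly <- model$backbone$layers[[li]]
    if (!(ly$group %in% groups)) next
    lr <- if (ly$group == "base") schedule$lr_pretrained else
      schedule$lr_addon_and_prototypes
    if (is.null(model$opt$layers[[li]]))
      model$opt$layers[[li]] <- list(vW = 0 * ly$W, vb = 0 * ly$b)
    v <- model$opt$layers[[li]]
    v$vW <- mu * v$vW - lr * scale[ly$group] * g$dW
    v$vb <- mu * v$vb - lr * scale[ly$group] * g$db
    model$backbone$layers[[li]]$W <- ly$W + v$vW
    model$backbone$layers[[li]]$b <- ly$b + v$vb
    model$opt$layers[[li]] <- v
  }
  model$opt$vFP <- mu * model$opt$vFP -
    schedule$lr_addon_and_prototypes * scale["proto"] * dFP
  model$patterns$vectors <- pmax(FP + model$opt$vFP, 0)

  pred <- model$classes[max.col(logits, ties.method = "first")]
  list(model = model, loss = loss, correct = sum(pred == labels))
}

run_epoch <- function(model, train_data, schedule, groups) {
  n <- length(train_data)
  ord <- sample.int(n)
  tot <- c(ce = 0, clst = 0, sep = 0, total = 0)
  nb <- 0L; ncorrect <- 0L
  for (start in seq(1L, n, by = schedule$batch_size)) {
    idx <- ord[start:min(start + schedule$batch_size - 1L, n)]
    st <- sgd_batch_step(model, train_data[idx], schedule, groups)
    model <- st$model
    tot <- tot + c(st$loss$ce, st$loss$clst, st$loss$sep, st$loss$total)
    nb <- nb + 1L
    ncorrect <- ncorrect + st$correct
  }
  model$epoch <- model$epoch + 1L
  model$log <- rbind(model$log, data.frame(
    epoch = model$epoch, stage = paste(groups, collapse = "+"),
    ce = tot[1] / nb, clst = tot[2] / nb, sep = tot[3] / nb,
    total = tot[4] / nb, train_acc = ncorrect / n, row.names = NULL))
  model
}

#' Pretrain the backbone with a temporary linear classification head
#'
#' The staged schedule assumes the base convolutional stack starts from
#' informative (pretrained) features and protects them with a small learning
#' rate.  When no pretrained checkpoint exists, this stage plays that role:
#' it trains the whole backbone plus a temporary global-average-pooling
#' linear classifier head by SGD on cross-entropy, then discards the head.
#' Afterwards the latent cells carry class-evidence features shaped by the
#' task itself, and the prototype stages can run against them exactly as
#' they would against transferred features.
#'
#' @param model A fresh `pp_model`.
#' @param train_data List of [image_record()]s.
#' @param epochs Pretraining epochs.
#' @param lr Backbone learning rate (momentum 0.9).
#' @param head_lr Learning rate of the temporary linear head; hotter than
#'   the backbone so the classification signal reaches the features early.
#' @param batch_size Mini-batch size.
#' @return The model with a pretrained backbone (prototypes untouched).
#' @export
pretrain_backbone <- function(model, train_data, epochs = 6L, lr = 3e-3,
                              head_ridge = 1e-2, batch_size = 32L) {
  D <- model$backbone$latent_dim
  classes <- model$classes
  stopifnot(length(classes) == 2)
  vel <- list(layers = vector("list", length(model$backbone$layers)))
  mu <- 0.9
  n <- length(train_data)
  labels_all <- vapply(train_data, `[[`, "", "label")
  y <- as.numeric(labels_all == classes[2])
  gap_features <- function() {
    G <- matrix(0, n, D)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, n)
      X <- records_to_input(model$backbone, train_data[idx])
      fw <- backbone_forward(model$backbone, X, length(idx))
      Np <- fw$Hl * fw$Wl
      for (k in seq_along(idx))
        G[idx[k], ] <- colMeans(fw$latent[((k - 1L) * Np + 1L):(k * Np), ,
                                          drop = FALSE])
    }
    G
  }
  for (e in seq_len(epochs)) {
    # refit the temporary head to optimality on the current features
    G <- gap_features()
    fitl <- glmnet::glmnet(G, y, family = "binomial", alpha = 0,
                           lambda = head_ridge, standardize = TRUE)
    w2 <- as.numeric(fitl$beta)
    b2 <- as.numeric(fitl$a0)
    Wh <- cbind(-w2 / 2, w2 / 2)
    bh <- c(-b2 / 2, b2 / 2)
    # one SGD epoch on the backbone with the head fixed
    ord <- sample.int(n)
    tot <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      records <- train_data[idx]
      labels <- vapply(records, `[[`, "", "label")
      B <- length(records)
      X <- records_to_input(model$backbone, records)
      fw <- backbone_forward(model$backbone, X, B, train = TRUE)
      Np <- fw$Hl * fw$Wl
      pooled <- matrix(0, B, D)
      for (i in seq_len(B))
        pooled[i, ] <- colMeans(fw$latent[((i - 1L) * Np + 1L):(i * Np), ,
                                          drop = FALSE])
      logits <- sweep(pooled %*% Wh, 2, bh, "+")
      colnames(logits) <- classes
      probs <- exp(logits - apply(logits, 1, max))
      probs <- probs / rowSums(probs)
      onehot <- outer(labels, classes, "==") + 0
      tot <- tot + cross_entropy_term(logits, labels); nb <- nb + 1L
      dlogit <- (probs - onehot) / B
      dpooled <- tcrossprod(dlogit, Wh)             # B x D
      dLatent <- matrix(0, B * Np, D)
      for (i in seq_len(B))
        dLatent[((i - 1L) * Np + 1L):(i * Np), ] <-
          matrix(dpooled[i, ] / Np, Np, D, byrow = TRUE)
      grads <- backbone_backward(model$backbone, fw$caches, dLatent)
      for (li in seq_along(grads)) {
        g <- grads[[li]]
        if (is.null(g)) next
        ly <- model$backbone$layers[[li]]
        if (is.null(vel$layers[[li]]))
          vel$layers[[li]] <- list(vW = 0 * ly$W, vb = 0 * ly$b)
        v <- vel$layers[[li]]
        v$vW <- mu * v$vW - lr * g$dW
        v$vb <- mu * v$vb - lr * g$db
        model$backbone$layers[[li]]$W <- ly$W + v$vW
        model$backbone$layers[[li]]$b <- ly$b + v$vb
        vel$layers[[li]] <- v
      }
    }
    model$log <- rbind(model$log, data.frame(
      epoch = model$epoch, stage = "pretrain", ce = tot / nb, clst = NA,
      sep = NA, total = tot / nb, train_acc = NA, row.names = NULL))
  }
  model
}

#' Warm-up stage
#'
#' Trains only the add-on 1x1 layers and the prototype vectors for
#' `warmup_epochs` epochs; the base stack and the class connections stay
#' bit-identical.
#'
#' @param model A fresh `pp_model`.
#' @param train_data List of [image_record()]s.
#' @param schedule A [training_schedule()].
#' @export
warmup_stage <- function(model, train_data, schedule) {
  for (e in seq_len(schedule$warmup_epochs))
    model <- run_epoch(model, train_data, schedule, groups = "addon")
  model
}

#' One joint-stage epoch
#'
#' SGD over all convolutional layers (base at `lr_pretrained`, add-on at
#' `lr_addon_and_prototypes`) plus the prototypes; class connections frozen.
#'
#' @inheritParams warmup_stage
#' @export
joint_stage_epoch <- function(model, train_data, schedule) {
  run_epoch(model, train_data, schedule, groups = c("base", "addon"))
}

#' Initialize prototypes from class-unique push patches
#'
#' Feature patterns are produced by the model from the push dataset; this
#' initializer realizes that directly.  Every brain-area latent patch of
#' every push image is scored by its *class uniqueness* — the smallest
#' squared distance to any patch of the other class's push images (the same
#' quantity the separation loss maximizes).  Each class's prototypes are
#' initialized to its top-ranked unique patches, drawn from distinct push
#' images for diversity.  Class-shared codes (healthy tissue, background)
#' score near zero and are never selected, so prototypes start in
#' class-evidential code regions and the SGD stages refine rather than
#' rediscover them.
#'
#' @param model A `pp_model` with a (pre)trained backbone.
#' @param push_data Push records covering every class.
#' @param batch_size Forward batch size.
#' @return The model with initialized prototype vectors and provenance.
#' @export
init_prototypes_from_push <- function(model, push_data, batch_size = 32L) {
  labels <- vapply(push_data, `[[`, "", "label")
  ids <- vapply(push_data, `[[`, "", "id")
  side <- model$backbone$latent_side
  stride <- model$backbone$spatial_stride
  rf <- model$backbone$receptive_field
  codes <- list(); info <- list()
  for (start in seq(1L, length(push_data), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(push_data))
    X <- records_to_input(model$backbone, push_data[idx])
    fw <- backbone_forward(model$backbone, X, length(idx))
    Np <- fw$Hl * fw$Wl
    for (k in seq_along(idx)) {
      i <- idx[k]
      pm <- fw$latent[((k - 1L) * Np + 1L):(k * Np), , drop = FALSE]
      ok <- which(brain_patch_mask(push_data[[i]], side, stride, rf))
      if (!length(ok)) ok <- seq_len(Np)
      cl <- labels[i]
      codes[[cl]] <- rbind(codes[[cl]], pm[ok, , drop = FALSE])
      info[[cl]] <- rbind(info[[cl]], cbind(img = i, patch = ok))
    }
  }
  per_class <- model$cfg$prototypes_per_class
  for (cl in unique(model$patterns$class_id)) {
    other <- do.call(rbind, codes[setdiff(names(codes), cl)])
    if (is.null(other))
      stop("configuration error: push set lacks a second class")
    X <- codes[[cl]]
    mind <- rep(Inf, nrow(X))
    for (st in seq(1L, nrow(other), by = 2000L)) {
      Yc <- other[st:min(st + 1999L, nrow(other)), , drop = FALSE]
      d2 <- outer(rowSums(X^2), rep(1, nrow(Yc))) +
        outer(rep(1, nrow(X)), rowSums(Yc^2)) - 2 * tcrossprod(X, Yc)
      mind <- pmin(mind, apply(d2, 1, min))
    }
    # candidate pool: clearly class-unique codes (top quartile of the
    # separation score).  Within the pool, prefer *typical* exemplars —
    # medoids, patches centrally located among the pool codes of other
    # images — over extreme variants, so every same-class image finds a
    # close match to every prototype at explanation time.  One prototype
    # per push image for provenance diversity.
    pool <- which(mind >= stats::quantile(mind, 0.90))
    P <- X[pool, , drop = FALSE]
    k <- min(25L, length(pool) - 1L)
    cent <- vapply(seq_along(pool), function(t) {
      d <- rowSums((P - matrix(P[t, ], nrow(P), ncol(P), byrow = TRUE))^2)
      mean(sort(d)[2:(k + 1L)])
    }, 0)
    ord <- pool[order(cent)]
    distinct <- ord[!duplicated(info[[cl]][ord, "img"])]
    if (length(distinct) < per_class)
      distinct <- c(distinct, setdiff(ord, distinct))
    sel <- distinct[seq_len(per_class)]
    rows <- which(model$patterns$class_id == cl)
    for (t in seq_along(sel)) {
      p <- rows[t]
      model$patterns$vectors[p, ] <- X[sel[t], ]
      model$patterns$source_image_id[p] <- ids[info[[cl]][sel[t], "img"]]
      j <- info[[cl]][sel[t], "patch"]
      model$patterns$source_location[p, ] <-
        c(((j - 1L) %/% side) + 1L, ((j - 1L) %% side) + 1L)
    }
  }
  model$push_records <- push_data
  model
}

#' Project prototypes onto push-set latent patches
#'
#' Replaces every prototype by the nearest (squared Euclidean distance)
#' latent patch among push images *of its own class*, recording the source
#' image id and latent location.  After projection each prototype is
#' bit-equal to a real latent patch, so it can be visualized as an image
#' part, and its pooled score on its source image is exactly
#' `log(1/epsilon)`.
#'
#' @param model A `pp_model`.
#' @param push_data List of [image_record()]s containing every class.
#' @export
project_prototypes <- function(model, push_data, batch_size = 32L) {
  labels <- vapply(push_data, `[[`, "", "label")
  ids <- vapply(push_data, `[[`, "", "id")
  missing <- setdiff(unique(model$patterns$class_id), labels)
  if (length(missing))
    stop("configuration error: push set lacks class(es): ",
         paste(missing, collapse = ", "))
  # latents of all push images
  lat <- list()
  for (start in seq(1L, length(push_data), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(push_data))
    X <- records_to_input(model$backbone, push_data[idx])
    fw <- backbone_forward(model$backbone, X, length(idx))
    Np <- fw$Hl * fw$Wl
    for (k in seq_along(idx))
      lat[[idx[k]]] <- fw$latent[((k - 1L) * Np + 1L):(k * Np), , drop = FALSE]
  }
  Wl <- model$backbone$latent_side
  pmasks <- lapply(push_data, brain_patch_mask, latent_side = Wl,
                   stride = model$backbone$spatial_stride,
                   rf = model$backbone$receptive_field)
  for (p in seq_len(nrow(model$patterns$vectors))) {
    cl <- model$patterns$class_id[p]
    fp <- model$patterns$vectors[p, ]
    best <- list(d2 = Inf)
    for (i in which(labels == cl)) {
      pm <- lat[[i]]
      cand <- which(pmasks[[i]])
      if (!length(cand)) cand <- seq_len(nrow(pm))
      d2 <- rowSums(pm[cand, , drop = FALSE]^2) -
        2 * drop(pm[cand, , drop = FALSE] %*% fp) + sum(fp^2)
      j <- which.min(d2)
      if (d2[j] < best$d2)
        best <- list(d2 = d2[j], img = i, patch = cand[j])
    }
    model$patterns$vectors[p, ] <- lat[[best$img]][best$patch, ]
    model$patterns$source_image_id[p] <- ids[best$img]
    model$patterns$source_location[p, ] <- c(
      ((best$patch - 1L) %/% Wl) + 1L, ((best$patch - 1L) %% Wl) + 1L)
  }
  model$projected <- TRUE
  model$opt$vFP <- 0 * model$opt$vFP          # restart prototype momentum
  model$push_records <- push_data
  model
}

#' Convex last-layer optimization
#'
#' With backbone and prototypes frozen, re-fits the class-connection weights
#' by full-batch gradient descent on cross-entropy plus an L1 penalty
#' `lambda * sum(|cross-class weights|)`, then clamps: cross-class weights to
#' exactly 0, same-class weights to >= 0.  Only the connection matrix
#' changes.
#'
#' @inheritParams warmup_stage
#' @export
convex_last_layer <- function(model, train_data, schedule,
                              batch_size = 32L) {
  labels <- vapply(train_data, `[[`, "", "label")
  n <- length(train_data)
  # frozen pooled scores, cached once
  S <- matrix(NA_real_, n, nrow(model$patterns$vectors))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    S[idx, ] <- model_score_batch(model, train_data[idx])$scores
  }
  sel_all <- lapply(seq_len(n), function(i)
    sort(unique(unlist(topk_per_class(S[i, ], model$patterns,
                                      model$classes, model$cfg$top_k)))))
  same <- outer(model$patterns$class_id, model$classes, "==")
  onehot <- outer(labels, model$classes, "==") + 0
  conn <- model$conn
  for (it in seq_len(schedule$last_layer_iters)) {
    logits <- matrix(0, n, length(model$classes),
                     dimnames = list(NULL, model$classes))
    dconn <- 0 * conn
    for (i in seq_len(n)) {
      ps <- sel_all[[i]]
      logits[i, ] <- drop(S[i, ps] %*% conn[ps, , drop = FALSE])
    }
    probs <- exp(logits - apply(logits, 1, max))
    probs <- probs / rowSums(probs)
    dlogit <- (probs - onehot) / n
    for (i in seq_len(n)) {
      ps <- sel_all[[i]]
      dconn[ps, ] <- dconn[ps, ] + outer(S[i, ps], dlogit[i, ])
    }
    dconn[!same] <- dconn[!same] + schedule$lambda * sign(conn[!same])
    conn <- conn - schedule$lr_last_layer * dconn
  }
  conn[!same] <- 0
  conn[same] <- pmax(conn[same], 0)
  model$conn <- conn
  model
}

#' Fit the full three-stage schedule
#'
#' Orchestrates warm-up, joint epochs, and — after each scheduled push epoch
#' — prototype projection followed by the convex last-layer stage.  The run
#' is fully reproducible from `schedule$seed`.
#'
#' @param model A fresh `pp_model` (or `NULL` to build one from
#'   `backbone_spec`).
#' @param train_data,push_data Lists of [image_record()]s; the push set must
#'   contain every class.
#' @param schedule A [training_schedule()].
#' @param checkpoint_dir Optional directory receiving a checkpoint after
#'   each push event.
#' @return The trained `pp_model` (projected iff at least one push epoch ran).
#' @export
fit <- function(model, train_data, push_data, schedule = training_schedule(),
                checkpoint_dir = NULL) {
  set.seed(schedule$seed)
  model <- warmup_stage(model, train_data, schedule)
  if (schedule$total_epochs > schedule$warmup_epochs) {
    for (e in (schedule$warmup_epochs + 1L):schedule$total_epochs) {
      model <- joint_stage_epoch(model, train_data, schedule)
      if (e %in% schedule$push_epochs) {
        model <- project_prototypes(model, push_data)
        model <- convex_last_layer(model, train_data, schedule)
        if (!is.null(checkpoint_dir)) {
          dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
          save_checkpoint(model, file.path(checkpoint_dir,
                                           sprintf("push_epoch_%03d.rds", e)))
        }
      }
    }
  }
  model
}
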