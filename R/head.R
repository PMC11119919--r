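#' Similarity-based classifier head
#'
#' Class logits are formed from the pooled similarity scores: for each class,
#' the `top_k` highest-scoring prototypes *of that class* are selected and
#' their scores are weighted by the non-negative class-connection weights and
#' summed.  The predicted class is the argmax of the logits.  A separate
#' *global* ranking across all classes' prototypes is used by the local
#' explanation and the reliability criteria.
#'
#' @name head
NULL

#' Initialize class-connection weights
#'
#' One row per prototype, one column per class.  Same-class entries start at
#' 1 and cross-class entries at `incorrect_class_connection` (default -0.5).
#' The initial negative cross-class weight matters during the SGD stages: it
#' penalizes prototypes whose similarity is equally high on every class
#' (e.g. patterns latched onto class-common background), which keeps
#' prototypes on class-discriminative parts.  The convex last-layer stage
#' subsequently zeroes all negative connections so the final model relies
#' only on positive evidence ("this looks like a class-A part"), never on
#' negative reasoning.
#'
#' @param patterns A [feature_patterns()] set.
#' @param classes Character vector of class labels in configured order.
#' @param incorrect_class_connection Initial cross-class weight (<= 0).
#' @export
init_class_connections <- function(patterns,
                                   classes = sort(unique(patterns$class_id)),
                                   incorrect_class_connection = -0.5) {
  P <- nrow(patterns$vectors)
  conn <- matrix(incorrect_class_connection, P, length(classes),
                 dimnames = list(NULL, classes))
  for (j in seq_along(classes))
    conn[patterns$class_id == classes[j], j] <- 1
  conn
}

# Indices (into the full prototype set) of the per-class top-k scorers among
# unpruned prototypes of that class.  scores is a full-length vector with NA
# at pruned positions.
topk_per_class <- function(scores, patterns, classes, k) {
  lapply(stats::setNames(classes, classes), function(cl) {
    cand <- which(patterns$class_id == cl & !patterns$flags$pruned)
    if (!length(cand))
      stop("empty-class error: class ", cl, " has no unpruned prototypes")
    cand[order(-scores[cand])][seq_len(min(k, length(cand)))]
  })
}

#' Class logits from pooled similarity scores
#'
#' For each class, the `top_k` highest-scoring prototypes of that class are
#' selected; every selected prototype then contributes `score x weight` to
#' each logit through its row of the connection matrix.  Once cross-class
#' weights are zero (the state every convex stage leaves behind) this is
#' exactly the per-class sum: logit of class `c` = sum over the top-`k`
#' class-`c` prototypes of their weighted scores.  Before that stage, a
#' negative cross-class weight lets a prototype that fires on every class
#' pull down the competing logit.
#'
#' @param scores Numeric vector of pooled similarity scores, one per
#'   prototype row in `patterns` (entries at pruned positions are ignored).
#' @param conn Class-connection weight matrix (`P x n_classes`, columns
#'   named by class).
#' @param patterns A [feature_patterns()] set.
#' @param cfg An [attention_config()]; `top_k` scores per class enter the
#'   logit.  When a class has fewer unpruned prototypes than `top_k`, all are
#'   used and a warning is logged.
#' @return Named numeric vector of logits.
#' @export
class_logits <- function(scores, conn, patterns, cfg = attention_config()) {
  classes <- colnames(conn)
  sel <- topk_per_class(scores, patterns, classes, cfg$top_k)
  short <- vapply(sel, length, 0L) < cfg$top_k
  if (any(short))
    warning("fewer than top_k unpruned prototypes for class(es): ",
            paste(classes[short], collapse = ", "), "; using all available")
  selu <- sort(unique(unlist(sel)))
  vapply(classes, function(cl)
    sum(scores[selu] * conn[selu, cl]), 0)
}

#' Predict the class from logits
#'
#' Argmax with a deterministic tie-break: an exact tie returns the first
#' class in configured order and emits a message.
#'
#' @param logits Named numeric vector of finite logits.
#' @export
predict_class <- function(logits) {
  if (any(!is.finite(logits))) stop("numeric error: non-finite logit")
  best <- which(logits == max(logits))
  if (length(best) > 1) message("logit tie; taking first configured class")
  names(logits)[best[1]]
}
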