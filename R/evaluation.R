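#' Evaluation: metrics, prototype QC, reliability screening
#'
#' Classification metrics from confusion counts; prototype quality control
#' (background-invalid and duplicate detection, pruning with re-evaluation);
#' the two-criterion reliability assessment of individual predictions; and
#' summary/statistical comparisons of the reliability tallies.
#'
#' @name evaluation
NULL

#' Confusion counts
#'
#' @param TP,FP,TN,FN Non-negative counts with a declared positive class.
#' @param positive Label of the positive class.
#' @export
confusion_counts <- function(TP, FP, TN, FN, positive = "A") {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN, positive = positive),
            class = "confusion_counts")
}

# Confusion counts from prediction data frame (predict_dataset output).
confusion_from_predictions <- function(pred, positive = "A") {
  confusion_counts(
    TP = sum(pred$label == positive & pred$predicted == positive),
    FP = sum(pred$label != positive & pred$predicted == positive),
    TN = sum(pred$label != positive & pred$predicted != positive),
    FN = sum(pred$label == positive & pred$predicted != positive),
    positive = positive)
}

#' Classification metrics
#'
#' Accuracy, precision, specificity, sensitivity and F1 from confusion
#' counts.  A metric whose denominator is zero is reported as `NA`
#' (undefined), not an error.
#'
#' @param counts A [confusion_counts()].
#' @return Named numeric vector `ACC`, `PRE`, `SPE`, `SEN`, `F1`.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    tot <- TP + FP + TN + FN
    stopifnot(tot > 0)
    div <- function(a, b) if (b > 0) a / b else NA_real_
    pre <- div(TP, TP + FP)
    sen <- div(TP, TP + FN)
    f1 <- if (!is.na(pre) && !is.na(sen) && pre + sen > 0)
      2 * pre * sen / (pre + sen) else NA_real_
    c(ACC = div(TP + TN, tot), PRE = pre, SPE = div(TN, TN + FP),
      SEN = sen, F1 = f1)
  })
}

#' Flag background-invalid prototypes
#'
#' A prototype is background-invalid when the peak of its self-activation
#' map on its source push image lies outside that image's lesion mask; it is
#' sub-classified as image-background (outside the brain mask) or
#' brain-background (inside the brain but outside the lesion).  Manual
#' overrides can be supplied as a data frame (or CSV path) with columns
#' `prototype` and `flag` (logical).
#'
#' @param model A trained, projected `pp_model`.
#' @param push_data Push set with lesion and brain masks.
#' @param manual Optional manual flag table or CSV path.
#' @return Data frame, one row per prototype: `background_invalid`,
#'   `background_kind` (`"none"`, `"brain"`, `"image"`),
#'   `manually_flagged`.
#' @export
flag_background_prototypes <- function(model, push_data = model$push_records,
                                       manual = NULL) {
  P <- nrow(model$patterns$vectors)
  flags <- data.frame(prototype = seq_len(P),
                      background_invalid = FALSE,
                      background_kind = "none",
                      manually_flagged = FALSE,
                      stringsAsFactors = FALSE)
  has_masks <- !is.null(push_data) &&
    all(vapply(push_data, function(r)
      !is.null(r$lesion_mask) && !is.null(r$brain_mask), TRUE))
  if (has_masks) {
    ge <- explain_global(model, push_data)
    for (e in ge$entries) {
      px <- e$argmax_pixel
      rec <- e$source_record
      in_lesion <- rec$lesion_mask[px[1], px[2]] > 0
      if (!in_lesion) {
        flags$background_invalid[e$prototype] <- TRUE
        flags$background_kind[e$prototype] <-
          if (rec$brain_mask[px[1], px[2]] > 0) "brain" else "image"
      }
    }
  } else {
    warning("masks unavailable: background flags limited to the manual file")
  }
  if (!is.null(manual)) {
    if (is.character(manual)) manual <- utils::read.csv(manual)
    flags$manually_flagged[manual$prototype[as.logical(manual$flag)]] <- TRUE
  }
  flags
}

#' Detect duplicate prototypes
#'
#' Flags within-class prototype pairs whose vectors have cosine similarity
#' at or above `cosine_threshold` (default 0.999 — effectively identical,
#' which projection onto the same latent patch produces); the later-indexed
#' member of each pair is flagged.
#'
#' @param patterns A [feature_patterns()] set.
#' @param cosine_threshold Similarity threshold in `[0, 1]`.
#' @return Logical vector, `TRUE` for duplicates.
#' @export
detect_duplicates <- function(patterns, cosine_threshold = 0.999) {
  V <- patterns$vectors
  P <- nrow(V)
  stopifnot(P >= 2)
  nrm <- sqrt(rowSums(V^2))
  dup <- rep(FALSE, P)
  for (p in seq_len(P - 1)) {
    if (dup[p]) next
    for (q in (p + 1):P) {
      if (patterns$class_id[q] != patterns$class_id[p]) next
      if (nrm[p] == 0 || nrm[q] == 0) {
        cs <- as.numeric(nrm[p] == 0 && nrm[q] == 0)
      } else cs <- sum(V[p, ] * V[q, ]) / (nrm[p] * nrm[q])
      if (cs >= cosine_threshold) dup[q] <- TRUE
    }
  }
  dup
}

#' Prune flagged prototypes and re-evaluate
#'
#' Marks the flagged prototypes pruned (no retraining), recomputes test-set
#' predictions with the reduced prototype set, and reports metrics before
#' and after.  Optionally re-fits the class connections with the convex
#' stage after pruning.
#'
#' @param model A trained `pp_model`.
#' @param prune Logical vector (length = prototypes) or prototype indices.
#' @param test_data Test records.
#' @param refit_connections If `TRUE`, run [convex_last_layer()] on
#'   `train_data` after pruning.
#' @param train_data,schedule Needed only when `refit_connections = TRUE`.
#' @return List with `before`, `after` (metric vectors), `model` (pruned)
#'   and the two prediction frames.
#' @export
prune_and_reevaluate <- function(model, prune, test_data,
                                 refit_connections = FALSE,
                                 train_data = NULL, schedule = NULL,
                                 positive = model$classes[1]) {
  if (!is.logical(prune)) {
    z <- rep(FALSE, nrow(model$patterns$vectors)); z[prune] <- TRUE
    prune <- z
  }
  for (cl in model$classes)
    if (all(prune[model$patterns$class_id == cl] |
            model$patterns$flags$pruned[model$patterns$class_id == cl]))
      stop("refusing to prune: class ", cl, " would have no prototypes left")
  pred_before <- predict_dataset(model, test_data)
  before <- classification_metrics(confusion_from_predictions(pred_before,
                                                              positive))
  model$patterns$flags$pruned <- model$patterns$flags$pruned | prune
  if (refit_connections)
    model <- convex_last_layer(model, train_data, schedule)
  pred_after <- predict_dataset(model, test_data)
  after <- classification_metrics(confusion_from_predictions(pred_after,
                                                             positive))
  list(before = before, after = after, model = model,
       pred_before = pred_before, pred_after = pred_after)
}

#' Assess the reliability of one local explanation
#'
#' Two criteria: (1) every top-10 prototype belongs to the reference class
#' (ground truth in `"truth"` mode, the model's prediction in `"predicted"`
#' mode); (2) every top-10 row's activation peak on the test image lies
#' inside the lesion mask — the automated proxy for concept consistency.
#' A prediction is reliable iff it is correct and both criteria hold.
#'
#' @param explanation A `local_explanation` (computed on the unpruned set).
#' @param truth_label Ground-truth label of the image (`NA` allowed in
#'   `"predicted"` mode).
#' @param lesion_mask,brain_mask Binary masks of the test image; when the
#'   lesion mask is missing, criterion 2 (and hence `reliable`) is `NA`.
#' @param mode `"truth"` or `"predicted"` reference class for criterion 1.
#' @return A `reliability_verdict`: flags, `mismatch_count` (top-10 rows
#'   from the other class) and `background_hits` (peaks in image- vs
#'   brain-background).
#' @export
assess_reliability <- function(explanation, truth_label,
                               lesion_mask = NULL, brain_mask = NULL,
                               mode = c("truth", "predicted")) {
  mode <- match.arg(mode)
  ref <- if (mode == "truth") truth_label else explanation$prediction
  rows <- explanation$rows
  crit1 <- all(rows$class_id == ref)
  mismatch <- sum(rows$class_id != ref)
  correct <- !is.na(truth_label) && explanation$prediction == truth_label
  if (is.null(lesion_mask)) {
    crit2 <- NA
    bg <- c(image = NA_integer_, brain = NA_integer_)
  } else {
    pk <- cbind(rows$peak_row, rows$peak_col)
    in_lesion <- lesion_mask[pk] > 0
    crit2 <- all(in_lesion)
    in_brain <- if (is.null(brain_mask)) rep(TRUE, nrow(pk)) else
      brain_mask[pk] > 0
    bg <- c(image = sum(!in_lesion & !in_brain),
            brain = sum(!in_lesion & in_brain))
  }
  structure(list(id = explanation$id, truth_label = truth_label,
                 prediction = explanation$prediction,
                 prediction_correct = correct,
                 criterion1_all_top10_same_class = crit1,
                 criterion2_all_top10_concept_consistent = crit2,
                 reliable = if (is.na(crit2)) NA else correct && crit1 && crit2,
                 mismatch_count = mismatch, background_hits = bg),
            class = "reliability_verdict")
}

verdicts_to_frame <- function(verdicts) {
  do.call(rbind, lapply(verdicts, function(v) data.frame(
    id = v$id, truth = v$truth_label, prediction = v$prediction,
    correct = v$prediction_correct,
    criterion1 = v$criterion1_all_top10_same_class,
    criterion2 = v$criterion2_all_top10_concept_consistent,
    reliable = v$reliable, mismatch = v$mismatch_count,
    bg_image = v$background_hits["image"],
    bg_brain = v$background_hits["brain"], row.names = NULL)))
}

#' Reliability summary tables
#'
#' Per group (all / correct / wrong / unreliable-but-correct) and per class:
#' mean and sample (n-1) SD of the matched and mismatched top-10 counts, and
#' of the image-/brain-background hit counts.
#'
#' @param verdicts List of `reliability_verdict`s.
#' @param top_k The `top_k` used (to form matched = top_k - mismatched).
#' @return Data frame with one row per (group, class) present.
#' @export
reliability_summary <- function(verdicts, top_k = 10L) {
  df <- verdicts_to_frame(verdicts)
  groups <- list(all = rep(TRUE, nrow(df)),
                 correct = df$correct,
                 wrong = !df$correct,
                 unreliable = df$correct & !df$reliable & !is.na(df$reliable))
  out <- NULL
  msd <- function(x) c(mean = mean(x), sd = stats::sd(x))
  for (g in names(groups)) {
    for (cl in sort(unique(df$truth))) {
      sel <- groups[[g]] & df$truth == cl
      if (!any(sel)) next
      mm <- msd(df$mismatch[sel])
      mt <- msd(top_k - df$mismatch[sel])
      bi <- msd(df$bg_image[sel])
      bb <- msd(df$bg_brain[sel])
      out <- rbind(out, data.frame(
        group = g, class = cl, n = sum(sel),
        matched_mean = mt[1], matched_sd = mt[2],
        mismatched_mean = mm[1], mismatched_sd = mm[2],
        bg_image_mean = bi[1], bg_image_sd = bi[2],
        bg_brain_mean = bb[1], bg_brain_sd = bb[2], row.names = NULL))
    }
  }
  out
}

#' Paired test of background sources
#'
#' Two-sided Wilcoxon signed-rank test comparing, per image, the number of
#' top-10 activation peaks in image background versus brain background.
#' Zero-difference pairs are dropped (the standard convention).  When every
#' pair is tied the test is undefined and `NA`s are returned.
#'
#' @param verdicts List of `reliability_verdict`s.
#' @param classes Optional class subset (by truth label).
#' @return List with `statistic` (W), `p_value`, `n_pairs` (non-zero pairs).
#' @export
background_source_test <- function(verdicts, classes = NULL) {
  df <- verdicts_to_frame(verdicts)
  if (!is.null(classes)) df <- df[df$truth %in% classes, ]
  x <- df$bg_image; y <- df$bg_brain
  nz <- sum(x != y, na.rm = TRUE)
  if (nz == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n_pairs = 0L))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n_pairs = nz)
}

#' Evaluate a model end to end
#'
#' Convenience wrapper: predicts the test set, computes local explanations
#' and reliability verdicts for every test image, and returns metrics,
#' verdicts and summary tables.
#'
#' @param model A trained, projected `pp_model`.
#' @param test_data Test records (with masks for criterion 2).
#' @param mode Reference-class mode for criterion 1.
#' @return List with `predictions`, `metrics`, `verdicts`, `summary`,
#'   `reliable_correct_fraction`.
#' @export
evaluate_model <- function(model, test_data, mode = "truth",
                           positive = model$classes[1]) {
  pred <- predict_dataset(model, test_data)
  metrics <- classification_metrics(confusion_from_predictions(pred, positive))
  verdicts <- lapply(test_data, function(rec) {
    ex <- explain_local(model, rec)
    assess_reliability(ex, rec$label, rec$lesion_mask, rec$brain_mask,
                       mode = mode)
  })
  df <- verdicts_to_frame(verdicts)
  rcf <- if (any(df$correct)) mean(df$reliable[df$correct]) else NA_real_
  list(predictions = pred, metrics = metrics, verdicts = verdicts,
       summary = reliability_summary(verdicts, model$cfg$top_k),
       reliable_correct_fraction = rcf)
}
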