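#' Desk-scale phantom experiment
#'
#' End-to-end study on synthetic lesion phantoms: generate a balanced
#' two-class dataset with masks, z-score normalize, train a tiny-backbone
#' prototype-part model through the three-stage schedule, and evaluate
#' held-out accuracy, prototype validity (self-activation peak inside the
#' source lesion mask) and the reliability of correct predictions under the
#' two screening criteria.
#'
#' Default problem size: 100 training + 30 test images per class at 64x64,
#' 10 prototypes per class, 6 pretraining epochs and 16 three-stage epochs
#' with pushes after epochs 10 and 16 — small enough to train in minutes on
#' one CPU while leaving the phantom classes clearly separable.
#'
#' @param seed Integer seed for data, initialization and training.
#' @param n_train_per_class,n_test_per_class Images per class.
#' @param image_size Phantom side in pixels.
#' @param prototypes_per_class Feature patterns per class.
#' @param schedule A [training_schedule()]; `NULL` uses the desk-scale
#'   default above (the schedule seed is always forced to `seed`).
#' @param push_per_class Push-set size per class.
#' @return List with `model`, `train`, `test`, `push`, `evaluation` (from
#'   [evaluate_model()]), `validity` (per-prototype logical, peak in source
#'   lesion), `accuracy`, `validity_fraction`, `reliable_correct_fraction`.
#' @export
run_phantom_experiment <- function(seed = 1L,
                                   n_train_per_class = 100L,
                                   n_test_per_class = 30L,
                                   image_size = 64L,
                                   prototypes_per_class = 10L,
                                   schedule = NULL,
                                   push_per_class = 30L) {
  # desk-scale schedule: after task pretraining the base counts as
  # pretrained and is protected by the small base learning rate
  if (is.null(schedule))
    schedule <- training_schedule(warmup_epochs = 2L, total_epochs = 16L,
                                  push_epochs = c(10L, 16L),
                                  batch_size = 32L, seed = seed)
  schedule$seed <- as.integer(seed)
  n_pc <- n_train_per_class + n_test_per_class
  ds <- generate_dataset(n_pc, image_size = image_size, seed = seed)
  # standard slice pipeline: normalize, crop the background away so feature
  # learning concentrates on brain area, resize to the model input side
  ds <- lapply(ds, function(r)
    resize_image(crop_background(zscore_normalize(r)), image_size))
  # interleaved A,B,...: first 2*n_train_per_class records form the train set
  train <- ds[seq_len(2L * n_train_per_class)]
  test <- ds[(2L * n_train_per_class + 1L):(2L * n_pc)]
  labs <- vapply(train, `[[`, "", "label")
  set.seed(seed + 1000L)
  push <- train[c(sample(which(labs == "A"), push_per_class),
                  sample(which(labs == "B"), push_per_class))]

  cfg <- attention_config(prototypes_per_class = prototypes_per_class,
                          top_k = 10L)
  model <- pp_model(backbone_spec("tiny", input_side = image_size),
                    classes = c("A", "B"), cfg = cfg, seed = seed)
  # no pretrained checkpoint exists for the tiny base: pretrain it on the
  # task itself, then seed prototypes from class-unique push patches
  set.seed(seed)
  model <- pretrain_backbone(model, train, epochs = 6L)
  model <- init_prototypes_from_push(model, push)
  model <- fit(model, train, push, schedule)

  ev <- evaluate_model(model, test)
  flags <- flag_background_prototypes(model, push)
  validity <- !flags$background_invalid
  list(model = model, train = train, test = test, push = push,
       evaluation = ev, validity = validity,
       accuracy = unname(ev$metrics["ACC"]),
       validity_fraction = mean(validity),
       reliable_correct_fraction = ev$reliable_correct_fraction)
}

#' Corrupt a model by re-pointing prototypes at background patches
#'
#' Screening-property probe: re-points a fraction of one class's prototypes
#' to latent patches of push images whose activation peak lies *outside* the
#' lesion mask (brain background), mimicking a model that has latched onto
#' clinically irrelevant tissue.  Explanations of such a model should be
#' flagged unreliable by the mask-based concept-consistency criterion, so
#' its reliability rate drops below the intact model's.
#'
#' @param model A trained, projected `pp_model`.
#' @param push_data Push records with masks.
#' @param class_id Class whose prototypes are corrupted.
#' @param fraction Fraction of that class's prototypes to re-point.
#' @return The corrupted model.
#' @export
corrupt_prototypes <- function(model, push_data = model$push_records,
                               class_id = model$classes[1],
                               fraction = 0.5) {
  idx <- which(model$patterns$class_id == class_id)
  n_corrupt <- ceiling(fraction * length(idx))
  victims <- idx[seq_len(n_corrupt)]
  ids <- vapply(push_data, `[[`, "", "id")
  labels <- vapply(push_data, `[[`, "", "label")
  Wl <- model$backbone$latent_side
  stride <- model$backbone$spatial_stride
  k <- 0L
  for (i in which(labels == class_id)) {
    rec <- push_data[[i]]
    latent <- extract_features(model$backbone, rec)
    pm <- latent_patches(latent)
    # background patches: receptive-cell center outside the lesion mask but
    # inside the brain
    for (j in seq_len(nrow(pm))) {
      r <- ((j - 1L) %/% Wl) + 1L; c <- ((j - 1L) %% Wl) + 1L
      pr <- round((r - 0.5) * stride + 0.5); pc <- round((c - 0.5) * stride + 0.5)
      if (rec$lesion_mask[pr, pc] == 0 && rec$brain_mask[pr, pc] > 0 &&
          sum(pm[j, ]^2) > 0) {
        k <- k + 1L
        model$patterns$vectors[victims[k], ] <- pm[j, ]
        model$patterns$source_image_id[victims[k]] <- ids[i]
        model$patterns$source_location[victims[k], ] <- c(r, c)
        if (k == n_corrupt) break
      }
    }
    if (k == n_corrupt) break
  }
  if (k < n_corrupt)
    warning("only ", k, " of ", n_corrupt,
            " prototypes could be re-pointed to background patches")
  model
}
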