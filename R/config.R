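#' Run configuration
#'
#' A single YAML file holds every tunable of a run, in nested sections
#' mirroring the pipeline stages.  Unknown keys are rejected by name so
#' misspellings cannot silently fall back to defaults.
#'
#' @name config
NULL

config_defaults <- function() {
  list(
    seed = 1L,
    output_root = "runs",
    data = list(n_per_class = 100L, image_size = 64L),
    preprocess = list(train_fraction = 0.70, push_per_class = 30L,
                      include_originals = TRUE, augment = FALSE,
                      rotation_limit = 20, shear_limit = 10,
                      skew_magnitude = 0.2, copies_per_op = 2L),
    backbone = list(base = "tiny", out_channels = 128L, input_side = 64L,
                    addon_mid = NULL),
    attention = list(epsilon = 1e-4, prototypes_per_class = 50L, top_k = 10L),
    head = list(top_k_in_training = TRUE),
    losses = list(r1 = 0.8, r2 = 0.08),
    schedule = list(warmup_epochs = 5L, total_epochs = 100L,
                    push_epochs = c(20L, 40L, 60L, 80L, 100L),
                    last_layer_iters = 20L,
                    lr_addon_and_prototypes = 3e-3, lr_pretrained = 1e-4,
                    lr_last_layer = 1e-4, lambda = 1e-4, batch_size = 32L,
                    clip_grad_norm = 5),
    explain = list(threshold_quantile = 0.95),
    evaluate = list(mode = "truth", positive_class = "A",
                    duplicate_cosine_threshold = 0.999)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("config validation error: unknown key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  for (k in names(user)) {
    if (is.null(user[[k]])) next            # YAML '~' means "use default"
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML file, applies defaults for absent keys, and validates that
#' no unknown keys are present.  An empty or missing-body file returns the
#' full defaults.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  cfg <- merge_config(config_defaults(), user)
  structure(cfg, class = "run_config")
}

#' Save a configuration
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  # stable content hash without external digest dependencies
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997 + 1)) %% 1e9
}

# Helper constructors from a config
schedule_from_config <- function(config) {
  s <- config$schedule
  training_schedule(warmup_epochs = s$warmup_epochs,
                    total_epochs = s$total_epochs,
                    push_epochs = unlist(s$push_epochs),
                    last_layer_iters = s$last_layer_iters,
                    lr_addon_and_prototypes = s$lr_addon_and_prototypes,
                    lr_pretrained = s$lr_pretrained,
                    lr_last_layer = s$lr_last_layer,
                    lambda = s$lambda, batch_size = s$batch_size,
                    clip_grad_norm = s$clip_grad_norm,
                    seed = config$seed)
}

model_from_config <- function(config, classes = c("A", "B")) {
  bs <- backbone_spec(base = config$backbone$base,
                      out_channels = config$backbone$out_channels,
                      input_side = config$backbone$input_side,
                      addon_mid = config$backbone$addon_mid)
  cfg <- attention_config(epsilon = config$attention$epsilon,
                          prototypes_per_class = config$attention$prototypes_per_class,
                          top_k = config$attention$top_k)
  lw <- loss_weights(r1 = config$losses$r1, r2 = config$losses$r2)
  pp_model(bs, classes = classes, cfg = cfg, lw = lw, seed = config$seed)
}
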