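# Small trained fixture model shared across test files (built once per run).
# 24 training phantoms at 64x64, 2 prototypes per class, 4 epochs with one
# push: enough structure for contract tests, small enough to train in
# seconds.

fixture_training_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(16, 64, seed = 101)
      ds <- lapply(ds, function(r)
        resize_image(crop_background(zscore_normalize(r)), 64))
      labs <- vapply(ds, `[[`, "", "label")
      cache <<- list(train = ds[1:24], test = ds[25:32],
                     push = ds[c(which(labs == "A")[1:6],
                                 which(labs == "B")[1:6])])
    }
    cache
  }
})

fixture_model_spec <- function(seed = 7) {
  pp_model(backbone_spec("tiny", input_side = 64, out_channels = 32,
                         addon_mid = 32),
           classes = c("A", "B"),
           cfg = attention_config(prototypes_per_class = 2, top_k = 2),
           seed = seed)
}

fixture_schedule <- function(seed = 7, total = 4L, push = c(3L, 4L),
                             warmup = 1L) {
  training_schedule(warmup_epochs = warmup, total_epochs = total,
                    push_epochs = push, batch_size = 12L, seed = seed)
}

fixture_trained_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture_training_data()
      model <- fixture_model_spec()
      cache <<- fit(model, fx$train, fx$push, fixture_schedule())
    }
    cache
  }
})
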