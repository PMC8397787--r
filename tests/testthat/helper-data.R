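# Shared desk-scale fixtures. Expensive objects (rendered datasets, the
# trained reference model) are built once per session and memoized, so
# every test that needs a trained classifier shares one honest training
# run.

.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Desk-scale preprocessing: centered ROI at half the frame, 64x64 input.
desk_roi_cfg <- function() roi_config(roi_fraction = 0.5, output_side = 64)

desk_canvas <- c(192, 256)

# Render a class-balanced dataset and preprocess with the centered chain.
render_centered_xy <- function(n_per_class, seed) {
  m <- generate_manifest(rep_len(n_per_class, 5), canvas = desk_canvas,
                         rng_seed = seed)
  cfg <- desk_roi_cfg()
  imgs <- lapply(seq_len(nrow(m)), function(i)
    preprocess_image(render_manifest_image(m, i), cfg))
  list(manifest = m, x = imgs, y = match(m$label, oral_classes()),
       pid = m$patient_id)
}

# Random-positioning counterpart: lesions placed anywhere, random crop.
render_random_xy <- function(n_per_class, seed) {
  m <- generate_manifest(rep_len(n_per_class, 5), protocol = "random",
                         canvas = desk_canvas, rng_seed = seed)
  imgs <- lapply(seq_len(nrow(m)), function(i)
    simulate_random_positioning(render_manifest_image(m, i), 0.5,
                                derive_seed(seed, "randcrop", i),
                                output_side = 64))
  list(manifest = m, x = imgs, y = match(m$label, oral_classes()),
       pid = m$patient_id)
}

desk_train_cfg <- function(epochs, lr = 0.05, drops = c(8), max_steps = Inf) {
  train_config(initial_lr = lr, lr_drop_epochs = drops, epochs = epochs,
               folds = 1, max_steps = max_steps)
}

demo_train_data <- function()
  memo_fixture("train200", function() render_centered_xy(200, 101))

demo_val_data <- function()
  memo_fixture("val50", function() render_centered_xy(50, 202))

# The reference trained classifier: 200 images/class at 64x64, tiny
# backbone, 18 epochs.
demo_model_fit <- function() memo_fixture("fit", function() {
  tr <- demo_train_data(); va <- demo_val_data()
  train_model(tr$x, tr$y, desk_train_cfg(18, drops = c(10, 15)),
              val = list(x = va$x, y = va$y), roi_cfg = desk_roi_cfg(),
              rng_seed = 404)
})

# A model with random (untrained but nonzero) head weights, for tests of
# forward-pass identities that need non-degenerate logits.
random_head_model <- function(seed = 5) {
  m <- make_model(rng_seed = seed)
  m$head_conv$W <- with_seed(seed, matrix(stats::rnorm(5 * 64, sd = 0.3), 5, 64))
  m$head_conv$b <- with_seed(seed + 1, stats::rnorm(5, sd = 0.1))
  m$head_bn$running_mean <- with_seed(seed + 2, stats::rnorm(5, sd = 0.05))
  m$head_bn$running_var <- with_seed(seed + 3, stats::runif(5, 0.5, 1.5))
  m
}
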