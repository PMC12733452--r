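# a tiny dataset + frozen model give a perfectly constant validation metric,
# which exposes the scheduler/early-stop bookkeeping deterministically
frozen_toy_fit <- function(max_epochs = 30, ckdir = NULL) {
  stack <- phantom_slice_stack(8, image_size = 16, seed = 2)
  va <- phantom_slice_stack(4, image_size = 16, seed = 3)
  m <- build_unet(model_spec("unet", input_size = c(16, 16, 3),
                             base_width = 2, depth = 2, seed = 1))
  freeze_parameters(m)
  cfg <- train_config(batch_size = 8, learning_rate = 1e-4,
                      max_epochs = max_epochs, seed = 5)
  train(m, stack, va, cfg, checkpoint_dir = ckdir)
}
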