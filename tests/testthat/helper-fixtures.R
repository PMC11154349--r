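# Shared small fixtures and a lazy cache for the expensive acceptance
# fixtures (built once per test run, reused across criteria).

tiny_layout <- function(m = 5L) {
  full <- standard_1020_layout()
  electrode_layout(full$names[seq_len(m)],
                   full$coords[seq_len(m), , drop = FALSE])
}

tiny_config <- function(m = 5L, ...) {
  defaults <- list(n_channels = m, d_model = 8L, n_heads = 2L,
                   window_K = 3L, avg_n = 2L, alpha = 1.5, k_edges = 2L,
                   diffusion_dim = 3L, hidden_dim = 4L, seed = 3L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

tiny_model <- function(m = 5L, ...) dtgcn_model(tiny_config(m, ...),
                                                layout = tiny_layout(m))

random_clip <- function(n = 20L, m = 5L, seed = 1L, seizure = TRUE) {
  set.seed(seed)
  fine <- integer(n)
  if (seizure) fine[seq(n %/% 3, n %/% 2)] <- 1L
  eeg_clip(matrix(rnorm(n * m), n, m), fs = n, fine_labels = fine,
           seizure_class = if (seizure) "GN" else "none",
           clip_seconds = 1)
}

.acc_cache <- new.env(parent = emptyenv())

acc_fixture <- function(name, build) {
  if (is.null(.acc_cache[[name]])) .acc_cache[[name]] <- build()
  .acc_cache[[name]]
}

# The end-to-end stated world of acceptance criterion 6: 200 synthetic
# 19-channel records (one 12 s clip each) at 64 Hz, multitask model with
# hidden size 16, trained <= 15 epochs.
acc_data <- function() acc_fixture("data", function() {
  generate_dataset(synth_config(seed = 42), 200)
})

acc_model <- function() acc_fixture("model", function() {
  data <- acc_data()
  mcfg <- model_config(hidden_dim = 16L, d_model = 32L,
                       diffusion_dim = 8L, task = "multitask", seed = 1L)
  train_dtgcn(dtgcn_model(mcfg), data,
              train_config(learning_rate = 1e-2, max_epochs = 12L,
                           batch_size = 8L, seed = 1L))
})
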