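# Shared fixtures: all images are generated in code at test time.

make_test_images <- function(preset, n, size = 48L, seed_off = 0L,
                             log_compress = TRUE) {
  lapply(seq_len(n), function(i) {
    spec <- sample_phantom_spec(size, size, seed = i + seed_off)
    simulate_bscan(make_reflectivity_map(spec), preset,
                   seed = 31L * i + seed_off, log_compress = log_compress,
                   source_id = sprintf("%s_%03d", preset$name, i))
  })
}

# a tiny, fast training configuration for smoke runs
smoke_config <- function(epochs = 2L, interval = 2L, seed = 1L, crop = 32L) {
  desk_training_config(epochs = epochs, checkpoint_interval = interval,
                       seed = seed, resize = crop + 4L, crop = crop,
                       width = 8L, n_res_blocks = 1L,
                       nce_layers = c(0L, 4L, 8L, 10L),
                       patches_per_layer = 16L, embed_dim = 16L,
                       d_width = 8L)
}

# random unit-norm embedding rows
unit_rows <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

# hand-built patch_features object (bypasses the encoder) for loss oracles
make_patch_features <- function(n_layers, S, d, tau = 0.07, seed = 1L) {
  set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(l) {
    list(queries = unit_rows(S, d), positives = unit_rows(S, d),
         locations = seq_len(S))
  })
  names(layers) <- as.character(seq_len(n_layers) - 1L)
  structure(list(layers = layers, tau = tau), class = "patch_features")
}
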