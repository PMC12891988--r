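# Shared fixtures: small cohorts and fast network specs so unit tests run
# in seconds. The acceptance tests use the full-size defaults instead.

tiny_config <- function(n_per_class = 20L, d = 40L, s = 4L, seed = 7L,
                        coupling = "coupled", ...) {
  synthetic_config(n_classes = 3L, n_per_class = n_per_class, d_f = d,
                   d_g = d, shared_dim = s, coupling = coupling,
                   seed = seed, ...)
}

tiny_ae_spec <- function(d_in = 40L, d_out = 40L, bottleneck = 16L,
                         epochs = 30L, lr = 1e-3, seed = 1L) {
  autoencoder_spec(d_in, d_out, encoder_widths = c(32L, 24L),
                   bottleneck = bottleneck, decoder_widths = c(24L, 32L),
                   epochs = epochs, learning_rate = lr, seed = seed)
}

tiny_mono_spec <- function(latent_dim = 16L, epochs = 40L, lr = 1e-3,
                           seed = 1L, ...) {
  monogram_spec(latent_dim = latent_dim, hidden_widths = c(64L, 32L),
                epochs = epochs, learning_rate = lr, seed = seed, ...)
}

# Latents + labels with clear class structure, for monogram-stage tests
# that do not need the autoencoder stage.
tiny_latents <- function(n_per_class = 12L, l = 16L, n_classes = 3L,
                         sep = 3, seed = 11L) {
  set.seed(seed)
  n <- n_per_class * n_classes
  centers <- matrix(rnorm(n_classes * l, sd = sep), n_classes, l)
  cls <- rep(seq_len(n_classes), each = n_per_class)
  U <- centers[cls, ] + matrix(rnorm(n * l), n, l)
  V <- centers[cls, ] * 0.5 + matrix(rnorm(n * l), n, l)
  list(U = U, V = V,
       labels = paste0("class_", LETTERS[cls]),
       ids = sprintf("P%03d", seq_len(n)))
}

random_archive <- function(n = 20L, n_classes = 2L, seed = 5L,
                           real = FALSE) {
  set.seed(seed)
  bits <- matrix(sample(0:1, n * 64L, replace = TRUE), n, 64L)
  monogram_archive(sprintf("P%03d", seq_len(n)),
                   paste0("class_", sample(LETTERS[seq_len(n_classes)], n,
                                           replace = TRUE)),
                   bits,
                   real = if (real) matrix(tanh(rnorm(n * 64L)), n, 64L))
}
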