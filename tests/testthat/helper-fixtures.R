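# Shared fixtures. Heavy objects (trained models, large synthetic sets) are
# built once per test run and memoised in `.fixtures`.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Desk-scale model: the reference layer graph at reduced width.
desk_model_config <- function(seq_length = 300L, seed = 202L) {
  model_config(
    seq_length = seq_length, conv_channels = 16L, lstm_hidden = 32L,
    attention_heads = 4L, fc_sizes = c(32L, 32L),
    channel_attention_reduction = 4L, seed = seed
  )
}

desk_train_config <- function(epochs = 8L, seed = 303L) {
  train_config(epochs = epochs, seed = seed)
}

# Tiny model for fast structural tests.
tiny_model_config <- function(seq_length = 30L, seed = 7L, ...) {
  model_config(
    seq_length = seq_length, conv_channels = 4L, lstm_hidden = 8L,
    attention_heads = 2L, fc_sizes = c(8L, 8L),
    channel_attention_reduction = 2L, seed = seed, ...
  )
}

# Study conditions: AT-rich 300-nt leaders whose only class signal is a
# discriminative motif planted in the proximal -1..-30 window.
proximal_signal_spec <- function(n_per_class = 2000L, seed = 101L) {
  synthetic_spec(
    n_per_class = n_per_class, length = 300L, at_fraction = 0.70,
    class_motifs = list(
      alga = list(motif = "GCCGCG", window = c(-20L, -9L), prob = 1),
      plant = list(motif = NULL, window = NULL, prob = 0)
    ),
    seed = seed
  )
}

# Control conditions: the same signal planted distally (-100..-130), so
# proximal truncation leaves it untouched.
distal_signal_spec <- function(n_per_class = 600L, seed = 111L) {
  synthetic_spec(
    n_per_class = n_per_class, length = 300L, at_fraction = 0.70,
    class_motifs = list(
      alga = list(motif = "GCCGCG", window = c(-130L, -100L), prob = 1),
      plant = list(motif = NULL, window = NULL, prob = 0)
    ),
    seed = seed
  )
}

random_at_rich <- function(n, length = 300L, seed = 1L, at = 0.70) {
  spec <- synthetic_spec(
    n_per_class = n, length = length, at_fraction = at,
    class_motifs = list(x = list(motif = NULL, window = NULL, prob = 0)),
    seed = seed
  )
  generate_leaders(spec)
}

# The main trained synthetic experiment, shared by several acceptance tests:
# full-length + truncated arms under the identical recipe.
get_main_experiment <- function() {
  memo("main_experiment", function() {
    leaders <- generate_leaders(proximal_signal_spec())
    truncation_experiment(
      leaders,
      remove = 30L,
      model_cfg = desk_model_config(),
      train_cfg = desk_train_config()
    )
  })
}

get_control_experiment <- function() {
  memo("control_experiment", function() {
    leaders <- generate_leaders(distal_signal_spec())
    truncation_experiment(
      leaders,
      remove = 30L,
      model_cfg = desk_model_config(seed = 203L),
      train_cfg = desk_train_config(seed = 304L)
    )
  })
}
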