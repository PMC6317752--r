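# Shared fixtures. Heavy objects (trained models) are built once per test
# run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

# small network + random sequences for gradient/likelihood oracles
tiny_setup <- function(seed = 1, n_context = 3, n_pb = 1, n_input = 4,
                       T_len = 6, n_seq = 2) {
  cfg <- network_config(n_input = n_input, n_context = n_context,
                        n_pb = n_pb, tau = 4, n_joint = n_input - 2)
  params <- init_network_params(cfg, n_sequences = n_seq, seed = seed)
  set.seed(seed + 500)
  params$u0_pb <- matrix(stats::rnorm(n_pb * n_seq, 0, 0.5), n_pb, n_seq)
  seqs <- lapply(seq_len(n_seq), function(i)
    matrix(stats::runif(T_len * n_input, -0.7, 0.7), T_len, n_input))
  list(cfg = cfg, params = params, seqs = seqs)
}

# central finite differences of the accumulated likelihood
fd_gradient <- function(params, cfg, seqs, dims, field, h = 1e-5) {
  arr <- params[[field]]
  fd <- arr * 0
  for (i in seq_along(arr)) {
    pp <- params; pp[[field]][i] <- arr[i] + h
    pm <- params; pm[[field]][i] <- arr[i] - h
    fd[i] <- (accumulate_likelihood(pp, cfg, seqs, dims = dims) -
                accumulate_likelihood(pm, cfg, seqs, dims = dims)) / (2 * h)
  }
  fd
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(a) + abs(b), floor))
}

# reduced-scale experiment profile shared by the learning/adaptation tests
reduced_specs <- function() behavior_specs(length_scale = 1 / 8)

reduced_config <- function() {
  network_config(n_context = 20, learning_epochs = 10000L)
}

reduced_targets <- function() {
  if (is.null(.fixture_cache$targets))
    .fixture_cache$targets <- make_target_set(reduced_specs(), 3, seed = 1)
  .fixture_cache$targets
}

# one trained reduced-scale model, shared across test files
reduced_model <- function() {
  if (is.null(.fixture_cache$model))
    .fixture_cache$model <- train_offline(reduced_targets(),
                                          reduced_config(), seed = 1,
                                          epochs = 10000L,
                                          select = "best")
  .fixture_cache$model
}

reduced_library <- function() {
  if (is.null(.fixture_cache$library))
    .fixture_cache$library <- behavior_library(reduced_targets())
  .fixture_cache$library
}
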