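#' Offline supervised training of the S-CTRNN with PB
#'
#' Fits all synaptic weights, biases, and one PB initial internal state
#' per target sequence by full-batch gradient descent with momentum on
#' the accumulated heteroscedastic negative log-likelihood, teacher-forced
#' by default (each step's input is the recorded value, its target the
#' next recorded value). Through this joint optimization the associations
#' between behaviors and regions of PB space self-organize: sequences of
#' the same behavior end up with nearby PB states.
#'
#' @param targets List of `vp_sequence` training sequences.
#' @param config An `sctrnn_config`.
#' @param seed Integer seed for the weight initialization.
#' @param epochs Number of full-batch updates (defaults to
#'   `config$learning_epochs`; the full-scale default is 300000, reduced
#'   profiles use a few thousand).
#' @param teacher_forcing If `FALSE`, inputs after the first step are the
#'   network's own mean predictions (closed-loop training) and gradients
#'   flow through the feedback path.
#' @param init_params Optional pre-built `sctrnn_params` (overrides
#'   `seed`).
#' @param select Which parameters the model keeps: `"final"` (the fixed
#'   epoch count's last update, the full-scale protocol) or `"best"`
#'   (the epoch with the lowest accumulated NLL). At reduced scale the
#'   momentum dynamics oscillate around the optimum, so a fixed stopping
#'   epoch can land mid-excursion; `"best"` removes that lottery without
#'   changing the optimization path.
#' @return An `sctrnn_model`: trained `params`, the `config`, per-epoch
#'   `loss_history`, `sequence_labels`, learned PB states grouped by
#'   behavior (`pb_by_behavior`), and the seed.
#' @export
train_offline <- function(targets, config, seed = 1L,
                          epochs = config$learning_epochs,
                          teacher_forcing = TRUE, init_params = NULL,
                          select = c("final", "best")) {
  select <- match.arg(select)
  stopifnot(length(targets) >= 1, epochs >= 1)
  params <- if (is.null(init_params))
    init_network_params(config, n_sequences = length(targets), seed = seed)
  else init_params
  io <- lapply(targets, function(s) .io_split(.seq_matrix(s)))
  # the learning rate applies to the time-normalized gradient: the raw
  # Eq.-7-style sum grows linearly with sequence length, which would make
  # the fixed rate/momentum pair divergent for the variance units
  grad_scale <- 1 / mean(vapply(io, function(z) nrow(z$X), numeric(1)))
  fit <- cpp_train(unclass(params),
                   lapply(io, `[[`, "X"),
                   lapply(io, `[[`, "targets"),
                   params$u0_pb,
                   config$tau, config$variance_offset_K,
                   config$variance_floor_epsilon,
                   seq_len(config$n_output),
                   config$learning_rate_alpha, config$momentum_eta,
                   as.integer(epochs), !teacher_forcing, grad_scale)
  keep <- if (select == "best") fit$best_params else fit$params
  params[.setdiff_pb(.param_fields)] <- keep[.setdiff_pb(.param_fields)]
  for (nm in c("b_c", "b_o", "b_v")) params[[nm]] <- drop(params[[nm]])
  params$u0_pb <- if (select == "best") fit$best_u0_pb else fit$u0_pb
  labels <- vapply(targets, function(s)
    if (inherits(s, "vp_sequence")) s$behavior_label else NA_character_,
    character(1))
  model <- list(params = params, config = config,
                loss_history = fit$loss_history,
                sequence_labels = labels,
                pb_by_behavior = .split_pb(fit$u0_pb, labels),
                seed = if (is.null(init_params)) as.integer(seed)
                       else init_params$seed)
  class(model) <- "sctrnn_model"
  model
}

.setdiff_pb <- function(fields) setdiff(fields, "u0_pb")

#' @export
print.sctrnn_model <- function(x, ...) {
  cat(sprintf(paste0("<sctrnn_model> %d context units, %d PB units, ",
                     "%d sequences, %d epochs\n  final loss %.4g ",
                     "(initial %.4g)\n"),
              x$config$n_context, x$config$n_pb,
              length(x$sequence_labels), length(x$loss_history),
              x$loss_history[length(x$loss_history)], x$loss_history[1]))
  invisible(x)
}

#' Learned PB internal state for a behavior
#'
#' The mean of the learned PB initial internal states of the behavior's
#' training sequences; used as the starting "intention" of a trial.
#'
#' @param model An `sctrnn_model`.
#' @param behavior Behavior label.
#' @return PB internal-state vector.
#' @export
pb_for_behavior <- function(model, behavior) {
  m <- model$pb_by_behavior[[behavior]]
  if (is.null(m)) stop("no learned PB states for behavior '", behavior, "'")
  rowMeans(m)
}

#' Closed-loop sequence generation
#'
#' Rolls the trained network forward for `T_len` steps feeding each mean
#' prediction back as the next input, starting from a zero context state,
#' a fixed PB internal state, and one external input vector. This is how
#' a learned behavior is regenerated without any external data.
#'
#' @param model An `sctrnn_model`.
#' @param pb_internal PB internal-state vector.
#' @param x_initial Initial sensory input (length `n_input`).
#' @param T_len Number of prediction steps.
#' @param K Variance offset in force.
#' @return List with `mean_y` (`T_len x n_output`) and `variance_v`
#'   (`T_len x n_variance`), class `sctrnn_generation`.
#' @export
generate_closed_loop <- function(model, pb_internal, x_initial, T_len,
                                 K = model$config$variance_offset_K) {
  stopifnot(T_len >= 1,
            length(x_initial) == model$config$n_input,
            length(pb_internal) == model$config$n_pb)
  f <- cpp_forward(unclass(model$params),
                   matrix(x_initial, nrow = 1),
                   pb_internal, numeric(model$config$n_context),
                   model$config$tau, K,
                   model$config$variance_floor_epsilon, TRUE,
                   as.integer(T_len))
  out <- list(mean_y = f$Y, variance_v = f$V)
  class(out) <- "sctrnn_generation"
  out
}
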