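#' Network configuration for an S-CTRNN with parametric bias
#'
#' Collects the architecture and optimization hyperparameters of a
#' stochastic continuous-time recurrent neural network (S-CTRNN) with
#' parametric bias (PB) units. The network maps the current 10-dimensional
#' visuo-proprioceptive input (8 joint angles + 2 ball-position
#' coordinates) to a prediction of the mean and variance of the next
#' input. Sensory dimensionality is shared by the input, output and
#' variance unit groups.
#'
#' @param n_input Number of input units (sensory dimensionality).
#' @param n_context Number of leaky-integrator context units.
#' @param n_pb Number of parametric-bias units (the "intention" code).
#' @param tau Shared time constant of the context units; `tau >= 1`.
#'   PB units are treated as the exact constant branch of the dynamics
#'   (infinite time constant), not as a large finite `tau`.
#' @param learning_rate_alpha Gradient-descent learning rate (both phases).
#' @param momentum_eta Momentum coefficient in `[0, 1)`.
#' @param window_W Length of the sliding error-regression window.
#' @param variance_offset_K Constant added to the variance units' internal
#'   states before exponentiation; `K = 0` is the normal condition,
#'   `K > 0` increases and `K < 0` decreases the estimated sensory
#'   variance (aberrant precision manipulation).
#' @param variance_floor_epsilon Minimum estimated variance; strictly
#'   positive.
#' @param adaptation_iters PB regression iterations per environment step.
#' @param learning_epochs Default number of offline training epochs.
#' @param n_joint Number of proprioceptive (joint) dimensions; the
#'   remaining `n_input - n_joint` dimensions are vision.
#'
#' @return An object of class `sctrnn_config` (a named list).
#' @export
network_config <- function(n_input = 10L, n_context = 50L, n_pb = 2L,
                           tau = 4, learning_rate_alpha = 1e-4,
                           momentum_eta = 0.9, window_W = 10L,
                           variance_offset_K = 0,
                           variance_floor_epsilon = 1e-5,
                           adaptation_iters = 20L,
                           learning_epochs = 300000L,
                           n_joint = 8L) {
  stopifnot(n_input >= 1, n_context >= 1, n_pb >= 1,
            tau >= 1, variance_floor_epsilon > 0,
            momentum_eta >= 0, momentum_eta < 1,
            window_W >= 1, adaptation_iters >= 1, learning_epochs >= 1,
            n_joint >= 1, n_joint < n_input)
  cfg <- list(n_input = as.integer(n_input),
              n_context = as.integer(n_context),
              n_pb = as.integer(n_pb),
              n_output = as.integer(n_input),
              n_variance = as.integer(n_input),
              tau = tau,
              learning_rate_alpha = learning_rate_alpha,
              momentum_eta = momentum_eta,
              window_W = as.integer(window_W),
              variance_offset_K = variance_offset_K,
              variance_floor_epsilon = variance_floor_epsilon,
              adaptation_iters = as.integer(adaptation_iters),
              learning_epochs = as.integer(learning_epochs),
              n_joint = as.integer(n_joint))
  class(cfg) <- "sctrnn_config"
  cfg
}

#' Vision dimension indices of a configuration
#' @param config An `sctrnn_config`.
#' @return Integer indices of the vision dimensions (after the joints).
#' @export
vision_dims <- function(config) {
  seq.int(config$n_joint + 1L, config$n_input)
}

#' Joint dimension indices of a configuration
#' @param config An `sctrnn_config`.
#' @return Integer indices of the proprioceptive dimensions.
#' @export
joint_dims <- function(config) {
  seq_len(config$n_joint)
}

#' Initialize S-CTRNN parameters
#'
#' Draws synaptic weights from uniform distributions scaled by the fan-in
#' of the source group (`[-1/sqrt(N_I), 1/sqrt(N_I)]` for input weights,
#' `[-1/sqrt(N_C), 1/sqrt(N_C)]` for context- and PB-sourced weights),
#' biases from `[-1, 1]`, and sets all per-sequence PB initial internal
#' states to zero.
#'
#' The connection topology is fixed: input, recurrent-context and PB
#' connections feed the context units only; output and variance units read
#' the current context activations only. There are no direct
#' input-to-output, input-to-variance or PB-to-output paths.
#'
#' @param config An `sctrnn_config`.
#' @param n_sequences Number of training sequences (one PB initial state
#'   per sequence).
#' @param seed Integer seed for the weight draw.
#' @return An object of class `sctrnn_params`: matrices `W_xc`, `W_cc`,
#'   `W_pc`, `W_co`, `W_cv`, bias vectors `b_c`, `b_o`, `b_v`, and the
#'   `n_pb x n_sequences` matrix `u0_pb`, plus the seed used.
#' @export
init_network_params <- function(config, n_sequences = 1L, seed = 1L) {
  stopifnot(inherits(config, "sctrnn_config"), n_sequences >= 1)
  runif_mat <- function(nr, nc, lim) {
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ni <- config$n_input; nc <- config$n_context; np <- config$n_pb
  no <- config$n_output; nv <- config$n_variance
  p <- list(
    W_xc = runif_mat(nc, ni, 1 / sqrt(ni)),
    W_cc = runif_mat(nc, nc, 1 / sqrt(nc)),
    W_pc = runif_mat(nc, np, 1 / sqrt(nc)),
    W_co = runif_mat(no, nc, 1 / sqrt(nc)),
    W_cv = runif_mat(nv, nc, 1 / sqrt(nc)),
    b_c = stats::runif(nc, -1, 1),
    b_o = stats::runif(no, -1, 1),
    b_v = stats::runif(nv, -1, 1),
    u0_pb = matrix(0, np, n_sequences),
    seed = as.integer(seed))
  class(p) <- "sctrnn_params"
  p
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Fresh network state
#'
#' @param config An `sctrnn_config`.
#' @param internal_pb PB internal-state vector (length `n_pb`).
#' @return An `sctrnn_state`: step counter, internal and activation values
#'   of the context and PB units. Context internal states start at zero.
#' @export
initial_state <- function(config, internal_pb = numeric(config$n_pb)) {
  stopifnot(length(internal_pb) == config$n_pb)
  s <- list(step_t = 0L,
            internal_context = numeric(config$n_context),
            internal_pb = as.numeric(internal_pb),
            activation_context = tanh(numeric(config$n_context)),
            activation_pb = tanh(as.numeric(internal_pb)))
  class(s) <- "sctrnn_state"
  s
}

#' Advance the internal states by one time step
#'
#' Applies the leaky-integrator rule to the context units: the new internal
#' state is `(1/tau)` times the summed synaptic drive (input, recurrent
#' context, PB, bias) plus `(1 - 1/tau)` times the previous internal state.
#' PB internal states are constant. Output and variance internal states are
#' instantaneous functions of the new context activations and their biases.
#'
#' @param params An `sctrnn_params`.
#' @param config An `sctrnn_config`.
#' @param prev An `sctrnn_state`.
#' @param x_t Sensory input vector of length `n_input`.
#' @return List with `state` (advanced `sctrnn_state`, `step_t`
#'   incremented), `internal_output` and `internal_variance`.
#' @export
step_internal_states <- function(params, config, prev, x_t) {
  if (length(x_t) != config$n_input)
    stop("input has length ", length(x_t), "; network expects ",
         config$n_input)
  stopifnot(inherits(prev, "sctrnn_state"))
  tau <- config$tau
  drive <- params$W_xc %*% x_t + params$W_cc %*% prev$activation_context +
    params$W_pc %*% prev$activation_pb + params$b_c
  u_c <- drop(drive) / tau + (1 - 1 / tau) * prev$internal_context
  c_t <- tanh(u_c)
  u_o <- drop(params$W_co %*% c_t + params$b_o)
  u_v <- drop(params$W_cv %*% c_t + params$b_v)
  state <- prev
  state$step_t <- prev$step_t + 1L
  state$internal_context <- u_c
  state$activation_context <- c_t
  list(state = state, internal_output = u_o, internal_variance = u_v)
}

#' Unit-group activation functions
#'
#' PB, context and output units use the hyperbolic tangent. Variance units
#' use `exp(u + K) + epsilon`, which is strictly positive and bounded below
#' by `epsilon`; `K` shifts the estimated log-variance (the aberrant
#' sensory-precision manipulation scales all estimated variances by
#' `exp(K)` above the floor). The exponent argument is capped at 30 so the
#' function is total on finite reals.
#'
#' @param internal Internal-state vector.
#' @param unit_group One of `"pb"`, `"context"`, `"output"`, `"variance"`.
#' @param K Variance offset (variance group only).
#' @param epsilon Variance floor (variance group only).
#' @return Activation vector.
#' @export
activate <- function(internal, unit_group = c("pb", "context", "output",
                                              "variance"),
                     K = 0, epsilon = 1e-5) {
  unit_group <- match.arg(unit_group)
  if (unit_group == "variance") {
    exp(pmin(internal + K, 30)) + epsilon
  } else {
    tanh(internal)
  }
}

#' Heteroscedastic Gaussian negative log-likelihood
#'
#' The per-dimension, per-step objective
#' `ln(2*pi*v)/2 + (y_target - y)^2 / (2*v)`: a precision-weighted squared
#' prediction error plus the log-volume of the estimated uncertainty.
#' Minimizing it jointly fits predictions and their variance; at fixed
#' error `e` the optimum over `v` is `v = e^2`.
#'
#' @param y Predicted mean (vectorized).
#' @param v Predicted variance, `> 0`.
#' @param y_target Target value.
#' @return Elementwise negative log-likelihood.
#' @export
negative_log_likelihood <- function(y, v, y_target) {
  if (any(v <= 0)) stop("invalid variance: v must be strictly positive")
  log(2 * pi * v) / 2 + (y_target - y)^2 / (2 * v)
}

.seq_matrix <- function(s) {
  if (inherits(s, "vp_sequence")) s$values else as.matrix(s)
}

# Teacher-forced (input, target) split of a recorded sequence: the input at
# prediction step t is the recorded state at t, the target is the state at
# t + 1.
.io_split <- function(values) {
  T_len <- nrow(values)
  stopifnot(T_len >= 2)
  list(X = values[-T_len, , drop = FALSE],
       targets = values[-1, , drop = FALSE])
}

#' Accumulated negative log-likelihood over sequences
#'
#' Sums the per-step objective over the requested output dimensions, all
#' prediction steps, and all sequences, with teacher-forced inputs (each
#' step's input is the recorded value, the target is the next recorded
#' value). This is the offline learning objective.
#'
#' @param params An `sctrnn_params` (must hold one PB initial internal
#'   state column per sequence).
#' @param config An `sctrnn_config`.
#' @param sequences List of `vp_sequence` objects or `T x n_input`
#'   matrices.
#' @param dims Output dimensions included in the sum (default all).
#' @param K Variance offset in force.
#' @return Total negative log-likelihood (scalar).
#' @export
accumulate_likelihood <- function(params, config, sequences,
                                  dims = seq_len(config$n_output),
                                  K = config$variance_offset_K) {
  if (length(sequences) == 0) return(0)
  if (ncol(params$u0_pb) < length(sequences))
    stop("params hold ", ncol(params$u0_pb),
         " PB initial states but ", length(sequences),
         " sequences were given")
  total <- 0
  for (s in seq_along(sequences)) {
    io <- .io_split(.seq_matrix(sequences[[s]]))
    total <- total + cpp_sequence_nll(
      unclass(params), io$X, io$targets, params$u0_pb[, s],
      numeric(config$n_context), config$tau, K,
      config$variance_floor_epsilon, as.integer(dims), FALSE)
  }
  total
}

#' Exact BPTT gradients of the accumulated likelihood
#'
#' Back-propagation through time of the accumulated negative
#' log-likelihood with respect to either all parameters (learning) or the
#' per-sequence PB initial internal states only (adaptation). The gradient
#' of sequence `s`'s PB state depends only on sequence `s`.
#'
#' @inheritParams accumulate_likelihood
#' @param wrt `"all"` or `"pb"`.
#' @return List with `loss` and gradient arrays named like the parameter
#'   fields (`W_xc`, ..., `b_v`, and `u0_pb` as an `n_pb x S` matrix).
#' @export
bptt_gradients <- function(params, config, sequences,
                           dims = seq_len(config$n_output),
                           wrt = c("all", "pb"),
                           K = config$variance_offset_K) {
  wrt <- match.arg(wrt)
  zero <- lapply(unclass(params)[c("W_xc", "W_cc", "W_pc", "W_co", "W_cv",
                                   "b_c", "b_o", "b_v")],
                 function(m) m * 0)
  g <- zero
  pb_g <- matrix(0, config$n_pb, length(sequences))
  loss <- 0
  for (s in seq_along(sequences)) {
    io <- .io_split(.seq_matrix(sequences[[s]]))
    r <- cpp_bptt(unclass(params), io$X, io$targets, params$u0_pb[, s],
                  numeric(config$n_context), config$tau, K,
                  config$variance_floor_epsilon, as.integer(dims), FALSE,
                  wrt == "pb")
    loss <- loss + r$loss
    if (wrt == "all")
      for (nm in names(g)) g[[nm]] <- g[[nm]] + r[[nm]]
    pb_g[, s] <- r$u_pb
  }
  c(list(loss = loss), if (wrt == "all") g, list(u0_pb = pb_g))
}

#' Gradient-descent-with-momentum update
#'
#' `delta_new = -alpha * grad + eta * prev_delta`;
#' `theta_new = theta + delta_new`.
#'
#' @param theta Parameter array.
#' @param grad Gradient of the objective at `theta`.
#' @param prev_delta Previous update (same shape).
#' @param alpha Learning rate.
#' @param eta Momentum coefficient.
#' @return List with `theta` and `delta`.
#' @export
gradient_update <- function(theta, grad, prev_delta, alpha = 1e-4,
                            eta = 0.9) {
  stopifnot(length(theta) == length(grad),
            length(theta) == length(prev_delta))
  delta <- -alpha * grad + eta * prev_delta
  list(theta = theta + delta, delta = delta)
}
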