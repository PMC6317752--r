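#' Build a sliding error-regression window
#'
#' A window holds the boundary conditions from which the network
#' regenerates its recent past: the input at the window's first step
#' (proprioception seeded from the network's own earlier prediction,
#' vision from the observation), the observed vision targets over the
#' window, the context internal state just before the window, and the
#' current PB internal state with its momentum buffer. On construction
#' the window is regenerated closed-loop from these conditions.
#'
#' @param model An `sctrnn_model`.
#' @param x1 Input vector at the window's first step.
#' @param targets `Wlen x n_input` matrix; only the columns in `dims`
#'   are used as targets (observed vision by default).
#' @param uc0 Context internal state before the window (zeros at trial
#'   start).
#' @param pb_internal Current PB internal state.
#' @param momentum PB momentum buffer (zeros when the window advances).
#' @param dims Output dimensions entering the windowed objective;
#'   defaults to the vision dimensions.
#' @param start_step 1-based trial step of the window's first entry.
#' @param K Variance offset in force.
#' @return An `sctrnn_window`.
#' @export
regression_window <- function(model, x1, targets, uc0 = NULL,
                              pb_internal, momentum = NULL,
                              dims = vision_dims(model$config),
                              start_step = 1L,
                              K = model$config$variance_offset_K) {
  cfg <- model$config
  targets <- as.matrix(targets)
  if (nrow(targets) < 1) stop("empty window")
  if (is.null(uc0)) uc0 <- numeric(cfg$n_context)
  if (is.null(momentum)) momentum <- numeric(cfg$n_pb)
  w <- list(start_step = as.integer(start_step), x1 = as.numeric(x1),
            targets = targets, uc0 = as.numeric(uc0),
            pb_internal = as.numeric(pb_internal),
            momentum = as.numeric(momentum),
            dims = as.integer(dims), K = K)
  w$generated <- .regen_window(model, w)
  class(w) <- "sctrnn_window"
  w
}

.regen_window <- function(model, w) {
  cpp_forward(unclass(model$params), matrix(w$x1, nrow = 1),
              w$pb_internal, w$uc0, model$config$tau, w$K,
              model$config$variance_floor_epsilon, TRUE,
              nrow(w$targets))
}

#' Accumulated negative log-likelihood of a window
#'
#' Sum of the per-step heteroscedastic negative log-likelihood between
#' the window's regenerated predictions and its observed targets, over
#' the window steps and requested dimensions (the 2 vision dimensions by
#' default — the adaptation objective is computed from vision states and
#' visual feedback).
#'
#' @param window An `sctrnn_window`.
#' @param dims Dimensions to include (defaults to the window's own).
#' @return Scalar NLL.
#' @export
windowed_nll <- function(window, dims = window$dims) {
  stopifnot(inherits(window, "sctrnn_window"))
  Y <- window$generated$Y
  V <- window$generated$V
  sum(negative_log_likelihood(Y[, dims, drop = FALSE],
                              V[, dims, drop = FALSE],
                              window$targets[, dims, drop = FALSE]))
}

#' PB error regression over a window
#'
#' The postdiction step of online adaptation: `n_iters` cycles of
#' closed-loop window regeneration, PB-only BPTT gradient of the windowed
#' negative log-likelihood, and a momentum gradient update of the PB
#' internal state; all other parameters stay frozen. Returns the updated
#' window and the one-step-ahead prediction generated from the final PB
#' state.
#'
#' @param model An `sctrnn_model`.
#' @param window An `sctrnn_window`.
#' @param n_iters Number of PB updates (default
#'   `config$adaptation_iters`).
#' @param K Variance offset in force (defaults to the window's).
#' @param feedback_grad Propagate the window gradient through the
#'   prediction-to-input feedback path. Off by default: the regenerated
#'   inputs are treated as given, which keeps the effective curvature of
#'   the window objective near that of the forward model; with the
#'   feedback term the PB update chronically overshoots even in the
#'   normal condition.
#' @return List with `window` (updated PB, momentum, regenerated
#'   predictions), `nll_pre`, `nll_post`, and `prediction` (`mean_y`,
#'   `variance_v` for the next step).
#' @export
regress_pb <- function(model, window,
                       n_iters = model$config$adaptation_iters,
                       K = window$K, feedback_grad = FALSE) {
  stopifnot(inherits(window, "sctrnn_window"), n_iters >= 1)
  cfg <- model$config
  r <- cpp_regress_window(unclass(model$params), window$pb_internal,
                          window$momentum, window$uc0, window$x1,
                          window$targets, window$dims,
                          as.integer(n_iters), cfg$learning_rate_alpha,
                          cfg$momentum_eta, cfg$tau, K,
                          cfg$variance_floor_epsilon, feedback_grad)
  window$pb_internal <- drop(r$u_pb)
  window$momentum <- drop(r$momentum)
  window$generated <- r$window
  window$K <- K
  list(window = window, nll_pre = r$nll_pre, nll_post = r$nll_post,
       prediction = list(mean_y = drop(r$pred_y),
                         variance_v = drop(r$pred_v)))
}

#' Run one interactive adaptation trial
#'
#' Couples the trained network to the ball environment. Each time step:
#' the commanded joint angles (the network's own mean joint prediction)
#' are sent to the environment, the ball position is observed, the
#' sliding window advances, and the PB internal state is re-optimized by
#' [regress_pb()] (momentum resets when the window advances). The
#' prediction for the next step generated from the final PB supplies the
#' next joint command.
#'
#' @param model A trained `sctrnn_model`.
#' @param schedule A `situation_schedule` covering the trial.
#' @param K Variance offset applied throughout the trial.
#' @param seed Integer seed for the environment noise.
#' @param initial_behavior Behavior whose learned PB state (mean of its
#'   training sequences' states) initializes the trial intention.
#' @param specs Behavior specs for the environment (must match the
#'   training generators).
#' @param noise_sigma Environment observation noise (defaults to the
#'   specs' value).
#' @param dims Dimensions entering the adaptation objective (vision by
#'   default; set to `seq_len(config$n_output)` for the all-output
#'   variant).
#' @param feedback_grad Passed to [regress_pb()].
#' @return An `sctrnn_trace` data frame with one row per step: PB
#'   activations and internal states, windowed NLL after postdiction,
#'   commanded joints, observed vision, and `K`.
#' @export
run_interactive_trial <- function(model, schedule, K = 0, seed = 1L,
                                  initial_behavior = schedule$behaviors[1],
                                  specs = behavior_specs(),
                                  noise_sigma = NULL,
                                  dims = vision_dims(model$config),
                                  feedback_grad = FALSE) {
  cfg <- model$config
  T_total <- schedule$total_steps
  W <- cfg$window_W
  nj <- cfg$n_joint
  env <- ball_environment(schedule, specs, noise_sigma = noise_sigma,
                          seed = seed)
  u_pb <- pb_for_behavior(model, initial_behavior)

  cmd <- matrix(NA_real_, T_total, nj)         # commanded joints per step
  obs <- matrix(NA_real_, T_total, 2)          # observed ball position
  pb_act <- matrix(NA_real_, T_total, cfg$n_pb)
  pb_int <- matrix(NA_real_, T_total, cfg$n_pb)
  nll <- numeric(T_total)

  # the robot starts in its intended behavior's home posture
  cmd[1, ] <- drop(specs[[initial_behavior]]$joints(0))
  vdims <- vision_dims(cfg)
  uc_bound <- numeric(cfg$n_context)  # context internal before the window

  for (t in seq_len(T_total)) {
    obs[t, ] <- environment_step(env, cmd[t, ], t)
    if (t == 1) {
      # no predictions yet: one forward step provides the first command
      f <- cpp_forward(unclass(model$params),
                       matrix(c(cmd[1, ], obs[1, ]), nrow = 1), u_pb,
                       numeric(cfg$n_context), cfg$tau, K,
                       cfg$variance_floor_epsilon, TRUE, 1L)
      if (T_total >= 2) cmd[2, ] <- f$Y[1, seq_len(nj)]
      nll[1] <- 0  # empty window: empty sum
    } else {
      s <- max(1L, t - W)  # window covers network steps s .. t-1
      Wlen <- t - s
      targets <- matrix(0, Wlen, cfg$n_input)
      targets[, vdims] <- obs[seq(s + 1, t), , drop = FALSE]
      w <- regression_window(model, c(cmd[s, ], obs[s, ]), targets,
                             uc_bound, u_pb, momentum = NULL,
                             dims = dims, start_step = s, K = K)
      r <- tryCatch(
        regress_pb(model, w, feedback_grad = feedback_grad),
        error = function(e)
          stop("trial aborted at step ", t, ": ", conditionMessage(e),
               call. = FALSE))
      u_pb <- r$window$pb_internal
      nll[t] <- r$nll_post
      if (t < T_total) cmd[t + 1, ] <- r$prediction$mean_y[seq_len(nj)]
      # postdicted boundary state for the next, advanced window
      s_next <- max(1L, t + 1L - W)
      if (s_next > s) uc_bound <- r$window$generated$Uc[s_next - s, ]
    }
    pb_act[t, ] <- tanh(u_pb)
    pb_int[t, ] <- u_pb
  }
  trace <- data.frame(step = seq_len(T_total), K = K,
                      nll_windowed = nll)
  for (i in seq_len(cfg$n_pb)) trace[[paste0("pb_", i)]] <- pb_act[, i]
  for (i in seq_len(cfg$n_pb)) trace[[paste0("pb_u_", i)]] <- pb_int[, i]
  for (i in seq_len(nj)) trace[[paste0("joint_", i)]] <- cmd[, i]
  trace$obs_x <- obs[, 1]
  trace$obs_y <- obs[, 2]
  attr(trace, "initial_behavior") <- initial_behavior
  attr(trace, "schedule") <- schedule
  attr(trace, "seed") <- as.integer(seed)
  class(trace) <- c("sctrnn_trace", "data.frame")
  trace
}

#' Joint-command matrix of a trace
#' @param trace An `sctrnn_trace`.
#' @return `T x n_joint` matrix of the commanded (generated) joints.
#' @export
trace_joints <- function(trace) {
  as.matrix(trace[, grep("^joint_", names(trace)), drop = FALSE])
}

#' Mean windowed NLL per time step of a trace
#'
#' The post-regression windowed negative log-likelihood divided by the
#' window length, averaged over the trial (warm-up step 1 excluded).
#'
#' @param trace An `sctrnn_trace`.
#' @param window_W Window length used in the trial.
#' @return Scalar mean NLL per time step.
#' @export
trace_mean_nll <- function(trace, window_W = 10L) {
  t_seq <- trace$step
  wlen <- pmin(t_seq - 1L, window_W)
  keep <- wlen >= 1L
  mean(trace$nll_windowed[keep] / wlen[keep])
}
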