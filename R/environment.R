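#' Built-in specifications of the four ball-playing behaviors
#'
#' Defines the synthetic stand-ins for the four learned behaviors. Each
#' behavior has 8 quasi-periodic joint-angle trajectories (sums of one to
#' two sinusoids with behavior-specific amplitudes, periods, phases and
#' rest offsets) and a 2-D ball trajectory:
#' \describe{
#'   \item{right / left}{the ball rolls from the partner's side out to the
#'     robot's right (or left) and is returned; the active arm swings with
#'     the ball cycle while the other arm idles.}
#'   \item{self_play}{the robot rolls the ball in a small loop directly in
#'     front of itself with both arms.}
#'   \item{attract}{an up-down motion of both arms while the partner moves
#'     the ball left and right on the far side.}
#' }
#' Nominal trajectories stay within `[-0.45, 0.45]`, the mid-range of the
#' sensor scale: the sensor clip at `[-0.8, 0.8]` never activates for
#' noise below `sigma = 0.05`, and the reduced-scale network can
#' reproduce the movements down to its observation-noise floor, as the
#' physical robot did at full scale.
#'
#' @param length_scale Multiplier on the nominal sequence lengths
#'   (1600/1900/1600/1200 steps for right/left/self_play/attract); used to
#'   scale whole experiments down.
#' @param period_scale Multiplier on the behavior periods (full-scale
#'   periods 40/50/30/24 steps). Defaults to `sqrt(length_scale)`: when
#'   exemplars are shortened, periods shrink with the square root so that
#'   each exemplar still contains enough cycles for the network to lock
#'   the oscillation frequency, while several steps per cycle remain for
#'   the `tau = 4` context units to resolve.
#' @param noise_sigma Observation noise s.d. applied by the generators.
#' @return Named list of four `behavior_spec` objects with fields `label`,
#'   `period`, `joints` (function of 0-based step), `vision` (idem),
#'   `noise_sigma`, `nominal_length`.
#' @export
behavior_specs <- function(length_scale = 1,
                           period_scale = sqrt(length_scale),
                           noise_sigma = 0.02) {
  mk <- function(label, period, nominal_length, joints, vision,
                 hold_vision = NULL) {
    # floor of 10 steps per cycle: ~2.5 tau, the slowest oscillation the
    # tau = 4 context units can represent comfortably
    period <- max(10L, as.integer(round(period * period_scale)))
    s <- list(label = label, period = period,
              nominal_length = as.integer(round(nominal_length *
                                                  length_scale)),
              joints = joints(period), vision = vision(period),
              hold_vision = hold_vision, noise_sigma = noise_sigma)
    class(s) <- "behavior_spec"
    s
  }
  # out-and-back path parameter: 0 at the partner, 1 at the robot
  leg <- function(phi) (1 - cos(phi)) / 2

  right <- mk("right", 40L, 1600,
    joints = function(P) function(t) {
      phi <- 2 * pi * (t %% P) / P
      cbind(0.33 * sin(phi),
            0.21 * sin(phi + 0.8) + 0.06,
            0.18 * cos(phi) - 0.06,
            0.12 * sin(phi + 1.6),
            -0.18 + 0.03 * sin(phi),
            0.12 + 0.03 * cos(phi),
            -0.06 + 0.024 * sin(phi + 0.5),
            0.09 + 0.024 * cos(phi + 0.5))
    },
    vision = function(P) function(t) {
      phi <- 2 * pi * (t %% P) / P
      a <- leg(phi)
      cbind(0.3 * a, -0.33 + 0.66 * a)
    },
    hold_vision = c(0.3, 0.33))

  left <- mk("left", 50L, 1900,
    joints = function(P) function(t) {
      phi <- 2 * pi * (t %% P) / P
      cbind(0.18 + 0.03 * sin(phi),
            -0.12 + 0.03 * cos(phi),
            0.06 + 0.024 * sin(phi + 0.5),
            -0.09 + 0.024 * cos(phi + 0.5),
            0.33 * sin(phi),
            0.21 * sin(phi + 0.8) - 0.06,
            0.18 * cos(phi) + 0.06,
            0.12 * sin(phi + 1.6))
    },
    vision = function(P) function(t) {
      phi <- 2 * pi * (t %% P) / P
      a <- leg(phi)
      cbind(-0.3 * a, -0.33 + 0.66 * a)
    },
    hold_vision = c(-0.3, 0.33))

  self_play <- mk("self_play", 30L, 1600,
    joints = function(P) function(t) {
      phi <- 2 * pi * (t %% P) / P
      cbind(0.15 * sin(phi) + 0.21,
            0.15 * cos(phi) - 0.18,
            0.12 * sin(phi + 1.0) + 0.15,
            0.12 * cos(phi + 1.0) - 0.15,
            0.15 * sin(phi) - 0.21,
            0.15 * cos(phi) + 0.18,
            0.12 * sin(phi + 1.0) - 0.15,
            0.12 * cos(phi + 1.0) + 0.15)
    },
    vision = function(P) function(t) {
      # a tight rolling loop directly in front of the robot: when the
      # ball is placed there and sits, self-play is the best explanation
      phi <- 2 * pi * (t %% P) / P
      cbind(0.08 * sin(phi), 0.38 + 0.06 * cos(phi))
    })

  attract <- mk("attract", 24L, 1200,
    joints = function(P) function(t) {
      phi <- 2 * pi * (t %% P) / P
      cbind(0.36 * sin(phi) - 0.03,
            0.18 * sin(phi + 0.5),
            0.15 * cos(phi) + 0.09,
            0.09 * sin(phi + 1.2),
            0.36 * sin(phi) + 0.03,
            0.18 * sin(phi + 0.5),
            0.15 * cos(phi) - 0.09,
            0.09 * sin(phi + 1.2))
    },
    vision = function(P) function(t) {
      phi <- 2 * pi * (t %% P) / P
      cbind(0.3 * sin(phi), -0.33 + 0.048 * cos(2 * phi))
    })

  list(right = right, left = left, self_play = self_play,
       attract = attract)
}

.clip_range <- function(x, lim = 0.8) pmin(pmax(x, -lim), lim)

#' Nominal (noise-free) trajectory of a behavior
#' @param spec A `behavior_spec`.
#' @param t Vector of 0-based time steps.
#' @return `length(t) x 10` matrix (8 joints + 2 vision).
#' @export
nominal_trajectory <- function(spec, t) {
  cbind(spec$joints(t), spec$vision(t))
}

#' Generate a labeled training set of visuo-proprioceptive sequences
#'
#' Draws `n_per_behavior` noisy exemplars of each behavior: the nominal
#' quasi-periodic trajectory plus i.i.d. Gaussian observation noise, with
#' the sequence length jittered uniformly by up to 5 percent so exemplars
#' differ in length as real recordings would. Values are clipped to
#' `[-0.8, 0.8]` (clipping never activates at the default amplitudes and
#' noise).
#'
#' @param specs Behavior specs (see [behavior_specs()]).
#' @param n_per_behavior Exemplars per behavior (3 by default).
#' @param seed Integer seed.
#' @param length_jitter Relative half-width of the uniform length jitter.
#' @return List of `vp_sequence` objects, ordered by behavior.
#' @export
make_target_set <- function(specs = behavior_specs(), n_per_behavior = 3L,
                            seed = 1L, length_jitter = 0.05) {
  stopifnot(n_per_behavior >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- list()
  idx <- 0L
  for (spec in specs) {
    for (k in seq_len(n_per_behavior)) {
      idx <- idx + 1L
      T_len <- max(2L, as.integer(round(
        spec$nominal_length * stats::runif(1, 1 - length_jitter,
                                           1 + length_jitter))))
      vals <- nominal_trajectory(spec, seq_len(T_len) - 1)
      if (spec$noise_sigma > 0)
        vals <- vals + matrix(stats::rnorm(length(vals), 0,
                                           spec$noise_sigma),
                              nrow(vals), ncol(vals))
      out[[idx]] <- vp_sequence(.clip_range(vals), spec$label,
                                sequence_index = idx)
    }
  }
  out
}

#' Situation schedule for an interactive trial
#'
#' An ordered list of behavior situations imposed by the (simulated)
#' experimenter. Start steps are 0-based, strictly increasing, and the
#' first entry must start at step 0.
#'
#' @param start_steps Integer vector of 0-based segment start steps.
#' @param behaviors Character vector of behavior labels, same length.
#' @param total_steps Total trial length.
#' @return A `situation_schedule`.
#' @export
situation_schedule <- function(start_steps, behaviors, total_steps) {
  start_steps <- as.integer(start_steps)
  stopifnot(length(start_steps) == length(behaviors),
            length(start_steps) >= 1,
            start_steps[1] == 0L,
            !is.unsorted(start_steps, strictly = TRUE),
            all(behaviors %in% behavior_labels()),
            total_steps > max(start_steps))
  s <- list(start_steps = start_steps, behaviors = as.character(behaviors),
            total_steps = as.integer(total_steps))
  class(s) <- "situation_schedule"
  s
}

.active_segment <- function(schedule, t0) {
  if (t0 >= schedule$total_steps)
    stop("schedule exhausted at step ", t0)
  i <- findInterval(t0, schedule$start_steps)
  list(behavior = schedule$behaviors[i],
       phase = t0 - schedule$start_steps[i])
}

#' Create an interactive ball environment
#'
#' Stand-in for the ball, table and human partner during online
#' adaptation. The ball follows the active behavior's nominal trajectory
#' with Gaussian observation noise, and its phase is contingent on the
#' robot, as it would be with a human partner:
#' \describe{
#'   \item{right / left}{the partner rolls the ball out on their own
#'     timing, but the return leg advances only while the robot's
#'     commanded arm posture matches the nominal returning motion at a
#'     phase within `phase_tol` of the ball's; otherwise the ball waits
#'     at the robot's side, and after `max_hold` steps the partner
#'     completes the return themselves.}
#'   \item{self_play / attract}{the ball keeps moving on its small
#'     loop (the partner demonstrates the roll, or moves the ball
#'     themselves); its phase free-runs.}
#' }
#'
#' @param schedule A `situation_schedule`.
#' @param specs Behavior specs.
#' @param noise_sigma Observation noise s.d. (overrides the specs' value
#'   if not `NULL`).
#' @param seed Integer seed for the observation noise.
#' @param phase_tol Gate half-width as a fraction of the period.
#' @param match_tol Maximum absolute joint mismatch accepted by the gate.
#' @param max_hold Steps the partner waits before completing a return
#'   the robot missed, as a fraction of the period.
#' @return A `ball_environment` object with internal state.
#' @export
ball_environment <- function(schedule, specs = behavior_specs(),
                             noise_sigma = NULL, seed = 1L,
                             phase_tol = 0.10, match_tol = 0.25,
                             max_hold = 0.15) {
  stopifnot(inherits(schedule, "situation_schedule"))
  e <- new.env(parent = emptyenv())
  e$schedule <- schedule
  e$specs <- specs
  e$noise_sigma <- noise_sigma
  e$phase_tol <- phase_tol
  e$match_tol <- match_tol
  e$max_hold <- max_hold
  e$segment <- 1L
  e$phase <- 0L
  e$hold_count <- 0L
  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  e$rng <- .Random.seed_save()
  .Random.seed_restore(old)
  class(e) <- "ball_environment"
  e
}

#' Advance the environment by one step
#'
#' @param env A `ball_environment`.
#' @param commanded_joints The robot's 8 commanded joint angles for this
#'   step.
#' @param t 1-based trial time step.
#' @return Observed ball position (2-vector), clipped to `[-0.8, 0.8]`.
#' @export
environment_step <- function(env, commanded_joints, t) {
  stopifnot(inherits(env, "ball_environment"))
  t0 <- t - 1L
  if (t0 >= env$schedule$total_steps)
    stop("schedule exhausted at step ", t0)
  seg <- findInterval(t0, env$schedule$start_steps)
  if (seg != env$segment) {       # situation switch: partner restarts
    env$segment <- seg
    env$phase <- 0L
    env$hold_count <- 0L
  }
  behavior <- env$schedule$behaviors[seg]
  spec <- env$specs[[behavior]]
  sigma <- if (is.null(env$noise_sigma)) spec$noise_sigma else
    env$noise_sigma
  P <- spec$period
  matched <- .gate_open(spec, commanded_joints, env$phase, env$phase_tol,
                        env$match_tol)
  advance <- TRUE
  if (!is.null(spec$hold_vision)) {  # right / left
    returning <- (env$phase %% P) / P >= 0.5
    if (returning && !matched) {
      # the ball waits at the robot's side; after max_hold steps the
      # partner completes the return themselves
      env$hold_count <- env$hold_count + 1L
      advance <- env$hold_count > env$max_hold * P
    } else {
      env$hold_count <- 0L
    }
  }
  vis <- drop(spec$vision(env$phase))
  if (advance) env$phase <- env$phase + 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  .Random.seed_restore(env$rng)
  obs <- vis + stats::rnorm(2, 0, sigma)
  env$rng <- .Random.seed_save()
  .clip_range(obs)
}

# The gate opens when the commanded posture matches the nominal joint
# trajectory at some phase within +-phase_tol of the current one; the
# best-matching phase is returned (NA when nothing matches).
.match_phase <- function(spec, commanded_joints, phase, phase_tol,
                         match_tol) {
  offs <- seq(-round(phase_tol * spec$period),
              round(phase_tol * spec$period))
  best <- NA_integer_
  best_err <- match_tol
  for (d in offs) {
    ph <- (phase + d) %% spec$period
    nom <- drop(spec$joints(ph))
    err <- max(abs(commanded_joints - nom))
    if (err < best_err) {
      best_err <- err
      best <- as.integer(ph)
    }
  }
  best
}

.gate_open <- function(spec, commanded_joints, phase, phase_tol,
                       match_tol) {
  !is.na(.match_phase(spec, commanded_joints, phase, phase_tol, match_tol))
}
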