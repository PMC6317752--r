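# Forward dynamics, activations, likelihood and gradient machinery.

test_that("leaky integration follows the firing-rate update rule", {
  cfg <- network_config(n_input = 2, n_context = 1, n_pb = 1, tau = 4,
                        n_joint = 1)
  p <- init_network_params(cfg, 1, seed = 1)
  # single context unit, one input weight 1, everything else zero
  p$W_xc[] <- c(1, 0); p$W_cc[] <- 0; p$W_pc[] <- 0
  p$b_c[] <- 0
  st <- initial_state(cfg)
  out <- step_internal_states(p, cfg, st, c(0.8, 0))
  # u = (1/4) * 0.8 + (3/4) * 0 = 0.2
  expect_equal(out$state$internal_context, 0.2)
  expect_equal(out$state$step_t, 1L)
  # tau = 1: leak term vanishes, u equals the summed drive exactly
  cfg1 <- network_config(n_input = 2, n_context = 1, n_pb = 1, tau = 1,
                         n_joint = 1)
  st1 <- initial_state(cfg1)
  st1$internal_context <- 5  # would persist if the leak term survived
  out1 <- step_internal_states(p, cfg1, st1, c(0.8, 0))
  expect_equal(out1$state$internal_context, tanh(5) * 0 + 0.8)
})

test_that("all-zero parameters are a fixed point of the context dynamics", {
  cfg <- network_config(n_input = 3, n_context = 4, n_pb = 2, tau = 4,
                        n_joint = 1)
  p <- init_network_params(cfg, 1, seed = 2)
  for (nm in c("W_xc", "W_cc", "W_pc", "b_c")) p[[nm]][] <- 0
  st <- initial_state(cfg)
  for (t in 1:5) st <- step_internal_states(p, cfg, st, runif(3))$state
  expect_equal(st$internal_context, numeric(4))
})

test_that("PB internal states never change during forward propagation", {
  s <- tiny_setup(seed = 3)
  st <- initial_state(s$cfg, internal_pb = 0.7)
  for (t in 1:7) st <- step_internal_states(s$params, s$cfg, st,
                                            runif(4, -0.5, 0.5))$state
  expect_identical(st$internal_pb, 0.7)
  f <- sctrnn:::cpp_forward(unclass(s$params), s$seqs[[1]], 0.7,
                            numeric(3), 4, 0, 1e-5, FALSE, 6L)
  expect_equal(nrow(f$Y), 6L)
})

test_that("input of the wrong length is rejected", {
  s <- tiny_setup()
  st <- initial_state(s$cfg)
  expect_error(step_internal_states(s$params, s$cfg, st, c(1, 2)),
               "length")
})

test_that("activation functions match their unit groups", {
  expect_equal(activate(0, "output"), 0)
  expect_equal(activate(c(-1, 2), "context"), tanh(c(-1, 2)))
  expect_equal(activate(0, "variance", K = 0, epsilon = 1e-5), 1.00001)
  expect_equal(activate(0, "variance", K = 8, epsilon = 1e-5),
               exp(8) + 1e-5)
  # overflow guard: finite for arbitrarily large internal states
  expect_true(is.finite(activate(1e6, "variance", K = 8)))
})

test_that("variance activation obeys the K-scaling identity and the floor", {
  eps <- 1e-5
  u <- seq(-12, 12, length.out = 41)
  for (K in c(-8, -4, 0, 4, 8)) {
    vK <- activate(u, "variance", K = K, epsilon = eps)
    v0 <- activate(u, "variance", K = 0, epsilon = eps)
    expect_equal(vK, exp(K) * (v0 - eps) + eps, tolerance = 1e-14)
    expect_true(all(vK >= eps))
  }
})

test_that("negative log-likelihood matches its closed form", {
  # both terms vanish at perfect prediction with v = 1/(2*pi)
  expect_equal(negative_log_likelihood(0.3, 1 / (2 * pi), 0.3), 0)
  # zero error leaves only the log-volume term
  expect_equal(negative_log_likelihood(0.1, 2, 0.1), log(4 * pi) / 2)
  # unit error, unit variance
  expect_equal(negative_log_likelihood(0, 1, 1), log(2 * pi) / 2 + 0.5,
               tolerance = 1e-10)
  expect_equal(round(negative_log_likelihood(0, 1, 1), 5), 1.41894)
  expect_error(negative_log_likelihood(0, -1, 1), "variance")
  # at fixed error e the minimizer over v is e^2
  e <- 0.37
  v_star <- optimize(function(v) negative_log_likelihood(0, v, e),
                     c(1e-6, 10))$minimum
  expect_equal(v_star, e^2, tolerance = 1e-4)
})

test_that("accumulated likelihood is additive and composes per-step terms", {
  s <- tiny_setup(seed = 4, T_len = 4)
  expect_equal(accumulate_likelihood(s$params, s$cfg, list()), 0)
  one <- accumulate_likelihood(s$params, s$cfg, s$seqs[1])
  # identical PB states for both sequences -> duplicate doubles the total
  p2 <- s$params
  p2$u0_pb[, 2] <- p2$u0_pb[, 1]
  expect_equal(accumulate_likelihood(p2, s$cfg, s$seqs[c(1, 1)]), 2 * one)
  # equals the sum of per-step calls to the scalar likelihood
  io <- sctrnn:::.io_split(s$seqs[[1]])
  f <- sctrnn:::cpp_forward(unclass(s$params), io$X, s$params$u0_pb[, 1],
                            numeric(3), s$cfg$tau, 0, 1e-5, FALSE,
                            nrow(io$X))
  by_hand <- sum(negative_log_likelihood(f$Y, f$V, io$targets))
  expect_equal(one, by_hand, tolerance = 1e-12)
  # missing PB entry is a configuration error
  expect_error(accumulate_likelihood(s$params, s$cfg,
                                     c(s$seqs, s$seqs[1])), "PB")
})

test_that("BPTT gradients match central finite differences", {
  fields <- c("W_xc", "W_cc", "W_pc", "W_co", "W_cv", "b_c", "b_o", "b_v",
              "u0_pb")
  for (seed in 1:4) {
    s <- tiny_setup(seed = seed, n_context = sample(2:5, 1),
                    T_len = sample(3:8, 1))
    dims <- seq_len(s$cfg$n_input)
    g <- bptt_gradients(s$params, s$cfg, s$seqs, dims = dims, wrt = "all")
    for (nm in fields) {
      fd <- fd_gradient(s$params, s$cfg, s$seqs, dims, nm)
      expect_lt(max_rel_err(as.numeric(g[[nm]]), as.numeric(fd)), 1e-4)
    }
    # PB-only selector agrees with the full gradient's PB block
    gp <- bptt_gradients(s$params, s$cfg, s$seqs, dims = dims, wrt = "pb")
    expect_equal(gp$u0_pb, g$u0_pb, tolerance = 1e-12)
  }
})

test_that("PB gradients are separable across sequences", {
  s <- tiny_setup(seed = 9, n_seq = 2)
  g12 <- bptt_gradients(s$params, s$cfg, s$seqs, wrt = "pb")
  g1 <- bptt_gradients(s$params, s$cfg, s$seqs[1], wrt = "pb")
  expect_equal(g12$u0_pb[, 1], g1$u0_pb[, 1], tolerance = 1e-12)
})

test_that("closed-loop PB gradients include the feedback path", {
  s <- tiny_setup(seed = 11, n_pb = 2, n_context = 3)
  cfg <- s$cfg
  u_pb <- c(0.3, -0.4)
  x1 <- runif(4, -0.5, 0.5)
  W <- 7
  targets <- matrix(runif(W * 4, -0.5, 0.5), W, 4)
  dims <- 3:4
  nll_of <- function(upb)
    sctrnn:::cpp_sequence_nll(unclass(s$params), matrix(x1, 1), targets,
                              upb, numeric(3), cfg$tau, 0, 1e-5,
                              as.integer(dims), TRUE)
  g <- sctrnn:::cpp_bptt(unclass(s$params), matrix(x1, 1), targets, u_pb,
                         numeric(3), cfg$tau, 0, 1e-5, as.integer(dims),
                         TRUE, TRUE)
  h <- 1e-5
  fd <- vapply(1:2, function(i) {
    up <- u_pb; up[i] <- up[i] + h
    um <- u_pb; um[i] <- um[i] - h
    (nll_of(up) - nll_of(um)) / (2 * h)
  }, numeric(1))
  expect_lt(max_rel_err(g$u_pb, fd), 1e-4)
})

test_that("variance internal-state optimum recovers the squared error", {
  # one variance unit driven only by its bias: optimize b_v at fixed error
  e <- 0.25
  nll_b <- function(b) negative_log_likelihood(0, exp(b) + 1e-5, e)
  b_star <- optimize(nll_b, c(-12, 3))$minimum
  expect_equal(exp(b_star) + 1e-5, e^2, tolerance = 0.01 * e^2)
})

test_that("momentum updates follow the two-term recursion", {
  up <- gradient_update(1, 2, 0.5, alpha = 0.1, eta = 0)
  expect_equal(up$delta, -0.2)
  expect_equal(up$theta, 0.8)
  # zero gradient: geometric decay of the previous delta
  d <- 1
  for (i in 1:5) d <- gradient_update(0, 0, d, alpha = 0.1,
                                      eta = 0.9)$delta
  expect_equal(d, 0.9^5)
  expect_equal(formals(gradient_update)$alpha, 1e-4)
  expect_equal(formals(gradient_update)$eta, 0.9)
})

test_that("checkpoints round-trip bit-exactly", {
  s <- tiny_setup(seed = 21)
  cfg <- reduced_config()
  ts <- reduced_targets()[c(1, 4, 7, 10)]
  m <- train_offline(ts, cfg, seed = 5, epochs = 3)
  dir <- file.path(tempdir(), "ckpt_test")
  save_checkpoint(m, dir)
  m2 <- load_checkpoint(dir)
  for (nm in c("W_xc", "W_cc", "W_pc", "W_co", "W_cv", "b_c", "b_o",
               "b_v", "u0_pb"))
    expect_identical(m2$params[[nm]], m$params[[nm]])
  expect_equal(m2$config$n_context, cfg$n_context)
  expect_equal(m2$sequence_labels, m$sequence_labels)
  unlink(dir, recursive = TRUE)
})

test_that("sequence CSV round-trips values and label", {
  ts <- make_target_set(behavior_specs(length_scale = 1 / 64), 1, seed = 3)
  f <- file.path(tempdir(), "seq_test.csv")
  write_sequence_csv(ts[[2]], f)
  back <- read_sequence_csv(f)
  expect_equal(back$values, ts[[2]]$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$behavior_label, ts[[2]]$behavior_label)
  unlink(c(f, paste0(f, ".json")))
})
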