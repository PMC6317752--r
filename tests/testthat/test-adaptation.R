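# Sliding-window error regression and interactive trials.

test_that("windowed NLL is the plain sum of per-step contributions", {
  m <- reduced_model()
  s <- reduced_targets()[[1]]
  W <- 10
  w <- regression_window(m, x1 = s$values[1, ],
                         targets = s$values[2:(W + 1), ],
                         pb_internal = m$params$u0_pb[, 1])
  total <- windowed_nll(w)
  per_step <- sapply(seq_len(W), function(t)
    sum(negative_log_likelihood(w$generated$Y[t, 9:10],
                                w$generated$V[t, 9:10],
                                w$targets[t, 9:10])))
  expect_equal(total, sum(per_step), tolerance = 1e-12)
  expect_error(regression_window(m, s$values[1, ],
                                 s$values[0, , drop = FALSE],
                                 pb_internal = m$params$u0_pb[, 1]),
               "empty")
  # perfect predictions with v = 1/(2*pi) give exactly zero
  w0 <- w
  w0$targets[, 9:10] <- w0$generated$Y[, 9:10]
  w0$generated$V[, 9:10] <- 1 / (2 * pi)
  expect_equal(windowed_nll(w0), 0, tolerance = 1e-12)
  expect_equal(network_config()$window_W, 10L)
})

test_that("PB regression descends the windowed objective without momentum", {
  m <- reduced_model()
  m$config$momentum_eta <- 0
  s <- reduced_targets()[[4]]
  w <- regression_window(m, x1 = s$values[1, ],
                         targets = s$values[2:11, ],
                         pb_internal = pb_for_behavior(m, "right"))
  pre <- windowed_nll(w)
  r <- regress_pb(m, w)
  expect_lte(r$nll_post, pre)
  expect_equal(r$nll_pre, pre, tolerance = 1e-10)
})

test_that("higher estimated variance shrinks the PB update", {
  # the same window regressed at K = 8 moves the PB less than at K = 0:
  # down-weighted prediction errors drive weaker intention updates
  m <- reduced_model()
  s <- reduced_targets()[[7]]
  disp <- sapply(c(0, 8), function(K) {
    w <- regression_window(m, x1 = s$values[1, ],
                           targets = s$values[2:11, ],
                           pb_internal = pb_for_behavior(m, "left"),
                           K = K)
    r <- regress_pb(m, w, K = K)
    sqrt(sum((r$window$pb_internal - w$pb_internal)^2))
  })
  expect_lt(disp[2], disp[1])
})

test_that("PB displacement is monotonically non-increasing in K", {
  m <- reduced_model()
  s <- reduced_targets()[[10]]
  disp <- sapply(c(-8, -4, 0, 4, 8), function(K) {
    w <- regression_window(m, x1 = s$values[1, ],
                           targets = s$values[2:11, ],
                           pb_internal = pb_for_behavior(m, "right"),
                           K = K)
    r <- regress_pb(m, w, K = K)
    sqrt(sum((r$window$pb_internal - w$pb_internal)^2))
  })
  expect_true(all(diff(disp) <= 1e-12))
})

test_that("trials have one record per step and are reproducible", {
  m <- reduced_model()
  sch <- situation_schedule(0L, "attract", 60L)
  tr <- run_interactive_trial(m, sch, K = 0, seed = 5,
                              initial_behavior = "attract",
                              specs = reduced_specs())
  expect_s3_class(tr, "sctrnn_trace")
  expect_equal(nrow(tr), 60L)
  expect_true(all(is.finite(tr$nll_windowed)))
  expect_equal(dim(trace_joints(tr)), c(60L, 8L))
  tr2 <- run_interactive_trial(m, sch, K = 0, seed = 5,
                               initial_behavior = "attract",
                               specs = reduced_specs())
  expect_identical(tr$nll_windowed, tr2$nll_windowed)
  expect_identical(trace_joints(tr), trace_joints(tr2))
})

test_that("error regression switches intention toward the situation", {
  # mismatched start: within 50 steps the PB activation is closer to the
  # environment behavior's learned PB than to the initial behavior's
  m <- reduced_model()
  sch <- situation_schedule(0L, "attract", 60L)
  tr <- run_interactive_trial(m, sch, K = 0, seed = 3,
                              initial_behavior = "left",
                              specs = reduced_specs())
  pb50 <- as.numeric(tr[50, c("pb_1", "pb_2")])
  d_env <- sqrt(sum((pb50 - tanh(pb_for_behavior(m, "attract")))^2))
  d_init <- sqrt(sum((pb50 - tanh(pb_for_behavior(m, "left")))^2))
  expect_lt(d_env, d_init)
})

test_that("decreased sensory variance inflates the error signal", {
  m <- reduced_model()
  sch <- situation_schedule(0L, "right", 80L)
  nll <- sapply(c(0, -8), function(K)
    trace_mean_nll(run_interactive_trial(m, sch, K = K, seed = 9,
                                         initial_behavior = "right",
                                         specs = reduced_specs())))
  expect_gt(nll[2], nll[1])
})

test_that("momentum decays geometrically when the window gradient is zero", {
  # synthetic check of the update recursion used inside the regression
  m <- reduced_model()
  m$config$momentum_eta <- 0.9
  up <- gradient_update(c(1, 1), c(0, 0), c(0.1, -0.2),
                        alpha = m$config$learning_rate_alpha, eta = 0.9)
  expect_equal(up$delta, 0.9 * c(0.1, -0.2))
})
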