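# PCA projection, histograms, KL divergence, movement amount, labels.

test_that("projection recovers an exactly 2-D embedding", {
  set.seed(1)
  T_ <- 300
  z <- cbind(3 * sin(seq_len(T_) / 7), 2 * cos(seq_len(T_) / 11))
  emb <- matrix(0, T_, 8)
  emb[, 3] <- z[, 1]; emb[, 6] <- z[, 2]
  emb <- emb + matrix(0.2, T_, 8)  # constant offset in the other dims
  pr <- fit_projection(list(emb))
  # reconstruction through the 2-D map is exact
  zz <- project2d(emb, pr)
  recon <- sweep(zz %*% t(pr$loading_matrix), 2, -pr$center)
  expect_equal(recon, emb, tolerance = 1e-10, ignore_attr = TRUE)
  # explained variance equals the top-2 eigenvalues of the pooled covariance
  ev <- sort(eigen(stats::cov(emb), symmetric = TRUE)$values,
             decreasing = TRUE)[1:2]
  expect_equal(as.numeric(pr$explained_variance),
               ev * (T_ - 1) / (T_ - 1), tolerance = 1e-10)
  # deterministic: same data gives the identical loading matrix
  pr2 <- fit_projection(list(emb))
  expect_identical(pr$loading_matrix, pr2$loading_matrix)
  expect_true(all(apply(pr$loading_matrix, 2,
                        function(v) v[which.max(abs(v))]) > 0))
  expect_error(fit_projection(list(matrix(0.2, 50, 8))), "degenerate")
})

test_that("histograms are normalized with right-closed top edge", {
  pr_N <- 1
  const <- matrix(c(0.31, -0.52), 5, 2, byrow = TRUE)
  h <- histogram2d(const, pr_N, n_bin = 20)
  expect_equal(sum(h$grid), 1, tolerance = 1e-12)
  expect_equal(max(h$grid), 1)
  # boundary value at +N lands in the last bin
  hb <- histogram2d(matrix(c(1, 1), 1, 2), pr_N, n_bin = 20)
  expect_equal(hb$grid[20, 20], 1)
  # exact uniform coverage: m points per bin -> every bin 1/n_bin^2
  nb <- 4
  centers <- (seq_len(nb) - 0.5) / nb * 2 - 1
  gridpts <- as.matrix(expand.grid(centers, centers))
  hu <- histogram2d(gridpts[rep(seq_len(nb^2), 3), ], 1, n_bin = nb)
  expect_true(all(abs(hu$grid - 1 / nb^2) < 1e-12))
  expect_error(histogram2d(matrix(c(1.5, 0), 1, 2), pr_N), "domain")
})

test_that("KL divergence matches its closed form and is nonnegative", {
  mk <- function(g) structure(list(grid = g, n_bin = nrow(g), N = 1),
                              class = "behavior_histogram")
  p <- mk(matrix(c(0.5, 0.5, 0, 0), 2, 2))
  expect_equal(kl_divergence(p, p, 0), 0)
  q <- mk(matrix(c(0.25, 0.75, 0, 0), 2, 2))
  expect_equal(kl_divergence(p, q, 0),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:50) {
    a <- matrix(rexp(16), 4, 4); a <- a / sum(a)
    b <- matrix(rexp(16), 4, 4); b <- b / sum(b)
    expect_gte(kl_divergence(mk(a), mk(b), 1e-6), 0)
  }
  expect_error(kl_divergence(p, mk(matrix(0.25, 2, 2) * 0 + 0.25)), NA)
  expect_error(kl_divergence(p, mk(matrix(1 / 9, 3, 3))), "match")
})

test_that("movement amount follows the mean absolute step change", {
  expect_equal(movement_amount(matrix(0.3, 10, 8)), 0)
  # one joint alternating +-a: every transition contributes 2a
  a <- 0.3; T_ <- 50
  m <- matrix(0, T_, 8)
  m[, 1] <- a * (-1)^(seq_len(T_))
  expect_equal(movement_amount(m), 2 * a * (T_ - 1) / T_)
  expect_error(movement_amount(matrix(0, 1, 8)), "2 time steps")
})

test_that("threshold is half the minimum ordered-pair KL", {
  mk <- function(g) structure(list(grid = g / sum(g), n_bin = nrow(g),
                                   N = 1), class = "behavior_histogram")
  q1 <- mk(matrix(c(8, 1, 1, 1), 2, 2))
  q2 <- mk(matrix(c(1, 8, 1, 1), 2, 2))
  kls <- c(kl_divergence(q1, q2, 0), kl_divergence(q2, q1, 0))
  expect_equal(compute_threshold(list(q1, q2), 0), 0.5 * min(kls))
  expect_warning(compute_threshold(list(q1, q1, q2), 0), "degenerate")
  lib <- reduced_library()
  expect_gt(lib$xi, 0)
})

test_that("the four constructed segment types get their intended labels", {
  lib <- reduced_library()
  ts <- reduced_targets()
  labs <- vapply(ts, function(s) s$behavior_label, character(1))
  seg_of <- function(b) {
    v <- ts[[match(b, labs)]]$values[1:101, 1:8]
    v
  }
  # self-match: a segment of the target behavior's own training data
  for (b in behavior_labels()) {
    cls <- classify_segment(seg_of(b), b, lib)
    expect_equal(cls$label, "outwardly_normal")
    expect_lt(cls$kl_by_behavior[[b]], lib$xi)
  }
  # frozen posture away from the learned distributions
  frozen <- matrix(rep(c(0.75, -0.75), each = 4), 101, 8, byrow = TRUE)
  cls_f <- classify_segment(frozen, "right", lib)
  expect_equal(cls_f$label, "freezing")
  expect_lt(cls_f$d, 0.02)
  # a different learned behavior, moving
  cls_i <- classify_segment(seg_of("left"), "right", lib)
  expect_equal(cls_i$label, "inappropriate_learned_movement")
  # large-amplitude random walk resembling no learned behavior
  set.seed(99)
  rw <- apply(matrix(rnorm(101 * 8, 0, 0.3), 101, 8), 2, cumsum)
  rw <- 0.75 * rw / max(abs(rw))
  cls_u <- classify_segment(rw, "right", lib)
  expect_equal(cls_u$label, "unlearned_movement")
  expect_gte(cls_u$d, 0.02)
  expect_error(classify_segment(seg_of("left"), "hopscotch", lib),
               "unknown")
})

test_that("every (d, KL) combination maps to exactly one label", {
  lib <- reduced_library()
  # exercise the rule table directly over a grid of synthetic outcomes
  xi <- lib$xi
  rule <- function(d, kl_target, kl_other) {
    if (kl_target < xi) "outwardly_normal"
    else if (d >= 0.02 && min(kl_target, kl_other) < xi)
      "inappropriate_learned_movement"
    else if (d >= 0.02) "unlearned_movement"
    else "freezing"
  }
  for (d in c(0, 0.019, 0.02, 0.5))
    for (klt in c(xi / 2, xi, 2 * xi))
      for (klo in c(xi / 2, xi, 2 * xi)) {
        lab <- rule(d, klt, klo)
        expect_true(lab %in% classification_labels())
      }
})

test_that("labels are invariant to the smoothing constant over decades", {
  ts <- reduced_targets()
  labs <- vapply(ts, function(s) s$behavior_label, character(1))
  for (lam in c(1e-8, 1e-6, 1e-4)) {
    lib <- behavior_library(ts, smoothing_lambda = lam)
    cls <- classify_segment(ts[[match("left", labs)]]$values[1:101, 1:8],
                            "right", lib)
    expect_equal(cls$label, "inappropriate_learned_movement")
    cls2 <- classify_segment(ts[[match("right", labs)]]$values[1:101, 1:8],
                             "right", lib)
    expect_equal(cls2$label, "outwardly_normal")
  }
})
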