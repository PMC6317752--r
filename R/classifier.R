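#' Fit the 2-D principal-component projection of joint space
#'
#' Pools the learned joint time series, mean-centers them, and keeps the
#' top two principal components. The projection is made unique by a
#' deterministic sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param joint_series List of `T x 8` joint-angle matrices (the learned
#'   training series).
#' @return A `projection2d`: `loading_matrix` (8 x 2, orthonormal
#'   columns), `center`, `explained_variance` (top-2 eigenvalues of the
#'   pooled covariance), and `domain_bound_N` (max absolute projected
#'   value over the fitting data).
#' @export
fit_projection <- function(joint_series) {
  pooled <- do.call(rbind, lapply(joint_series, as.matrix))
  stopifnot(nrow(pooled) >= 2)
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12)
    stop("degenerate projection: pooled data have rank < 2")
  load2 <- pc$rotation[, 1:2, drop = FALSE]
  for (k in 1:2) {
    j <- which.max(abs(load2[, k]))
    if (load2[j, k] < 0) load2[, k] <- -load2[, k]
  }
  z <- sweep(pooled, 2, pc$center) %*% load2
  p <- list(loading_matrix = load2, center = pc$center,
            explained_variance = pc$sdev[1:2]^2,
            domain_bound_N = max(abs(z)),
            fitted_on = sprintf("%d pooled time points", nrow(pooled)))
  class(p) <- "projection2d"
  p
}

#' Project joint series with a fitted map
#' @param joint_series `T x 8` matrix.
#' @param projection A `projection2d`.
#' @return `T x 2` matrix of principal-component scores.
#' @export
project2d <- function(joint_series, projection) {
  sweep(as.matrix(joint_series), 2, projection$center) %*%
    projection$loading_matrix
}

#' 2-D occurrence histogram of a projected time series
#'
#' Counts state occurrences on an `n_bin x n_bin` equal-width grid over
#' `[-N, N]^2` (N from the projection) and normalizes to a probability
#' distribution. The top edge is right-closed: values exactly at `N` fall
#' in the last bin.
#'
#' @param series2d `T x 2` matrix of projected states.
#' @param projection A `projection2d` (fixes the bounds), or a single
#'   positive number `N`.
#' @param n_bin Bins per axis.
#' @return A `behavior_histogram`: `grid` (probabilities summing to 1),
#'   `n_bin`, `N`.
#' @export
histogram2d <- function(series2d, projection, n_bin = 20L) {
  N <- if (inherits(projection, "projection2d"))
    projection$domain_bound_N else as.numeric(projection)
  z <- as.matrix(series2d)
  if (any(abs(z) > N * (1 + 1e-12)))
    stop("values outside [-N, N]: projection domain bound exceeded")
  idx <- function(x) pmax(1L, pmin(n_bin,
                                   as.integer(floor((x + N) / (2 * N) *
                                                      n_bin)) + 1L))
  grid <- matrix(0, n_bin, n_bin)
  tab <- table(factor(idx(z[, 1]), levels = seq_len(n_bin)),
               factor(idx(z[, 2]), levels = seq_len(n_bin)))
  grid[] <- as.numeric(tab) / nrow(z)
  h <- list(grid = grid, n_bin = as.integer(n_bin), N = N)
  class(h) <- "behavior_histogram"
  h
}

#' Kullback-Leibler divergence between behavior histograms
#'
#' `sum p * ln(p / q)` over bins, after adding `smoothing_lambda`
#' pseudo-mass per bin to both distributions and renormalizing (raw KL is
#' infinite when `p` has mass where `q` has none; the smoothing keeps the
#' divergence finite without changing labels for lambda anywhere in
#' `[1e-8, 1e-4]`).
#'
#' @param p,q `behavior_histogram`s on identical grids.
#' @param smoothing_lambda Pseudo-mass per bin.
#' @return Nonnegative divergence; 0 iff the smoothed distributions are
#'   equal.
#' @export
kl_divergence <- function(p, q, smoothing_lambda = 1e-6) {
  stopifnot(inherits(p, "behavior_histogram"),
            inherits(q, "behavior_histogram"))
  if (p$n_bin != q$n_bin || !isTRUE(all.equal(p$N, q$N)))
    stop("histogram grids do not match")
  nb2 <- p$n_bin^2
  ps <- (p$grid + smoothing_lambda) / (1 + smoothing_lambda * nb2)
  qs <- (q$grid + smoothing_lambda) / (1 + smoothing_lambda * nb2)
  on <- ps > 0
  sum(ps[on] * log(ps[on] / qs[on]))
}

#' Movement amount of a joint time series
#'
#' The mean per-step total absolute joint-angle change,
#' `d = (1/T) * sum_t sum_i |y_{i,t+1} - y_{i,t}|`, normalized by the
#' series length `T`. `d < 0.02` defines freezing.
#'
#' @param joint_series `T x 8` matrix, `T >= 2`.
#' @return Scalar `d >= 0`.
#' @export
movement_amount <- function(joint_series) {
  m <- as.matrix(joint_series)
  if (nrow(m) < 2) stop("movement amount needs at least 2 time steps")
  sum(abs(diff(m))) / nrow(m)
}

#' Behavior-discrimination threshold
#'
#' Half of the minimum KL divergence over ordered pairs of distinct
#' learned histograms (both directions are considered since KL is
#' asymmetric).
#'
#' @param learned_histograms Named list of `behavior_histogram`s (one per
#'   learned behavior).
#' @param smoothing_lambda Pseudo-mass per bin for the KL evaluations.
#' @return Threshold `xi`; a warning is raised if two learned histograms
#'   coincide (degenerate threshold 0).
#' @export
compute_threshold <- function(learned_histograms,
                              smoothing_lambda = 1e-6) {
  n <- length(learned_histograms)
  stopifnot(n >= 2)
  kls <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    kls <- c(kls, kl_divergence(learned_histograms[[i]],
                                learned_histograms[[j]],
                                smoothing_lambda))
  xi <- 0.5 * min(kls)
  if (xi == 0)
    warning("degenerate threshold: two learned histograms coincide")
  xi
}

#' Build the learned-behavior reference library
#'
#' Fits the 2-D projection on the pooled learned joint series, builds one
#' histogram per behavior (its exemplars pooled), and computes the
#' threshold `xi`. Assessed segments are projected with this frozen map;
#' if a segment exceeds the domain bound `N`, the bound is enlarged and
#' all histograms are re-derived on the wider grid.
#'
#' @param target_set List of `vp_sequence`s (the training set).
#' @param n_bin Bins per axis.
#' @param smoothing_lambda KL pseudo-mass per bin.
#' @param n_joint Number of leading joint dimensions.
#' @param spatial_smooth Apply one bin of 3x3 boxcar (kernel) smoothing to
#'   every histogram before KL comparison. Short learned series
#'   under-cover their own observation-noise band on the grid, which
#'   inflates the divergence through bins the learned histogram missed by
#'   sampling accident; the smoothing removes that sparse-sample artifact
#'   while keeping distinct behaviors separated.
#' @return An `sctrnn_library`: `projection`, `histograms`, `xi`,
#'   `n_bin`, `smoothing_lambda`, and the projected learned series
#'   (`learned_z`, for re-binning).
#' @export
behavior_library <- function(target_set, n_bin = 20L,
                             smoothing_lambda = 1e-6, n_joint = 8L,
                             spatial_smooth = TRUE) {
  labels <- vapply(target_set, function(s) s$behavior_label, character(1))
  joints <- lapply(target_set, function(s)
    s$values[, seq_len(n_joint), drop = FALSE])
  projection <- fit_projection(joints)
  learned_z <- list()
  for (b in unique(labels)) {
    z <- do.call(rbind, lapply(joints[labels == b], project2d,
                               projection = projection))
    learned_z[[b]] <- z
  }
  lib <- list(projection = projection, learned_z = learned_z,
              n_bin = as.integer(n_bin),
              smoothing_lambda = smoothing_lambda,
              spatial_smooth = spatial_smooth)
  lib$histograms <- lapply(learned_z, function(z)
    .maybe_smooth(histogram2d(z, projection, n_bin), spatial_smooth))
  lib$xi <- compute_threshold(lib$histograms, smoothing_lambda)
  class(lib) <- "sctrnn_library"
  lib
}

.rebin_library <- function(lib, N_new) {
  lib$projection$domain_bound_N <- N_new
  lib$histograms <- lapply(lib$learned_z, function(z)
    .maybe_smooth(histogram2d(z, N_new, lib$n_bin), lib$spatial_smooth))
  lib$xi <- compute_threshold(lib$histograms, lib$smoothing_lambda)
  lib
}

# 3x3 boxcar dilation of a histogram grid: kernel density smoothing for
# sparse occupancy histograms. Short learned series under-cover their own
# observation-noise band on a 20x20 grid, which inflates KL by stray-bin
# penalties; one bin of spatial smoothing removes that artifact while
# leaving distinct behaviors' loops separated.
.boxcar3 <- function(grid) {
  n <- nrow(grid)
  out <- matrix(0, n, n)
  for (di in -1:1) for (dj in -1:1) {
    out[max(1, 1 - di):min(n, n - di), max(1, 1 - dj):min(n, n - dj)] <-
      out[max(1, 1 - di):min(n, n - di), max(1, 1 - dj):min(n, n - dj)] +
      grid[max(1, 1 + di):min(n, n + di), max(1, 1 + dj):min(n, n + dj)]
  }
  out / sum(out)
}

.maybe_smooth <- function(h, smooth) {
  if (smooth) h$grid <- .boxcar3(h$grid)
  h
}

#' Classify a generated movement segment
#'
#' Projects the segment's joint angles with the library's frozen map,
#' compares its state histogram with each learned behavior by KL
#' divergence, and applies the four-way decision rule:
#' \enumerate{
#'   \item `D_KL(p || q_target) < xi`: **outwardly_normal**;
#'   \item `d < 0.02` and every learned KL `>= xi`: **freezing**;
#'   \item `d >= 0.02` and every learned KL `>= xi`:
#'     **unlearned_movement**;
#'   \item `d >= 0.02` and some learned KL `< xi`:
#'     **inappropriate_learned_movement**.
#' }
#' The residual case (`d < 0.02` with some non-target KL below `xi`) is
#' labeled freezing: movement has effectively stopped.
#'
#' @param segment_joints `T x 8` matrix of generated joint angles
#'   (`T >= 2`).
#' @param target_behavior The behavior appropriate to the situation.
#' @param library An `sctrnn_library`.
#' @return A `classification_result`: `label`, `d`, `kl_by_behavior`,
#'   `xi`.
#' @export
classify_segment <- function(segment_joints, target_behavior, library) {
  stopifnot(inherits(library, "sctrnn_library"))
  if (!target_behavior %in% names(library$histograms))
    stop("unknown target behavior '", target_behavior, "'")
  z <- project2d(segment_joints, library$projection)
  N <- library$projection$domain_bound_N
  if (any(abs(z) > N)) {
    library <- .rebin_library(library, max(abs(z)))
    N <- library$projection$domain_bound_N
  }
  p <- .maybe_smooth(histogram2d(z, N, n_bin = library$n_bin),
                     library$spatial_smooth)
  kl <- vapply(library$histograms, function(q)
    kl_divergence(p, q, library$smoothing_lambda), numeric(1))
  d <- movement_amount(segment_joints)
  xi <- library$xi
  label <-
    if (kl[[target_behavior]] < xi) "outwardly_normal"
    else if (d >= 0.02 && any(kl < xi)) "inappropriate_learned_movement"
    else if (d >= 0.02) "unlearned_movement"
    else "freezing"
  res <- list(label = label, d = d, kl_by_behavior = kl, xi = xi)
  class(res) <- "classification_result"
  res
}

#' The four overt behavior labels
#' @return Character vector of classification labels.
#' @export
classification_labels <- function() {
  c("outwardly_normal", "freezing", "unlearned_movement",
    "inappropriate_learned_movement")
}
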