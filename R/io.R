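#' Save a trained model checkpoint
#'
#' Writes a directory holding `meta.json` (configuration, seed, training
#' metadata, loss history) and one CSV per parameter array with 17
#' significant digits, which round-trips IEEE-754 doubles exactly.
#'
#' @param model An `sctrnn_model` (see [train_offline()]).
#' @param dir Checkpoint directory (created if needed).
#' @export
save_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "sctrnn_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config = unclass(model$config),
               seed = model$seed,
               epochs = length(model$loss_history),
               loss_history = model$loss_history,
               sequence_labels = model$sequence_labels,
               param_fields = .param_fields)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in .param_fields) {
    m <- model$params[[nm]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    .write_matrix_17g(m, file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

.param_fields <- c("W_xc", "W_cc", "W_pc", "W_co", "W_cv",
                   "b_c", "b_o", "b_v", "u0_pb")

.write_matrix_17g <- function(m, path) {
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                         collapse = ","))
  writeLines(lines, path)
}

.read_matrix_17g <- function(path, as_vector = FALSE) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  m <- do.call(rbind, lapply(rows, as.numeric))
  if (as_vector && ncol(m) == 1) drop(m) else m
}

#' Load a model checkpoint saved by [save_checkpoint()]
#' @param dir Checkpoint directory.
#' @return An `sctrnn_model`.
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  config <- network_config(
    n_input = cfg$n_input, n_context = cfg$n_context, n_pb = cfg$n_pb,
    tau = cfg$tau, learning_rate_alpha = cfg$learning_rate_alpha,
    momentum_eta = cfg$momentum_eta, window_W = cfg$window_W,
    variance_offset_K = cfg$variance_offset_K,
    variance_floor_epsilon = cfg$variance_floor_epsilon,
    adaptation_iters = cfg$adaptation_iters,
    learning_epochs = cfg$learning_epochs, n_joint = cfg$n_joint)
  params <- list()
  for (nm in .param_fields) {
    vec_field <- nm %in% c("b_c", "b_o", "b_v")
    params[[nm]] <- .read_matrix_17g(file.path(dir, paste0(nm, ".csv")),
                                     as_vector = vec_field)
  }
  params$seed <- meta$seed
  class(params) <- "sctrnn_params"
  labels <- meta$sequence_labels
  model <- list(params = params, config = config,
                loss_history = meta$loss_history,
                sequence_labels = labels,
                pb_by_behavior = .split_pb(params$u0_pb, labels),
                seed = meta$seed)
  class(model) <- "sctrnn_model"
  model
}

.split_pb <- function(u0_pb, labels) {
  out <- list()
  for (b in unique(labels))
    out[[b]] <- u0_pb[, labels == b, drop = FALSE]
  out
}
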