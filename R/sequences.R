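#' Visuo-proprioceptive sequence
#'
#' A `T x 10` time series of scaled sensory values: 8 joint angles
#' followed by 2 ball-position coordinates, each mapped to
#' `[-0.8, 0.8]`, with a behavior label. Used both as teacher-forced
#' training targets and as recorded trial observations.
#'
#' @param values `T x n` numeric matrix, all entries in `[-0.8, 0.8]`,
#'   `T >= 2`.
#' @param behavior_label One of `"right"`, `"left"`, `"self_play"`,
#'   `"attract"`.
#' @param sequence_index Optional index of the sequence in a training set.
#' @param n_joint Number of leading joint dimensions.
#' @return A `vp_sequence` object.
#' @export
vp_sequence <- function(values, behavior_label,
                        sequence_index = NA_integer_, n_joint = 8L) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 2, is.numeric(values))
  if (any(abs(values) > 0.8 + 1e-12))
    stop("sequence values must lie in [-0.8, 0.8]")
  behavior_label <- match.arg(behavior_label, behavior_labels())
  s <- list(values = values,
            length_T = nrow(values),
            behavior_label = behavior_label,
            sequence_index = as.integer(sequence_index),
            n_joint = as.integer(n_joint))
  class(s) <- "vp_sequence"
  s
}

#' The four learned behavior labels
#' @return Character vector of the four ball-playing behaviors.
#' @export
behavior_labels <- function() c("right", "left", "self_play", "attract")

#' @export
print.vp_sequence <- function(x, ...) {
  cat(sprintf("<vp_sequence> %s, T = %d, %d dims (%d joints + %d vision)\n",
              x$behavior_label, x$length_T, ncol(x$values), x$n_joint,
              ncol(x$values) - x$n_joint))
  invisible(x)
}

#' Write a sequence as CSV with a JSON sidecar
#'
#' The CSV holds one row per time step with header
#' `joint_0..joint_7, vision_x, vision_y`; the sidecar
#' (`<path>.json`) records the behavior label and scaling metadata.
#'
#' @param seq_obj A `vp_sequence`.
#' @param path CSV file path.
#' @export
write_sequence_csv <- function(seq_obj, path) {
  stopifnot(inherits(seq_obj, "vp_sequence"))
  nj <- seq_obj$n_joint
  nv <- ncol(seq_obj$values) - nj
  cols <- c(sprintf("joint_%d", seq_len(nj) - 1L),
            if (nv == 2) c("vision_x", "vision_y")
            else sprintf("vision_%d", seq_len(nv) - 1L))
  df <- as.data.frame(seq_obj$values)
  names(df) <- cols
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(behavior_label = seq_obj$behavior_label,
               sequence_index = seq_obj$sequence_index,
               n_joint = nj,
               scaling = list(lower = -0.8, upper = 0.8))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sequence written by [write_sequence_csv()]
#' @param path CSV file path (expects `<path>.json` sidecar).
#' @return A `vp_sequence`.
#' @export
read_sequence_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vp_sequence(as.matrix(df), meta$behavior_label,
              sequence_index = meta$sequence_index,
              n_joint = as.integer(meta$n_joint))
}
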