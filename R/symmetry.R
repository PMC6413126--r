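#' Per-frame region vectors of a sequence
#'
#' Container for the ordered per-frame `region_vectors` of one walking
#' sequence: an n x 12 matrix, one row per retained frame, columns
#' `TL.x ... BR.z`.
#'
#' @param frames List of `region_vectors`, one per frame, or an n x 12
#'   numeric matrix in the same column order.
#' @return An object of class `sequence_features`.
#' @export
sequence_features <- function(frames) {
  if (is.matrix(frames)) {
    m <- frames
    if (ncol(m) != 12) stop_gait("parameter", "expected 12 columns")
  } else {
    if (length(frames) < 1)
      stop_gait("empty_input", "a sequence needs at least one frame")
    m <- t(vapply(frames, function(v) {
      stopifnot(inherits(v, "region_vectors"))
      as.vector(t(unclass(v)))
    }, numeric(12)))
  }
  colnames(m) <- as.vector(t(outer(c("TL", "TR", "BL", "BR"),
                                   c("x", "y", "z"), paste, sep = ".")))
  structure(m, class = c("sequence_features", "matrix", "array"))
}

#' @export
print.sequence_features <- function(x, ...) {
  cat(sprintf("<sequence_features> %d frames\n", nrow(x)))
  invisible(x)
}

row_to_region_vectors <- function(r) {
  region_vectors(r[1:3], r[4:6], r[7:9], r[10:12])
}

#' Mean posture of a sequence
#'
#' Component-wise mean of the four accumulated region vectors across the
#' retained frames.
#'
#' @param seq A `sequence_features` object.
#' @return A `region_vectors` object.
#' @export
mean_posture <- function(seq) {
  stopifnot(inherits(seq, "sequence_features"))
  row_to_region_vectors(colMeans(unclass(seq)))
}

#' Frame-based gait symmetry index
#'
#' Computes the basic per-frame index on the chosen anatomical plane for
#' every frame and averages: the temporal factor enters *after* the angle
#' computation. Frames whose relevant projections are degenerate are
#' dropped with a warning rather than zero-filled (a zero angle would
#' spuriously signal symmetry).
#'
#' @param seq A `sequence_features` object.
#' @param plane `"transverse"`, `"sagittal"` or `"coronal"`.
#' @param lower_only Use only the bottom (lower-body) region pair.
#' @return Index in radians (non-negative; higher = more asymmetric).
#' @export
frame_index <- function(seq, plane, lower_only = FALSE) {
  stopifnot(inherits(seq, "sequence_features"))
  vals <- apply(unclass(seq), 1, function(r)
    basic_index(row_to_region_vectors(r), plane, lower_only, .na = TRUE))
  bad <- is.na(vals)
  if (all(bad))
    stop_gait("empty_input", "all frames degenerate for this plane")
  if (any(bad))
    warning(sprintf("dropping %d degenerate frame(s) for plane %s",
                    sum(bad), plane))
  mean(vals[!bad])
}

#' Segment-based gait symmetry index
#'
#' Averages the four accumulated region vectors across frames first (the
#' mean posture) and applies the basic index once. The temporal factor
#' enters *before* the angle computation, so periodic left-right depth
#' differences of a symmetric walk cancel in the mean.
#'
#' @inheritParams frame_index
#' @return Index in radians (non-negative; higher = more asymmetric).
#' @export
segment_index <- function(seq, plane, lower_only = FALSE) {
  stopifnot(inherits(seq, "sequence_features"))
  basic_index(mean_posture(seq), plane, lower_only)
}

#' Plane weights for the combined index
#'
#' @param wt,ws,wc Non-negative weights for the transverse, sagittal and
#'   coronal indices; at least one must be positive.
#' @param scheme Index scheme the weights were fitted for.
#' @return An object of class `plane_weights`.
#' @export
plane_weights <- function(wt, ws, wc, scheme = "segment") {
  w <- c(wt = wt, ws = ws, wc = wc)
  if (any(!is.finite(w)) || any(w < 0))
    stop_gait("parameter", "weights must be finite and non-negative")
  if (all(w == 0))
    stop_gait("degenerate", "all plane weights are zero")
  structure(list(wt = wt, ws = ws, wc = wc, scheme = scheme),
            class = "plane_weights")
}

#' @export
print.plane_weights <- function(x, ...) {
  cat(sprintf("<plane_weights> wt=%.4g ws=%.4g wc=%.4g (%s scheme)\n",
              x$wt, x$ws, x$wc, x$scheme))
  invisible(x)
}

#' Fit plane weights from normal-gait training sequences
#'
#' The weight of each anatomical plane is the population variance of that
#' plane's index over the training sequences — variance as a measure of the
#' information the index carries. Only *normal* (symmetric) gaits should be
#' supplied: fitting on abnormal patterns would bias the combination toward
#' the particular anomalies seen in training.
#'
#' @param training List of `sequence_features` from normal gaits (>= 2).
#' @param scheme `"segment"` (default, the better-performing scheme) or
#'   `"frame"`.
#' @param lower_only Fit on lower-body indices.
#' @return A [plane_weights()] object.
#' @export
fit_weights <- function(training, scheme = c("segment", "frame"),
                        lower_only = FALSE) {
  scheme <- match.arg(scheme)
  if (!is.list(training) || length(training) < 2)
    stop_gait("insufficient", "need at least 2 normal training sequences")
  idx_fun <- if (scheme == "segment") segment_index else frame_index
  idx <- vapply(c("transverse", "sagittal", "coronal"), function(p)
    vapply(training, idx_fun, numeric(1), plane = p,
           lower_only = lower_only), numeric(length(training)))
  pop_var <- function(x) mean((x - mean(x))^2)
  w <- apply(idx, 2, pop_var)
  if (all(w == 0))
    stop_gait("degenerate",
              "all plane-index variances are zero (identical training sequences)")
  plane_weights(w[["transverse"]], w[["sagittal"]], w[["coronal"]], scheme)
}

#' Weighted combined gait symmetry index
#'
#' `I = wt * I_transverse + ws * I_sagittal + wc * I_coronal`, each operand
#' the chosen-scheme index. Pairwise or single-plane combinations are
#' expressed by zero weights.
#'
#' @param seq A `sequence_features` object.
#' @param weights A [plane_weights()] object.
#' @param scheme Index scheme; defaults to the scheme the weights carry.
#' @param lower_only Use lower-body indices.
#' @return Combined index (weighted radians).
#' @export
combined_index <- function(seq, weights, scheme = NULL, lower_only = FALSE) {
  stopifnot(inherits(weights, "plane_weights"))
  if (is.null(scheme)) scheme <- weights$scheme
  idx_fun <- if (scheme == "segment") segment_index else frame_index
  w <- c(weights$wt, weights$ws, weights$wc)
  planes <- c("transverse", "sagittal", "coronal")
  # zero-weight planes are skipped so their degeneracies cannot propagate
  sum(vapply(seq_along(planes), function(i) {
    if (w[i] == 0) 0
    else w[i] * idx_fun(seq, planes[i], lower_only = lower_only)
  }, numeric(1)))
}
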