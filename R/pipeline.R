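#' Extract per-frame region vectors from a depth sequence
#'
#' Runs the geometric front end on every frame: reproject masked body
#' pixels to a 3D cloud, estimate camera-facing surface normals, and
#' accumulate them over the 2x2 silhouette grid. Frames with no body
#' pixels or no valid normals are dropped with a warning.
#'
#' @param x A `gait_sequence` from [simulate_walk()]/[read_sequence()], or
#'   a list of [depth_frame()]s (then `intrinsics` is required).
#' @param intrinsics A [camera_intrinsics()]; taken from the sequence's
#'   config when `x` is a `gait_sequence`.
#' @param radius Normal-estimation neighborhood radius in metres.
#' @return A [sequence_features()] object.
#' @export
extract_features <- function(x, intrinsics = NULL, radius = 0.03) {
  if (inherits(x, "gait_sequence")) {
    if (is.null(intrinsics)) intrinsics <- config_intrinsics(x$config)
    frames <- x$frames
  } else frames <- x
  if (is.null(intrinsics))
    stop_gait("parameter", "intrinsics required for a bare frame list")
  out <- vector("list", length(frames))
  dropped <- 0L
  for (i in seq_along(frames)) {
    rv <- tryCatch({
      cloud <- reproject(frames[[i]], intrinsics)
      split_regions(cloud, estimate_normals(cloud, radius))
    }, gait_empty_input = function(e) NULL)
    if (is.null(rv)) dropped <- dropped + 1L else out[[i]] <- rv
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (dropped > 0)
    warning(sprintf("dropped %d frame(s) with no usable body points", dropped))
  if (length(out) == 0)
    stop_gait("empty_input", "no usable frames in sequence")
  sequence_features(out)
}

#' Score a sequence under every processing-flow variant
#'
#' Computes the symmetry index for the 12 variants
#' {frame, segment} x {transverse, sagittal, coronal} x {full, lower}.
#'
#' @param seq A [sequence_features()] object.
#' @return Data frame with columns `scheme`, `plane`, `body`, `value`.
#' @export
score_sequence <- function(seq) {
  stopifnot(inherits(seq, "sequence_features"))
  grid <- expand.grid(scheme = c("frame", "segment"),
                      plane = c("transverse", "sagittal", "coronal"),
                      body = c("full", "lower"),
                      stringsAsFactors = FALSE)
  grid$value <- mapply(function(sc, pl, bd) {
    f <- if (sc == "segment") segment_index else frame_index
    f(seq, pl, lower_only = (bd == "lower"))
  }, grid$scheme, grid$plane, grid$body)
  grid
}

#' Per-frame feature table
#'
#' One row per retained frame: the six anatomical-plane angle components
#' (`NA` where the frame is degenerate for a plane) and the twelve
#' accumulated region-vector components.
#'
#' @param seq A [sequence_features()] object.
#' @param path Optional CSV output path.
#' @return Data frame (invisibly when `path` is given).
#' @export
features_table <- function(seq, path = NULL) {
  stopifnot(inherits(seq, "sequence_features"))
  ang <- t(apply(unclass(seq), 1, function(r) {
    v <- row_to_region_vectors(r)
    vapply(list(c("TL", "TR"), c("BL", "BR")), function(pair) {
      vapply(c("transverse", "sagittal", "coronal"), function(p)
        angle_pair(v[pair[1], ], v[pair[2], ], p, .na = TRUE), numeric(1))
    }, numeric(3))
  }))
  colnames(ang) <- c("alpha_top", "beta_top", "gamma_top",
                     "alpha_bottom", "beta_bottom", "gamma_bottom")
  out <- data.frame(frame_index = seq_len(nrow(seq)), ang, unclass(seq),
                    check.names = FALSE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write fitted plane weights as JSON
#'
#' @param weights A [plane_weights()] object.
#' @param path Output path.
#' @param trained_on Optional identifiers of the training sequences.
#' @return `path`, invisibly.
#' @export
write_weights_json <- function(weights, path, trained_on = character()) {
  stopifnot(inherits(weights, "plane_weights"))
  jsonlite::write_json(list(wt = weights$wt, ws = weights$ws,
                            wc = weights$wc, scheme = weights$scheme,
                            trained_on = trained_on),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# -- sequence directories ---------------------------------------------------

#' Write a gait sequence to a directory
#'
#' One 16-bit depth PNG (millimetres) and one 8-bit mask PNG per frame,
#' plus a `manifest.json` recording the label, asymmetry parameters,
#' camera, frame rate and unit scale.
#'
#' @param seq A `gait_sequence`.
#' @param dir Output directory (created if missing).
#' @param unit_scale Metres per stored PNG unit (default 0.001).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir, unit_scale = 0.001) {
  stopifnot(inherits(seq, "gait_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames))
    write_depth_png(seq$frames[[i]],
                    file.path(dir, sprintf("depth_%04d.png", i)),
                    unit_scale = unit_scale,
                    mask_path = file.path(dir, sprintf("mask_%04d.png", i)))
  manifest <- list(label = seq$label,
                   asymmetry_magnitude = as.list(seq$asymmetry_magnitude),
                   n_frames = length(seq$frames),
                   unit_scale = unit_scale,
                   fps = seq$config$fps,
                   camera = seq$config$camera,
                   seed = seq$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a gait sequence from a directory written by [write_sequence()]
#'
#' @param dir Sequence directory containing `manifest.json`.
#' @return A `gait_sequence` (config fields limited to what the manifest
#'   stores: camera, fps, seed).
#' @export
read_sequence <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_gait("format", paste("no manifest.json in", dir))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  frames <- lapply(seq_len(manifest$n_frames), function(i)
    read_depth_png(file.path(dir, sprintf("depth_%04d.png", i)),
                   unit_scale = manifest$unit_scale,
                   mask_path = file.path(dir, sprintf("mask_%04d.png", i))))
  cfg <- list(camera = manifest$camera, fps = manifest$fps,
              seed = manifest$seed)
  structure(list(frames = frames, label = manifest$label,
                 asymmetry_magnitude = unlist(manifest$asymmetry_magnitude),
                 config = cfg),
            class = "gait_sequence")
}
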