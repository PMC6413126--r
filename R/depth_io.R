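#' Depth frame container
#'
#' A single depth map in metres with an optional body mask. Depth value 0 is
#' the invalid/no-return sentinel and is never treated as a surface.
#'
#' @param depth Numeric matrix of depths in metres (rows = image rows,
#'   top-down); 0 marks invalid pixels.
#' @param mask Optional logical matrix of the same shape marking body pixels.
#' @return An object of class `depth_frame`.
#' @export
depth_frame <- function(depth, mask = NULL) {
  if (!is.matrix(depth) || !is.numeric(depth))
    stop_gait("format", "depth must be a numeric matrix")
  if (any(depth < 0, na.rm = TRUE))
    stop_gait("format", "depth values must be non-negative")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(depth)))
      stop_gait("format", "mask shape must equal depth shape")
    mask <- matrix(as.logical(mask), nrow(depth), ncol(depth))
  }
  structure(list(depth = depth, mask = mask), class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("<depth_frame> %d x %d px, %d valid, %s\n",
              nrow(x$depth), ncol(x$depth), sum(x$depth > 0),
              if (is.null(x$mask)) "no mask"
              else sprintf("%d masked", sum(x$mask))))
  invisible(x)
}

#' Read a 16-bit grayscale depth PNG
#'
#' Stored integer values are multiplied by `unit_scale` (default: stored
#' millimetres to metres). Zero stays zero and keeps its invalid-pixel
#' meaning.
#'
#' @param path Path to a single-channel 16-bit PNG.
#' @param unit_scale Metres per stored integer unit (default 0.001).
#' @param mask_path Optional path to a body-mask PNG (any nonzero = body).
#' @return A [depth_frame()].
#' @export
read_depth_png <- function(path, unit_scale = 0.001, mask_path = NULL) {
  img <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stop_gait("format", conditionMessage(e)))
  info <- attr(img, "info")
  if (length(dim(img)) != 2)
    stop_gait("format", sprintf("expected single-channel PNG, got %d channels",
                                dim(img)[3]))
  if (!is.null(info$bit.depth) && info$bit.depth != 16)
    stop_gait("format", sprintf("expected 16-bit PNG, got %d-bit",
                                info$bit.depth))
  depth <- round(img * 65535) * unit_scale
  attributes(depth) <- list(dim = dim(depth))
  mask <- if (!is.null(mask_path)) read_mask_png(mask_path)
  depth_frame(depth, mask)
}

#' Read a body-mask PNG
#'
#' @param path Path to a grayscale PNG; any nonzero pixel is body.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop_gait("format", conditionMessage(e)))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' Write a depth frame as a 16-bit grayscale PNG
#'
#' Depths are divided by `unit_scale` and rounded to 16-bit integers
#' (default: metres stored as millimetres). If the frame has a mask it is
#' written alongside as an 8-bit PNG (255 = body) at `mask_path`.
#'
#' @param frame A [depth_frame()].
#' @param path Output PNG path.
#' @param unit_scale Metres per stored unit (default 0.001).
#' @param mask_path Optional output path for the mask PNG.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(frame, path, unit_scale = 0.001,
                            mask_path = NULL) {
  stopifnot(inherits(frame, "depth_frame"))
  ints <- round(frame$depth / unit_scale)
  if (any(ints > 65535))
    stop_gait("parameter", "depth exceeds 16-bit range at this unit_scale")
  write_png16_gray(ints, path)
  if (!is.null(mask_path)) {
    if (is.null(frame$mask))
      stop_gait("parameter", "frame has no mask to write")
    png::writePNG(matrix(as.numeric(frame$mask),
                         nrow(frame$depth), ncol(frame$depth)), mask_path)
  }
  invisible(path)
}

#' Segment the body with a 3D bounding box
#'
#' Fills the frame's mask with exactly the pixels whose reprojected 3D point
#' falls inside the half-open box `[min, max)` on every axis. Invalid
#' (zero-depth) pixels are never marked. This is the depth-based fallback
#' for setups where the camera-treadmill geometry is fixed; externally
#' supplied masks (e.g. from an SDK body labeller) can be attached to the
#' frame instead.
#'
#' @param frame A [depth_frame()].
#' @param box List with numeric length-3 elements `min` and `max` (metres,
#'   camera space), `min < max` on each axis.
#' @param intrinsics A [camera_intrinsics()].
#' @return The frame with its mask replaced.
#' @export
segment_body <- function(frame, box, intrinsics) {
  stopifnot(inherits(frame, "depth_frame"))
  bmin <- as.numeric(box$min); bmax <- as.numeric(box$max)
  if (length(bmin) != 3 || length(bmax) != 3 || any(!is.finite(c(bmin, bmax))))
    stop_gait("parameter", "box must have finite numeric min and max of length 3")
  if (any(bmin >= bmax))
    stop_gait("parameter", "degenerate box: min must be < max on every axis")
  d <- frame$depth
  nr <- nrow(d); nc <- ncol(d)
  # zero-based pixel grids: u = column, v = row
  v <- matrix(0:(nr - 1), nr, nc)
  u <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  xyz <- pixel_to_camera(as.vector(u), as.vector(v), as.vector(d), intrinsics)
  inside <- xyz[, 1] >= bmin[1] & xyz[, 1] < bmax[1] &
            xyz[, 2] >= bmin[2] & xyz[, 2] < bmax[2] &
            xyz[, 3] >= bmin[3] & xyz[, 3] < bmax[3] &
            as.vector(d) > 0
  frame$mask <- matrix(inside, nr, nc)
  frame
}

#' Reproject masked body pixels to a 3D point cloud
#'
#' Applies the pinhole back-projection to every masked pixel with valid
#' (positive) depth: `x = (u - cx) d / fx`, `y = (cy - v) d / fy`, `z = d`,
#' with zero-based `(u, v) = (column, row)` and the row axis negated so that
#' camera space has x to the image left, y up, z toward the subject.
#'
#' @param frame A [depth_frame()] with a mask.
#' @param intrinsics A [camera_intrinsics()].
#' @return An object of class `frame_points`: list with `points` (n x 3
#'   matrix, metres) and `pixels` (n x 2 integer matrix of zero-based
#'   (row, col) source pixels).
#' @export
reproject <- function(frame, intrinsics) {
  stopifnot(inherits(frame, "depth_frame"))
  if (is.null(frame$mask))
    stop_gait("parameter",
              "frame has no mask; segment first or supply one (refusing to guess the body region)")
  sel <- which(frame$mask & frame$depth > 0, arr.ind = TRUE)
  if (nrow(sel) == 0)
    stop_gait("empty_input", "no masked pixels with valid depth")
  v <- sel[, 1] - 1L  # zero-based row
  u <- sel[, 2] - 1L  # zero-based col
  d <- frame$depth[sel]
  pts <- pixel_to_camera(u, v, d, intrinsics)
  structure(list(points = pts,
                 pixels = cbind(row = v, col = u)),
            class = "frame_points")
}

#' @export
print.frame_points <- function(x, ...) {
  cat(sprintf("<frame_points> %d points\n", nrow(x$points)))
  invisible(x)
}

#' Read intrinsics and segmentation box from a JSON config
#'
#' Expected keys: `fx`, `fy`, `cx`, `cy`, optional `unit_scale` and
#' `box: {min: [x,y,z], max: [x,y,z]}`.
#'
#' @param path JSON file path.
#' @return List with `intrinsics`, `unit_scale`, and `box` (or NULL).
#' @examples
#' cfg <- read_camera_config(system.file("extdata", "kinect2_camera.json",
#'                                       package = "gaitnormals"))
#' cfg$intrinsics
#' @export
read_camera_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("fx", "fy", "cx", "cy"))
    if (is.null(cfg[[k]])) stop_gait("format", paste("config missing", k))
  list(intrinsics = camera_intrinsics(cfg$fx, cfg$fy, cfg$cx, cfg$cy),
       unit_scale = if (is.null(cfg$unit_scale)) 0.001 else cfg$unit_scale,
       box = cfg$box)
}

#' Export a point cloud as ASCII PLY
#'
#' Writes per-vertex x, y, z and, when normals are supplied, nx, ny, nz
#' (only points with a valid normal are written in that case).
#'
#' @param cloud A `frame_points` object.
#' @param path Output path.
#' @param normals Optional `normal_cloud` parallel to `cloud`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, normals = NULL) {
  stopifnot(inherits(cloud, "frame_points"))
  pts <- cloud$points
  props <- c("x", "y", "z")
  if (!is.null(normals)) {
    stopifnot(inherits(normals, "normal_cloud"))
    keep <- normals$valid
    pts <- cbind(pts[keep, , drop = FALSE],
                 normals$normals[keep, , drop = FALSE])
    props <- c(props, "nx", "ny", "nz")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               sprintf("property float %s", props),
               "end_header"), con)
  utils::write.table(format(pts, trim = TRUE, scientific = FALSE, digits = 8),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
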