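#' Pinhole camera intrinsics
#'
#' Bundles the focal lengths and principal point of a pinhole depth camera.
#' Pixel coordinates are zero-based, `(u, v) = (column, row)` with rows
#' counted downward in the stored raster.
#'
#' @param fx,fy Focal lengths in pixels (must be positive).
#' @param cx,cy Principal point (column, row) in pixels.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' camera_intrinsics(365.6, 365.6, 255.5, 211.5)
#' @export
camera_intrinsics <- function(fx, fy, cx, cy) {
  vals <- c(fx = fx, fy = fy, cx = cx, cy = cy)
  if (!all(is.finite(vals)))
    stop_gait("parameter", "intrinsics must be finite")
  if (fx <= 0 || fy <= 0)
    stop_gait("parameter", "focal lengths fx, fy must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> fx=%g fy=%g cx=%g cy=%g\n",
              x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

# Pinhole forward projection, the exact inverse of reproject_points().
# Returns (u, v, d) for camera-space points; used for round-trip checks
# and by segment_body().
project_points <- function(xyz, intrinsics) {
  xyz <- as_xyz_matrix(xyz)
  d <- xyz[, 3]
  cbind(u = xyz[, 1] * intrinsics$fx / d + intrinsics$cx,
        v = intrinsics$cy - xyz[, 2] * intrinsics$fy / d,
        d = d)
}

# Core of the pinhole back-projection: vectors of pixel columns u, rows v
# (zero-based) and depths d -> n x 3 camera-space coordinates with x to the
# image left convention and y up (row axis negated).
pixel_to_camera <- function(u, v, d, intrinsics) {
  cbind(x = (u - intrinsics$cx) * d / intrinsics$fx,
        y = (intrinsics$cy - v) * d / intrinsics$fy,
        z = d)
}

as_xyz_matrix <- function(x) {
  x <- rbind(x)
  if (ncol(x) != 3) stop_gait("parameter", "expected 3-column coordinates")
  storage.mode(x) <- "double"
  x
}
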