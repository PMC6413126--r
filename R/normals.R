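#' Estimate camera-facing surface normals for a body point cloud
#'
#' For each point, all points within `radius` metres (closed Euclidean
#' ball, the point itself included) form its neighborhood; the normal is
#' the unit eigenvector of the neighborhood's population covariance matrix
#' associated with the smallest eigenvalue. Since every body surface seen
#' by the depth camera faces it, normals are oriented so their z-component
#' is non-positive (flipped when needed).
#'
#' Points are marked invalid (and skipped downstream) when the neighborhood
#' has fewer than 3 points or the two smallest covariance eigenvalues are
#' numerically equal, leaving the normal direction unidentifiable.
#'
#' The default 3 cm radius trades noise suppression against locality: the
#' per-point normals are later summed over large silhouette regions, which
#' itself averages out residual noise, so a small neighborhood suffices.
#'
#' @param cloud A `frame_points` object from [reproject()].
#' @param radius Neighborhood radius in metres (default 0.03).
#' @param tie_tol Relative eigenvalue-gap tolerance below which the normal
#'   is declared ambiguous (default 1e-9).
#' @return An object of class `normal_cloud`: list with `normals` (n x 3
#'   matrix of unit vectors, rows undefined where invalid) and `valid`
#'   (logical n-vector).
#' @examples
#' cam <- camera_intrinsics(100, 100, 15.5, 15.5)
#' d <- matrix(2, 32, 32)
#' fr <- depth_frame(d, matrix(TRUE, 32, 32))
#' nc <- estimate_normals(reproject(fr, cam))
#' head(nc$normals)  # flat wall: all (0, 0, -1)
#' @export
estimate_normals <- function(cloud, radius = 0.03, tie_tol = 1e-9) {
  stopifnot(inherits(cloud, "frame_points"))
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0)
    stop_gait("parameter", "radius must be a positive number")
  if (nrow(cloud$points) == 0)
    stop_gait("empty_input", "empty point cloud")
  res <- .estimate_normals_cpp(cloud$points, radius, tie_tol)
  structure(list(normals = res$normals, valid = res$valid),
            class = "normal_cloud")
}

#' @export
print.normal_cloud <- function(x, ...) {
  cat(sprintf("<normal_cloud> %d normals (%d valid)\n",
              length(x$valid), sum(x$valid)))
  invisible(x)
}
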