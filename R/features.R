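#' Accumulate normals over the 2x2 silhouette grid
#'
#' The grid is the tight 2D bounding box of the body pixels, split at its
#' horizontal and vertical midlines into four equal-size cells; every valid
#' normal is added (vector sum) into the cell containing its source pixel.
#' Cells are half-open: a pixel exactly on a midline goes to the left/top
#' cell. "Left"/"right" are image-side labels (top-left of the image is the
#' subject's right in a frontal view); since left is always compared with
#' right under the same convention, the symmetry indices do not depend on
#' which anatomical side the label denotes.
#'
#' @param cloud A `frame_points` object.
#' @param normals A parallel `normal_cloud`.
#' @return An object of class `region_vectors`: a 4 x 3 matrix with rows
#'   `TL`, `TR`, `BL`, `BR` (top/bottom x image left/right).
#' @export
split_regions <- function(cloud, normals) {
  stopifnot(inherits(cloud, "frame_points"), inherits(normals, "normal_cloud"))
  if (length(normals$valid) != nrow(cloud$points))
    stop_gait("parameter", "cloud and normals are not parallel")
  if (!any(normals$valid))
    stop_gait("empty_input", "no valid normals to accumulate")
  px <- cloud$pixels
  mid_row <- (min(px[, "row"]) + max(px[, "row"])) / 2
  mid_col <- (min(px[, "col"]) + max(px[, "col"])) / 2
  keep <- normals$valid
  top  <- px[keep, "row"] <= mid_row
  left <- px[keep, "col"] <= mid_col
  nm <- normals$normals[keep, , drop = FALSE]
  acc <- function(sel) {
    if (!any(sel)) c(0, 0, 0) else colSums(nm[sel, , drop = FALSE])
  }
  v <- rbind(TL = acc(top & left),  TR = acc(top & !left),
             BL = acc(!top & left), BR = acc(!top & !left))
  colnames(v) <- c("x", "y", "z")
  structure(v, class = c("region_vectors", class(v)))
}

#' Region vectors from explicit components
#'
#' Convenience constructor for a `region_vectors` object from four 3-vectors.
#'
#' @param TL,TR,BL,BR Numeric length-3 vectors (x, y, z).
#' @return A `region_vectors` object.
#' @export
region_vectors <- function(TL, TR, BL, BR) {
  v <- rbind(TL = as.numeric(TL), TR = as.numeric(TR),
             BL = as.numeric(BL), BR = as.numeric(BR))
  if (ncol(v) != 3 || !all(is.finite(v)))
    stop_gait("parameter", "each region vector must be a finite 3-vector")
  colnames(v) <- c("x", "y", "z")
  structure(v, class = c("region_vectors", class(v)))
}

# -- anatomical-plane angles -------------------------------------------------

plane_project <- function(u, plane) {
  switch(plane,
         transverse = c(u[1], 0, u[3]),
         sagittal   = c(0, u[2], u[3]),
         coronal    = c(u[1], u[2], 0),
         stop_gait("parameter", paste("unknown plane:", plane)))
}

# reflection of the projected right-side vector: about +z for the
# transverse plane, about +y for the coronal plane, none for sagittal
plane_reflect <- function(u, plane) {
  switch(plane,
         transverse = c(-u[1], -u[2], u[3]),
         sagittal   = u,
         coronal    = c(-u[1], u[2], -u[3]))
}

angle_pair <- function(uL, uR, plane, .na = FALSE) {
  pL <- plane_project(as.numeric(uL), plane)
  pR <- plane_reflect(plane_project(as.numeric(uR), plane), plane)
  nL <- sqrt(sum(pL^2)); nR <- sqrt(sum(pR^2))
  if (nL < 1e-12 || nR < 1e-12) {
    if (.na) return(NA_real_)
    stop_gait("degenerate",
              sprintf("zero %s-plane projection (left norm %.3g, right norm %.3g)",
                      plane, nL, nR))
  }
  acos(min(1, max(-1, sum(pL * pR) / (nL * nR))))
}

#' Left-right angle on an anatomical plane
#'
#' Projects the left- and right-side accumulated vectors onto the chosen
#' anatomical plane and returns the angle (radians, in \[0, pi\]) between
#' the left vector and the mirrored right vector. The mirroring makes the
#' angle vanish for a perfectly left-right symmetric posture:
#' \describe{
#'   \item{transverse}{projection (x, 0, z); right side reflected about the
#'     +z direction.}
#'   \item{sagittal}{projection (0, y, z); no reflection, the projections of
#'     a symmetric pair already coincide.}
#'   \item{coronal}{projection (x, y, 0); right side reflected about the +y
#'     direction.}
#' }
#'
#' @param uL,uR Numeric 3-vectors: accumulated normals of the left and right
#'   region (image-side convention).
#' @return Angle in radians.
#' @export
angle_transverse <- function(uL, uR) angle_pair(uL, uR, "transverse")

#' @rdname angle_transverse
#' @export
angle_sagittal <- function(uL, uR) angle_pair(uL, uR, "sagittal")

#' @rdname angle_transverse
#' @export
angle_coronal <- function(uL, uR) angle_pair(uL, uR, "coronal")

#' Six-component angle feature of one frame or mean posture
#'
#' Top and bottom left-right angles for each of the three anatomical planes.
#'
#' @param v A `region_vectors` object.
#' @return Named numeric vector `alpha_top`, `alpha_bottom`, `beta_top`,
#'   `beta_bottom`, `gamma_top`, `gamma_bottom` (radians).
#' @export
angle_triple <- function(v) {
  stopifnot(inherits(v, "region_vectors"))
  out <- c(alpha_top    = angle_pair(v["TL", ], v["TR", ], "transverse"),
           alpha_bottom = angle_pair(v["BL", ], v["BR", ], "transverse"),
           beta_top     = angle_pair(v["TL", ], v["TR", ], "sagittal"),
           beta_bottom  = angle_pair(v["BL", ], v["BR", ], "sagittal"),
           gamma_top    = angle_pair(v["TL", ], v["TR", ], "coronal"),
           gamma_bottom = angle_pair(v["BL", ], v["BR", ], "coronal"))
  out
}

#' Basic per-posture symmetry index
#'
#' Sum of the top and bottom left-right angles on one anatomical plane,
#' in \[0, 2 pi\]; with `lower_only = TRUE` only the bottom term (the
#' lower-body variant) is returned. Higher = more asymmetric.
#'
#' @param v A `region_vectors` object.
#' @param plane One of `"transverse"`, `"sagittal"`, `"coronal"`, or
#'   `"all"` for a named vector of all three.
#' @param lower_only Use only the bottom region pair.
#' @param .na Return `NA` instead of erroring on a degenerate projection
#'   (used by sequence aggregation, which drops such frames).
#' @return Numeric index (or named length-3 vector for `plane = "all"`).
#' @export
basic_index <- function(v, plane = "all", lower_only = FALSE, .na = FALSE) {
  stopifnot(inherits(v, "region_vectors"))
  one <- function(p) {
    bottom <- angle_pair(v["BL", ], v["BR", ], p, .na = .na)
    if (lower_only) return(bottom)
    angle_pair(v["TL", ], v["TR", ], p, .na = .na) + bottom
  }
  if (identical(plane, "all"))
    return(c(transverse = one("transverse"),
             sagittal   = one("sagittal"),
             coronal    = one("coronal")))
  one(match.arg(plane, c("transverse", "sagittal", "coronal")))
}
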