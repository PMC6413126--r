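# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (all-pairs loops, explicit formulas) so it shares no
# code path with the package internals it checks.

make_frame_points <- function(points, pixels = NULL) {
  points <- rbind(points)
  if (is.null(pixels))
    pixels <- cbind(row = seq_len(nrow(points)) - 1L, col = 0L)
  structure(list(points = points,
                 pixels = cbind(row = pixels[, 1], col = pixels[, 2])),
            class = "frame_points")
}

make_normal_cloud <- function(normals, valid = NULL) {
  normals <- rbind(normals)
  if (is.null(valid)) valid <- rep(TRUE, nrow(normals))
  structure(list(normals = normals, valid = valid), class = "normal_cloud")
}

# O(n^2) PCA normal estimation: all-pairs neighborhoods, explicit
# population covariance, base-R eigen, camera-facing flip
brute_normals <- function(pts, radius, tie_tol = 1e-9) {
  n <- nrow(pts)
  normals <- matrix(0, n, 3)
  valid <- logical(n)
  for (i in seq_len(n)) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2 +
          (pts[, 3] - pts[i, 3])^2
    nb <- pts[d2 <= radius^2, , drop = FALSE]
    if (nrow(nb) < 3) next
    mu <- colMeans(nb)
    cc <- sweep(nb, 2, mu)
    C <- crossprod(cc) / nrow(nb)
    e <- eigen(C, symmetric = TRUE)  # eigenvalues descending
    ev <- rev(e$values)
    if ((ev[2] - ev[1]) < tie_tol * max(ev[3], 1e-300)) next
    v <- e$vectors[, 3]
    if (v[3] > 0) v <- -v
    normals[i, ] <- v
    valid[i] <- TRUE
  }
  list(normals = normals, valid = valid)
}

# straight-line evaluation of the three plane angles and the basic index,
# written symbol by symbol from the defining formulas
oracle_angle <- function(uL, uR, plane) {
  if (plane == "transverse") {
    hL <- c(uL[1], 0, uL[3]); hR <- c(uR[1], 0, uR[3])
    zax <- c(0, 0, 1)
    hRr <- 2 * sum(zax * hR) * zax - hR
  } else if (plane == "sagittal") {
    hL <- c(0, uL[2], uL[3]); hRr <- c(0, uR[2], uR[3])
  } else {
    hL <- c(uL[1], uL[2], 0); hR <- c(uR[1], uR[2], 0)
    yax <- c(0, 1, 0)
    hRr <- 2 * sum(yax * hR) * yax - hR
  }
  acos(max(-1, min(1, sum(hL * hRr) / (sqrt(sum(hL^2)) * sqrt(sum(hRr^2))))))
}

oracle_basic_index <- function(v, plane) {
  oracle_angle(v["TL", ], v["TR", ], plane) +
    oracle_angle(v["BL", ], v["BR", ], plane)
}

# AUC by enumerating every (abnormal, normal) pair
brute_auc <- function(normal, abnormal) {
  wins <- 0
  for (a in abnormal) for (nn in normal)
    wins <- wins + (a > nn) + 0.5 * (a == nn)
  wins / (length(abnormal) * length(normal))
}

# dense depth frame of a sphere cap (front pole toward the camera),
# deterministic, all normals clearly non-grazing
sphere_cap_frame <- function(n = 40, R = 0.5, z0 = 2.5, fov_px = 400) {
  # even n: the mirror midline falls between pixel columns, so no pixel
  # lies on it and left/right cells are exact mirror partners
  cx <- (n - 1) / 2
  cam <- camera_intrinsics(fov_px, fov_px, cx, cx)
  depth <- matrix(0, n, n)
  for (r in 1:n) for (cl in 1:n) {
    # ray through pixel center; intersect with sphere centered (0,0,z0)
    dx <- (cl - 1 - cx) / fov_px
    dy <- (cx - (r - 1)) / fov_px
    a <- dx^2 + dy^2 + 1
    b <- -2 * z0
    disc <- b^2 - 4 * a * (z0^2 - R^2)
    if (disc > 0) {
      z <- (-b - sqrt(disc)) / (2 * a)
      if ((dx^2 + dy^2) * z^2 < (0.55 * R)^2)  # keep the front cap only
        depth[r, cl] <- z
    }
  }
  list(frame = depth_frame(depth, depth > 0), intrinsics = cam,
       center = c(0, 0, z0), R = R)
}

random_cloud <- function(n, seed) {
  set.seed(seed)
  # body-like slab: ~0.5 m wide, 1 m tall, shallow depth relief
  make_frame_points(cbind(runif(n, -0.25, 0.25), runif(n, -0.5, 0.5),
                          2.3 + 0.05 * sin(seq_len(n))))
}

half_res_camera <- function() {
  list(fx = 182.8, fy = 182.8, cx = 127.5, cy = 105.5,
       width = 256, height = 212)
}
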