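#' Configuration for a synthetic walking-depth sequence
#'
#' Describes one rendered treadmill walk: an articulated body (ellipsoid
#' torso, sphere head, cylinder arms and legs) viewed by a frontal pinhole
#' depth camera mounted at `camera_height` metres with the subject
#' `subject_distance` metres away, walking in place at `cadence` strides
#' per second. Defaults emulate a Kinect-2 treadmill setup (512 x 424,
#' 13 fps, camera at 1.7 m, subject at 2.3 m).
#'
#' Two asymmetry families are modelled, mirroring how abnormal gaits are
#' produced in treadmill studies:
#' \describe{
#'   \item{`tilt_deg`}{lateral whole-body roll about the depth axis, as when
#'     a sole is padded under one foot; sign selects the side.}
#'   \item{`leg_asym`}{one leg's swing amplitude is scaled by
#'     `1 - |leg_asym|`, its phase delayed by `|leg_asym| * pi / 8`, and its
#'     swing center shifted backward by `0.5 |leg_asym|` radians, as when a
#'     weight is mounted on one ankle (unequal left/right speed *and*
#'     displacement); sign selects the leg. The displacement term matters:
#'     a pure zero-mean amplitude change would leave the mean posture —
#'     and hence the segment-based index — unchanged.}
#' }
#' The sequence is labelled `"normal"` iff both are zero.
#'
#' @param n_frames Number of frames (default 26 = two gait cycles at the
#'   default cadence and frame rate).
#' @param fps Frame rate (default 13).
#' @param cadence Strides per second (default 1; one stride = full cycle).
#' @param camera List `fx, fy, cx, cy, width, height` (pixels).
#' @param camera_height Camera height above the ground in metres.
#' @param subject_distance Camera-to-subject distance in metres.
#' @param body List of body dimensions in metres (see Details).
#' @param amp_leg,amp_arm Sagittal swing amplitudes in radians; arms swing
#'   in antiphase with the ipsilateral leg.
#' @param tilt_deg Lateral body tilt in degrees (|tilt_deg| < 30).
#' @param leg_asym Leg swing asymmetry in \[-1, 1\].
#' @param noise_sd Per-pixel i.i.d. Gaussian depth noise sd in metres
#'   (default 0.005, ToF-like).
#' @param oversample Surface sample density multiplier for rasterisation.
#' @param seed RNG seed; sequences are bit-reproducible given the config.
#' @details Body fields: `height` (scales nothing by itself; informative),
#'   `hip_height`, `hip_width`, `shoulder_width`, `torso_rx/ry/rz`
#'   (ellipsoid semi-axes), `head_r`, `arm_len`, `arm_r`, `leg_len`,
#'   `leg_r`. The limb labelled "left" is on the +x (image left) side.
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(n_frames = 26, fps = 13, cadence = 1,
                        camera = list(fx = 365.6, fy = 365.6,
                                      cx = 255.5, cy = 211.5,
                                      width = 512, height = 424),
                        camera_height = 1.7, subject_distance = 2.3,
                        body = list(height = 1.75, hip_height = 0.90,
                                    hip_width = 0.18, shoulder_width = 0.38,
                                    torso_rx = 0.16, torso_ry = 0.30,
                                    torso_rz = 0.11, head_r = 0.10,
                                    arm_len = 0.58, arm_r = 0.042,
                                    leg_len = 0.88, leg_r = 0.062),
                        amp_leg = 0.25, amp_arm = 0.18,
                        tilt_deg = 0, leg_asym = 0,
                        noise_sd = 0.005, oversample = 2,
                        seed = 1L) {
  if (n_frames < 1) stop_gait("parameter", "n_frames must be >= 1")
  if (fps <= 0 || cadence <= 0)
    stop_gait("parameter", "fps and cadence must be positive")
  if (noise_sd < 0) stop_gait("parameter", "noise_sd must be >= 0")
  if (abs(tilt_deg) >= 30) stop_gait("parameter", "|tilt_deg| must be < 30")
  if (abs(leg_asym) >= 1) stop_gait("parameter", "|leg_asym| must be < 1")
  if (subject_distance <= 0.5)
    stop_gait("parameter", "subject must be in front of the camera")
  structure(list(n_frames = as.integer(n_frames), fps = fps,
                 cadence = cadence, camera = camera,
                 camera_height = camera_height,
                 subject_distance = subject_distance, body = body,
                 amp_leg = amp_leg, amp_arm = amp_arm,
                 tilt_deg = tilt_deg, leg_asym = leg_asym,
                 noise_sd = noise_sd, oversample = oversample,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Intrinsics of a walk configuration's camera
#' @param config A [walk_config()] (or its `camera` list).
#' @return A [camera_intrinsics()].
#' @export
config_intrinsics <- function(config) {
  cam <- if (!is.null(config$camera)) config$camera else config
  camera_intrinsics(cam$fx, cam$fy, cam$cx, cam$cy)
}

# -- surface sampling (mirror-symmetrized so a zero-asymmetry body is ------
#    exactly left-right symmetric in continuous space) ----------------------

# n points on an ellipsoid surface centered at origin
sample_ellipsoid <- function(n, semi) {
  m <- ceiling(n / 2)
  g <- matrix(rnorm(3 * m), m, 3)
  g <- g / sqrt(rowSums(g^2))
  p <- sweep(g, 2, semi, "*")
  rbind(p, p * rep(c(-1, 1, 1), each = m))
}

# n points on the side of a cylinder of radius r from y = 0 down to
# y = -len; axis along -y, origin at the pivot. No end caps: a cap disc
# faces straight up/down, its normals have zero z-component and the
# camera-facing orientation rule cannot resolve their sign.
sample_cylinder <- function(n, r, len) {
  u <- runif(n, 0, 2 * pi)
  h <- runif(n, 0, len)
  cbind(r * cos(u), -h, r * sin(u))
}

approx_ellipsoid_area <- function(semi) {
  p <- 1.6
  4 * pi * ((semi[1]^p * semi[2]^p + semi[1]^p * semi[3]^p +
             semi[2]^p * semi[3]^p) / 3)^(1 / p)
}

rot_x <- function(pts, theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  cbind(pts[, 1], pts[, 2] * c0 - pts[, 3] * s0,
        pts[, 2] * s0 + pts[, 3] * c0)
}

rot_z <- function(pts, theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  cbind(pts[, 1] * c0 - pts[, 2] * s0,
        pts[, 1] * s0 + pts[, 2] * c0, pts[, 3])
}

translate <- function(pts, v) sweep(pts, 2, v, "+")

# build per-sequence surface samples; one sample set per left/right pair,
# mirrored in x, so the pair is geometrically identical
build_body_samples <- function(config) {
  b <- config$body
  cam <- config$camera
  px_per_m2 <- cam$fx * cam$fy / config$subject_distance^2
  n_for <- function(area) max(200L, ceiling(config$oversample * area * px_per_m2))
  semi <- c(b$torso_rx, b$torso_ry, b$torso_rz)
  # hand sphere and forward-pointing foot ellipsoid ride in the limb's
  # local frame, so they inherit its swing
  hand_r <- 0.9 * b$arm_r + 0.01
  foot_semi <- c(b$leg_r * 0.8, 0.035, 0.11)
  arm <- rbind(
    sample_cylinder(n_for(2 * pi * b$arm_r * b$arm_len), b$arm_r, b$arm_len),
    translate(sample_ellipsoid(n_for(4 * pi * hand_r^2), rep(hand_r, 3)),
              c(0, -b$arm_len - 0.02, 0)))
  leg <- rbind(
    sample_cylinder(n_for(2 * pi * b$leg_r * b$leg_len), b$leg_r, b$leg_len),
    translate(sample_ellipsoid(n_for(approx_ellipsoid_area(foot_semi)),
                               foot_semi),
              c(0, -b$leg_len, -0.06)))
  mirror_x <- function(p) p * rep(c(-1, 1, 1), each = nrow(p))
  pelvis_semi <- c(b$hip_width / 2 + b$leg_r + 0.015, 0.12, b$torso_rz)
  list(torso = sample_ellipsoid(n_for(approx_ellipsoid_area(semi)), semi),
       pelvis = sample_ellipsoid(n_for(approx_ellipsoid_area(pelvis_semi)),
                                 pelvis_semi),
       head = sample_ellipsoid(n_for(4 * pi * b$head_r^2), rep(b$head_r, 3)),
       arm_left = arm, arm_right = mirror_x(arm),
       leg_left = leg, leg_right = mirror_x(leg))
}

# limb pitch angles (radians, rotation about x) for frame phase phi;
# the weighted leg swings lower (scaled amplitude), lags (phase delay)
# and its swing center shifts backward (unequal mean displacement)
limb_angles <- function(config, phi) {
  a <- config$leg_asym
  amp_l <- config$amp_leg; amp_r <- config$amp_leg
  ph_l <- 0; ph_r <- 0; off_l <- 0; off_r <- 0
  if (a > 0) { amp_r <- amp_r * (1 - a); ph_r <- -a * pi / 8; off_r <- -0.5 * a }
  if (a < 0) { amp_l <- amp_l * (1 + a); ph_l <- a * pi / 8;  off_l <- 0.5 * a }
  list(leg_left  = off_l + amp_l * sin(phi + ph_l),
       leg_right = off_r + amp_r * sin(phi + pi + ph_r),
       arm_left  = config$amp_arm * sin(phi + pi),
       arm_right = config$amp_arm * sin(phi))
}

# world coordinates of every sample point at frame phase phi;
# world origin on the ground under the body center, y up,
# +z pointing away from the camera
pose_body <- function(samples, config, phi) {
  b <- config$body
  ang <- limb_angles(config, phi)
  shoulder_y <- b$hip_height + 2 * b$torso_ry - 0.06
  parts <- list(
    translate(samples$torso, c(0, b$hip_height + b$torso_ry, 0)),
    translate(samples$pelvis, c(0, b$hip_height - 0.02, 0)),
    translate(samples$head,
              c(0, b$hip_height + 2 * b$torso_ry + 0.02 + b$head_r, 0)),
    translate(rot_x(samples$arm_left, ang$arm_left),
              c(b$shoulder_width / 2, shoulder_y, 0)),
    translate(rot_x(samples$arm_right, ang$arm_right),
              c(-b$shoulder_width / 2, shoulder_y, 0)),
    translate(rot_x(samples$leg_left, ang$leg_left),
              c(b$hip_width / 2, b$hip_height, 0)),
    translate(rot_x(samples$leg_right, ang$leg_right),
              c(-b$hip_width / 2, b$hip_height, 0)))
  pts <- do.call(rbind, parts)
  if (config$tilt_deg != 0)
    pts <- rot_z(pts, config$tilt_deg * pi / 180)  # roll about ground center
  list(points = pts,
       prim = rep.int(seq_along(parts), vapply(parts, nrow, integer(1))))
}

# rasterize one posed body into a depth frame (z-buffer, nearest wins;
# ties to the earlier primitive, torso first)
render_frame <- function(posed, config) {
  cam <- config$camera
  x <- posed$points[, 1]
  y <- posed$points[, 2] - config$camera_height
  z <- posed$points[, 3] + config$subject_distance
  keep <- z > 0.1
  u <- round(x[keep] * cam$fx / z[keep] + cam$cx)
  v <- round(cam$cy - y[keep] * cam$fy / z[keep])
  z <- z[keep]; prim <- posed$prim[keep]
  inb <- u >= 0 & u < cam$width & v >= 0 & v < cam$height
  u <- u[inb]; v <- v[inb]; z <- z[inb]; prim <- prim[inb]
  if (length(z) == 0) stop_gait("parameter", "body renders outside the image")
  depth <- matrix(0, cam$height, cam$width)
  ord <- order(z, prim, decreasing = TRUE)  # winner (min z, min prim) last
  depth[v[ord] + 1L + u[ord] * cam$height] <- z[ord]
  depth
}

#' Simulate a synthetic treadmill walking depth sequence
#'
#' Renders `n_frames` depth maps of an articulated body walking in place:
#' legs swing sinusoidally about the hips at the configured cadence with
#' the contralateral arm in antiphase; the configured lateral tilt and leg
#' asymmetry are applied; every body primitive is surface-sampled,
#' projected by the pinhole model, z-buffered per pixel (nearest wins) and
#' perturbed by i.i.d. Gaussian depth noise. The mask is exactly the set of
#' rendered pixels, so segmentation is perfect by construction (the method
#' under study begins after segmentation).
#'
#' @param config A [walk_config()].
#' @return An object of class `gait_sequence`: list with `frames` (list of
#'   [depth_frame()]s with masks), `label` (`"normal"`/`"abnormal"`),
#'   `asymmetry_magnitude` (named vector `tilt_deg`, `leg_asym`), and
#'   `config`.
#' @examples
#' seq <- simulate_walk(walk_config(n_frames = 2, noise_sd = 0))
#' seq$frames[[1]]
#' @export
simulate_walk <- function(config) {
  stopifnot(inherits(config, "walk_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(config$seed)
  samples <- build_body_samples(config)
  frames <- vector("list", config$n_frames)
  for (i in seq_len(config$n_frames)) {
    phi <- 2 * pi * config$cadence * (i - 1) / config$fps
    depth <- render_frame(pose_body(samples, config, phi), config)
    mask <- depth > 0
    if (config$noise_sd > 0) {
      nb <- sum(mask)
      depth[mask] <- pmax(depth[mask] + rnorm(nb, 0, config$noise_sd), 0.01)
    }
    frames[[i]] <- depth_frame(depth, mask)
  }
  label <- if (config$tilt_deg == 0 && config$leg_asym == 0)
    "normal" else "abnormal"
  structure(list(frames = frames, label = label,
                 asymmetry_magnitude = c(tilt_deg = config$tilt_deg,
                                         leg_asym = config$leg_asym),
                 config = config),
            class = "gait_sequence")
}

#' @export
print.gait_sequence <- function(x, ...) {
  cat(sprintf("<gait_sequence> %d frames, %s (tilt %g deg, leg_asym %g)\n",
              length(x$frames), x$label,
              x$asymmetry_magnitude["tilt_deg"],
              x$asymmetry_magnitude["leg_asym"]))
  invisible(x)
}

#' Build a labelled synthetic benchmark of pseudo-subjects
#'
#' Per pseudo-subject (randomized body proportions, cadence and swing
#' amplitude): 1 normal sequence plus 8 abnormal ones — lateral tilt at
#' plus/minus a small and a large level, and leg asymmetry at plus/minus a
#' small and a large level — mirroring a 9-gaits-per-subject treadmill
#' protocol. Sequence configurations are returned (not rendered frames):
#' each is materialized on demand with [simulate_walk()], keeping an
#' 81-sequence benchmark within ordinary memory.
#'
#' The default rendering camera is a 2x-binned 256 x 212 variant of the
#' full sensor so a full benchmark evaluation runs at desk scale; pass
#' `base = walk_config()` for full resolution.
#'
#' @param n_subjects Number of pseudo-subjects (>= 2; default 9).
#' @param seed Benchmark-level RNG seed.
#' @param base A [walk_config()] used as template (its tilt/asym are
#'   overridden per sequence).
#' @param tilt_levels Small and large tilt magnitudes in degrees.
#' @param asym_levels Small and large leg-asymmetry magnitudes.
#' @return An object of class `gait_benchmark`: list with `sequences`
#'   (list of per-sequence specs: `sequence_id`, `subject`, `label`,
#'   `family`, `magnitude`, `config`), `n_subjects`, `seed`.
#' @export
make_benchmark <- function(n_subjects = 9, seed = 1,
                           base = walk_config(
                             n_frames = 200,
                             camera = list(fx = 182.8, fy = 182.8,
                                           cx = 127.5, cy = 105.5,
                                           width = 256, height = 212)),
                           tilt_levels = c(4, 8),
                           asym_levels = c(0.2, 0.4)) {
  if (n_subjects < 2) stop_gait("parameter", "need at least 2 subjects")
  stopifnot(inherits(base, "walk_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  gaits <- rbind(
    data.frame(family = "none", tilt = 0, asym = 0),
    data.frame(family = "tilt",
               tilt = c(tilt_levels, -tilt_levels), asym = 0),
    data.frame(family = "leg",
               tilt = 0, asym = c(asym_levels, -asym_levels)))
  seqs <- list()
  for (s in seq_len(n_subjects)) {
    height <- runif(1, 1.56, 1.84)           # subject stature range
    sc <- height / 1.75
    body <- lapply(base$body, function(d) d * sc)
    body$height <- height
    cadence <- runif(1, 0.85, 1.10)
    amp_leg <- runif(1, 0.20, 0.30)
    amp_arm <- runif(1, 0.14, 0.22)
    seeds <- sample.int(.Machine$integer.max - 1L, nrow(gaits))
    for (g in seq_len(nrow(gaits))) {
      cfg <- base
      cfg$body <- body
      cfg$cadence <- cadence
      cfg$amp_leg <- amp_leg
      cfg$amp_arm <- amp_arm
      cfg$tilt_deg <- gaits$tilt[g]
      cfg$leg_asym <- gaits$asym[g]
      cfg$seed <- seeds[g]
      seqs[[length(seqs) + 1L]] <- list(
        sequence_id = sprintf("s%02d_g%d", s, g),
        subject = s,
        label = if (gaits$family[g] == "none") "normal" else "abnormal",
        family = gaits$family[g],
        magnitude = c(tilt_deg = gaits$tilt[g], leg_asym = gaits$asym[g]),
        config = cfg)
    }
  }
  structure(list(sequences = seqs, n_subjects = n_subjects, seed = seed),
            class = "gait_benchmark")
}

#' @export
print.gait_benchmark <- function(x, ...) {
  labs <- vapply(x$sequences, `[[`, "", "label")
  cat(sprintf("<gait_benchmark> %d subjects, %d sequences (%d normal)\n",
              x$n_subjects, length(x$sequences), sum(labs == "normal")))
  invisible(x)
}
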