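test_that("16-bit depth PNG round trip preserves millimetre values", {
  d <- matrix(0, 8, 10)
  d[2, 3] <- 2.3       # 2300 mm
  d[5, 7] <- 0.001     # 1 mm, smallest representable
  d[8, 10] <- 65.535   # max representable
  fr <- depth_frame(d, d > 0)
  f <- withr::local_tempfile(fileext = ".png")
  fm <- withr::local_tempfile(fileext = ".png")
  write_depth_png(fr, f, mask_path = fm)
  back <- read_depth_png(f, mask_path = fm)
  expect_equal(back$depth, d, tolerance = 1e-12)
  expect_identical(back$mask, d > 0)
  # zero stays zero = invalid
  expect_identical(back$depth[1, 1], 0)
})

test_that("stored unit scale converts integers to metres", {
  d <- matrix(c(0, 2.3), 1, 2)  # written as mm by default
  f <- withr::local_tempfile(fileext = ".png")
  write_depth_png(depth_frame(d), f)
  expect_equal(read_depth_png(f, unit_scale = 0.001)$depth[1, 2], 2.3)
  expect_equal(read_depth_png(f, unit_scale = 0.01)$depth[1, 2], 23)
})

test_that("malformed depth PNGs are rejected", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(12), c(2, 2, 3)), f)  # RGB
  expect_error(read_depth_png(f), class = "gait_format")
  png::writePNG(matrix(0.5, 2, 2), f)             # 8-bit grayscale
  expect_error(read_depth_png(f), class = "gait_format")
  expect_error(read_depth_png(withr::local_tempfile()), class = "gait_format")
})

test_that("bounding-box segmentation matches per-pixel brute force", {
  cam <- camera_intrinsics(50, 50, 7.5, 7.5)
  set.seed(42)
  d <- matrix(runif(256, 1.5, 3.5), 16, 16)
  d[sample(256, 30)] <- 0  # dropouts
  box <- list(min = c(-0.3, -0.4, 2.0), max = c(0.25, 0.35, 3.0))
  fr <- segment_body(depth_frame(d), box, cam)
  # independent loop: apply the back-projection and bounds per pixel
  expected <- matrix(FALSE, 16, 16)
  for (r in 1:16) for (cl in 1:16) {
    dep <- d[r, cl]
    if (dep <= 0) next
    x <- (cl - 1 - 7.5) * dep / 50
    y <- (7.5 - (r - 1)) * dep / 50
    expected[r, cl] <- x >= box$min[1] && x < box$max[1] &&
      y >= box$min[2] && y < box$max[2] &&
      dep >= box$min[3] && dep < box$max[3]
  }
  expect_identical(fr$mask, expected)
  expect_gt(sum(expected), 0)  # fixture actually exercises inclusion
})

test_that("segmentation boxes handle edge cases", {
  cam <- camera_intrinsics(50, 50, 1.5, 1.5)
  d <- matrix(2, 4, 4)
  # box entirely behind the far depth -> empty mask
  fr <- segment_body(depth_frame(d), list(min = c(-1, -1, 5), max = c(1, 1, 6)), cam)
  expect_false(any(fr$mask))
  # single included pixel
  d2 <- matrix(0, 4, 4); d2[2, 2] <- 2
  fr2 <- segment_body(depth_frame(d2), list(min = c(-1, -1, 1), max = c(1, 1, 3)), cam)
  expect_identical(which(fr2$mask), which(d2 > 0))
  # degenerate box
  expect_error(
    segment_body(depth_frame(d), list(min = c(0, 0, 2), max = c(0, 1, 3)), cam),
    class = "gait_parameter")
})

test_that("reprojection matches the pinhole model hand cases", {
  cam <- camera_intrinsics(500, 500, 320, 240)
  d <- matrix(0, 480, 640)
  d[241, 321] <- 2.0  # pixel (u, v) = (320, 240): the principal point
  d[241, 421] <- 2.0  # u = 420: x = (420 - 320) * 2 / 500 = 0.4
  fp <- reproject(depth_frame(d, d > 0), cam)
  at <- function(u, v) fp$points[fp$pixels[, "col"] == u &
                                 fp$pixels[, "row"] == v, ]
  expect_equal(unname(at(320, 240)), c(0, 0, 2), tolerance = 1e-12)
  expect_equal(unname(at(420, 240))[1], 0.4, tolerance = 1e-12)
  # y axis points up: a pixel in a *lower* image row has smaller y
  d2 <- matrix(0, 480, 640); d2[100, 321] <- 2; d2[400, 321] <- 2
  fp2 <- reproject(depth_frame(d2, d2 > 0), cam)
  ys <- fp2$points[order(fp2$pixels[, "row"]), 2]
  expect_gt(ys[1], ys[2])
})

test_that("projection round trip is the identity and Eq is homogeneous", {
  cam <- camera_intrinsics(365.6, 365.6, 255.5, 211.5)
  set.seed(1)
  n <- 200
  d <- matrix(runif(424 * 512, 1, 4), 424, 512)
  mask <- matrix(FALSE, 424, 512); mask[sample(424 * 512, n)] <- TRUE
  fp <- reproject(depth_frame(d, mask), cam)
  expect_identical(nrow(fp$points), sum(mask))  # no silent drops
  uvd <- gaitnormals:::project_points(fp$points, cam)
  expect_lt(max(abs(uvd[, "u"] - fp$pixels[, "col"])), 1e-9)
  expect_lt(max(abs(uvd[, "v"] - fp$pixels[, "row"])), 1e-9)
  expect_lt(max(abs(uvd[, "d"] - fp$points[, 3])), 1e-12)
  # doubling depth doubles all three coordinates
  fp2 <- reproject(depth_frame(2 * d, mask), cam)
  expect_equal(fp2$points, 2 * fp$points, tolerance = 1e-12)
})

test_that("frames without a usable mask are rejected, not guessed", {
  cam <- camera_intrinsics(50, 50, 1.5, 1.5)
  d <- matrix(2, 4, 4)
  expect_error(reproject(depth_frame(d), cam), class = "gait_parameter")
  expect_error(reproject(depth_frame(d, matrix(FALSE, 4, 4)), cam),
               class = "gait_empty_input")
  # masked pixels with zero depth are excluded
  d[1, 1] <- 0
  fp <- reproject(depth_frame(d, matrix(TRUE, 4, 4)), cam)
  expect_identical(nrow(fp$points), 15L)
})

test_that("camera JSON config and PLY export round trip", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(fx = 365.6, fy = 360, cx = 255.5, cy = 211.5,
                            unit_scale = 0.001,
                            box = list(min = c(-1, -1, 1), max = c(1, 1, 3))),
                       f, auto_unbox = TRUE)
  cfg <- read_camera_config(f)
  expect_s3_class(cfg$intrinsics, "camera_intrinsics")
  expect_equal(cfg$intrinsics$fy, 360)
  expect_equal(unlist(cfg$box$max), c(1, 1, 3), ignore_attr = TRUE)

  fp <- make_frame_points(cbind(c(0.1, -0.2), c(0.3, 0), c(2, 2.5)))
  nc <- make_normal_cloud(rbind(c(0, 0, -1), c(1, 0, 0) / sqrt(1)))
  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(fp, ply, nc)
  lines <- readLines(ply)
  expect_identical(lines[1], "ply")
  expect_true("property float nz" %in% lines)
  vals <- scan(text = lines[length(lines) - 1], quiet = TRUE)
  expect_equal(vals[1:3], c(0.1, 0.3, 2))
})
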