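test_that("singleton regions receive exactly their normal", {
  px <- rbind(c(0, 0), c(0, 9), c(9, 0), c(9, 9))  # (row, col) corners
  pts <- cbind(0, 0, rep(2, 4))
  a <- c(1, 2, -3); b <- c(-1, 0, -1); cc <- c(0, 1, -2); d <- c(2, 2, -2)
  rv <- split_regions(make_frame_points(pts, px),
                      make_normal_cloud(rbind(a, b, cc, d)))
  expect_equal(unname(rv["TL", ]), a)
  expect_equal(unname(rv["TR", ]), b)
  expect_equal(unname(rv["BL", ]), cc)
  expect_equal(unname(rv["BR", ]), d)
})

test_that("region accumulation matches brute-force midline assignment", {
  set.seed(11)
  n <- 50
  px <- cbind(row = sample(3:40, n, TRUE), col = sample(5:60, n, TRUE))
  nm <- matrix(rnorm(3 * n), n, 3)
  valid <- runif(n) > 0.15
  rv <- split_regions(make_frame_points(cbind(0, 0, rep(2, n)), px),
                      make_normal_cloud(nm, valid))
  # independent loop with explicit midline comparisons
  mr <- (min(px[, 1]) + max(px[, 1])) / 2
  mc <- (min(px[, 2]) + max(px[, 2])) / 2
  acc <- list(TL = c(0, 0, 0), TR = c(0, 0, 0),
              BL = c(0, 0, 0), BR = c(0, 0, 0))
  for (i in seq_len(n)) {
    if (!valid[i]) next
    key <- paste0(if (px[i, 1] <= mr) "T" else "B",
                  if (px[i, 2] <= mc) "L" else "R")
    acc[[key]] <- acc[[key]] + nm[i, ]
  }
  for (k in names(acc)) expect_equal(unname(rv[k, ]), acc[[k]])
  # conservation: the four cells partition the valid normals
  expect_equal(colSums(unclass(rv)), colSums(nm[valid, , drop = FALSE]),
               ignore_attr = TRUE)
})

test_that("midline pixels go to the left/top cell", {
  # bbox rows 0..4, cols 0..4: midlines exactly at pixel 2
  px <- rbind(c(0, 0), c(4, 4), c(2, 2))
  nm <- rbind(c(0, 0, -1), c(0, 0, -1), c(1, 1, -1))
  rv <- split_regions(make_frame_points(cbind(0, 0, c(2, 2, 2)), px),
                      make_normal_cloud(nm))
  expect_equal(unname(rv["TL", ]), c(1, 1, -2))
  expect_equal(unname(rv["BR", ]), c(0, 0, -1))
})

test_that("plane angles reproduce the defining hand-worked cases", {
  # transverse: mirror pair -> 0; identical vectors -> pi/2
  # (zero-angle cases sit at the acos precision floor of ~2e-8)
  expect_lt(angle_transverse(c(1, 5, -1), c(-1, -5, -1)), 1e-6)
  expect_equal(angle_transverse(c(1, 0, -1), c(1, 0, -1)), pi / 2,
               tolerance = 1e-9)
  # sagittal: identical -> 0; orthogonal projections -> pi/2
  expect_lt(angle_sagittal(c(2, 1, -1), c(2, 1, -1)), 1e-6)
  expect_equal(angle_sagittal(c(3, 1, 0), c(-7, 0, 1)), pi / 2,
               tolerance = 1e-9)
  # coronal: mirror pair -> 0; identical x-vectors -> pi
  expect_lt(angle_coronal(c(1, 2, -9), c(-1, 2, -4)), 1e-6)
  expect_equal(angle_coronal(c(1, 0, 0), c(1, 0, 0)), pi, tolerance = 1e-9)
})

test_that("zero-norm projections raise degenerate-feature errors", {
  expect_error(angle_transverse(c(0, 1, 0), c(1, 0, -1)),
               class = "gait_degenerate")
  expect_error(angle_sagittal(c(1, 0, 0), c(0, 1, -1)),
               class = "gait_degenerate")
  expect_error(angle_coronal(c(0, 0, 1), c(1, 1, 0)),
               class = "gait_degenerate")
})

test_that("angles agree with a straight-line oracle on random vectors", {
  set.seed(3)
  for (i in 1:40) {
    uL <- rnorm(3); uR <- rnorm(3)
    expect_equal(angle_transverse(uL, uR), oracle_angle(uL, uR, "transverse"),
                 tolerance = 1e-12)
    expect_equal(angle_sagittal(uL, uR), oracle_angle(uL, uR, "sagittal"),
                 tolerance = 1e-12)
    expect_equal(angle_coronal(uL, uR), oracle_angle(uL, uR, "coronal"),
                 tolerance = 1e-12)
  }
})

test_that("angles are scale invariant and reflections are involutions", {
  set.seed(5)
  for (i in 1:20) {
    uL <- rnorm(3); uR <- rnorm(3); s <- runif(2, 0.01, 100)
    for (p in c("transverse", "sagittal", "coronal")) {
      a1 <- gaitnormals:::angle_pair(uL, uR, p)
      expect_equal(gaitnormals:::angle_pair(s[1] * uL, s[2] * uR, p), a1,
                   tolerance = 1e-12)
      expect_gte(a1, 0); expect_lte(a1, pi)
      proj <- gaitnormals:::plane_project(uR, p)
      twice <- gaitnormals:::plane_reflect(gaitnormals:::plane_reflect(proj, p), p)
      expect_lt(sqrt(sum((twice - proj)^2)), 1e-12)
    }
  }
})

test_that("the basic index adds top and bottom terms", {
  set.seed(8)
  v <- region_vectors(rnorm(3), rnorm(3), rnorm(3), rnorm(3))
  for (p in c("transverse", "sagittal", "coronal")) {
    expect_equal(basic_index(v, p), oracle_basic_index(v, p),
                 tolerance = 1e-12)
    expect_equal(basic_index(v, p, lower_only = TRUE),
                 oracle_angle(v["BL", ], v["BR", ], p), tolerance = 1e-12)
    expect_gte(basic_index(v, p), 0)
    expect_lte(basic_index(v, p), 2 * pi)
  }
  expect_equal(unname(basic_index(v)["sagittal"]), basic_index(v, "sagittal"))
})

test_that("mirror-symmetric frames have null angle features", {
  # constructed symmetric cloud + normals
  set.seed(13)
  n <- 60
  pxL <- cbind(row = sample(0:30, n, TRUE), col = sample(0:14, n, TRUE))
  pxR <- cbind(row = pxL[, 1], col = 31L - pxL[, 2])
  nmL <- cbind(rnorm(n), rnorm(n), -abs(rnorm(n)) - 0.2)
  nmR <- nmL %*% diag(c(-1, 1, 1))
  rv <- split_regions(
    make_frame_points(matrix(0, 2 * n, 3), rbind(pxL, pxR)),
    make_normal_cloud(rbind(nmL, nmR)))
  expect_lt(max(abs(angle_triple(rv))), 1e-6)
  expect_lt(max(basic_index(rv)), 1e-6)

  # full estimation path on a rendered symmetric surface (sphere cap)
  cap <- sphere_cap_frame()
  cl <- reproject(cap$frame, cap$intrinsics)
  rv2 <- split_regions(cl, estimate_normals(cl, 0.03))
  expect_lt(max(abs(angle_triple(rv2))), 1e-6)
})
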