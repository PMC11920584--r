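test_that("Snell refraction: identity limits, 45-degree air/water, and TIR", {
  n <- c(0, 0, 1)
  # normal incidence: direction unchanged for any index pair
  expect_equal(refract_direction(c(0, 0, -1), n, 1.0, 1.49), c(0, 0, -1))
  # equal indices: unchanged at any incidence
  set.seed(2)
  for (rep in 1:5) {
    d <- unitize(c(rnorm(2), -abs(rnorm(1)) - 0.1))
    expect_equal(refract_direction(d, n, 1.33, 1.33), d, tolerance = 1e-12)
  }
  # 45 degrees air -> water: arcsin(sin 45 / 1.33) = 32.1176 degrees,
  # embedded in the plane of incidence (2D scalar construction oracle)
  d45 <- c(sin(pi / 4), 0, -cos(pi / 4))
  t45 <- refract_direction(d45, n, 1.0, 1.33)
  th2 <- asin(sin(pi / 4) / 1.33)
  expect_equal(t45, c(sin(th2), 0, -cos(th2)), tolerance = 1e-12)
  # total internal reflection: water -> air beyond the critical angle
  dcrit <- c(sin(70 * pi / 180), 0, -cos(70 * pi / 180))
  expect_null(refract_direction(dcrit, n, 1.33, 1.0))
})

test_that("every refraction satisfies Snell's law, coplanarity, and reversibility", {
  set.seed(8)
  media_pairs <- rbind(c(1.0, 1.49), c(1.49, 1.33), c(1.33, 1.0),
                       c(1.0, 1.33))
  for (rep in 1:40) {
    nrm <- unitize(rnorm(3))
    d <- unitize(rnorm(3))
    if (sum(d * nrm) > -0.05) d <- unitize(d - 2 * sum(d * nrm) * nrm)
    if (sum(d * nrm) > -0.05) next
    p <- media_pairs[(rep %% 4) + 1, ]
    tr <- refract_direction(d, nrm, p[1], p[2])
    if (is.null(tr)) next
    sin1 <- sqrt(1 - sum(d * nrm)^2)
    sin2 <- sqrt(1 - sum(tr * nrm)^2)
    expect_lt(abs(p[1] * sin1 - p[2] * sin2), 1e-12)
    # coplanar with (d, normal)
    expect_lt(abs(det(cbind(d, nrm, tr))), 1e-12)
    # reversibility: swap indices, reverse the ray
    back <- refract_direction(-tr, -nrm, p[2], p[1])
    expect_equal(back, -d, tolerance = 1e-9)
  }
})

test_that("ray/cylinder intersection matches the closed-form quadratic", {
  cyl <- cylinder()
  hit <- intersect_cylinder(c(300, 0, 76.2), c(-1, 0, 0), cyl, "outer")
  expect_equal(hit$point, c(76.2, 0, 76.2), tolerance = 1e-12)
  expect_equal(hit$normal, c(1, 0, 0), tolerance = 1e-12)
  # parallel to the axis, outside the radius: miss
  expect_null(intersect_cylinder(c(100, 0, 10), c(0, 0, 1), cyl, "outer"))
  # above the end caps: miss (height clipping)
  expect_null(intersect_cylinder(c(300, 0, -50), c(-1, 0, 0), cyl, "outer"))

  set.seed(12)
  for (rep in 1:30) {
    o <- c(runif(1, 150, 400), runif(1, -200, 200), runif(1, -50, 200))
    d <- unitize(c(-1, runif(1, -0.5, 0.5), runif(1, -0.5, 0.5)))
    h <- intersect_cylinder(o, d, cyl, "outer")
    # independent quadratic-formula oracle on x^2 + y^2 = r^2
    a <- d[1]^2 + d[2]^2
    b <- 2 * (o[1] * d[1] + o[2] * d[2])
    cc <- o[1]^2 + o[2]^2 - cyl$outer_radius^2
    disc <- b^2 - 4 * a * cc
    if (disc < 0) { expect_null(h); next }
    roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
    zs <- o[3] + roots * d[3]
    okz <- roots > 1e-9 & zs >= 0 & zs <= cyl$height
    if (!any(okz)) { expect_null(h); next }
    expect_equal(h$t, roots[okz][1], tolerance = 1e-9)
    expect_equal(sum(h$point[1:2]^2), cyl$outer_radius^2, tolerance = 1e-6)
  }
})

test_that("the default trace grid casts exactly 480,000 rays", {
  cyl <- cylinder()
  v <- rig_views(turntable_rig(n_views = 1, cyl = cyl))[[1]]
  rf <- trace_view(v, cyl, optical_media())
  expect_equal(rf$width * rf$height, 480000L)
  expect_equal(c(rf$width, rf$height), c(800L, 600L))
  expect_length(rf$t_max, 480000L)
  expect_equal(dim(as_ray_tensor(rf)), c(3L, 800L, 600L))
  # a healthy share of rays enters the water volume
  expect_gt(mean(rf$valid), 0.2)
  # every valid in-water ray starts on the inner wall
  i <- which(rf$valid)[seq(1, sum(rf$valid), length.out = 500)]
  rad <- sqrt(rf$origin[i, 1]^2 + rf$origin[i, 2]^2)
  expect_lt(max(abs(rad - cyl$inner_radius)), 1e-6)
})

test_that("uniform media reduce tracing to straight pinhole rays", {
  cyl <- small_cylinder()
  v <- rig_views(test_rig(1, cyl))[[1]]
  rf <- trace_view(v, cyl, uniform_media(), c(160, 120))
  pr <- rootcarve:::pinhole_rays(v, 160, 120)
  i <- which(rf$valid)
  crossmag <- sqrt(rowSums(cbind(
    rf$dir[i, 2] * pr$dirs[i, 3] - rf$dir[i, 3] * pr$dirs[i, 2],
    rf$dir[i, 3] * pr$dirs[i, 1] - rf$dir[i, 1] * pr$dirs[i, 3],
    rf$dir[i, 1] * pr$dirs[i, 2] - rf$dir[i, 2] * pr$dirs[i, 1])^2))
  expect_lt(max(crossmag), 1e-12)  # sin of the angular deviation
})

test_that("the meridional axis ray passes undeviated and deviation grows with index contrast", {
  cyl <- cylinder()
  # odd-sized grid so one pixel center sits exactly on the optical axis
  intr <- intrinsics(500, 500, 100, 75, 201, 151)
  rig <- turntable_rig(n_views = 1, ring_radius = 500, cyl = cyl, intr = intr)
  v <- rig_views(rig)[[1]]
  rf <- trace_view(v, cyl, optical_media(), c(201, 151))
  center_idx <- 76 + 151 * 100  # row 76, col 101 (1-based) on a 151 x 201 grid
  expect_true(rf$valid[center_idx])
  pr <- rootcarve:::pinhole_rays(v, 201, 151)
  dev <- sqrt(sum(cross3_test(rf$dir[center_idx, ], pr$dirs[center_idx, ])^2))
  expect_lt(dev, 1e-9)
  # the axis ray's in-water origin lies in the meridional plane (y = 0)
  expect_lt(abs(rf$origin[center_idx, 2]), 1e-9)

  # monotone deviation: same off-axis pixel, increasing water index
  off_idx <- 76 + 151 * 140
  devs <- vapply(c(1.0, 1.1, 1.2, 1.33), function(nw) {
    rfw <- trace_view(v, cyl, optical_media(1, nw, nw), c(201, 151))
    acos(min(1, abs(sum(rfw$dir[off_idx, ] * pr$dirs[off_idx, ]))))
  }, 0)
  expect_true(all(diff(devs) > 0))
})

test_that("voxel visibility masks match a per-ray slab-test oracle", {
  cyl <- small_cylinder()
  v <- rig_views(test_rig(1, cyl, grid = c(80, 60)))[[1]]
  rf <- trace_view(v, cyl, optical_media(), c(80, 60))

  # out-of-volume voxel: empty mask with the flag
  m0 <- pixel_visibility_mask(c(0, 0, -30), 2, rf)
  expect_false(any(m0))
  expect_true(isTRUE(attr(m0, "out_of_volume")))

  # voxel spanning the full cross-section at mid-height: mask = valid rays
  # whose segment crosses that height band
  mbig <- pixel_visibility_mask(c(0, 0, 40), 39.9, rf)
  expect_true(all(mbig[!matrix(rf$valid, 60, 80)] == FALSE))
  expect_gt(sum(mbig), 0.5 * sum(rf$valid))

  set.seed(19)
  for (rep in 1:3) {
    ctr <- c(runif(2, -20, 20), runif(1, 20, 60))
    half <- runif(1, 2, 6)
    mask <- pixel_visibility_mask(ctr, half, rf)
    ii <- sample(which(rf$valid), 400)
    for (k in ii[1:50]) {
      o <- rf$origin[k, ]; d <- rf$dir[k, ]
      t0 <- 0; t1 <- rf$t_max[k]; okk <- TRUE
      for (ax in 1:3) {
        if (abs(d[ax]) < 1e-14) {
          if (o[ax] < ctr[ax] - half || o[ax] > ctr[ax] + half) okk <- FALSE
        } else {
          ta <- (ctr[ax] - half - o[ax]) / d[ax]
          tb <- (ctr[ax] + half - o[ax]) / d[ax]
          t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
        }
      }
      expect_identical(unname(mask[k]), okk && t0 <= t1)
    }
  }
})

test_that("visible fraction is the masked foreground proportion", {
  mask <- matrix(FALSE, 10, 10); mask[3:6, 3:6] <- TRUE
  full <- matrix(TRUE, 10, 10)
  expect_equal(visible_fraction(mask, full), 1)
  disjoint <- matrix(FALSE, 10, 10); disjoint[9:10, 9:10] <- TRUE
  expect_equal(visible_fraction(mask, disjoint), 0)
  expect_equal(visible_fraction(matrix(FALSE, 10, 10), full), 0)
  set.seed(4)
  m <- matrix(runif(100) < 0.4, 10, 10)
  s <- matrix(runif(100) < 0.5, 10, 10)
  acc <- 0; tot <- 0
  for (i in 1:100) { if (m[i]) { tot <- tot + 1; if (s[i]) acc <- acc + 1 } }
  expect_equal(visible_fraction(m, s), acc / tot)
})

test_that("rayfield binary caches round-trip exactly", {
  cyl <- small_cylinder()
  v <- rig_views(test_rig(1, cyl))[[1]]
  rf <- trace_view(v, cyl, optical_media(), c(40, 30))
  tf <- tempfile(fileext = ".rayf")
  write_rayfield(rf, tf)
  back <- read_rayfield(tf)
  expect_identical(back$valid, rf$valid)
  expect_equal(back$origin, rf$origin, tolerance = 1e-15)
  expect_equal(back$dir, rf$dir, tolerance = 1e-15)
  expect_equal(back$t_max, rf$t_max, tolerance = 1e-15)
  expect_equal(back$cylinder$inner_radius, cyl$inner_radius)
})

test_that("tracing refuses a camera inside the canister", {
  cyl <- cylinder()
  intr <- intrinsics(100, 100, 20, 15, 40, 30)
  v <- camera_view(intr, extrinsics(diag(3), c(0, 0, -10)))
  expect_error(trace_view(v, cyl, optical_media(), c(40, 30)),
               class = "rootcarve_invalid_geometry")
})
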