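# hand-built octree models for arithmetic checks
manual_model <- function(side, leaves, max_depth = 0L) {
  structure(list(origin = c(-side / 2, -side / 2, -side / 2), side = side,
                 max_depth = max_depth, leaf_size = side / 2^max_depth,
                 leaves = leaves, cylinder = NULL,
                 config = carve_config(s_min = side / 2^max_depth),
                 n_views = 0L),
            class = "octree_model")
}

test_that("total volume is N s^3 in mL, summed over heterogeneous leaves", {
  # 1000 leaves at s = 0.27 mm -> 19.683 mm^3 = 0.019683 mL
  lv <- data.frame(level = 0L, ix = seq_len(1000) - 1L, iy = 0L, iz = 0L,
                   unobserved = 0L)
  m <- manual_model(side = 0.27, leaves = lv)
  expect_equal(total_volume(m), 1000 * 0.27^3 / 1000)
  expect_equal(total_volume(m), 0.019683)

  empty <- manual_model(1, data.frame(level = integer(), ix = integer(),
                                      iy = integer(), iz = integer(),
                                      unobserved = integer()))
  expect_equal(total_volume(empty), 0)

  # the largest validation cube: a single 125-mm leaf is 1953.125 mL
  big <- manual_model(125, data.frame(level = 0L, ix = 0L, iy = 0L, iz = 0L,
                                      unobserved = 0L))
  expect_equal(total_volume(big), 1953.125)

  # mixed-depth model equals the flat enumeration of all leaf cubes
  lv2 <- rbind(data.frame(level = 1L, ix = 0L, iy = 0L, iz = 0L, unobserved = 0L),
               data.frame(level = 2L, ix = 2:3, iy = 2L, iz = 2L, unobserved = 0L))
  m2 <- manual_model(side = 8, leaves = lv2, max_depth = 2L)
  grid <- to_flat_grid(m2)
  expect_equal(total_volume(m2), sum(grid) * attr(grid, "cell")^3 / 1000)
  expect_equal(total_volume(m2), (4^3 + 2 * 2^3) / 1000)
})

test_that("voxel classification follows the all/some/none rule with an unseen guard", {
  cyl <- small_cylinder()
  v <- rig_views(test_rig(1, cyl, grid = c(80, 60)))[[1]]
  rf <- trace_view(v, cyl, uniform_media(), c(80, 60))
  full <- matrix(TRUE, 60, 80)
  none <- matrix(FALSE, 60, 80)
  half <- matrix(FALSE, 60, 80); half[, 1:40] <- TRUE
  ctr <- c(0, 0, 40)
  expect_equal(as.character(classify_voxel(ctr, 10, full, rf)), "occupied")
  expect_equal(as.character(classify_voxel(ctr, 10, none, rf)), "empty")
  st <- classify_voxel(ctr, 10, half, rf)
  expect_equal(as.character(st), "undecided")
  expect_gt(attr(st, "fraction"), 0)
  expect_lt(attr(st, "fraction"), 1)
  # explicit thresholds: half-covered voxel with tau_full 0.99 / tau_empty 0.01
  expect_equal(as.character(classify_voxel(ctr, 10, half, rf,
                                           carve_config(tau_full = 0.99,
                                                        tau_empty = 0.01))),
               "undecided")
  # a voxel inside the cylinder but outside this camera's frustum is unseen
  expect_equal(as.character(classify_voxel(c(0, 0, 79), 1.5, full, rf)),
               "unseen")
})

test_that("hierarchical carve equals the brute-force flat-grid carver", {
  cyl <- small_cylinder()
  rig <- test_rig(6, cyl, grid = c(96, 72))
  sph <- shape_sphere(center = c(8, -5, 45), radius = 14)
  cvs <- make_carve_views(sph, rig, grid = c(96, 72))
  cfg <- carve_config(s_min = 5)  # depth 4 on the 80-mm root cube
  model <- carve(cvs, cyl, cfg)
  expect_equal(model$max_depth, 4L)
  oct <- to_flat_grid(model, include_unobserved = TRUE)
  ref <- carve_dense(cvs, cyl, cfg, depth = 4L)
  # compare over cells fully inside the cylinder (identical premask domain)
  G <- 16; cell <- attr(oct, "cell")
  ctrs <- (seq_len(G) - 0.5) * cell - 40
  idx <- as.matrix(expand.grid(1:G, 1:G, 1:G))
  cx <- ctrs[idx[, 1]]; cy <- ctrs[idx[, 2]]
  fully_in <- sqrt(cx^2 + cy^2) + cell * sqrt(2) / 2 < cyl$inner_radius
  expect_equal(oct[idx[fully_in, ]], ref$occupied[idx[fully_in, ]])
})

test_that("the carved hull contains the object and bounds its volume from above", {
  cyl <- small_cylinder()
  rig <- test_rig(20, cyl, grid = c(160, 120))
  sph <- shape_sphere(center = c(0, 0, 42), radius = 16)
  cvs <- make_carve_views(sph, rig, grid = c(160, 120))
  model <- carve(cvs, cyl, carve_config(s_min = 1.25))
  V <- total_volume(model)
  Vtrue <- 4 / 3 * pi * 16^3 / 1000
  expect_gte(V, Vtrue)

  # all interior samples (a leaf-diagonal inside the surface) are occupied
  grid <- to_flat_grid(model)
  cell <- attr(grid, "cell")
  set.seed(6)
  pts <- matrix(rnorm(3000), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) *
    runif(1000, 0, 16 - 2 * cell * sqrt(3))
  pts <- t(t(pts) + c(0, 0, 42))
  ijk <- floor(t(t(pts) - attr(grid, "origin")) / cell) + 1L
  expect_true(all(grid[ijk]))

  # single full-frame view: everything visible in the frustum survives
  full_view <- cvs[[1]]
  full_view$silhouette <- matrix(TRUE, 120, 160)
  m1 <- carve(list(full_view), cyl, carve_config(s_min = 10))
  expect_gt(total_volume(m1, include_unobserved = TRUE),
            0.5 * pi * 40^2 * 80 / 1000)

  expect_error(carve(list(), cyl), class = "rootcarve_no_evidence")
})

test_that("adding views or refining resolution never inflates the hull", {
  cyl <- small_cylinder()
  rig <- test_rig(16, cyl, grid = c(96, 72))
  sph <- shape_sphere(center = c(6, 2, 40), radius = 15)
  cvs <- make_carve_views(sph, rig, grid = c(96, 72))
  cfg <- carve_config(s_min = 2.5)
  vols <- vapply(c(4, 8, 16), function(k)
    total_volume(carve(cvs[seq_len(k)], cyl, cfg)), 0)
  expect_true(all(diff(vols) <= 1e-12))

  # refining the leaf size only sharpens the hull downward
  v_coarse <- total_volume(carve(cvs, cyl, carve_config(s_min = 5)))
  v_fine <- total_volume(carve(cvs, cyl, carve_config(s_min = 2.5)))
  expect_lte(v_fine, v_coarse + 1e-12)
})

test_that("empty silhouettes carve everything; full frames carve nothing visible", {
  cyl <- small_cylinder()
  rig <- test_rig(4, cyl, grid = c(80, 60))
  sph <- shape_sphere(center = c(0, 0, 40), radius = 12)
  cvs <- make_carve_views(sph, rig, grid = c(80, 60))
  for (i in seq_along(cvs)) cvs[[i]]$silhouette <- matrix(FALSE, 60, 80)
  m <- carve(cvs, cyl, carve_config(s_min = 5))
  expect_equal(total_volume(m), 0)
})

test_that("cube-union meshes are watertight with exact enclosed volume", {
  one <- manual_model(2, data.frame(level = 0L, ix = 0L, iy = 0L, iz = 0L,
                                    unobserved = 0L))
  mesh1 <- export_mesh(one)
  expect_equal(nrow(mesh1$faces), 12L)
  expect_equal(mesh_volume(mesh1), total_volume(one), tolerance = 1e-9)

  # two adjacent voxels: the shared face is removed (20 triangles, not 24)
  two <- manual_model(2, data.frame(level = 1L, ix = 0:1, iy = 0L, iz = 0L,
                                    unobserved = 0L), max_depth = 1L)
  mesh2 <- export_mesh(two)
  expect_equal(nrow(mesh2$faces), 20L)
  expect_equal(mesh_volume(mesh2), total_volume(two), tolerance = 1e-9)

  # a carved model round-trips its volume through the divergence theorem
  cyl <- small_cylinder()
  rig <- test_rig(8, cyl, grid = c(96, 72))
  sph <- shape_sphere(center = c(0, 0, 40), radius = 14)
  cvs <- make_carve_views(sph, rig, grid = c(96, 72))
  model <- carve(cvs, cyl, carve_config(s_min = 2.5))
  mesh <- export_mesh(model)
  expect_equal(mesh_volume(mesh), total_volume(model), tolerance = 1e-6)

  # file formats write and contain the right element counts
  for (ext in c("obj", "ply", "stl")) {
    tf <- tempfile(fileext = paste0(".", ext))
    export_mesh(two, tf)
    expect_true(file.exists(tf))
    expect_gt(file.size(tf), 100)
  }
  empty <- manual_model(1, data.frame(level = integer(), ix = integer(),
                                      iy = integer(), iz = integer(),
                                      unobserved = integer()))
  expect_error(export_mesh(empty), class = "rootcarve_empty_mesh")
})

test_that("straight-ray carving matches direct corner projection of voxels", {
  # uniform media: the visibility mask must stay inside the pixel bounding
  # box of the voxel's eight projected corners (textbook shape-from-silhouette)
  cyl <- small_cylinder()
  v <- rig_views(test_rig(1, cyl, grid = c(160, 120)))[[1]]
  rf <- trace_view(v, cyl, uniform_media(), c(160, 120))
  set.seed(33)
  for (rep in 1:5) {
    ctr <- c(runif(2, -15, 15), runif(1, 25, 55))
    half <- runif(1, 3, 6)
    corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * half
    uv <- project_point(v, t(t(corners) + ctr))
    mask <- pixel_visibility_mask(ctr, half, rf)
    px <- which(mask, arr.ind = TRUE)  # (row, col) = (v + 1, u + 1)
    if (nrow(px) == 0) next
    expect_gte(min(px[, 2]) - 1, floor(min(uv[, 1])) - 1)
    expect_lte(max(px[, 2]) - 1, ceiling(max(uv[, 1])) + 1)
    expect_gte(min(px[, 1]) - 1, floor(min(uv[, 2])) - 1)
    expect_lte(max(px[, 1]) - 1, ceiling(max(uv[, 2])) + 1)
  }
})
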