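# Shared fixture builders: a small canister and scaled-down turntable rigs
# so geometry tests run at desk scale. All scenes are generated in code.

small_cylinder <- function() {
  cylinder(outer_radius = 43.175, wall = 3.175, height = 80)  # inner r = 40
}

# a rig whose field of view frames the given canister on a small ray grid
test_rig <- function(n_views, cyl = small_cylinder(), grid = c(160, 120),
                     ring_radius = 300) {
  f <- grid[2] * ring_radius / (1.3 * cyl$height)
  turntable_rig(n_views = n_views, ring_radius = ring_radius, cyl = cyl,
                intr = intrinsics(f, f, grid[1] / 2 - 0.5, grid[2] / 2 - 0.5,
                                  grid[1], grid[2]))
}

# trace + render every view of a shape; media can differ between the
# rendering and carving sides (matched by default)
make_carve_views <- function(shape, rig, grid = c(160, 120),
                             render_media = uniform_media(),
                             carve_media = render_media) {
  lapply(rig_views(rig), function(v) {
    rf_render <- trace_view(v, rig$cylinder, render_media, grid)
    sil <- render_silhouette(shape, v, rig$cylinder, rf = rf_render)
    rf <- if (identical(unclass(render_media), unclass(carve_media)))
      rf_render else trace_view(v, rig$cylinder, carve_media, grid)
    list(view = v, silhouette = sil, rayfield = rf)
  })
}

# random world-to-camera pose looking roughly at the origin from distance d
random_pose <- function(d = 500) {
  dir <- unitize(rnorm(3))
  C <- dir * d
  z <- unitize(-dir + rnorm(3, 0, 0.05))
  x <- unitize(cross3_test(c(0, 0, 1) + rnorm(3, 0, 0.01), z))
  y <- cross3_test(z, x)
  R <- rbind(x, y, z, deparse.level = 0)
  extrinsics(R, drop(-R %*% C))
}

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unitize <- function(v) v / sqrt(sum(v^2))

rot_dist <- function(R1, R2) {
  ct <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(pmin(1, pmax(-1, ct)))
}
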