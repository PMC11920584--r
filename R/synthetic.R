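# Synthetic ground-truth scenes: analytic shapes, turntable camera rings,
# and silhouettes forward-rendered through the same optical model the
# carver uses, so every pipeline stage is testable without image data.

new_scene_shape <- function(kind, params, inside, volume, bounds,
                            ray_hit = NULL) {
  structure(list(kind = kind, params = params, inside = inside,
                 volume = volume, bounds = bounds, ray_hit = ray_hit),
            class = "scene_shape")
}

#' @export
print.scene_shape <- function(x, ...) {
  v <- x$volume
  cat(sprintf("<scene_shape> %s, volume %.3f mL (%s%s)\n", x$kind,
              v$value / 1000, v$method,
              if (is.finite(v$se) && v$se > 0)
                sprintf(", SE %.4f mL", v$se / 1000) else ""))
  invisible(x)
}

#' Axis-aligned cube test shape
#'
#' @param center 3-vector, mm.
#' @param side Side length, mm.
#' @return A `scene_shape` with analytic volume `side^3`.
#' @export
shape_cube <- function(center = c(0, 0, 76.2), side = 50) {
  stopifnot(side > 0)
  half <- side / 2
  inside <- function(pts)
    abs(pts[, 1] - center[1]) <= half &
    abs(pts[, 2] - center[2]) <= half &
    abs(pts[, 3] - center[3]) <= half
  ray_hit <- function(O, D, tmax) {
    tmin <- rep(0, nrow(O)); tmx <- tmax
    ok <- rep(TRUE, nrow(O))
    for (ax in 1:3) {
      lo <- center[ax] - half; hi <- center[ax] + half
      d <- D[, ax]; o <- O[, ax]
      par <- abs(d) < 1e-14
      t1 <- (lo - o) / d; t2 <- (hi - o) / d
      l <- pmin(t1, t2); u <- pmax(t1, t2)
      l[par] <- ifelse(o[par] >= lo & o[par] <= hi, -Inf, Inf)
      u[par] <- ifelse(o[par] >= lo & o[par] <= hi, Inf, -Inf)
      tmin <- pmax(tmin, l); tmx <- pmin(tmx, u)
    }
    ok & tmin <= tmx
  }
  new_scene_shape("cube", list(center = center, side = side), inside,
                  list(value = side^3, se = 0, method = "analytic"),
                  bounds = rbind(center - half, center + half), ray_hit)
}

#' Sphere test shape
#'
#' @param center 3-vector, mm.
#' @param radius mm.
#' @export
shape_sphere <- function(center = c(0, 0, 76.2), radius = 20) {
  stopifnot(radius > 0)
  inside <- function(pts)
    rowSums(t(t(pts) - center)^2) <= radius^2
  ray_hit <- function(O, D, tmax) {
    oc <- t(t(O) - center)
    b <- 2 * rowSums(oc * D)
    cc <- rowSums(oc^2) - radius^2
    disc <- b^2 - 4 * cc
    ok <- disc >= 0
    sq <- sqrt(pmax(0, disc))
    t1 <- (-b - sq) / 2; t2 <- (-b + sq) / 2
    ok & t2 >= 0 & t1 <= tmax
  }
  new_scene_shape("sphere", list(center = center, radius = radius), inside,
                  list(value = 4 / 3 * pi * radius^3, se = 0,
                       method = "analytic"),
                  bounds = rbind(center - radius, center + radius), ray_hit)
}

#' Vertical cylinder-segment test shape
#'
#' A finite solid cylinder with vertical axis, emulating tap-root-like
#' bodies (radish, carrot crowns).
#'
#' @param center_xy Axis position `(x, y)`, mm.
#' @param z_range `c(z_top, z_bottom)` axial extent, mm.
#' @param radius mm.
#' @export
shape_cylinder_segment <- function(center_xy = c(0, 0), z_range = c(40, 110),
                                   radius = 15) {
  stopifnot(radius > 0, z_range[2] > z_range[1])
  inside <- function(pts)
    (pts[, 1] - center_xy[1])^2 + (pts[, 2] - center_xy[2])^2 <= radius^2 &
    pts[, 3] >= z_range[1] & pts[, 3] <= z_range[2]
  ray_hit <- function(O, D, tmax) {
    # radial quadratic intersected with the z slab, clipped to [0, tmax]
    a <- D[, 1]^2 + D[, 2]^2
    ox <- O[, 1] - center_xy[1]; oy <- O[, 2] - center_xy[2]
    b <- 2 * (ox * D[, 1] + oy * D[, 2])
    cc <- ox^2 + oy^2 - radius^2
    disc <- b^2 - 4 * a * cc
    okq <- disc >= 0 & a > 1e-16
    sq <- sqrt(pmax(0, disc))
    t1 <- (-b - sq) / (2 * a); t2 <- (-b + sq) / (2 * a)
    # vertical rays: inside/outside decided by cc
    t1[a <= 1e-16] <- ifelse(cc[a <= 1e-16] <= 0, -Inf, Inf)
    t2[a <= 1e-16] <- ifelse(cc[a <= 1e-16] <= 0, Inf, -Inf)
    dz <- D[, 3]; ozr <- O[, 3]
    par <- abs(dz) < 1e-14
    z1 <- (z_range[1] - ozr) / dz; z2 <- (z_range[2] - ozr) / dz
    zl <- pmin(z1, z2); zu <- pmax(z1, z2)
    zl[par] <- ifelse(ozr[par] >= z_range[1] & ozr[par] <= z_range[2], -Inf, Inf)
    zu[par] <- ifelse(ozr[par] >= z_range[1] & ozr[par] <= z_range[2], Inf, -Inf)
    lo <- pmax(t1, zl, 0); hi <- pmin(t2, zu, tmax)
    okq & lo <= hi
  }
  vol <- pi * radius^2 * diff(z_range)
  new_scene_shape("cylinder-segment",
                  list(center_xy = center_xy, z_range = z_range,
                       radius = radius),
                  inside, list(value = vol, se = 0, method = "analytic"),
                  bounds = rbind(c(center_xy - radius, z_range[1]),
                                 c(center_xy + radius, z_range[2])),
                  ray_hit)
}

# distance-based inside test for a table of tapered capsule segments
segments_inside <- function(seg, pts) {
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(seg))) {
    a <- c(seg$x0[i], seg$y0[i], seg$z0[i])
    b <- c(seg$x1[i], seg$y1[i], seg$z1[i])
    ab <- b - a
    L2 <- sum(ab^2)
    ap <- t(t(pts) - a)
    tt <- if (L2 < 1e-12) rep(0, nrow(pts)) else
      pmin(1, pmax(0, (ap %*% ab) / L2))
    d2 <- rowSums((ap - outer(drop(tt), ab))^2)
    r <- seg$r0[i] + (seg$r1[i] - seg$r0[i]) * drop(tt)
    inside <- inside | d2 <= r^2
  }
  inside
}

#' Random branching-root test shape
#'
#' A union of tapered capsules along a random downward-growing tree,
#' standing in for 3D-printed synthetic root structures. Geometry is fully
#' determined by the seed. Ground-truth volume comes from seeded
#' Monte-Carlo integration over the bounding box (reported with its
#' standard error), except for the single untapered capsule
#' (`n_branches = 0`, `taper = 1`), which has the closed form
#' `pi r^2 L + 4/3 pi r^3`.
#'
#' @param seed Integer; fixes the branch graph and the volume Monte-Carlo.
#' @param n_branches Number of lateral branches (0 = single capsule trunk).
#' @param trunk_length,trunk_radius Trunk dimensions, mm.
#' @param taper Radius ratio tip/base along each segment (1 = no taper).
#' @param cyl Canister the shape must fit inside (with 2 mm margin);
#'   branches bending outside are reflected back toward the axis.
#' @param mc_samples Monte-Carlo samples for the volume estimate.
#' @return A `scene_shape` with a `segments` table in `params`.
#' @export
make_branching_root <- function(seed = 1L, n_branches = 5L,
                                trunk_length = 60, trunk_radius = 4,
                                taper = 0.6, cyl = cylinder(),
                                mc_samples = 2e5) {
  stopifnot(n_branches >= 0, trunk_radius > 0, trunk_length > 0,
            taper > 0, taper <= 1)
  margin <- 2
  rmax_xy <- cyl$inner_radius - margin
  seg <- with_seed(seed, {
    top <- c(0, 0, 4)
    bot <- c(0, 0, min(4 + trunk_length, cyl$height - margin))
    s <- data.frame(x0 = top[1], y0 = top[2], z0 = top[3],
                    x1 = bot[1], y1 = bot[2], z1 = bot[3],
                    r0 = trunk_radius, r1 = trunk_radius * taper)
    for (b in seq_len(n_branches)) {
      parent <- sample.int(nrow(s), 1)
      u <- runif(1, 0.2, 0.9)
      a <- c(s$x0[parent], s$y0[parent], s$z0[parent])
      bb <- c(s$x1[parent], s$y1[parent], s$z1[parent])
      start <- a + u * (bb - a)
      r_here <- (s$r0[parent] + u * (s$r1[parent] - s$r0[parent])) * 0.8
      dir <- unitize(c(rnorm(2, 0, 1), abs(rnorm(1, 1.2, 0.4))))
      len <- runif(1, 0.3, 0.6) * trunk_length
      end <- start + dir * len
      # keep inside the canister: fold back toward the axis if needed
      rr <- sqrt(end[1]^2 + end[2]^2)
      if (rr > rmax_xy) {
        end[1:2] <- end[1:2] * (2 * rmax_xy - rr) / rr
      }
      end[3] <- min(end[3], cyl$height - margin)
      s <- rbind(s, data.frame(x0 = start[1], y0 = start[2], z0 = start[3],
                               x1 = end[1], y1 = end[2], z1 = end[3],
                               r0 = r_here, r1 = r_here * taper))
    }
    s
  })
  rmax <- max(seg$r0, seg$r1)
  lo <- c(min(seg$x0, seg$x1) - rmax, min(seg$y0, seg$y1) - rmax,
          min(seg$z0, seg$z1) - rmax)
  hi <- c(max(seg$x0, seg$x1) + rmax, max(seg$y0, seg$y1) + rmax,
          max(seg$z0, seg$z1) + rmax)
  inside <- function(pts) segments_inside(seg, pts)
  if (n_branches == 0 && taper == 1) {
    L <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
    vol <- list(value = pi * trunk_radius^2 * L + 4 / 3 * pi * trunk_radius^3,
                se = 0, method = "analytic")
  } else {
    vol <- mc_volume(inside, lo, hi, n = mc_samples, seed = seed + 7919L)
  }
  new_scene_shape("branching-root",
                  list(segments = seg, seed = seed, n_branches = n_branches,
                       taper = taper),
                  inside, vol, bounds = rbind(lo, hi))
}

# Monte-Carlo volume of an inside() predicate over box [lo, hi]
mc_volume <- function(inside, lo, hi, n = 2e5, seed = 1L) {
  vbox <- prod(hi - lo)
  p <- with_seed(seed, {
    pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
                 runif(n, lo[3], hi[3]))
    mean(inside(pts))
  })
  list(value = p * vbox, se = vbox * sqrt(p * (1 - p) / n),
       method = "monte-carlo", n = n)
}

#' Monte-Carlo volume of a scene shape
#'
#' Independent volume estimate of any `scene_shape` by uniform sampling of
#' its bounding box; returns the estimate and its standard error (mm^3).
#'
#' @param shape A `scene_shape`.
#' @param n Samples.
#' @param seed RNG seed.
#' @export
shape_volume_mc <- function(shape, n = 1e6, seed = 1L) {
  mc_volume(shape$inside, shape$bounds[1, ], shape$bounds[2, ], n, seed)
}

#' Turntable camera rig
#'
#' `n_views` cameras equally spaced in angle on a horizontal ring around
#' the canister axis, all aimed at a common look-at point. The defaults
#' place the cameras at canister mid-height on an 800 mm ring with a focal
#' length that frames the full canister on an 800 x 600 grid; the long
#' working distance keeps the perspective divergence of the silhouette
#' cones (and hence the visual-hull excess) small.
#'
#' @param n_views Number of equidistant views (40 matches one full
#'   turntable revolution at 9 degree steps).
#' @param ring_radius mm from the canister axis.
#' @param camera_height Height (axial coordinate) of the ring; default
#'   canister mid-height.
#' @param look_at 3-vector; default the canister center.
#' @param intr An [intrinsics()]; default `fx = fy = 2400` px on 800 x 600
#'   (frames the canister plus the marker strip above the net-pot plane).
#' @param cyl The [cylinder()] being imaged.
#' @return Object of class `turntable_rig`.
#' @export
turntable_rig <- function(n_views = 40L, ring_radius = 800,
                          camera_height = NULL, look_at = NULL,
                          intr = NULL, cyl = cylinder()) {
  stopifnot(n_views >= 1, ring_radius > cyl$outer_radius)
  camera_height <- camera_height %||% (cyl$height / 2)
  look_at <- look_at %||% (cyl$origin + cyl$axis * cyl$height / 2)
  intr <- intr %||% intrinsics(fx = 2400, fy = 2400, cx = 399.5, cy = 299.5,
                               width = 800, height = 600)
  structure(list(n_views = as.integer(n_views), ring_radius = ring_radius,
                 camera_height = camera_height, look_at = look_at,
                 intrinsics = intr, cylinder = cyl),
            class = "turntable_rig")
}

#' Camera views of a turntable rig
#'
#' Builds the [camera_view()] for each ring position. The camera "up" in
#' image coordinates is aligned with the canister axis, so image rows run
#' along the axis (v increases toward the canister bottom).
#'
#' @param rig A [turntable_rig()].
#' @return List of `camera_view` objects.
#' @export
rig_views <- function(rig) {
  cyl <- rig$cylinder
  B <- cyl_basis(cyl)  # rows are the canonical axes in world coords
  ex <- B[1, ]; ey <- B[2, ]; ez <- B[3, ]
  lapply(seq_len(rig$n_views), function(i) {
    th <- 2 * pi * (i - 1) / rig$n_views
    C <- cyl$origin + rig$ring_radius * (cos(th) * ex + sin(th) * ey) +
      rig$camera_height * ez
    z <- unitize(rig$look_at - C)
    xax <- unitize(cross3(ez, z))
    yax <- cross3(z, xax)
    R <- rbind(xax, yax, z, deparse.level = 0)
    camera_view(rig$intrinsics, extrinsics(R, drop(-R %*% C)),
                image_id = sprintf("view_%03d", i))
  })
}

#' Forward-render a silhouette of a shape through the canister optics
#'
#' Traces the (optionally refracted) per-pixel rays of a view and marks a
#' pixel foreground iff the ray's in-water segment intersects the shape.
#' With `supersample > 1` an `s x s` sub-pixel grid is traced and a pixel is
#' foreground if any sub-ray hits; the default single center ray makes the
#' rendered silhouette exactly consistent with the ray set the carver uses,
#' which is what gives the carved hull its guaranteed-superset property.
#'
#' @param shape A `scene_shape`.
#' @param view A [camera_view()].
#' @param cyl A [cylinder()].
#' @param media An [optical_media()]; pass [uniform_media()] to disable
#'   refraction.
#' @param grid_resolution `c(width, height)` of the ray/silhouette grid.
#' @param supersample Sub-pixel sampling factor (1 = pixel centers only).
#' @param rf Optionally a precomputed [trace_view()] result for this view
#'   (ignores `grid_resolution`/`media`).
#' @param step_frac For shapes without an analytic ray intersection
#'   (branching roots), sampling step along the ray as a fraction of the
#'   smallest branch radius.
#' @return A `silhouette` object at the grid resolution.
#' @export
render_silhouette <- function(shape, view, cyl = cylinder(),
                              media = optical_media(),
                              grid_resolution = c(800, 600),
                              supersample = 1L, rf = NULL,
                              step_frac = 1 / 3) {
  if (is.null(rf)) rf <- trace_view(view, cyl, media, grid_resolution)
  hit <- ray_hits_shape(shape, rf, step_frac)
  if (supersample > 1) {
    s <- as.integer(supersample)
    # jitter the principal point to shift the whole ray grid sub-pixel
    for (ij in seq_len(s * s)) {
      du <- ((ij - 1) %% s + 0.5) / s - 0.5
      dv <- ((ij - 1) %/% s + 0.5) / s - 0.5
      v2 <- view
      v2$intrinsics$cx <- view$intrinsics$cx - du
      v2$intrinsics$cy <- view$intrinsics$cy - dv
      rf2 <- trace_view(v2, cyl, rf$media, c(rf$width, rf$height))
      hit <- hit | ray_hits_shape(shape, rf2, step_frac)
    }
  }
  mask <- matrix(hit, rf$height, rf$width)
  structure(list(mask = mask, provenance = list(
    kind = "synthetic", shape = shape$kind,
    refraction = !identical(unclass(rf$media), unclass(uniform_media())),
    supersample = supersample)),
    class = "silhouette")
}

# does each valid ray's in-water segment intersect the shape?
ray_hits_shape <- function(shape, rf, step_frac = 1 / 3) {
  n <- rf$width * rf$height
  hit <- rep(FALSE, n)
  v <- rf$valid
  if (!any(v)) return(hit)
  O <- rf$origin[v, , drop = FALSE]
  D <- rf$dir[v, , drop = FALSE]
  tmx <- rf$t_max[v]
  if (!is.null(shape$ray_hit)) {
    hit[v] <- shape$ray_hit(O, D, tmx)
    return(hit)
  }
  # dense sampling along the segment for implicit shapes
  seg <- shape$params$segments
  rmin <- if (!is.null(seg)) min(seg$r0, seg$r1) else 1
  step <- max(rmin * step_frac, 0.05)
  # restrict to rays passing near the shape's bounding sphere
  bc <- colMeans(shape$bounds)
  br <- sqrt(sum((shape$bounds[2, ] - bc)^2))
  oc <- t(t(O) - bc)
  tproj <- -rowSums(oc * D)
  d2 <- rowSums(oc^2) - tproj^2
  near <- d2 <= br^2 & tproj + br > 0 & tproj - br < tmx
  idx <- which(near)
  hv <- rep(FALSE, nrow(O))
  if (length(idx)) {
    chunk <- 20000L
    for (start in seq(1, length(idx), by = chunk)) {
      ii <- idx[start:min(start + chunk - 1L, length(idx))]
      lo <- pmax(0, tproj[ii] - br)
      hi <- pmin(tmx[ii], tproj[ii] + br)
      nstep <- ceiling(max(hi - lo) / step)
      found <- rep(FALSE, length(ii))
      for (k in 0:nstep) {
        tt <- lo + (hi - lo) * k / max(nstep, 1)
        pts <- O[ii, , drop = FALSE] + D[ii, , drop = FALSE] * tt
        found <- found | shape$inside(pts)
      }
      hv[ii] <- found
    }
  }
  hit[v] <- hv
  hit
}

#' Marker strip layout around the net pot
#'
#' A two-row grid of fiducial markers wrapped around the net-pot perimeter:
#' `n_columns` equally spaced angular positions times two rows just above
#' the net-pot plane.
#'
#' @param n_columns Angular positions (total markers = `2 * n_columns`).
#' @param pot_radius Net-pot radius, mm.
#' @param marker_size Printed marker side, mm (metadata).
#' @param row_z Axial coordinates of the two rows (negative = above the
#'   net-pot plane, outside the liquid).
#' @return Data frame `id, x_mm, y_mm, z_mm` with a `layout` attribute.
#' @export
make_marker_grid <- function(n_columns = 12L, pot_radius = 38,
                             marker_size = 8, row_z = c(-16, -6)) {
  stopifnot(n_columns >= 2, length(row_z) == 2)
  th <- 2 * pi * (seq_len(n_columns) - 1) / n_columns
  df <- data.frame(
    id = seq_len(2L * n_columns),
    x_mm = rep(pot_radius * cos(th), 2),
    y_mm = rep(pot_radius * sin(th), 2),
    z_mm = rep(row_z, each = n_columns))
  attr(df, "layout") <- list(rows = 2L, columns = as.integer(n_columns),
                             marker_size = marker_size,
                             pot_radius = pot_radius)
  df
}

#' Simulated marker detections for every rig view
#'
#' Projects the marker centers into each camera, drops markers on the far
#' side of the pot (outward radial facing away from the camera) or behind
#' the camera, and optionally adds Gaussian pixel noise.
#'
#' @param rig A [turntable_rig()].
#' @param grid A [make_marker_grid()] layout.
#' @param noise_px Gaussian noise SD in pixels (0 = exact projections).
#' @param seed RNG seed for the noise.
#' @return List (one per view) of correspondence data frames with columns
#'   `id, x_mm, y_mm, z_mm, u_px, v_px`.
#' @export
make_marker_detections <- function(rig, grid, noise_px = 0, seed = 1L) {
  views <- rig_views(rig)
  X <- as.matrix(grid[, c("x_mm", "y_mm", "z_mm")])
  radial <- cbind(grid$x_mm, grid$y_mm, 0)
  radial <- radial / pmax(sqrt(rowSums(radial^2)), 1e-9)
  out <- with_seed(seed, lapply(views, function(v) {
    C <- camera_center(v$extrinsics)
    to_cam <- t(C - t(X))
    facing <- rowSums(radial * to_cam) > 0
    uv <- project_point(v, X)
    vis <- facing & !attr(uv, "behind") &
      uv[, 1] >= 0 & uv[, 1] < v$intrinsics$width &
      uv[, 2] >= 0 & uv[, 2] < v$intrinsics$height
    uv <- uv[vis, , drop = FALSE]
    if (noise_px > 0) uv <- uv + matrix(rnorm(length(uv), 0, noise_px),
                                        ncol = 2)
    data.frame(id = grid$id[vis], x_mm = X[vis, 1], y_mm = X[vis, 2],
               z_mm = X[vis, 3], u_px = uv[, 1], v_px = uv[, 2])
  }))
  names(out) <- vapply(views, function(v) v$image_id, "")
  out
}

#' Generate a complete synthetic scene on disk
#'
#' Renders silhouettes of a shape from every rig view (written as 1-bit
#' PNGs), exports the exact camera poses as JSON, and records the
#' ground-truth volume (with Monte-Carlo SE where not analytic) plus the
#' full scene configuration.
#'
#' @param shape A `scene_shape`.
#' @param rig A [turntable_rig()].
#' @param media An [optical_media()].
#' @param dir Output directory (created).
#' @param grid_resolution Ray/silhouette grid.
#' @param supersample Sub-pixel rendering factor.
#' @return Invisibly, the ground-truth record list (also written to
#'   `ground_truth.json`).
#' @export
simulate_scene <- function(shape, rig = turntable_rig(),
                           media = optical_media(), dir,
                           grid_resolution = c(800, 600), supersample = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  views <- rig_views(rig)
  for (i in seq_along(views)) {
    sil <- render_silhouette(shape, views[[i]], rig$cylinder, media,
                             grid_resolution, supersample)
    write_silhouette(sil, file.path(dir, sprintf("%s.png", views[[i]]$image_id)))
  }
  write_poses(views, file.path(dir, "poses.json"))
  truth <- list(shape = shape$kind, params = shape$params[
                  setdiff(names(shape$params), "segments")],
                volume_mm3 = shape$volume$value,
                volume_ml = shape$volume$value / 1000,
                volume_se_mm3 = shape$volume$se,
                volume_method = shape$volume$method,
                media = unclass(media),
                cylinder = unclass(rig$cylinder)[c("inner_radius",
                                                   "outer_radius", "height")],
                n_views = rig$n_views, grid = grid_resolution)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
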