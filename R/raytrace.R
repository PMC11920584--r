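#' Cylindrical canister geometry
#'
#' Describes the transparent acrylic growth canister: a hollow cylinder with
#' an outer wall (air/acrylic interface) and an inner wall (acrylic/water
#' interface). The default geometry is a 6-in diameter by 6-in tall canister
#' (outer radius 76.2 mm, height 152.4 mm) with 1/8-in stock acrylic walls.
#'
#' The axis origin sits at the net-pot plane and the axis direction points
#' down into the nutrient solution; axial coordinates inside the canister
#' run from 0 (top) to `height` (bottom).
#'
#' @param outer_radius Outer wall radius, mm.
#' @param wall Wall thickness, mm; `inner_radius = outer_radius - wall`.
#' @param height Canister height, mm.
#' @param origin 3-vector, axis origin (net-pot plane), mm.
#' @param axis Unit 3-vector, axis direction (into the liquid).
#' @return An object of class `canister_cylinder`.
#' @examples
#' cyl <- cylinder()
#' cyl$inner_radius
#' @export
cylinder <- function(outer_radius = 76.2, wall = 3.175, height = 152.4,
                     origin = c(0, 0, 0), axis = c(0, 0, 1)) {
  axis <- unitize(as.numeric(axis))
  stopifnot(outer_radius > 0, wall > 0, wall < outer_radius, height > 0,
            length(origin) == 3)
  structure(list(origin = as.numeric(origin), axis = axis,
                 inner_radius = outer_radius - wall,
                 outer_radius = outer_radius, height = height),
            class = "canister_cylinder")
}

#' Refractive indices of the imaging path
#'
#' Indices for the three media a camera ray crosses: air outside the
#' canister, the acrylic wall, and the nutrient solution (water with
#' dissolved nutrients).
#'
#' @param n_air,n_acrylic,n_water Dimensionless refractive indices, all >= 1.
#' @return An object of class `optical_media`.
#' @export
optical_media <- function(n_air = 1.00, n_acrylic = 1.49, n_water = 1.33) {
  stopifnot(n_air >= 1, n_acrylic >= 1, n_water >= 1)
  structure(list(n_air = n_air, n_acrylic = n_acrylic, n_water = n_water),
            class = "optical_media")
}

#' Uniform media (refraction disabled)
#'
#' All three indices equal, so rays pass through the canister walls without
#' bending. Useful for validating the carver against textbook straight-ray
#' shape-from-silhouette.
#' @export
uniform_media <- function() optical_media(1, 1, 1)

# rotation mapping cylinder axis onto +z (canonical frame)
cyl_basis <- function(cyl) {
  a <- cyl$axis
  if (abs(a[3]) > 0.999999) {
    if (a[3] > 0) return(diag(3))
    return(diag(c(1, -1, -1)))
  }
  z <- a
  x <- unitize(cross3(c(0, 0, 1), z))
  y <- cross3(z, x)
  rbind(x, y, z, deparse.level = 0)
}

#' Snell's-law refraction of a direction vector
#'
#' Vector form of Snell's law at a planar interface element: for incident
#' unit direction `d`, unit surface normal `n` oriented against the ray
#' (`d . n < 0`), and indices `n1` (incident side) and `n2` (transmitted
#' side), the transmitted direction is
#' `t = (n1/n2) d + ((n1/n2) cos(theta_i) - cos(theta_t)) n`.
#' The sines of the incident and refracted angles satisfy
#' `n1 sin(theta1) = n2 sin(theta2)` to machine precision.
#'
#' @param incident Unit 3-vector, incident direction.
#' @param normal Unit 3-vector, surface normal with `incident . normal < 0`.
#' @param n1,n2 Refractive indices of the incident and transmitted media.
#' @return Unit 3-vector of the refracted direction, or `NULL` under total
#'   internal reflection (only possible when `n1 > n2`).
#' @examples
#' # 45 degrees air -> water bends toward the normal (about 32.1 degrees)
#' d <- c(sin(pi / 4), 0, -cos(pi / 4))
#' refract_direction(d, c(0, 0, 1), 1.0, 1.33)
#' @export
refract_direction <- function(incident, normal, n1, n2) {
  stopifnot(abs(sum(incident^2) - 1) < 1e-9, abs(sum(normal^2) - 1) < 1e-9)
  ci <- -sum(incident * normal)
  if (ci <= 0) stop_rootcarve(
    "normal must be oriented against the incident ray (incident . normal < 0)",
    "rootcarve_bad_normal")
  r <- n1 / n2
  s2 <- r^2 * (1 - ci^2)  # sin^2(theta_t)
  if (s2 > 1) return(NULL)  # total internal reflection
  ct <- sqrt(1 - s2)
  unitize(r * incident + (r * ci - ct) * normal)
}

# vectorized refraction: D, N are n x 3 (unit rows), N oriented against D.
# returns list(dir = n x 3, tir = logical n)
refract_rows <- function(D, N, n1, n2) {
  ci <- -rowSums(D * N)
  r <- n1 / n2
  s2 <- r^2 * (1 - ci^2)
  # flag both total internal reflection and wrong-sided hits (a ray that
  # reaches the far wall from inside after passing over an end cap)
  tir <- s2 > 1 | ci <= 0 | is.na(ci)
  ct <- sqrt(pmax(0, 1 - s2))
  out <- r * D + (r * ci - ct) * N
  out <- unitize_rows(out)
  out[tir, ] <- NA_real_
  list(dir = out, tir = tir)
}

#' Ray / cylinder-wall intersection
#'
#' Nearest forward intersection of a ray with the inner or outer wall of the
#' canister, restricted to axial coordinates in `[0, height]` (rays that
#' would only cross the wall beyond the end caps miss).
#'
#' @param origin Ray origin, 3-vector mm.
#' @param direction Unit 3-vector.
#' @param cyl A [cylinder()].
#' @param radius `"inner"` or `"outer"` wall.
#' @return `NULL` on a miss, otherwise a list with `point` (3-vector),
#'   `normal` (outward radial unit 3-vector at the hit) and `t` (distance).
#' @export
intersect_cylinder <- function(origin, direction, cyl,
                               radius = c("outer", "inner")) {
  radius <- match.arg(radius)
  r <- if (radius == "inner") cyl$inner_radius else cyl$outer_radius
  hit <- cyl_intersect_rows(matrix(origin, 1), matrix(direction, 1), cyl, r,
                            root = "nearest")
  if (!hit$ok[1]) return(NULL)
  list(point = drop(hit$point), normal = drop(hit$normal), t = hit$t[1])
}

# vectorized ray/cylinder intersection in the cylinder frame.
# O, D: n x 3; r radius; root: "nearest" = smallest positive t with axial
# range valid (trying the far root if the near one is out of range),
# "second" = larger positive root (exit, for rays starting inside).
# Returns list(ok, t, point, normal) in *world* coordinates.
cyl_intersect_rows <- function(O, D, cyl, r, root = c("nearest", "second"),
                               eps = 1e-9) {
  root <- match.arg(root)
  B <- cyl_basis(cyl)
  Oc <- t(B %*% (t(O) - cyl$origin))
  Dc <- t(B %*% t(D))
  a <- Dc[, 1]^2 + Dc[, 2]^2
  b <- 2 * (Oc[, 1] * Dc[, 1] + Oc[, 2] * Dc[, 2])
  cc <- Oc[, 1]^2 + Oc[, 2]^2 - r^2
  disc <- b^2 - 4 * a * cc
  ok <- disc >= 0 & a > eps^2
  sq <- sqrt(pmax(0, disc))
  t1 <- (-b - sq) / (2 * a)
  t2 <- (-b + sq) / (2 * a)
  zr <- function(tt) Oc[, 3] + tt * Dc[, 3]
  inrange <- function(tt) tt > eps & zr(tt) >= 0 & zr(tt) <= cyl$height
  tt <- if (root == "second") {
    ifelse(inrange(t2), t2, NA_real_)
  } else {
    ifelse(inrange(t1), t1, ifelse(inrange(t2), t2, NA_real_))
  }
  ok <- ok & !is.na(tt)
  tt[!ok] <- NA_real_
  Pc <- Oc + Dc * tt
  Nc <- cbind(Pc[, 1] / r, Pc[, 2] / r, 0)
  P <- t(crossprod(B, t(Pc)) + cyl$origin)
  N <- t(crossprod(B, t(Nc)))
  list(ok = ok, t = tt, point = P, normal = N)
}

# pinhole ray directions (world, unit rows) for an intrinsics/pose on a
# w x h pixel grid; rays pass through 0-based pixel centers.
# Returns list(center = camera center, dirs = (w*h) x 3 in column-major
# (row index fastest) order matching an h x w R matrix.
pinhole_rays <- function(view, width, height) {
  K <- intrinsics_matrix(view$intrinsics)
  # scale intrinsics if the ray grid differs from the calibrated image size
  sx <- width / view$intrinsics$width
  sy <- height / view$intrinsics$height
  fx <- K[1, 1] * sx; fy <- K[2, 2] * sy
  cx <- K[1, 3] * sx; cy <- K[2, 3] * sy
  u <- rep(0:(width - 1), each = height)
  v <- rep(0:(height - 1), times = width)
  dc <- cbind((u - cx) / fx, (v - cy) / fy, 1)
  Dw <- t(crossprod(view$extrinsics$R, t(dc)))
  list(center = camera_center(view$extrinsics), dirs = unitize_rows(Dw))
}

#' Trace refracted viewing rays through the canister walls
#'
#' Casts one ray per pixel of a `grid_resolution` grid from the camera
#' center, refracts it at the outer wall (air to acrylic) and the inner wall
#' (acrylic to water), and records the resulting in-water ray: its origin on
#' the inner wall, its unit direction, and the distance `t_max` at which it
#' leaves the water volume again. The default 800 x 600 grid casts exactly
#' 480,000 primary rays.
#'
#' Rays that miss either wall, exit through the end caps, or undergo total
#' internal reflection are flagged invalid and never contribute carving
#' evidence.
#'
#' @param view A [camera_view()]; its camera center must lie outside the
#'   outer wall.
#' @param cyl A [cylinder()].
#' @param media An [optical_media()]; with all indices equal the traced rays
#'   are exactly the straight pinhole rays clipped to the canister interior.
#' @param grid_resolution `c(width, height)` of the ray grid; silhouettes at
#'   other resolutions are resampled to this grid by nearest neighbor.
#' @return An object of class `rayfield`: list with `width`, `height`,
#'   `origin` and `dir` ((w*h) x 3 matrices, column-major over the h x w
#'   pixel grid), `t_max`, logical `valid`, and the generating geometry.
#' @seealso [as_ray_tensor()] for the dense 3 x width x height layout,
#'   [pixel_visibility_mask()], [carve()].
#' @export
trace_view <- function(view, cyl = cylinder(), media = optical_media(),
                       grid_resolution = c(800, 600)) {
  stopifnot(length(grid_resolution) == 2, all(grid_resolution >= 1))
  w <- as.integer(grid_resolution[1]); h <- as.integer(grid_resolution[2])
  pr <- pinhole_rays(view, w, h)
  C <- pr$center
  B <- cyl_basis(cyl)
  Cc <- drop(B %*% (C - cyl$origin))
  if (Cc[1]^2 + Cc[2]^2 <= cyl$outer_radius^2)
    stop_rootcarve("camera center lies inside the outer canister wall",
                   "rootcarve_invalid_geometry")
  n <- w * h
  O0 <- matrix(C, n, 3, byrow = TRUE)
  # outer wall: air -> acrylic
  h1 <- cyl_intersect_rows(O0, pr$dirs, cyl, cyl$outer_radius)
  valid <- h1$ok
  rf1 <- refract_rows(pr$dirs, h1$normal, media$n_air, media$n_acrylic)
  valid <- valid & !rf1$tir
  # inner wall: acrylic -> water
  h2 <- cyl_intersect_rows(h1$point, rf1$dir, cyl, cyl$inner_radius)
  valid <- valid & h2$ok
  rf2 <- refract_rows(rf1$dir, h2$normal, media$n_acrylic, media$n_water)
  valid <- valid & !rf2$tir
  # in-water segment: exit through the far inner wall or an end-cap plane
  ex <- cyl_intersect_rows(h2$point, rf2$dir, cyl, cyl$inner_radius,
                           root = "second")
  Oc <- t(B %*% (t(h2$point) - cyl$origin))
  Dc <- t(B %*% t(rf2$dir))
  tz <- ifelse(abs(Dc[, 3]) > 1e-12,
               pmax((0 - Oc[, 3]) / Dc[, 3], (cyl$height - Oc[, 3]) / Dc[, 3]),
               Inf)
  t_max <- pmin(ifelse(ex$ok, ex$t, Inf), tz)
  valid <- valid & is.finite(t_max) & t_max > 0
  origin <- h2$point; dir <- rf2$dir
  origin[!valid, ] <- NA_real_; dir[!valid, ] <- NA_real_
  t_max[!valid] <- NA_real_
  structure(list(width = w, height = h, origin = origin, dir = dir,
                 t_max = t_max, valid = valid, cylinder = cyl, media = media,
                 camera = C, image_id = view$image_id %||% NA_character_),
            class = "rayfield")
}

#' @export
print.rayfield <- function(x, ...) {
  cat(sprintf("<rayfield> %d x %d grid, %d rays (%d valid, %.1f%%)\n",
              x$width, x$height, x$width * x$height, sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Dense ray-tensor layout
#'
#' Returns the refracted ray directions (or inner-wall origins) as a dense
#' `3 x width x height` array, the canonical layout for a traced view.
#'
#' @param rf A [trace_view()] result.
#' @param what `"dir"` or `"origin"`.
#' @export
as_ray_tensor <- function(rf, what = c("dir", "origin")) {
  what <- match.arg(what)
  m <- rf[[what]]
  a <- array(NA_real_, c(3L, rf$width, rf$height))
  for (k in 1:3) a[k, , ] <- t(matrix(m[, k], rf$height, rf$width))
  a
}

#' Per-pixel voxel visibility mask
#'
#' For an axis-aligned cubic voxel, marks the ray-grid pixels whose refracted
#' in-water segment intersects the voxel (slab test against the segment
#' `[0, t_max]`).
#'
#' @param voxel_center 3-vector, mm.
#' @param voxel_half_size Half the cube side, mm.
#' @param rf A [trace_view()] result.
#' @return `height x width` logical matrix. If the voxel lies entirely
#'   outside the water volume the mask is empty with attribute
#'   `out_of_volume = TRUE`.
#' @export
pixel_visibility_mask <- function(voxel_center, voxel_half_size, rf) {
  cyl <- rf$cylinder
  B <- cyl_basis(cyl)
  cc <- drop(B %*% (voxel_center - cyl$origin))
  rad <- sqrt(cc[1]^2 + cc[2]^2)
  half_diag <- voxel_half_size * sqrt(3)
  out <- (rad - half_diag > cyl$inner_radius) ||
    (cc[3] + half_diag < 0) || (cc[3] - half_diag > cyl$height)
  mask <- matrix(FALSE, rf$height, rf$width)
  if (out) {
    attr(mask, "out_of_volume") <- TRUE
    return(mask)
  }
  v <- rf$valid
  if (!any(v)) return(mask)
  O <- rf$origin[v, , drop = FALSE]
  D <- rf$dir[v, , drop = FALSE]
  tmx <- rf$t_max[v]
  tmin <- rep(0, nrow(O)); tmax <- tmx
  for (ax in 1:3) {
    lo <- voxel_center[ax] - voxel_half_size
    hi <- voxel_center[ax] + voxel_half_size
    d <- D[, ax]; o <- O[, ax]
    par <- abs(d) < 1e-14
    t1 <- (lo - o) / d; t2 <- (hi - o) / d
    l <- pmin(t1, t2); u <- pmax(t1, t2)
    l[par] <- ifelse(o[par] >= lo & o[par] <= hi, -Inf, Inf)
    u[par] <- ifelse(o[par] >= lo & o[par] <= hi, Inf, -Inf)
    tmin <- pmax(tmin, l); tmax <- pmin(tmax, u)
  }
  mask[v] <- tmin <= tmax
  mask
}

#' Fraction of a voxel's covering rays that land in the silhouette
#'
#' The bitwise-AND evidence measure of the carver: among the ray-grid pixels
#' whose refracted ray intersects a voxel, the proportion whose silhouette
#' pixel is foreground. Returns 0 for an empty mask.
#'
#' @param mask Logical matrix from [pixel_visibility_mask()].
#' @param silhouette Logical matrix of the same dimensions (or a
#'   `silhouette` object).
#' @export
visible_fraction <- function(mask, silhouette) {
  sil <- silhouette_mask(silhouette)
  stopifnot(all(dim(mask) == dim(sil)))
  n <- sum(mask)
  if (n == 0) return(0)
  sum(mask & sil) / n
}

#' Serialize a traced ray field to a binary cache file
#'
#' Layout: ASCII magic `"RAYF1\n"`, then two little-endian int32 (width,
#' height), then three dense float64 blocks of length `3*width*height`
#' (origins, directions, both column-major over the pixel grid with NA for
#' invalid rays), one float64 block of `t_max`, and `width*height` validity
#' bytes. Geometry metadata travels in a trailing JSON line.
#'
#' @param rf A [trace_view()] result.
#' @param path Output file.
#' @export
write_rayfield <- function(rf, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RAYF1\n", con, eos = NULL)
  writeBin(as.integer(c(rf$width, rf$height)), con, size = 4L, endian = "little")
  writeBin(as.numeric(rf$origin), con, size = 8L, endian = "little")
  writeBin(as.numeric(rf$dir), con, size = 8L, endian = "little")
  writeBin(as.numeric(rf$t_max), con, size = 8L, endian = "little")
  writeBin(as.raw(rf$valid), con)
  meta <- jsonlite::toJSON(list(cylinder = unclass(rf$cylinder),
                                media = unclass(rf$media), camera = rf$camera,
                                image_id = rf$image_id), auto_unbox = TRUE,
                           digits = NA)
  writeChar(paste0(as.character(meta), "\n"), con, eos = NULL)
  invisible(path)
}

#' @rdname write_rayfield
#' @export
read_rayfield <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 6L)
  if (!identical(magic, "RAYF1\n"))
    stop_rootcarve("not a rayfield cache file", "rootcarve_bad_cache")
  wh <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  n <- wh[1] * wh[2]
  origin <- matrix(readBin(con, "numeric", 3 * n, size = 8L, endian = "little"), n, 3)
  dir <- matrix(readBin(con, "numeric", 3 * n, size = 8L, endian = "little"), n, 3)
  t_max <- readBin(con, "numeric", n, size = 8L, endian = "little")
  valid <- as.logical(readBin(con, "raw", n))
  meta <- jsonlite::fromJSON(readLines(con, 1L))
  cyl <- cylinder(outer_radius = meta$cylinder$outer_radius,
                  wall = meta$cylinder$outer_radius - meta$cylinder$inner_radius,
                  height = meta$cylinder$height,
                  origin = meta$cylinder$origin, axis = meta$cylinder$axis)
  structure(list(width = wh[1], height = wh[2], origin = origin, dir = dir,
                 t_max = t_max, valid = valid, cylinder = cyl,
                 media = do.call(optical_media, meta$media),
                 camera = meta$camera, image_id = meta$image_id),
            class = "rayfield")
}
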