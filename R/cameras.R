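#' Camera intrinsics
#'
#' Pinhole intrinsics in pixel units. The 3x3 intrinsic matrix built from
#' these fields is upper triangular with positive diagonal.
#'
#' @param fx,fy Focal lengths, pixels (> 0).
#' @param cx,cy Principal point, pixels, inside the image bounds.
#' @param width,height Image size, pixels.
#' @param dist Optional radial distortion coefficients `(k1, k2)`; empty for
#'   a distortion-free model.
#' @return Object of class `intrinsics`.
#' @export
intrinsics <- function(fx, fy, cx, cy, width, height, dist = numeric(0)) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0,
            cx >= 0, cx < width, cy >= 0, cy < height,
            length(dist) %in% c(0L, 1L, 2L))
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height),
                 dist = as.numeric(dist)),
            class = "intrinsics")
}

#' @rdname intrinsics
#' @param x An `intrinsics` object.
#' @export
intrinsics_matrix <- function(x) {
  matrix(c(x$fx, 0, 0, 0, x$fy, 0, x$cx, x$cy, 1), 3, 3)
}

#' Camera extrinsics (world-to-camera rigid transform)
#'
#' @param R 3x3 orthonormal rotation, determinant +1, world to camera.
#' @param t 3-vector translation, mm; `x_cam = R x_world + t`.
#' @return Object of class `extrinsics`.
#' @export
extrinsics <- function(R, t) {
  if (!is_rotation_matrix(R))
    stop_rootcarve("R must be orthonormal with determinant +1",
                   "rootcarve_bad_rotation")
  stopifnot(length(t) == 3, all(is.finite(t)))
  structure(list(R = R, t = as.numeric(t)), class = "extrinsics")
}

#' @rdname extrinsics
#' @param x An `extrinsics` object.
#' @return `camera_center`: the camera center `-R't` in world mm.
#' @export
camera_center <- function(x) drop(-crossprod(x$R, x$t))

#' A calibrated, posed camera
#'
#' Bundles intrinsics, extrinsics, the 3x4 projection matrix
#' `P = K [R | t]`, and a source-image identifier.
#'
#' @param intrinsics An [intrinsics()].
#' @param extrinsics An [extrinsics()].
#' @param image_id Optional identifier of the source image.
#' @export
camera_view <- function(intrinsics, extrinsics, image_id = NA_character_) {
  structure(list(intrinsics = intrinsics, extrinsics = extrinsics,
                 P = projection_matrix(intrinsics, extrinsics),
                 image_id = image_id),
            class = "camera_view")
}

#' 3x4 projection matrix
#'
#' `P = K [R | t]`: the 3x3 intrinsic matrix padded to 3x4 times the 4x4
#' rigid extrinsic transform. Projecting a homogeneous world point through
#' `P` and perspective-dividing yields pixel coordinates; the camera center
#' maps to the degenerate zero homogeneous point.
#'
#' @param intr An [intrinsics()].
#' @param extr An [extrinsics()].
#' @export
projection_matrix <- function(intr, extr) {
  intrinsics_matrix(intr) %*% cbind(extr$R, extr$t)
}

# apply radial distortion to normalized camera coords (n x 2)
apply_distortion <- function(xn, dist) {
  if (length(dist) == 0) return(xn)
  k1 <- dist[1]; k2 <- if (length(dist) > 1) dist[2] else 0
  r2 <- rowSums(xn^2)
  xn * (1 + k1 * r2 + k2 * r2^2)
}

#' Project world points to pixels
#'
#' Perspective projection through a [camera_view()], applying radial
#' distortion when the intrinsics carry coefficients. Points at or behind
#' the camera plane are flagged.
#'
#' @param view A [camera_view()].
#' @param world_point A 3-vector or an n x 3 matrix, mm.
#' @return An n x 2 matrix of `(u, v)` pixels with a logical attribute
#'   `behind` marking points with non-positive camera depth (their pixel
#'   rows are `NA`). Projecting the camera center itself is an error.
#' @export
project_point <- function(view, world_point) {
  X <- if (is.matrix(world_point)) world_point else matrix(world_point, 1)
  stopifnot(ncol(X) == 3)
  Xc <- t(view$extrinsics$R %*% t(X)) +
    matrix(view$extrinsics$t, nrow(X), 3, byrow = TRUE)
  r <- sqrt(rowSums(Xc^2))
  if (any(r < 1e-9))
    stop_rootcarve("cannot project the camera center (undefined projection)",
                   "rootcarve_undefined_projection")
  behind <- Xc[, 3] <= 0
  xn <- cbind(Xc[, 1] / Xc[, 3], Xc[, 2] / Xc[, 3])
  xn <- apply_distortion(xn, view$intrinsics$dist)
  uv <- cbind(view$intrinsics$fx * xn[, 1] + view$intrinsics$cx,
              view$intrinsics$fy * xn[, 2] + view$intrinsics$cy)
  uv[behind, ] <- NA_real_
  attr(uv, "behind") <- behind
  uv
}

# --- PnP pose estimation -------------------------------------------------

# DLT initialization from >= 6 correspondences, normalized image coords
pnp_dlt <- function(X, xn) {
  n <- nrow(X)
  A <- matrix(0, 2 * n, 12)
  Xh <- cbind(X, 1)
  A[seq(1, 2 * n, 2), 1:4] <- Xh
  A[seq(1, 2 * n, 2), 9:12] <- -xn[, 1] * Xh
  A[seq(2, 2 * n, 2), 5:8] <- Xh
  A[seq(2, 2 * n, 2), 9:12] <- -xn[, 2] * Xh
  p <- svd(A, nu = 0)$v[, 12]
  M <- matrix(p, 3, 4, byrow = TRUE)
  # fix sign so depths are positive for the majority of points
  depths <- Xh %*% M[3, ]
  if (sum(depths < 0) > n / 2) M <- -M
  sv <- svd(M[, 1:3])
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    sv$u[, 3] <- -sv$u[, 3]
    R <- sv$u %*% t(sv$v)
  }
  scale <- mean(sv$d)
  list(R = R, t = drop(M[, 4] / scale))
}

pnp_residuals <- function(par, R0, X, uv, intr) {
  R <- R0 %*% rot_from_axis_angle(par[1:3])
  t <- par[4:6]
  Xc <- t(R %*% t(X)) + matrix(t, nrow(X), 3, byrow = TRUE)
  xn <- cbind(Xc[, 1] / Xc[, 3], Xc[, 2] / Xc[, 3])
  xn <- apply_distortion(xn, intr$dist)
  uvp <- cbind(intr$fx * xn[, 1] + intr$cx, intr$fy * xn[, 2] + intr$cy)
  as.numeric(uvp - uv)
}

# damped Gauss-Newton with numeric Jacobian on (axis-angle, t)
pnp_refine <- function(R0, t0, X, uv, intr, iters = 60) {
  par <- c(0, 0, 0, t0)
  res <- pnp_residuals(par, R0, X, uv, intr)
  cost <- sum(res^2)
  lambda <- 1e-3
  for (it in seq_len(iters)) {
    J <- matrix(0, length(res), 6)
    hstep <- 1e-6 * pmax(1, abs(par))
    for (j in 1:6) {
      pp <- par; pp[j] <- pp[j] + hstep[j]
      pm <- par; pm[j] <- pm[j] - hstep[j]
      J[, j] <- (pnp_residuals(pp, R0, X, uv, intr) -
                   pnp_residuals(pm, R0, X, uv, intr)) / (2 * hstep[j])
    }
    g <- crossprod(J, res)
    H <- crossprod(J)
    improved <- FALSE
    for (k in 1:10) {
      step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- par - drop(step)
      rc <- pnp_residuals(cand, R0, X, uv, intr)
      if (sum(rc^2) < cost) {
        par <- cand; res <- rc; cost <- sum(rc^2)
        lambda <- max(lambda / 4, 1e-10)
        improved <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved || sqrt(sum(g^2)) < 1e-12) break
  }
  list(R = R0 %*% rot_from_axis_angle(par[1:3]), t = par[4:6],
       rms = sqrt(cost / (length(res) / 2)))
}

#' Estimate camera pose from 3D-2D marker correspondences (PnP)
#'
#' Perspective-n-Point pose estimation: given at least four fiducial-marker
#' centers with known world positions and their detected pixel centers,
#' recovers the world-to-camera rigid transform minimizing total squared
#' reprojection error. A direct linear transform provides the initial pose
#' (six or more points); an iterative damped Gauss-Newton refinement on the
#' rotation (axis-angle) and translation then minimizes the pixel residuals.
#' With four or five points the initialization falls back to a multi-start
#' search over viewing directions.
#'
#' @param correspondences A list with `X` (n x 3 world points, mm) and `x`
#'   (n x 2 pixels), or a data frame with columns `x_mm, y_mm, z_mm, u_px,
#'   v_px`.
#' @param intr An [intrinsics()].
#' @return An [extrinsics()] with attribute `rms` (root-mean-square
#'   reprojection residual, pixels).
#' @export
estimate_pose <- function(correspondences, intr) {
  cc <- correspondences
  if (is.data.frame(cc))
    cc <- list(X = as.matrix(cc[, c("x_mm", "y_mm", "z_mm")]),
               x = as.matrix(cc[, c("u_px", "v_px")]))
  X <- cc$X; uv <- cc$x
  stopifnot(is.matrix(X), is.matrix(uv), ncol(X) == 3, ncol(uv) == 2,
            nrow(X) == nrow(uv))
  n <- nrow(X)
  if (n < 4)
    stop_rootcarve("PnP needs four or more marker correspondences",
                   "rootcarve_insufficient_correspondences")
  if (any(uv[, 1] < 0 | uv[, 1] >= intr$width |
          uv[, 2] < 0 | uv[, 2] >= intr$height))
    stop_rootcarve("image points outside image bounds",
                   "rootcarve_bad_detections")
  Xc <- scale(X, scale = FALSE)
  sv <- svd(Xc, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop_rootcarve("marker points are collinear: degenerate PnP geometry",
                   "rootcarve_degenerate_geometry")
  K <- intrinsics_matrix(intr)
  xn <- cbind((uv[, 1] - intr$cx) / intr$fx, (uv[, 2] - intr$cy) / intr$fy)
  inits <- list()
  if (n >= 6) inits[[1]] <- pnp_dlt(X, xn)
  # multi-start fallback: cameras looking at the marker centroid from a
  # bundle of directions at a distance set by the apparent spread
  ctr <- colMeans(X)
  spread <- max(sqrt(rowSums(t(t(X) - ctr)^2)))
  appr <- max(sd(xn[, 1]), sd(xn[, 2]), 1e-3)
  dist0 <- spread / appr / 2
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0.7, 0.7, 0.2), c(-0.7, 0.7, -0.2), c(0.7, -0.7, 0.2),
                c(-0.7, -0.7, -0.2))
  for (i in seq_len(nrow(dirs))) {
    d <- unitize(dirs[i, ])
    Cc <- ctr + d * dist0
    z <- unitize(ctr - Cc)
    xax <- tryCatch(unitize(cross3(c(0, 0, 1), z)), error = function(e) c(1, 0, 0))
    yax <- cross3(z, xax)
    R <- rbind(xax, yax, z, deparse.level = 0)
    inits[[length(inits) + 1]] <- list(R = R, t = drop(-R %*% Cc))
  }
  best <- NULL
  for (ini in inits) {
    fit <- tryCatch(pnp_refine(ini$R, ini$t, X, uv, intr),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$rms < best$rms)) best <- fit
    if (!is.null(best) && best$rms < 1e-8) break
  }
  if (is.null(best))
    stop_rootcarve("pose refinement failed to converge",
                   "rootcarve_degenerate_geometry")
  out <- extrinsics(best$R, best$t)
  attr(out, "rms") <- best$rms
  out
}

#' Least-squares circle of best fit to 3D points
#'
#' Fits the best plane through the points (principal components), projects
#' into it, and fits a circle by linear least squares. Used to summarize the
#' turntable geometry of the estimated camera centers.
#'
#' @param centers n x 3 matrix of points, mm (n >= 3, not collinear).
#' @return Object of class `circle_fit`: `center` (3-vector), `radius` (mm),
#'   `normal` (unit plane normal), `residuals` (in-plane radial residuals
#'   per point, mm) and `rms`.
#' @export
fit_circle <- function(centers) {
  stopifnot(is.matrix(centers), ncol(centers) == 3)
  n <- nrow(centers)
  if (n < 3)
    stop_rootcarve("circle fit needs at least three points",
                   "rootcarve_degenerate_fit")
  ctr <- colMeans(centers)
  Xc <- t(t(centers) - ctr)
  sv <- svd(Xc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop_rootcarve("points are collinear: circle fit is degenerate",
                   "rootcarve_degenerate_fit")
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  normal <- cross3(e1, e2)
  P <- cbind(Xc %*% e1, Xc %*% e2)
  # algebraic (Kasa) fit: x^2 + y^2 + D x + E y + F = 0
  A <- cbind(P, 1)
  b <- -(P[, 1]^2 + P[, 2]^2)
  sol <- qr.solve(A, b)
  c2d <- -sol[1:2] / 2
  radius <- sqrt(sum(c2d^2) - sol[3])
  center <- ctr + c2d[1] * e1 + c2d[2] * e2
  resid <- sqrt((P[, 1] - c2d[1])^2 + (P[, 2] - c2d[2])^2) - radius
  structure(list(center = center, radius = radius, normal = unitize(normal),
                 residuals = resid, rms = sqrt(mean(resid^2))),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> radius %.3f mm, center (%.2f, %.2f, %.2f), rms %.3g mm\n",
              x$radius, x$center[1], x$center[2], x$center[3], x$rms))
  invisible(x)
}

# --- file interfaces -----------------------------------------------------

#' Read a fiducial-marker layout
#'
#' CSV with columns `id, x_mm, y_mm, z_mm`: the known 3D centers of the
#' marker strip wrapped around the net pot.
#' @param path CSV file.
#' @export
read_marker_layout <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("id", "x_mm", "y_mm", "z_mm") %in% names(df)))
  if (anyDuplicated(df$id))
    stop_rootcarve("marker ids must be unique", "rootcarve_bad_layout")
  df
}

#' Read per-image marker detections
#'
#' CSV with columns `image, id, u_px, v_px` (2D marker centers found by an
#' external fiducial detector).
#' @param path CSV file.
#' @export
read_detections <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("image", "id", "u_px", "v_px") %in% names(df)))
  df
}

#' Join a marker layout with one image's detections
#'
#' @param layout From [read_marker_layout()].
#' @param detections From [read_detections()], rows for a single image.
#' @return A correspondences data frame for [estimate_pose()].
#' @export
marker_correspondences <- function(layout, detections) {
  m <- merge(detections, layout, by = "id")
  m[, c("x_mm", "y_mm", "z_mm", "u_px", "v_px")]
}

#' Export / import camera poses as JSON
#'
#' One record per image: row-major 3x3 `R`, 3-vector `t`, and the intrinsics
#' block.
#'
#' @param views List of [camera_view()] objects.
#' @param path JSON file.
#' @export
write_poses <- function(views, path) {
  recs <- lapply(views, function(v) list(
    image = v$image_id,
    R = as.numeric(t(v$extrinsics$R)),
    t = v$extrinsics$t,
    intrinsics = unclass(v$intrinsics)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_poses
#' @export
read_poses <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    intr <- do.call(intrinsics, c(r$intrinsics[c("fx", "fy", "cx", "cy",
                                                 "width", "height")],
                                  list(dist = unlist(r$intrinsics$dist))))
    R <- matrix(unlist(r$R), 3, 3, byrow = TRUE)
    camera_view(intr, extrinsics(R, unlist(r$t)),
                image_id = r$image %||% NA_character_)
  })
}
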