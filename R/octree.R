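# Octree mark-and-refine space carving against refracted silhouette views.
#
# The root node is the axis-aligned cube circumscribing the inner canister
# volume (in the cylinder frame). A breadth-first queue classifies every
# node against every view from its covering-ray evidence: fully silhouetted
# in a view marks it occupied-for-that-view, fully outside marks it empty,
# a mixture makes it a split candidate. Empty in any view carves the node;
# a node still undecided at the target resolution is kept (the discrete
# visual hull converges to the true hull from above).

#' Carving configuration
#'
#' @param s_min Target leaf resolution, mm: refinement stops at the first
#'   depth whose leaf side is `<= s_min`. The default 0.3 mm gives
#'   0.298-mm leaves in the default canister, the operating resolution of
#'   the method.
#' @param tau_full Occupancy threshold on the visible fraction `f` of a
#'   voxel's covering rays: `f >= tau_full` marks the voxel fully
#'   silhouetted in a view. Default 1 (all covering rays land in the
#'   silhouette).
#' @param tau_empty Emptiness threshold: `f <= tau_empty` votes to carve.
#'   Default 0 (no covering ray lands in the silhouette).
#' @param min_views_to_carve Number of empty-view votes required to carve a
#'   voxel. The default 1 is strict intersection semantics (empty in any
#'   single view suffices); larger values relax the aggressive culling that
#'   erases thin roots under pose error.
#' @param max_depth Hard cap on octree depth (memory guard).
#' @export
carve_config <- function(s_min = 0.3, tau_full = 1.0, tau_empty = 0.0,
                         min_views_to_carve = 1L, max_depth = 12L) {
  stopifnot(s_min > 0, tau_full > 0, tau_full <= 1,
            tau_empty >= 0, tau_empty < 1, tau_empty < tau_full,
            min_views_to_carve >= 1)
  structure(list(s_min = s_min, tau_full = tau_full, tau_empty = tau_empty,
                 min_views_to_carve = as.integer(min_views_to_carve),
                 max_depth = as.integer(max_depth)),
            class = "carve_config")
}

# root cube circumscribing the inner cylinder, in the cylinder frame
root_cube <- function(cyl) {
  side <- max(2 * cyl$inner_radius, cyl$height)
  list(origin = c(-side / 2, -side / 2, cyl$height / 2 - side / 2),
       side = side)
}

# per-view ray bundle in the cylinder frame + foreground flag per valid ray
carve_view_rays <- function(sil, rf) {
  mask <- silhouette_mask(sil)
  if (nrow(mask) != rf$height || ncol(mask) != rf$width)
    stop_rootcarve("silhouette and ray grid dimensions differ",
                   "rootcarve_alignment_error")
  v <- rf$valid
  B <- cyl_basis(rf$cylinder)
  O <- t(B %*% (t(rf$origin[v, , drop = FALSE]) - rf$cylinder$origin))
  D <- t(B %*% t(rf$dir[v, , drop = FALSE]))
  list(O = O, D = D, tmax = rf$t_max[v], fg = as.vector(mask)[v])
}

# drop cells (0-based level-L indices) lying fully outside the inner
# cylinder volume
filter_cells_in_cylinder <- function(cells, cube, cell, cyl) {
  x0 <- cube$origin[1] + cells[, 1] * cell
  y0 <- cube$origin[2] + cells[, 2] * cell
  z0 <- cube$origin[3] + cells[, 3] * cell
  # nearest |coordinate| of the cell interval to the axis (0 if it straddles)
  nx <- pmin(abs(x0), abs(x0 + cell)) * (sign(x0) == sign(x0 + cell))
  ny <- pmin(abs(y0), abs(y0 + cell)) * (sign(y0) == sign(y0 + cell))
  keep <- nx^2 + ny^2 <= cyl$inner_radius^2 &
    z0 + cell >= 0 & z0 <= cyl$height
  cells[keep, , drop = FALSE]
}

#' Octree space carving of silhouette views into a visual hull
#'
#' Runs the mark-and-refine loop: starting from the root cube, each queued
#' node is scored against every view with its covering refracted rays
#' (fraction of covering rays landing in the silhouette). A node empty in
#' `min_views_to_carve` or more views is carved; a node partially covered
#' in some view is split into its eight children and re-queued until the
#' target resolution; surviving nodes are the occupied leaves of the
#' discrete visual hull. Nodes never covered by any ray keep their occupied
#' state but are flagged unobserved (absence of evidence does not carve).
#'
#' @param views A list; each element is a list with elements `silhouette`
#'   (a `silhouette` or logical matrix on the ray grid), `rayfield` (the
#'   matching [trace_view()] result) and optionally `view` (the
#'   [camera_view()], kept for provenance).
#' @param cyl The [cylinder()]; must be the one the rays were traced in.
#' @param config A [carve_config()].
#' @return Object of class `octree_model`: occupied-leaf table
#'   (`level, ix, iy, iz, unobserved`, 0-based indices in the root cube),
#'   root-cube geometry, and the carving configuration.
#' @seealso [total_volume()], [to_flat_grid()], [export_mesh()].
#' @export
carve <- function(views, cyl = cylinder(), config = carve_config()) {
  if (length(views) < 1)
    stop_rootcarve("carving needs at least one view (no evidence)",
                   "rootcarve_no_evidence")
  cube <- root_cube(cyl)
  max_depth <- min(config$max_depth,
                   ceiling(log2(cube$side / config$s_min)))
  bundles <- lapply(views, function(v) {
    rf <- v$rayfield %||% stop_rootcarve("view element missing 'rayfield'",
                                         "rootcarve_alignment_error")
    carve_view_rays(v$silhouette, rf)
  })
  dims <- vapply(views, function(v) c(v$rayfield$width, v$rayfield$height),
                 numeric(2))
  if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1)
    stop_rootcarve("all views must share one ray-grid resolution",
                   "rootcarve_alignment_error")
  active <- matrix(0L, 1, 3)  # level-0 root cell
  leaves <- vector("list", max_depth + 1L)
  for (L in 0:max_depth) {
    if (nrow(active) == 0) break
    cell <- cube$side / 2^L
    active <- filter_cells_in_cylinder(active, cube, cell, cyl)
    if (nrow(active) == 0) break
    n_act <- nrow(active)
    rng <- apply(active, 2, range)
    g0 <- cube$origin + rng[1, ] * cell
    nd <- rng[2, ] - rng[1, ] + 1L
    idx <- integer(prod(nd)) - 1L
    loc <- t(t(active) - rng[1, ])
    lin <- loc[, 1] + nd[1] * (loc[, 2] + nd[2] * loc[, 3])
    idx[lin + 1L] <- seq_len(n_act) - 1L
    n_empty <- integer(n_act)
    any_undec <- logical(n_act)
    any_seen <- logical(n_act)
    for (b in bundles) {
      acc <- .carve_accumulate_cpp(b$O[, 1], b$O[, 2], b$O[, 3],
                                   b$D[, 1], b$D[, 2], b$D[, 3],
                                   b$tmax, b$fg, idx,
                                   nd[1], nd[2], nd[3],
                                   g0[1], g0[2], g0[3], cell, n_act)
      seen <- acc$cover > 0L
      f <- ifelse(seen, acc$hit / acc$cover, NA_real_)
      emptyv <- seen & f <= config$tau_empty
      occv <- seen & f >= config$tau_full
      n_empty <- n_empty + emptyv
      any_undec <- any_undec | (seen & !emptyv & !occv)
      any_seen <- any_seen | seen
    }
    carved <- n_empty >= config$min_views_to_carve
    split <- !carved & any_undec & L < max_depth
    occ <- !carved & !split
    if (any(occ)) {
      leaves[[L + 1L]] <- cbind(level = L,
                                active[occ, , drop = FALSE],
                                unobserved = as.integer(!any_seen[occ]))
    }
    if (any(split)) {
      par <- active[split, , drop = FALSE]
      kid <- matrix(0L, 8L * nrow(par), 3L)
      r <- 0L
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        kid[r + seq_len(nrow(par)), ] <-
          cbind(2L * par[, 1] + dx, 2L * par[, 2] + dy, 2L * par[, 3] + dz)
        r <- r + nrow(par)
      }
      active <- kid
    } else active <- matrix(0L, 0, 3)
  }
  lv <- do.call(rbind, leaves[!vapply(leaves, is.null, TRUE)])
  if (is.null(lv)) lv <- matrix(0L, 0, 5,
                                dimnames = list(NULL, c("level", "ix", "iy",
                                                        "iz", "unobserved")))
  colnames(lv) <- c("level", "ix", "iy", "iz", "unobserved")
  structure(list(origin = cube$origin, side = cube$side,
                 max_depth = max_depth, leaf_size = cube$side / 2^max_depth,
                 leaves = as.data.frame(lv), cylinder = cyl,
                 config = config, n_views = length(views)),
            class = "octree_model")
}

#' @export
print.octree_model <- function(x, ...) {
  cat(sprintf(paste0("<octree_model> %d occupied leaves (depth <= %d, leaf ",
                     "%.3g mm), volume %.3f mL\n"),
              nrow(x$leaves), x$max_depth, x$leaf_size, total_volume(x)))
  un <- total_volume(x, include_unobserved = TRUE) - total_volume(x)
  if (un > 0) cat(sprintf("  plus %.3f mL unobserved (no covering rays)\n", un))
  invisible(x)
}

#' Classify one voxel against one view
#'
#' The per-view scoring rule of the carver, on the reference (per-pixel) R
#' path: computes the voxel's visibility mask, its visible fraction `f`
#' against the silhouette, and returns `"occupied"` (`f >= tau_full`),
#' `"empty"` (`f <= tau_empty`), `"undecided"` (between), or `"unseen"`
#' (no covering ray: the voxel keeps its prior state).
#'
#' @param center Voxel center, 3-vector mm.
#' @param side Voxel side, mm.
#' @param silhouette Silhouette (or logical matrix) on the ray grid.
#' @param rf The view's [trace_view()] result.
#' @param config A [carve_config()].
#' @return Classification string with attribute `fraction`.
#' @export
classify_voxel <- function(center, side, silhouette, rf,
                           config = carve_config()) {
  mask <- pixel_visibility_mask(center, side / 2, rf)
  if (!any(mask)) {
    out <- "unseen"
    attr(out, "fraction") <- NA_real_
    return(out)
  }
  f <- visible_fraction(mask, silhouette)
  out <- if (f >= config$tau_full) "occupied"
  else if (f <= config$tau_empty) "empty"
  else "undecided"
  attr(out, "fraction") <- f
  out
}

# reference carver: classify every cell of a flat grid at `depth`
# independently with the per-pixel R path (no octree, no C++); used as the
# brute-force oracle for the hierarchical carver.
carve_dense <- function(views, cyl = cylinder(), config = carve_config(),
                        depth = 4L) {
  cube <- root_cube(cyl)
  G <- 2^depth
  cell <- cube$side / G
  occ <- array(FALSE, c(G, G, G))
  for (iz in 0:(G - 1)) for (iy in 0:(G - 1)) for (ix in 0:(G - 1)) {
    ctr <- cube$origin + (c(ix, iy, iz) + 0.5) * cell
    # outside the inner cylinder: pre-marked empty
    lo <- ctr - cell / 2; hi <- ctr + cell / 2
    nx <- if (sign(lo[1]) == sign(hi[1])) min(abs(lo[1]), abs(hi[1])) else 0
    ny <- if (sign(lo[2]) == sign(hi[2])) min(abs(lo[2]), abs(hi[2])) else 0
    if (nx^2 + ny^2 > cyl$inner_radius^2 || hi[3] < 0 || lo[3] > cyl$height)
      next
    n_empty <- 0L
    for (v in views) {
      st <- classify_voxel(ctr, cell, v$silhouette, v$rayfield, config)
      if (st == "empty") n_empty <- n_empty + 1L
    }
    occ[ix + 1, iy + 1, iz + 1] <- n_empty < config$min_views_to_carve
  }
  list(occupied = occ, origin = cube$origin, side = cube$side, cell = cell)
}

#' Total volume of the carved model
#'
#' Sum over occupied leaves of the cubed side length (`V = N s^3` for a
#' uniform-resolution model; heterogeneous leaf sizes are summed as
#' `sum(s_i^3)`), converted from mm^3 to mL.
#'
#' @param model An [carve()] result.
#' @param include_unobserved Include voxels retained only because no ray
#'   ever covered them (reported separately by default).
#' @return Volume in mL.
#' @export
total_volume <- function(model, include_unobserved = FALSE) {
  lv <- model$leaves
  if (!include_unobserved) lv <- lv[lv$unobserved == 0L, , drop = FALSE]
  if (nrow(lv) == 0) return(0)
  sum((model$side / 2^lv$level)^3) / 1000
}

#' Expand the octree to a dense voxel grid
#'
#' The dense occupancy grid equivalent to the octree sampled at resolution
#' `s` (which must be a power-of-two subdivision of the root cube no finer
#' than the carved leaves).
#'
#' @param model An [carve()] result.
#' @param s Sampling resolution, mm; default the model's leaf size.
#' @param include_unobserved See [total_volume()].
#' @param max_cells Memory guard on the number of grid cells.
#' @return Logical `G x G x G` array with attributes `origin`, `side`,
#'   `cell`.
#' @export
to_flat_grid <- function(model, s = NULL, include_unobserved = FALSE,
                         max_cells = 2^27) {
  s <- s %||% model$leaf_size
  d <- log2(model$side / s)
  if (abs(d - round(d)) > 1e-6 || round(d) < 0)
    stop_rootcarve("s must be side / 2^d for an integer depth d",
                   "rootcarve_bad_resolution")
  d <- as.integer(round(d))
  if (d > model$max_depth)
    stop_rootcarve("requested resolution is finer than the carved leaves",
                   "rootcarve_bad_resolution")
  G <- 2^d
  if (G^3 > max_cells)
    stop_rootcarve("flat grid exceeds the configured cell cap",
                   "rootcarve_memory_guard")
  occ <- array(FALSE, c(G, G, G))
  lv <- model$leaves
  if (!include_unobserved) lv <- lv[lv$unobserved == 0L, , drop = FALSE]
  for (L in sort(unique(lv$level))) {
    sub <- lv[lv$level == L, , drop = FALSE]
    if (L <= d) {
      k <- 2^(d - L)  # each leaf covers k^3 fine cells
      off <- as.matrix(expand.grid(0:(k - 1), 0:(k - 1), 0:(k - 1)))
      for (j in seq_len(nrow(off))) {
        occ[cbind(sub$ix * k + off[j, 1] + 1L,
                  sub$iy * k + off[j, 2] + 1L,
                  sub$iz * k + off[j, 3] + 1L)] <- TRUE
      }
    } else {
      # leaves finer than the sampling grid: mark the containing cell
      k <- 2^(L - d)
      occ[cbind(sub$ix %/% k + 1L, sub$iy %/% k + 1L, sub$iz %/% k + 1L)] <- TRUE
    }
  }
  attr(occ, "origin") <- model$origin
  attr(occ, "side") <- model$side
  attr(occ, "cell") <- model$side / G
  occ
}

#' Export the carved surface as a triangle mesh
#'
#' Cube-union surface of the occupied voxels: every face between an
#' occupied and an empty (or outside) cell becomes two triangles with
#' outward orientation. The mesh is watertight, so its divergence-theorem
#' volume equals the voxel volume exactly.
#'
#' @param model An [carve()] result (must contain occupied leaves).
#' @param path Optional output file; format by extension (`.ply`, `.obj`,
#'   `.stl`).
#' @param s Sampling resolution passed to [to_flat_grid()].
#' @return Invisibly, a list with `vertices` (n x 3) and `faces` (m x 3,
#'   1-based, counter-clockwise outward).
#' @export
export_mesh <- function(model, path = NULL, s = NULL) {
  grid <- to_flat_grid(model, s)
  if (!any(grid))
    stop_rootcarve("model has no occupied voxels: empty mesh",
                   "rootcarve_empty_mesh")
  mesh <- grid_to_mesh(grid)
  if (!is.null(path)) write_mesh(mesh, path)
  invisible(mesh)
}

# boundary faces of a dense occupancy grid -> triangle soup
grid_to_mesh <- function(grid) {
  G <- dim(grid)
  origin <- attr(grid, "origin")
  cell <- attr(grid, "cell")
  pad <- array(FALSE, G + 2L)
  pad[2:(G[1] + 1), 2:(G[2] + 1), 2:(G[3] + 1)] <- grid
  verts <- list(); faces <- list(); nv <- 0L
  # for each axis and direction, faces where occupied meets not-occupied
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  idx <- which(grid, arr.ind = TRUE)
  for (d in dirs) {
    nb <- pad[cbind(idx[, 1] + 1L + d[1], idx[, 2] + 1L + d[2],
                    idx[, 3] + 1L + d[3])]
    face_cells <- idx[!nb, , drop = FALSE]
    if (nrow(face_cells) == 0) next
    ax <- which(d != 0)
    pos <- d[ax] > 0
    # the face plane offset within the cell along ax
    base <- t(t(face_cells) - 1)  # 0-based
    o <- matrix(0, nrow(face_cells), 3)
    o[, ax] <- if (pos) 1 else 0
    u <- ((ax) %% 3) + 1L; w <- ((ax + 1) %% 3) + 1L
    eu <- diag(3)[u, ]; ew <- diag(3)[w, ]
    mk <- function(du, dw) {
      p <- base + o + outer(rep(du, nrow(base)), eu) +
        outer(rep(dw, nrow(base)), ew)
      t(t(p) * cell + origin)
    }
    v00 <- mk(0, 0); v10 <- mk(1, 0); v11 <- mk(1, 1); v01 <- mk(0, 1)
    nface <- nrow(face_cells)
    verts[[length(verts) + 1L]] <- rbind(v00, v10, v11, v01)
    i00 <- nv + seq_len(nface); i10 <- i00 + nface
    i11 <- i10 + nface; i01 <- i11 + nface
    # orient CCW seen from outside (right-hand rule along +d)
    if (pos) f <- rbind(cbind(i00, i10, i11), cbind(i00, i11, i01))
    else f <- rbind(cbind(i00, i11, i10), cbind(i00, i01, i11))
    faces[[length(faces) + 1L]] <- f
    nv <- nv + 4L * nface
  }
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, faces))
}

#' Signed volume enclosed by a triangle mesh
#'
#' Divergence-theorem volume `sum det(v1, v2, v3) / 6` over the triangles;
#' positive for outward-oriented watertight meshes. In mL.
#'
#' @param mesh A list with `vertices` and `faces` (from [export_mesh()]).
#' @export
mesh_volume <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cr <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
              v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
              v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(rowSums(v1 * cr)) / 6 / 1000
}

write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices; Fc <- mesh$faces
  if (ext == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("f %d %d %d", Fc[, 1], Fc[, 2], Fc[, 3]), con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(Fc)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", Fc[, 1] - 1L, Fc[, 2] - 1L, Fc[, 3] - 1L),
               con)
  } else if (ext == "stl") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid rootcarve", con)
    for (i in seq_len(nrow(Fc))) {
      tri <- V[Fc[i, ], ]
      n <- unitize(cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ]))
      writeLines(c(sprintf("facet normal %.6f %.6f %.6f", n[1], n[2], n[3]),
                   "  outer loop",
                   sprintf("    vertex %.6f %.6f %.6f", tri[, 1], tri[, 2],
                           tri[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid rootcarve", con)
  } else stop_rootcarve(sprintf("unsupported mesh format '%s'", ext),
                        "rootcarve_bad_format")
  invisible(path)
}
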