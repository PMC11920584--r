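# internal numerical helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

# row-wise normalization of an n x 3 matrix
unitize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues: axis-angle vector (length = angle, rad) -> 3x3 rotation
rot_from_axis_angle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# angle (rad) between two rotation matrices
rotation_distance <- function(R1, R2) {
  ctheta <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(pmin(1, pmax(-1, ctheta)))
}

is_rotation_matrix <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

# run expr with a local RNG state seeded by `seed`, restoring global state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

stop_rootcarve <- function(msg, class) {
  stop(structure(class = c(class, "rootcarve_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
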