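#' Construct a 3D point set
#'
#' A point set is an n x 3 numeric matrix of finite coordinates with a
#' `label` (`"moving"` or `"reference"`) and a `source` attribute recording
#' where the points came from.
#'
#' @param coords numeric matrix (or coercible) with 3 columns.
#' @param label one of `"moving"`, `"reference"`.
#' @param source free-text provenance, e.g. a file path or `"synthetic"`.
#' @return an object of class `point_set`.
#' @export
point_set <- function(coords, label = c("moving", "reference"),
                      source = "memory") {
  label <- match.arg(label)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("a point set needs exactly 3 coordinate columns, got ", ncol(coords))
  storage.mode(coords) <- "double"
  if (nrow(coords) > 0L && !all(is.finite(coords)))
    stop("point set contains non-finite coordinates")
  dimnames(coords) <- NULL
  structure(coords, class = c("point_set", "matrix", "array"),
            label = label, source = source)
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points, label=%s, source=%s\n",
              nrow(x), attr(x, "label"), attr(x, "source")))
  if (nrow(x) > 0L) {
    rng <- apply(unclass(x), 2L, range)
    cat(sprintf("  extent: x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

as_coord_matrix <- function(ps) {
  m <- unclass(ps)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Angular distance between two 3-vectors
#'
#' The angle in `[0, pi]` between two nonzero vectors,
#' `acos` of the normalized dot product clamped to `[-1, 1]`.
#'
#' @param u,v numeric 3-vectors with positive norm.
#' @return angle in radians.
#' @export
angular_distance <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  stopifnot(length(u) == 3L, length(v) == 3L)
  a <- cpp_angular_distance(u, v)
  if (is.na(a))
    stop("angular_distance: zero-norm vector (degenerate)")
  a
}

#' Rotation matrix from an axis-angle vector (Rodrigues formula)
#'
#' @param r numeric 3-vector; direction is the rotation axis, norm the angle.
#'   The zero vector maps to the identity.
#' @return 3 x 3 rotation matrix.
#' @export
axis_angle_to_matrix <- function(r) {
  r <- as.numeric(r)
  stopifnot(length(r) == 3L, all(is.finite(r)))
  cpp_axis_angle_to_matrix(r)
}

#' Axis-angle vector from a rotation matrix
#'
#' Inverse of [axis_angle_to_matrix()]; the returned vector has norm in
#' `[0, pi]` (canonical form).
#'
#' @param R 3 x 3 rotation matrix.
#' @return numeric 3-vector.
#' @export
matrix_to_axis_angle <- function(R) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3L, 3L)))
  # quaternion extraction (Shepperd): numerically stable for all angles,
  # including near pi where the skew part vanishes
  tr <- sum(diag(R))
  if (tr >= max(diag(R))) {
    w <- sqrt(max(0, 1 + tr)) / 2  # >= 1/2 on this branch
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (4 * w)
  } else {
    k <- which.max(diag(R))
    i <- k; j <- i %% 3L + 1L; l <- j %% 3L + 1L
    s <- sqrt(max(0, 1 + R[i, i] - R[j, j] - R[l, l])) / 2
    v <- numeric(3)
    v[i] <- s
    w <- (R[l, j] - R[j, l]) / (4 * s)
    v[j] <- (R[j, i] + R[i, j]) / (4 * s)
    v[l] <- (R[l, i] + R[i, l]) / (4 * s)
    v <- v * sign(w + (w == 0))
    w <- abs(w)
  }
  nv <- sqrt(sum(v^2))
  if (nv < 1e-15) return(c(0, 0, 0))
  theta <- 2 * atan2(nv, w)
  if (theta > pi) theta <- theta - 2 * pi  # canonical: |angle| <= pi
  v / nv * theta
}

#' Similarity transformation y = s R (x + t)
#'
#' Holds both parameterizations of a 7-DoF similarity transform: the
#' pre-rotation translation `t_pre` of `y = s R (x + t_pre)` and the
#' canonical `t_canonical = s R t_pre` of `y = s R x + t_canonical`.
#' Exactly one of `rotation` (3 x 3 matrix) or `axis_angle` must be given;
#' exactly one of `t_pre` or `t_canonical`.
#'
#' @param s positive scale.
#' @param rotation 3 x 3 rotation matrix.
#' @param axis_angle axis-angle 3-vector, alternative to `rotation`.
#' @param t_pre,t_canonical translation 3-vectors (one of the two).
#' @return an object of class `similarity_transform` with fields `s`, `R`,
#'   `axis_angle`, `t_pre`, `t_canonical`.
#' @export
similarity_transform <- function(s = 1, rotation = NULL, axis_angle = NULL,
                                 t_pre = NULL, t_canonical = NULL) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("scale s must be a positive finite number")
  if (is.null(rotation) && is.null(axis_angle)) rotation <- diag(3)
  if (!is.null(axis_angle)) {
    if (!is.null(rotation)) stop("give either rotation or axis_angle, not both")
    rotation <- axis_angle_to_matrix(axis_angle)
  } else {
    axis_angle <- matrix_to_axis_angle(rotation)
  }
  rotation <- as.matrix(rotation)
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6 || det(rotation) < 0)
    stop("rotation is not a proper orthonormal matrix (deviation ", signif(err, 3), ")")
  if (is.null(t_pre) && is.null(t_canonical)) t_pre <- c(0, 0, 0)
  if (!is.null(t_pre) && !is.null(t_canonical))
    stop("give either t_pre or t_canonical, not both")
  if (is.null(t_pre)) {
    t_canonical <- as.numeric(t_canonical)
    t_pre <- as.numeric(crossprod(rotation, t_canonical)) / s
  } else {
    t_pre <- as.numeric(t_pre)
    t_canonical <- as.numeric(s * rotation %*% t_pre)
  }
  stopifnot(length(t_pre) == 3L, all(is.finite(t_pre)))
  structure(list(s = s, R = rotation, axis_angle = as.numeric(axis_angle),
                 t_pre = t_pre, t_canonical = t_canonical),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat("<similarity_transform>\n")
  cat(sprintf("  s          : %.6g\n", x$s))
  cat(sprintf("  axis-angle : (%.4f, %.4f, %.4f)  |angle| = %.4f rad\n",
              x$axis_angle[1], x$axis_angle[2], x$axis_angle[3],
              sqrt(sum(x$axis_angle^2))))
  cat(sprintf("  t_pre      : (%.4f, %.4f, %.4f)\n",
              x$t_pre[1], x$t_pre[2], x$t_pre[3]))
  cat(sprintf("  t_canonical: (%.4f, %.4f, %.4f)\n",
              x$t_canonical[1], x$t_canonical[2], x$t_canonical[3]))
  invisible(x)
}

#' Apply a similarity transform to a point set
#'
#' Maps every point through `y = s R x + t_canonical`, identically
#' `y = s R (x + t_pre)`.
#'
#' @param tf a [similarity_transform()].
#' @param ps a [point_set()] or n x 3 matrix.
#' @return transformed points, same class as the input.
#' @export
apply_transform <- function(tf, ps) {
  stopifnot(inherits(tf, "similarity_transform"))
  m <- if (inherits(ps, "point_set")) as_coord_matrix(ps) else as.matrix(ps)
  out <- tf$s * (m %*% t(tf$R)) +
    matrix(tf$t_canonical, nrow(m), 3L, byrow = TRUE)
  if (inherits(ps, "point_set"))
    point_set(out, label = attr(ps, "label"), source = attr(ps, "source"))
  else out
}

#' Invert a similarity transform
#'
#' @param tf a [similarity_transform()].
#' @return the inverse transform.
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "similarity_transform"))
  similarity_transform(s = 1 / tf$s, rotation = t(tf$R),
                       t_canonical = -as.numeric(t(tf$R) %*% tf$t_canonical) / tf$s)
}

#' Geodesic rotation error
#'
#' The angle of the relative rotation `R_est %*% t(R_gt)`,
#' `acos((trace - 1) / 2)` clamped to `[0, pi]`.
#'
#' @param R_est,R_gt 3 x 3 rotation matrices.
#' @return angle in radians.
#' @export
rotation_error <- function(R_est, R_gt) {
  tr <- sum(diag(R_est %*% t(R_gt)))
  acos(max(-1, min(1, (tr - 1) / 2)))
}

#' Axis-aligned cube in a 3D parameter space
#'
#' @param center numeric 3-vector.
#' @param half_side positive half side length; the half space diagonal is
#'   `half_side * sqrt(3)`.
#' @return an object of class `cube`.
#' @export
cube <- function(center, half_side) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, is.finite(half_side), half_side > 0)
  structure(list(center = center, half_side = half_side,
                 half_diagonal = half_side * sqrt(3)),
            class = "cube")
}

#' Octant subdivision of a cube
#'
#' @param cb a [cube()].
#' @return list of 8 disjoint child cubes whose union is the parent.
#' @export
cube_children <- function(cb) {
  stopifnot(inherits(cb, "cube"))
  h <- cb$half_side / 2
  lapply(0:7, function(oct) {
    off <- c(if (bitwAnd(oct, 1L)) h else -h,
             if (bitwAnd(oct, 2L)) h else -h,
             if (bitwAnd(oct, 4L)) h else -h)
    cube(cb$center + off, h)
  })
}

# Uniform random rotation via a random unit quaternion (uses the R RNG)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# unit directions of the rows; rows with norm < tol are flagged
unit_directions <- function(m, tol = 1e-9) {
  nrm <- sqrt(rowSums(m^2))
  ok <- nrm >= tol
  dirs <- m[ok, , drop = FALSE] / nrm[ok]
  list(dirs = dirs, keep = which(ok), n_dropped = sum(!ok))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
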