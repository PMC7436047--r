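#' Rotation consensus objective specification
#'
#' Built from the translated moving points `x* = x + t` and the reference
#' points. Only the directions of the position vectors matter, so the
#' objective is unaffected by the unknown relative scale. Points with norm
#' below `tol_norm` carry no direction and are excluded (their count is
#' recorded).
#'
#' @param X_star translated moving points ([point_set()] or matrix).
#' @param Y reference points.
#' @param eps_r angular inlier threshold, radians.
#' @param tol_norm norm below which a point has no usable direction.
#' @return a list of class `rotation_objective` with cached unit direction
#'   matrices.
#' @export
rotation_objective <- function(X_star, Y, eps_r, tol_norm = 1e-9) {
  stopifnot(eps_r > 0)
  Xm <- if (inherits(X_star, "point_set")) as_coord_matrix(X_star) else as.matrix(X_star)
  Ym <- if (inherits(Y, "point_set")) as_coord_matrix(Y) else as.matrix(Y)
  if (nrow(Xm) == 0L || nrow(Ym) == 0L) stop("empty point set")
  ux <- unit_directions(Xm, tol_norm)
  uy <- unit_directions(Ym, tol_norm)
  if (nrow(ux$dirs) == 0L || nrow(uy$dirs) == 0L)
    stop("all points degenerate (zero norm): no directions available")
  structure(list(Xdir = ux$dirs, Ydir = uy$dirs, eps_r = eps_r,
                 x_keep = ux$keep, y_keep = uy$keep,
                 n_dropped = ux$n_dropped + uy$n_dropped),
            class = "rotation_objective")
}

#' Evaluate the rotation consensus objective
#'
#' Counts the moving directions that come within `eps_r` of some reference
#' direction after rotating by `R`.
#'
#' @param spec a [rotation_objective()].
#' @param R 3 x 3 rotation matrix or axis-angle 3-vector.
#' @return integer consensus count.
#' @export
objective_Er <- function(spec, R) {
  stopifnot(inherits(spec, "rotation_objective"))
  r <- if (is.matrix(R)) matrix_to_axis_angle(R) else as.numeric(R)
  cpp_objective_Er(spec$Xdir, spec$Ydir, r, spec$eps_r)
}

#' Rotation uncertainty bound of an axis-angle cube
#'
#' For any rotation vector `a` in the cube and any direction `u`,
#' `angle(R_c u, R_a u)` is at most the cube's half space diagonal, clamped
#' at `pi` (`R_c` the rotation at the cube center).
#'
#' @param B a [cube()] in axis-angle space.
#' @return angle in radians.
#' @export
mu_bound <- function(B) {
  stopifnot(inherits(B, "cube"))
  min(B$half_diagonal, pi)
}

#' Upper bound of the rotation objective over an axis-angle cube
#'
#' The center rotation evaluated with the inlier threshold relaxed by
#' [mu_bound()]; at least `objective_Er(spec, R)` for every rotation in the
#' cube.
#'
#' @param spec a [rotation_objective()].
#' @param B a [cube()] in axis-angle space.
#' @return integer upper bound.
#' @export
upper_bound_Er <- function(spec, B) {
  stopifnot(inherits(spec, "rotation_objective"), inherits(B, "cube"))
  cpp_upper_bound_Er(spec$Xdir, spec$Ydir, B$center, B$half_side, spec$eps_r)
}

#' Globally optimal rotation search (branch and bound)
#'
#' Best-first branch and bound over the axis-angle cube `[-pi, pi]^3`
#' enclosing the ball of all rotations; cubes wholly outside the pi-ball
#' are discarded, cubes straddling it are kept (rotations beyond the ball
#' are redundant re-parameterizations). Control flow is identical to
#' [bnb_translation()]. Returns the incumbent rotation, its consensus, and
#' the inlier pairs at the incumbent (each moving direction paired with its
#' angularly nearest reference direction when within `eps_r`).
#'
#' The counting objective can have exactly tied maximizer regions (with
#' many reference directions and a generous threshold, several rotations
#' may cover every moving direction). `exclude` removes geodesic balls
#' around previously rejected rotations from the search, which lets a
#' caller enumerate distinct consensus-optimal basins; see
#' [register_point_sets()] for the verification loop built on it.
#'
#' @param spec a [rotation_objective()].
#' @param min_half_side resolution limit in radians.
#' @param max_nodes node expansion budget.
#' @param time_limit seconds of CPU time.
#' @param exclude optional matrix of axis-angle rows to avoid.
#' @param exclude_radius geodesic radius (radians) of each excluded ball.
#' @return list with `r` (axis-angle), `R` (matrix), `consensus`,
#'   `inlier_pairs` (matrix of moving/reference row indices into the
#'   original inputs), `nodes_expanded`, `termination`,
#'   `remaining_upper_bound`, `timed_out`.
#' @export
bnb_rotation <- function(spec, min_half_side = 0.01, max_nodes = 1e7,
                         time_limit = 1200, exclude = NULL,
                         exclude_radius = NULL) {
  stopifnot(inherits(spec, "rotation_objective"))
  if (is.null(exclude)) exclude <- matrix(numeric(0), 0L, 3L)
  exclude <- as.matrix(exclude)
  if (is.null(exclude_radius)) exclude_radius <- 2 * spec$eps_r
  res <- cpp_bnb_rotation(spec$Xdir, spec$Ydir, spec$eps_r, min_half_side,
                          max_nodes, time_limit, exclude, exclude_radius)
  res$r <- as.numeric(res$r)
  res$R <- axis_angle_to_matrix(res$r)
  nn <- cpp_nearest_angular(spec$Xdir, spec$Ydir, res$r)
  inl <- which(nn$angle <= spec$eps_r)
  res$inlier_pairs <- cbind(moving = spec$x_keep[inl],
                            reference = spec$y_keep[nn$j[inl]])
  res$inlier_angles <- nn$angle[inl]
  res
}

#' Read the rotation off the consensus correspondences
#'
#' The counting objective is flat on a plateau of radius about `eps_r`
#' around the true rotation (every inlier stays within the threshold), so
#' the branch-and-bound incumbent is only localized to within the inlier
#' threshold. This routine sharpens it to the plateau's natural point
#' estimate: starting from the incumbent, it alternates nearest-direction
#' assignment with the closed-form least-squares rotation of
#' [fit_rotation_pairs()] over the pairs within `eps_r`, until the
#' assignment stops changing. On clean data the fixed point reproduces the
#' generating rotation to machine precision.
#'
#' @param spec a [rotation_objective()].
#' @param r_init axis-angle start (typically the incumbent of
#'   [bnb_rotation()]).
#' @param max_iter assignment/refit iterations.
#' @return list with `R`, `r` (axis-angle), `inlier_pairs`, `n_iter`.
#' @export
refine_rotation <- function(spec, r_init, max_iter = 30L) {
  stopifnot(inherits(spec, "rotation_objective"))
  r_cur <- as.numeric(r_init)
  R_cur <- axis_angle_to_matrix(r_cur)
  pairs_prev <- NULL
  n_iter <- 0L
  repeat {
    nn <- cpp_nearest_angular(spec$Xdir, spec$Ydir, r_cur)
    inl <- which(nn$angle <= spec$eps_r)
    if (length(inl) < 3L) break
    if (!is.null(pairs_prev) && identical(nn$j[inl], pairs_prev)) break
    pairs_prev <- nn$j[inl]
    R_new <- fit_rotation_pairs(spec$Xdir[inl, , drop = FALSE],
                                spec$Ydir[nn$j[inl], , drop = FALSE])
    n_iter <- n_iter + 1L
    delta <- rotation_error(R_new, R_cur)
    R_cur <- R_new
    r_cur <- matrix_to_axis_angle(R_cur)
    if (delta < 1e-12 || n_iter >= max_iter) break
  }
  nn <- cpp_nearest_angular(spec$Xdir, spec$Ydir, r_cur)
  inl <- which(nn$angle <= spec$eps_r)
  list(R = R_cur, r = r_cur,
       inlier_pairs = cbind(moving = spec$x_keep[inl],
                            reference = spec$y_keep[nn$j[inl]]),
       n_iter = n_iter)
}

#' Least-squares rotation from direction correspondences
#'
#' Solves the orthogonal Procrustes (Wahba) problem for paired unit
#' directions by SVD, returning the rotation minimizing the summed squared
#' chordal distance. Used to read a point estimate off a consensus plateau:
#' the counting objective is flat wherever every inlier stays within the
#' threshold, so the branch-and-bound incumbent is only localized to within
#' `eps_r`; the consensus correspondences pin the rotation down.
#'
#' @param Xdir,Ydir matched unit direction matrices (rows correspond).
#' @return 3 x 3 rotation matrix.
#' @export
fit_rotation_pairs <- function(Xdir, Ydir) {
  Xdir <- as.matrix(Xdir); Ydir <- as.matrix(Ydir)
  stopifnot(nrow(Xdir) == nrow(Ydir), ncol(Xdir) == 3L, ncol(Ydir) == 3L,
            nrow(Xdir) >= 2L)
  B <- crossprod(Ydir, Xdir)  # sum_i y_i x_i^T
  sv <- svd(B)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}
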