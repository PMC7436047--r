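#' Translation consensus objective specification
#'
#' Packages the screened feature sets into the objective maximized by the
#' translation search: the number of moving features whose translated angle
#' triple `F(p, t)` comes within `eps_t` (Euclidean norm in angle-triple
#' space) of some reference feature triple.
#'
#' `match = "candidates"` restricts each moving feature to the reference
#' features it was screened against (its candidate pairs); `match = "all"`
#' matches against the whole of Q'. The candidate restriction gives the
#' same consensus at the true translation on clean data and a much more
#' selective objective elsewhere, which the branch and bound prunes far
#' faster; see the methods vignette.
#'
#' @param screen a [screen_pairs()] result.
#' @param eps_t inlier threshold, radians (Euclidean norm over the angle
#'   triple).
#' @param match `"candidates"` or `"all"`.
#' @return a list of class `translation_objective`.
#' @export
translation_objective <- function(screen, eps_t,
                                  match = c("candidates", "all")) {
  match <- match.arg(match)
  stopifnot(inherits(screen, "rsif_screen"), eps_t > 0)
  if (isTRUE(screen$empty))
    stop("empty screening result: no candidate feature pairs to match")
  qlist <- if (match == "candidates") screen$q_candidates else list()
  structure(list(Ppts = screen$P_points, Q = screen$Q_p, qlist = qlist,
                 eps_t = eps_t, match = match),
            class = "translation_objective")
}

#' Angle triple of a translated feature, F(p, t)
#'
#' The three pairwise angular distances of the feature's source points after
#' translating each by `t`. Components are `NA` when a translated point
#' falls at the origin (treated as a non-inlier by the objective).
#'
#' @param p an [build_rsif()] feature, or a 9-vector of triple coordinates.
#' @param t translation 3-vector.
#' @return numeric 3-vector of angles.
#' @export
eval_F <- function(p, t) {
  p9 <- if (inherits(p, "rsif")) as.numeric(t(p$points)) else as.numeric(p)
  stopifnot(length(p9) == 9L)
  cpp_eval_F(p9, as.numeric(t))
}

#' Evaluate the translation consensus objective at a point
#'
#' @param spec a [translation_objective()].
#' @param t translation 3-vector.
#' @return integer consensus count (each moving feature counted at most once).
#' @export
objective_Et <- function(spec, t) {
  stopifnot(inherits(spec, "translation_objective"))
  cpp_objective_Et(spec$Ppts, spec$Q, spec$qlist, as.numeric(t), spec$eps_t)
}

#' Uncertainty angle bound for a translated point over a cube
#'
#' The maximum angular deviation of `x + t` from `x + t0` over all `t` in a
#' cube centered at `t0` with half space diagonal `delta`:
#' `asin(delta / ||x + t0||)` when `delta <= ||x + t0||`, otherwise `pi`.
#'
#' @param x point 3-vector.
#' @param T a [cube()] in translation space.
#' @return angle in radians.
#' @export
beta_bound <- function(x, T) {
  stopifnot(inherits(T, "cube"))
  cpp_beta_bound(as.numeric(x), T$center, T$half_diagonal)
}

#' Guaranteed interval for an angular distance over a translation cube
#'
#' Bounds `angle(x1 + t, x2 + t)` for every `t` in the cube: the angle at
#' the cube center widened by the two uncertainty angle bounds, clamped to
#' `[0, pi]`.
#'
#' @param x1,x2 point 3-vectors.
#' @param T a [cube()].
#' @return numeric `c(lo, hi)`.
#' @export
angle_interval <- function(x1, x2, T) {
  stopifnot(inherits(T, "cube"))
  cpp_angle_interval(as.numeric(x1), as.numeric(x2), T$center, T$half_diagonal)
}

#' Lower bound on the feature distance over a translation cube
#'
#' Natural interval extension: per-component intervals of `F(p, t)` from
#' [angle_interval()], component gaps to the reference triple, and the norm
#' of the gap vector. Guaranteed to underestimate `||F(p, t) - q||` for all
#' `t` in the cube.
#'
#' @param p an [build_rsif()] feature or 9-vector of triple coordinates.
#' @param q reference angle triple (3-vector).
#' @param T a [cube()].
#' @return nonnegative lower bound.
#' @export
distance_lower_bound <- function(p, q, T) {
  stopifnot(inherits(T, "cube"))
  p9 <- if (inherits(p, "rsif")) as.numeric(t(p$points)) else as.numeric(p)
  cpp_distance_lower_bound(p9, as.numeric(q), T$center, T$half_diagonal)
}

#' Upper bound of the translation objective over a cube
#'
#' Counts the moving features whose distance lower bound to some admissible
#' reference feature is at most `eps_t`; at least `objective_Et(spec, t)`
#' for every `t` in the cube.
#'
#' @param spec a [translation_objective()].
#' @param T a [cube()].
#' @return integer upper bound.
#' @export
upper_bound_Et <- function(spec, T) {
  stopifnot(inherits(spec, "translation_objective"), inherits(T, "cube"))
  cpp_upper_bound_Et(spec$Ppts, spec$Q, spec$qlist, T$center, T$half_side,
                     spec$eps_t)
}

#' Globally optimal translation search (branch and bound)
#'
#' Best-first branch and bound over a cubic translation domain: cubes are
#' popped in order of decreasing upper bound (ties: larger cube first, then
#' insertion order), each popped cube's center is evaluated exactly to
#' update the incumbent, the cube is split into octants, and children whose
#' upper bound cannot beat the incumbent are pruned. Terminates with a
#' certificate when the best remaining upper bound no longer exceeds the
#' incumbent, or when cubes reach `min_half_side`.
#'
#' @param spec a [translation_objective()].
#' @param domain a [cube()] that must contain the true translation.
#' @param min_half_side resolution limit; cubes below it are not subdivided.
#' @param max_nodes node expansion budget.
#' @param time_limit seconds of CPU time before returning the incumbent
#'   flagged `timed_out`.
#' @return list with `t` (incumbent translation), `consensus`,
#'   `nodes_expanded`, `termination`, `remaining_upper_bound`, `timed_out`.
#' @export
bnb_translation <- function(spec, domain, min_half_side = 1e-3,
                            max_nodes = 1e7, time_limit = 1200) {
  stopifnot(inherits(spec, "translation_objective"), inherits(domain, "cube"))
  if (nrow(spec$Ppts) == 0L) stop("empty feature set: nothing to register")
  res <- cpp_bnb_translation(spec$Ppts, spec$Q, spec$qlist, domain$center,
                             domain$half_side, spec$eps_t, min_half_side,
                             max_nodes, time_limit)
  res$t <- as.numeric(res$t)
  res
}
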