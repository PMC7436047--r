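#' Rotation-and-scale-invariant features (RSIFs)
#'
#' An RSIF is built from an ordered triple of points: the angle triple `p`
#' of the pairwise angular distances between the three position vectors
#' (invariant to any common rotation and positive scaling about the origin),
#' and the difference-angle triple `g` of the pairwise angular distances
#' between the three difference vectors, which is additionally invariant to
#' common translation. Corresponding triples in two point sets related by a
#' similarity transform therefore carry identical `g` triples, which is what
#' the screening step matches.
#'
#' @param ps a [point_set()] or n x 3 matrix.
#' @param triple integer 3-vector of distinct row indices.
#' @param tol_norm positions/differences with norm below this are degenerate.
#' @param tol_collinear triples whose difference angles come within this of 0
#'   or pi are rejected as collinear.
#' @return a list of class `rsif` with fields `indices` (canonically
#'   ordered), `points` (3 x 3, rows in canonical order), `p`, `g`.
#' @export
build_rsif <- function(ps, triple, tol_norm = 1e-9, tol_collinear = 1e-3) {
  m <- if (inherits(ps, "point_set")) as_coord_matrix(ps) else as.matrix(ps)
  triple <- as.integer(triple)
  stopifnot(length(triple) == 3L)
  if (anyDuplicated(triple) || any(triple < 1L) || any(triple > nrow(m)))
    stop("triple must be three distinct valid row indices")
  f <- cpp_triple_features(m, matrix(triple, 1L, 3L), tol_norm, tol_collinear)
  if (!f$ok[1L])
    stop("degenerate triple: zero-norm vector or collinear points")
  idx <- as.integer(f$idx[1L, ])
  structure(list(indices = idx, points = m[idx, , drop = FALSE],
                 p = as.numeric(f$p[1L, ]), g = as.numeric(f$g[1L, ])),
            class = "rsif")
}

#' Canonical ordering of a point triple
#'
#' Orders the three points so that the side lengths opposite each point are
#' ascending; exact ties are broken by the sorted adjacent side lengths and
#' then by original position. The ordering is invariant under any similarity
#' transform of the triple, so corresponding triples in two sets produce
#' component-wise comparable features.
#'
#' @param pts 3 x 3 matrix, one point per row.
#' @return the permutation (integer 3-vector) such that `pts[perm, ]` is
#'   canonically ordered.
#' @export
canonical_order <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(all(dim(pts) == c(3L, 3L)))
  f <- cpp_triple_features(pts, matrix(1:3, 1L, 3L), 0, 0)
  as.integer(f$idx[1L, ])
}

#' Enumerate (or sample) index triples of a point set
#'
#' All `choose(n, 3)` combinations when that count is at most `cap`,
#' otherwise a uniform random sample of `cap` distinct combinations drawn
#' with the given seed. Triples are returned in ascending index order;
#' degenerate triples (zero-norm position or difference vectors, collinear
#' points) are dropped.
#'
#' @param ps a [point_set()] or n x 3 matrix with at least 3 rows.
#' @param cap maximum number of triples to enumerate.
#' @param seed integer seed for the sampling branch (ignored when
#'   enumerating exhaustively); `NULL` uses the current RNG state.
#' @inheritParams build_rsif
#' @return integer matrix with 3 columns of row indices.
#' @export
enumerate_triples <- function(ps, cap = 2e6, seed = NULL,
                              tol_norm = 1e-9, tol_collinear = 1e-3) {
  m <- if (inherits(ps, "point_set")) as_coord_matrix(ps) else as.matrix(ps)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 points to form triples, got ", n)
  tri <- with_seed(seed, cpp_enumerate_triples(n, cap))
  f <- cpp_triple_features(m, tri, tol_norm, tol_collinear)
  tri[f$ok, , drop = FALSE]
}

#' Build and rank RSIFs, keeping the top k
#'
#' Enumerates (or samples, above `cap`) the point triples of `ps`, builds an
#' RSIF from each non-degenerate triple, ranks them by the sum of the three
#' difference-angle components, and keeps the `k` best. The ranking score is
#' invariant to any similarity transform of the source points, so the same
#' triples rise to the top in two sets related by an unknown transform.
#'
#' @inheritParams enumerate_triples
#' @param k number of features to keep (default 300).
#' @return a list of class `rsif_set`: `idx` (k x 3 canonical indices),
#'   `p`, `g` (k x 3 angle matrices), `score`, `points` (k x 9 coordinates of
#'   the canonical triples), plus enumeration counters.
#' @export
rsif_top_k <- function(ps, k = 300, cap = 2e6, seed = NULL,
                       tol_norm = 1e-9, tol_collinear = 1e-3) {
  m <- if (inherits(ps, "point_set")) as_coord_matrix(ps) else as.matrix(ps)
  if (nrow(m) < 3L) stop("need at least 3 points, got ", nrow(m))
  stopifnot(k >= 1)
  res <- with_seed(seed, cpp_rsif_topk(m, cap, as.integer(k), tol_norm,
                                       tol_collinear))
  pts <- cbind(m[res$idx[, 1L], , drop = FALSE],
               m[res$idx[, 2L], , drop = FALSE],
               m[res$idx[, 3L], , drop = FALSE])
  structure(list(idx = res$idx, p = res$p, g = res$g, score = res$score,
                 points = pts, n_enumerated = res$n_enumerated,
                 n_nondegenerate = res$n_nondegenerate),
            class = "rsif_set")
}

#' @export
print.rsif_set <- function(x, ...) {
  cat(sprintf("<rsif_set> %d features (from %d enumerated, %d non-degenerate triples)\n",
              nrow(x$idx), x$n_enumerated, x$n_nondegenerate))
  invisible(x)
}

#' Screen candidate feature pairs between two ranked RSIF sets
#'
#' A pair (p, q) is a candidate when the Euclidean distance between their
#' translation-invariant difference-angle triples is at most `eps_f`. The
#' matched subsets P' and Q' are the features appearing in at least one
#' candidate pair.
#'
#' @param P1,Q1 [rsif_top_k()] results for the moving and reference set.
#' @param eps_f screening threshold, radians (Euclidean norm in
#'   angle-triple space).
#' @return a list of class `rsif_screen`: `P_prime`, `Q_prime` (row indices
#'   into P1/Q1), `pairs` (two-column matrix of candidate pairs, indices
#'   into `P_prime`/`Q_prime`), and the subsetted feature data.
#' @export
screen_pairs <- function(P1, Q1, eps_f) {
  stopifnot(inherits(P1, "rsif_set"), inherits(Q1, "rsif_set"), eps_f > 0)
  raw <- cpp_screen_pairs(P1$g, Q1$g, eps_f)
  if (nrow(raw) == 0L) {
    return(structure(list(P_prime = integer(0), Q_prime = integer(0),
                          pairs = raw, P_points = NULL, Q_p = NULL,
                          q_candidates = list(), empty = TRUE),
                     class = "rsif_screen"))
  }
  P_keep <- sort(unique(raw[, 1L]))
  Q_keep <- sort(unique(raw[, 2L]))
  # reindex pairs into the kept subsets
  pairs <- cbind(match(raw[, 1L], P_keep), match(raw[, 2L], Q_keep))
  q_candidates <- split(pairs[, 2L], factor(pairs[, 1L], levels = seq_along(P_keep)))
  q_candidates <- lapply(q_candidates, function(v) as.integer(sort(unique(v))))
  structure(list(P_prime = P_keep, Q_prime = Q_keep, pairs = pairs,
                 P_points = P1$points[P_keep, , drop = FALSE],
                 Q_p = Q1$p[Q_keep, , drop = FALSE],
                 q_candidates = q_candidates, empty = FALSE),
            class = "rsif_screen")
}

#' @export
print.rsif_screen <- function(x, ...) {
  if (isTRUE(x$empty)) cat("<rsif_screen> empty: no candidate pairs\n")
  else cat(sprintf("<rsif_screen> |P'|=%d |Q'|=%d, %d candidate pairs\n",
                   length(x$P_prime), length(x$Q_prime), nrow(x$pairs)))
  invisible(x)
}

# run expr under a temporary seed, restoring the RNG state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
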