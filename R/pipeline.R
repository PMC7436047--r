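#' Registration configuration
#'
#' Collects every tunable of the decomposed registration. The three inlier
#' thresholds are given in degrees and converted to radians internally:
#' `eps_f` and `eps_t` bound Euclidean norms over angle triples (so
#' `eps_t = 1` means a 1-degree norm in angle-triple space), `eps_r` bounds
#' a single angular distance.
#'
#' @param eps_f RSIF screening threshold, degrees (default 0.01).
#' @param eps_t translation search inlier threshold, degrees (default 1).
#' @param eps_r rotation search inlier threshold, degrees (default 10).
#' @param k_top number of top-ranked RSIFs kept per set (default 300).
#' @param triple_cap maximum triples enumerated per set; above it a seeded
#'   uniform sample is drawn.
#' @param domain_half_side half side of the cubic translation search
#'   domain; `NULL` selects `2 * max(||x_i||)` from the moving set.
#' @param min_half_side_t,min_half_side_r branch-and-bound resolution
#'   limits (translation units / radians).
#' @param match_mode `"candidates"` restricts translation matching to the
#'   screened candidate pairs, `"all"` matches against all of Q'.
#' @param refine_rotation refine the rotation incumbent with a closed-form
#'   fit on the consensus correspondences (see [fit_rotation_pairs()]).
#' @param verify_rotation accept a consensus-optimal rotation only when the
#'   median inlier residual is below `verify_tol`; on rejection the search
#'   is restarted with the rejected basin excluded (the counting objective
#'   can have exactly tied optima, and the residual picks the genuine
#'   alignment among them).
#' @param verify_tol residual acceptance threshold, radians; `NULL` uses
#'   `eps_r / 4`.
#' @param max_restarts rotation-search restarts before giving up and
#'   keeping the first (highest-consensus) candidate.
#' @param scale_pairs `"consensus"` uses only pairs within `eps_r` for the
#'   scale median, `"all"` uses every nearest-angle pair.
#' @param time_limit total runtime budget in seconds, enforced
#'   cooperatively between branch-and-bound node expansions.
#' @param consensus_floor minimum translation-stage consensus, as a
#'   fraction of the ranked feature count, below which the result is
#'   flagged unreliable (no-hallucination guard for unrelated inputs).
#' @param seed integer seed driving triple sampling.
#' @return a list of class `registration_config` (angles stored in radians).
#' @export
registration_config <- function(eps_f = 0.01, eps_t = 1, eps_r = 10,
                                k_top = 300, triple_cap = 2e6,
                                domain_half_side = NULL,
                                min_half_side_t = 1e-3,
                                min_half_side_r = 0.01,
                                match_mode = c("candidates", "all"),
                                refine_rotation = TRUE,
                                verify_rotation = TRUE,
                                verify_tol = NULL,
                                max_restarts = 4L,
                                scale_pairs = c("consensus", "all"),
                                time_limit = 1200,
                                consensus_floor = 0.05,
                                seed = 1L) {
  match_mode <- match.arg(match_mode)
  scale_pairs <- match.arg(scale_pairs)
  stopifnot(eps_f > 0, eps_t > 0, eps_r > 0, k_top >= 1, triple_cap >= 1,
            min_half_side_t > 0, min_half_side_r > 0, time_limit > 0)
  structure(list(eps_f = deg2rad(eps_f), eps_t = deg2rad(eps_t),
                 eps_r = deg2rad(eps_r), eps_f_deg = eps_f,
                 eps_t_deg = eps_t, eps_r_deg = eps_r,
                 k_top = as.integer(k_top), triple_cap = triple_cap,
                 domain_half_side = domain_half_side,
                 min_half_side_t = min_half_side_t,
                 min_half_side_r = min_half_side_r,
                 match_mode = match_mode,
                 refine_rotation = isTRUE(refine_rotation),
                 verify_rotation = isTRUE(verify_rotation),
                 verify_tol = verify_tol,
                 max_restarts = as.integer(max_restarts),
                 scale_pairs = scale_pairs,
                 time_limit = time_limit,
                 consensus_floor = consensus_floor,
                 seed = as.integer(seed)),
            class = "registration_config")
}

#' Estimate the scale factor from correspondences
#'
#' For each moving point (already translated and rotated), the angularly
#' nearest reference point is taken as its correspondence; pairs with
#' angular distance above `eps_r` are discarded (the consensus
#' restriction). Each retained pair contributes the ratio of reference to
#' moving norm, and the estimate is the median of the ratios (mean of the
#' middle two for an even count). Rotation preserves norms, so the moving
#' norm is computed on `x + t` directly.
#'
#' @param X_rot moving points after translation and rotation
#'   ([point_set()] or matrix).
#' @param Y reference points.
#' @param eps_r angular threshold for retaining pairs, radians; `Inf`
#'   retains every nearest-angle pair.
#' @param tol_norm points with norm below this are skipped.
#' @return list with `s` (the median ratio), `pairs` (retained index
#'   pairs), `ratios`.
#' @export
estimate_scale <- function(X_rot, Y, eps_r = Inf, tol_norm = 1e-9) {
  Xm <- if (inherits(X_rot, "point_set")) as_coord_matrix(X_rot) else as.matrix(X_rot)
  Ym <- if (inherits(Y, "point_set")) as_coord_matrix(Y) else as.matrix(Y)
  if (nrow(Xm) == 0L || nrow(Ym) == 0L) stop("empty point set")
  ux <- unit_directions(Xm, tol_norm)
  uy <- unit_directions(Ym, tol_norm)
  if (nrow(ux$dirs) == 0L || nrow(uy$dirs) == 0L)
    stop("no usable directions for scale estimation")
  nn <- cpp_nearest_angular(ux$dirs, uy$dirs, c(0, 0, 0))
  keep <- which(nn$angle <= eps_r)
  if (length(keep) == 0L)
    stop("scale estimation failed: no correspondence within the angular threshold")
  i <- ux$keep[keep]
  j <- uy$keep[nn$j[keep]]
  ratios <- sqrt(rowSums(Ym[j, , drop = FALSE]^2)) /
    sqrt(rowSums(Xm[i, , drop = FALSE]^2))
  list(s = stats::median(ratios), pairs = cbind(moving = i, reference = j),
       ratios = ratios)
}

#' Decomposed similarity registration of two 3D point sets
#'
#' Runs the full decomposition: RSIF construction and screening, global
#' translation search by branch and bound, global rotation search by branch
#' and bound on the translated points, and scale estimation by median of
#' correspondence norm ratios. No initialization or correspondences are
#' required.
#'
#' @param X moving [point_set()] (or n x 3 matrix), at least 3 points.
#' @param Y reference point set, at least 3 points.
#' @param config a [registration_config()].
#' @param ground_truth optional [similarity_transform()]; when supplied the
#'   result carries rotation/translation/scale errors and the success flag
#'   (rotation error < 0.1 rad, relative translation error < 0.1, absolute
#'   scale error < 0.1).
#' @param success_thresholds named list overriding the three success
#'   thresholds (`rotation`, `translation`, `scale`).
#' @return an object of class `registration_result`: `transform`, stage
#'   consensus counts and diagnostics, and (with ground truth) the error
#'   fields and `success`.
#' @export
register_point_sets <- function(X, Y, config = registration_config(),
                                ground_truth = NULL,
                                success_thresholds = list(rotation = 0.1,
                                                          translation = 0.1,
                                                          scale = 0.1)) {
  stopifnot(inherits(config, "registration_config"))
  Xm <- if (inherits(X, "point_set")) as_coord_matrix(X) else as.matrix(X)
  Ym <- if (inherits(Y, "point_set")) as_coord_matrix(Y) else as.matrix(Y)
  if (nrow(Xm) < 3L || nrow(Ym) < 3L)
    stop("registration needs at least 3 points in each set")
  t0 <- proc.time()[["elapsed"]]

  # Stage 1: features + screening
  P1 <- rsif_top_k(Xm, k = config$k_top, cap = config$triple_cap,
                   seed = config$seed)
  Q1 <- rsif_top_k(Ym, k = config$k_top, cap = config$triple_cap,
                   seed = config$seed + 1L)
  scr <- screen_pairs(P1, Q1, config$eps_f)
  if (isTRUE(scr$empty))
    stop("registration failed at screening: no feature pair within eps_f")

  # Stage 2: translation BnB
  hs <- config$domain_half_side
  if (is.null(hs)) hs <- 2 * max(sqrt(rowSums(Xm^2)))
  domain <- cube(c(0, 0, 0), hs)
  spec_t <- translation_objective(scr, config$eps_t, match = config$match_mode)
  budget <- function() max(1, config$time_limit - (proc.time()[["elapsed"]] - t0))
  tr <- bnb_translation(spec_t, domain, min_half_side = config$min_half_side_t,
                        time_limit = budget())
  t_star <- tr$t

  # Stage 3: rotation BnB on the translated moving set. The consensus can
  # be exactly tied between the genuine alignment and coincidental covers
  # (every moving direction within eps_r of *some* reference direction),
  # so candidates are verified by their median inlier residual and the
  # search restarts with rejected basins excluded.
  X_star <- Xm + matrix(t_star, nrow(Xm), 3L, byrow = TRUE)
  spec_r <- rotation_objective(X_star, Ym, config$eps_r)
  verify_tol <- if (is.null(config$verify_tol)) config$eps_r / 4 else config$verify_tol
  excluded <- NULL
  first <- NULL
  verified <- FALSE
  repeat {
    ro <- bnb_rotation(spec_r, min_half_side = config$min_half_side_r,
                       time_limit = budget(), exclude = excluded)
    R_star <- ro$R
    r_star <- ro$r
    if (config$refine_rotation && nrow(ro$inlier_pairs) >= 3L) {
      ref <- refine_rotation(spec_r, ro$r)
      R_star <- ref$R
      r_star <- ref$r
    }
    nn <- cpp_nearest_angular(spec_r$Xdir, spec_r$Ydir, r_star)
    resid <- nn$angle[nn$angle <= spec_r$eps_r]
    if (is.null(first)) first <- list(ro = ro, R = R_star)
    if (!config$verify_rotation ||
        (length(resid) >= 3L && stats::median(resid) <= verify_tol)) {
      verified <- TRUE
      break
    }
    if (ro$consensus <= 0 ||
        NROW(excluded) >= config$max_restarts || isTRUE(ro$timed_out)) {
      # no acceptable basin found: keep the first (highest-consensus) one
      ro <- first$ro
      R_star <- first$R
      break
    }
    excluded <- rbind(excluded, r_star)
  }

  # Stage 4: scale by median of correspondence norm ratios
  X_rot <- X_star %*% t(R_star)
  eps_sc <- if (config$scale_pairs == "consensus") config$eps_r else Inf
  sc <- estimate_scale(X_rot, Ym, eps_r = eps_sc)

  transform <- similarity_transform(s = sc$s, rotation = R_star,
                                    t_pre = t_star)
  # sanity floor: consensus is judged against the number of ranked features,
  # not the screened subset, so a near-empty screening cannot look confident
  n_ranked <- min(config$k_top, nrow(P1$idx), nrow(Q1$idx))
  reliable <- tr$consensus >= max(3, config$consensus_floor * n_ranked) &&
    !isTRUE(tr$timed_out) && !isTRUE(ro$timed_out) &&
    (verified || !config$verify_rotation)

  res <- list(transform = transform,
              translation_consensus = tr$consensus,
              rotation_consensus = ro$consensus,
              n_features = nrow(spec_t$Ppts),
              n_scale_pairs = nrow(sc$pairs),
              reliable = reliable,
              diagnostics = list(
                translation = tr[c("nodes_expanded", "termination",
                                   "remaining_upper_bound", "timed_out")],
                rotation = c(ro[c("nodes_expanded", "termination",
                                  "remaining_upper_bound", "timed_out")],
                             list(verified = verified,
                                  n_restarts = NROW(excluded))),
                screen = list(n_P_prime = length(scr$P_prime),
                              n_Q_prime = length(scr$Q_prime),
                              n_pairs = nrow(scr$pairs)),
                elapsed = proc.time()[["elapsed"]] - t0))
  if (!is.null(ground_truth)) {
    res <- c(res, evaluate_success(transform, ground_truth,
                                   thresholds = success_thresholds))
  }
  class(res) <- "registration_result"
  res
}

#' Compare an estimated transform against ground truth
#'
#' Errors follow the benchmark success criterion: geodesic rotation error,
#' translation error relative to the ground-truth norm (both in the
#' pre-rotation parameterization `y = s R (x + t)`), and absolute scale
#' error. Success requires all three below their thresholds.
#'
#' @param estimate,truth [similarity_transform()] objects.
#' @param thresholds named list: `rotation` (radians), `translation`
#'   (relative), `scale` (absolute).
#' @return list with `rotation_error_rad`, `translation_rel_error`,
#'   `scale_abs_error`, `success`.
#' @export
evaluate_success <- function(estimate, truth,
                             thresholds = list(rotation = 0.1,
                                               translation = 0.1,
                                               scale = 0.1)) {
  stopifnot(inherits(estimate, "similarity_transform"),
            inherits(truth, "similarity_transform"))
  re <- rotation_error(estimate$R, truth$R)
  te <- sqrt(sum((estimate$t_pre - truth$t_pre)^2)) /
    sqrt(sum(truth$t_pre^2))
  se <- abs(estimate$s - truth$s)
  list(rotation_error_rad = re, translation_rel_error = te,
       scale_abs_error = se,
       success = re < thresholds$rotation && te < thresholds$translation &&
         se < thresholds$scale)
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n")
  cat(sprintf("  consensus: translation %d/%d features, rotation %d points, %d scale pairs\n",
              x$translation_consensus, x$n_features, x$rotation_consensus,
              x$n_scale_pairs))
  cat(sprintf("  s = %.4f, |angle| = %.4f rad, t_pre = (%.4f, %.4f, %.4f)\n",
              x$transform$s, sqrt(sum(x$transform$axis_angle^2)),
              x$transform$t_pre[1], x$transform$t_pre[2], x$transform$t_pre[3]))
  if (!is.null(x$success))
    cat(sprintf("  vs truth: rot %.4f rad, trans rel %.4f, scale abs %.4f -> %s\n",
                x$rotation_error_rad, x$translation_rel_error,
                x$scale_abs_error, if (x$success) "SUCCESS" else "FAILURE"))
  if (!x$reliable) cat("  [flagged unreliable: low consensus or timeout]\n")
  invisible(x)
}

#' Target registration error
#'
#' Euclidean distance between each transformed moving landmark and its
#' paired reference landmark, with mean and standard deviation.
#'
#' @param tf a [similarity_transform()].
#' @param targets_moving,targets_reference paired landmark matrices
#'   (k x 3, equal row counts).
#' @return list with `tre` (per-target), `mean`, `sd`.
#' @export
target_registration_error <- function(tf, targets_moving, targets_reference) {
  A <- as.matrix(targets_moving)
  B <- as.matrix(targets_reference)
  if (nrow(A) != nrow(B)) stop("target lists differ in length")
  if (nrow(A) == 0L) stop("no targets supplied")
  mapped <- apply_transform(tf, A)
  tre <- sqrt(rowSums((mapped - B)^2))
  list(tre = tre, mean = mean(tre),
       sd = if (length(tre) > 1L) stats::sd(tre) else 0)
}

#' Serialize a transform or registration result to JSON
#'
#' @param x a [similarity_transform()] or `registration_result`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
transform_to_json <- function(x, path = NULL) {
  if (inherits(x, "registration_result")) {
    payload <- list(transform = transform_payload(x$transform),
                    translation_consensus = x$translation_consensus,
                    rotation_consensus = x$rotation_consensus,
                    n_scale_pairs = x$n_scale_pairs,
                    reliable = x$reliable)
    for (f in c("rotation_error_rad", "translation_rel_error",
                "scale_abs_error", "success"))
      if (!is.null(x[[f]])) payload[[f]] <- x[[f]]
  } else if (inherits(x, "similarity_transform")) {
    payload <- transform_payload(x)
  } else stop("cannot serialize object of class ", class(x)[1L])
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

transform_payload <- function(tf) {
  list(scale = tf$s, axis_angle = tf$axis_angle,
       rotation_matrix = unclass(tf$R), t_pre = tf$t_pre,
       t_canonical = tf$t_canonical)
}
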