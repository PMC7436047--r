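# Shared fixture builders. Everything is generated in code; tests derive all
# randomness from explicit seeds.

# internal compiled bindings exercised directly by the bound-soundness tests
cpp_beta_bound <- rsifreg:::cpp_beta_bound
cpp_angle_interval <- rsifreg:::cpp_angle_interval
cpp_distance_lower_bound <- rsifreg:::cpp_distance_lower_bound
cpp_upper_bound_Et <- rsifreg:::cpp_upper_bound_Et
cpp_objective_Er <- rsifreg:::cpp_objective_Er
cpp_upper_bound_Er <- rsifreg:::cpp_upper_bound_Er

# uniform random rotation matrix (unit quaternion), independent of the
# package's internal sampler so it can serve as an oracle
rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# angular distance oracle in plain R
ang_ref <- function(u, v) {
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

# clean moving/reference pair with a known similarity transform
make_clean_pair <- function(n = 50, seed = 1, s = NULL, t_pre = NULL) {
  set.seed(seed)
  X <- matrix(runif(3 * n, -1, 1), n, 3)
  R <- rand_rotation()
  if (is.null(s)) s <- runif(1, 1, 5)
  if (is.null(t_pre)) t_pre <- runif(3, -0.5, 0.5)
  gt <- similarity_transform(s = s, rotation = R, t_pre = t_pre)
  list(X = X, Y = unclass(apply_transform(gt, point_set(X))), gt = gt)
}

# screened translation objective for a clean pair (small n)
make_translation_spec <- function(pair, eps_t = deg(1), k = 50,
                                  match = "candidates") {
  P1 <- rsif_top_k(pair$X, k = k, seed = 11)
  Q1 <- rsif_top_k(pair$Y, k = k, seed = 12)
  scr <- screen_pairs(P1, Q1, deg(0.01))
  translation_objective(scr, eps_t, match = match)
}

deg <- function(x) x * pi / 180
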