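test_that("F(p, t) reproduces the angle triple of the translated points", {
  pair <- make_clean_pair(n = 10, seed = 2)
  f <- build_rsif(pair$X, c(1, 4, 7))
  # t = 0 reproduces p
  expect_equal(eval_F(f, c(0, 0, 0)), f$p, tolerance = 1e-12)
  # at the true translation, F(p, t) equals the corresponding reference triple
  q <- build_rsif(pair$Y, f$indices)
  expect_equal(sort(eval_F(f, pair$gt$t_pre)), sort(q$p), tolerance = 1e-9)
  # agrees with rebuilding the feature on explicitly translated points
  t_arb <- c(0.3, -0.2, 0.15)
  shifted <- pair$X + matrix(t_arb, nrow(pair$X), 3, byrow = TRUE)
  f_shift <- build_rsif(shifted, f$indices)
  expect_equal(sort(eval_F(f, t_arb)), sort(f_shift$p), tolerance = 1e-12)
})

test_that("translation consensus counts each feature once and matches brute force", {
  pair <- make_clean_pair(n = 30, seed = 4)
  spec <- make_translation_spec(pair, k = 30)
  M <- nrow(spec$Ppts)
  expect_equal(objective_Et(spec, pair$gt$t_pre), M)  # all inliers at truth
  # brute-force double loop oracle at arbitrary translations
  set.seed(9)
  for (i in 1:5) {
    t_try <- runif(3, -0.6, 0.6)
    cnt <- 0L
    for (m in seq_len(M)) {
      fm <- eval_F(spec$Ppts[m, ], t_try)
      qs <- spec$Q[spec$qlist[[m]], , drop = FALSE]
      d2 <- (qs[, 1] - fm[1])^2 + (qs[, 2] - fm[2])^2 + (qs[, 3] - fm[3])^2
      if (any(!is.na(d2) & d2 <= spec$eps_t^2)) cnt <- cnt + 1L
    }
    expect_identical(objective_Et(spec, t_try), cnt)
  }
  # vanishing threshold at a wrong translation: no consensus
  spec0 <- make_translation_spec(pair, eps_t = 1e-12, k = 30)
  expect_equal(objective_Et(spec0, c(0.31, 0.17, -0.23)), 0L)
})

test_that("uncertainty angle bound follows its closed form", {
  Tcube <- function(hs, center = c(0, 0, 0)) cube(center, hs)
  # ||x + t0|| = 1, delta = 0.5 -> asin(0.5)
  cb <- cube(c(0, 0, 0), 0.5 / sqrt(3))
  expect_equal(beta_bound(c(1, 0, 0), cb), pi / 6, tolerance = 1e-12)
  # delta > ||x + t0||: the bound saturates at pi
  cb2 <- cube(c(0, 0, 0), 2)
  expect_equal(beta_bound(c(0.1, 0, 0), cb2), pi)
  # zero-size cube: no deviation
  expect_equal(cpp_beta_bound(c(1, 2, 3), c(0, 0, 0), 0), 0)
})

test_that("angle intervals contain the translated angle for all t in the cube", {
  # zero-size cube collapses to the center angle
  x1 <- c(0.5, 0.1, -0.3); x2 <- c(-0.2, 0.8, 0.4); t0 <- c(0.1, 0.2, -0.1)
  ctr <- ang_ref(x1 + t0, x2 + t0)
  iv0 <- cpp_angle_interval(x1, x2, t0, 0)
  expect_equal(iv0, c(ctr, ctr), tolerance = 1e-12)
  # beta sum >= pi clamps to [0, pi]
  ivb <- angle_interval(c(0.05, 0, 0), c(0, 0.05, 0), cube(c(0, 0, 0), 1))
  expect_equal(ivb, c(0, pi))
  # Monte-Carlo containment audit
  set.seed(123)
  viol <- 0L
  for (i in 1:10000) {
    x1 <- runif(3, -1, 1); x2 <- runif(3, -1, 1)
    t0 <- runif(3, -1, 1); hs <- runif(1, 0.01, 0.8)
    tt <- t0 + runif(3, -hs, hs)
    a <- tryCatch(ang_ref(x1 + tt, x2 + tt), error = function(e) NA)
    if (is.na(a)) next
    iv <- cpp_angle_interval(x1, x2, t0, hs * sqrt(3))
    if (a < iv[1] - 1e-12 || a > iv[2] + 1e-12) viol <- viol + 1L
  }
  expect_identical(viol, 0L)
})

test_that("feature-distance lower bound never exceeds the true distance", {
  pair <- make_clean_pair(n = 8, seed = 6)
  f <- build_rsif(pair$X, c(1, 3, 5))
  p9 <- as.numeric(t(f$points))
  # q inside the interval box -> bound 0
  cb <- cube(c(0, 0, 0), 0.1)
  expect_equal(distance_lower_bound(f, eval_F(f, c(0.02, -0.03, 0.01)), cb), 0)
  # single displaced component: gap equals the displacement
  iv <- rbind(cpp_angle_interval(p9[1:3], p9[4:6], c(0, 0, 0), 0.1 * sqrt(3)),
              cpp_angle_interval(p9[1:3], p9[7:9], c(0, 0, 0), 0.1 * sqrt(3)),
              cpp_angle_interval(p9[4:6], p9[7:9], c(0, 0, 0), 0.1 * sqrt(3)))
  q <- c(iv[1, 2] + 0.2, mean(iv[2, ]), mean(iv[3, ]))
  expect_equal(distance_lower_bound(f, q, cb), 0.2, tolerance = 1e-12)
  # Monte-Carlo soundness: bound <= D(t) for sampled t in the cube
  set.seed(77)
  viol <- 0L
  for (i in 1:10000) {
    t0 <- runif(3, -0.5, 0.5); hs <- runif(1, 0.01, 0.5)
    q <- runif(3, 0, pi)
    tt <- t0 + runif(3, -hs, hs)
    ft <- eval_F(f, tt)
    if (any(is.na(ft))) next
    d_true <- sqrt(sum((ft - q)^2))
    lb <- cpp_distance_lower_bound(p9, q, t0, hs * sqrt(3))
    if (lb > d_true + 1e-12) viol <- viol + 1L
  }
  expect_identical(viol, 0L)
})

test_that("the cube upper bound dominates the objective", {
  pair <- make_clean_pair(n = 25, seed = 14)
  spec <- make_translation_spec(pair, k = 25)
  M <- nrow(spec$Ppts)
  # degenerate cube: bound equals the exact objective at the center
  for (t0 in list(c(0, 0, 0), pair$gt$t_pre, c(0.3, -0.1, 0.2))) {
    expect_equal(cpp_upper_bound_Et(spec$Ppts, spec$Q, spec$qlist, t0, 0,
                                    spec$eps_t),
                 objective_Et(spec, t0))
  }
  # a cube containing the truth attains the maximum on clean data
  cb <- cube(round(pair$gt$t_pre, 1), 0.2)
  expect_equal(upper_bound_Et(spec, cb), M)
  # bound >= grid max inside random cubes
  set.seed(15)
  for (i in 1:5) {
    ctr <- runif(3, -0.4, 0.4); hs <- runif(1, 0.05, 0.3)
    cb <- cube(ctr, hs)
    ub <- upper_bound_Et(spec, cb)
    g <- seq(-hs, hs, length.out = 5)
    vals <- sapply(g, function(a) sapply(g, function(b) sapply(g, function(c)
      objective_Et(spec, ctr + c(a, b, c)))))
    expect_gte(ub, max(vals))
  }
})

test_that("translation BnB recovers the truth on clean data with a certificate", {
  pair <- make_clean_pair(n = 100, seed = 19)
  spec <- make_translation_spec(pair, k = 100)
  res <- bnb_translation(spec, cube(c(0, 0, 0), 1))
  expect_equal(res$consensus, nrow(spec$Ppts))
  expect_lt(sqrt(sum((res$t - pair$gt$t_pre)^2)), 0.05)
  expect_match(res$termination, "gap_closed|resolution_reached|queue_exhausted")
  expect_false(res$timed_out)
})

test_that("a single feature pair yields consensus one", {
  pair <- make_clean_pair(n = 4, seed = 23, t_pre = c(0.2, -0.1, 0.3))
  P1 <- rsif_top_k(pair$X, k = 1)
  Q1 <- rsif_top_k(pair$Y, k = 1)
  scr <- screen_pairs(P1, Q1, deg(0.01))
  expect_false(scr$empty)
  spec <- translation_objective(scr, deg(1))
  res <- bnb_translation(spec, cube(c(0, 0, 0), 0.6))
  expect_equal(res$consensus, 1L)
})
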