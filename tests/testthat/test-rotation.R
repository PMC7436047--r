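test_that("rotation consensus is exact at the truth, scale-free, and matches brute force", {
  set.seed(33)
  X <- matrix(runif(3 * 40, -1, 1), 40, 3)
  R_gt <- rand_rotation()
  scales <- runif(40, 0.5, 4)           # arbitrary per-point positive scaling
  Y <- (X %*% t(R_gt)) * scales
  spec <- rotation_objective(X, Y, deg(10))
  expect_equal(objective_Er(spec, R_gt), 40L)
  # global rescaling leaves the count unchanged exactly
  spec2 <- rotation_objective(X, Y * 7.3, deg(10))
  r_try <- matrix_to_axis_angle(rand_rotation())
  expect_identical(objective_Er(spec, r_try), objective_Er(spec2, r_try))
  # brute-force double loop oracle
  for (i in 1:5) {
    r <- runif(3, -1, 1)
    Rm <- axis_angle_to_matrix(r)
    Zd <- spec$Xdir %*% t(Rm)
    cnt <- sum(apply(Zd %*% t(spec$Ydir), 1,
                     function(d) any(acos(pmin(1, pmax(-1, d))) <= spec$eps_r)))
    expect_identical(objective_Er(spec, r), as.integer(cnt))
  }
  # vanishing threshold at a random rotation: zero consensus (generic data)
  spec0 <- rotation_objective(X, Y, 1e-12)
  expect_equal(objective_Er(spec0, c(1.1, -0.7, 0.4)), 0L)
})

test_that("rotation cube uncertainty bound is sound", {
  expect_equal(mu_bound(cube(c(0, 0, 0), pi)), pi)  # initial cube clamps
  expect_equal(mu_bound(cube(c(0.1, 0.1, 0.1), 0.2)), 0.2 * sqrt(3),
               tolerance = 1e-12)
  expect_equal(cpp_upper_bound_Er(diag(3), diag(3), c(0, 0, 0), 0, deg(10)),
               cpp_objective_Er(diag(3), diag(3), c(0, 0, 0), deg(10)))
  # audit of the per-vector rotation bounds on random draws
  set.seed(44)
  viol_pair <- 0L; viol_cube <- 0L
  for (i in 1:10000) {
    a <- runif(3, -pi, pi) * runif(1)
    b <- a + runif(3, -0.5, 0.5)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    Ra <- axis_angle_to_matrix(a)
    Rb <- axis_angle_to_matrix(b)
    # angle(R_a u, R_b u) <= ||a - b||
    if (ang_ref(Ra %*% u, Rb %*% u) > sqrt(sum((a - b)^2)) + 1e-9)
      viol_pair <- viol_pair + 1L
    # cube version: center c, any a in the cube, bound mu_B
    hs <- runif(1, 0.01, 0.6)
    ctr <- runif(3, -1, 1)
    aa <- ctr + runif(3, -hs, hs)
    mu <- min(hs * sqrt(3), pi)
    if (ang_ref(axis_angle_to_matrix(ctr) %*% u,
                axis_angle_to_matrix(aa) %*% u) > mu + 1e-9)
      viol_cube <- viol_cube + 1L
  }
  expect_identical(viol_pair, 0L)
  expect_identical(viol_cube, 0L)
})

test_that("the relaxed-threshold upper bound dominates the objective on cubes", {
  set.seed(55)
  X <- matrix(runif(3 * 30, -1, 1), 30, 3)
  R_gt <- rand_rotation()
  Y <- (X %*% t(R_gt)) * 2.5
  spec <- rotation_objective(X, Y, deg(10))
  r_gt <- matrix_to_axis_angle(R_gt)
  # cube containing the truth attains full consensus
  cb <- cube(round(r_gt, 1), 0.2)
  expect_equal(upper_bound_Er(spec, cb), 30L)
  # bound >= sampled objective values inside random cubes
  for (i in 1:5) {
    ctr <- runif(3, -2, 2); hs <- runif(1, 0.05, 0.5)
    ub <- upper_bound_Er(spec, cube(ctr, hs))
    g <- seq(-hs, hs, length.out = 4)
    vals <- sapply(g, function(a) sapply(g, function(b) sapply(g, function(c)
      objective_Er(spec, ctr + c(a, b, c)))))
    expect_gte(ub, max(vals))
  }
})

test_that("rotation BnB recovers a known rotation with full consensus", {
  set.seed(66)
  X <- matrix(runif(3 * 100, -1, 1), 100, 3)
  R_gt <- rand_rotation()
  Y <- (X %*% t(R_gt)) * 3.1
  spec <- rotation_objective(X, Y, deg(10))
  res <- bnb_rotation(spec)
  expect_equal(res$consensus, 100L)
  expect_lt(rotation_error(res$R, R_gt), deg(10) + 1e-9)
  expect_false(res$timed_out)
  expect_equal(nrow(res$inlier_pairs), 100L)
  # identity case
  spec_id <- rotation_objective(X, X, deg(10))
  res_id <- bnb_rotation(spec_id)
  expect_equal(res_id$consensus, 100L)
  expect_lt(rotation_error(res_id$R, diag(3)), deg(10) + 1e-9)
})

test_that("consensus correspondence refinement reaches the exact rotation", {
  set.seed(67)
  X <- matrix(runif(3 * 80, -1, 1), 80, 3)
  R_gt <- rand_rotation()
  Y <- (X %*% t(R_gt)) * 1.7
  spec <- rotation_objective(X, Y, deg(10))
  # start from a plateau point displaced by ~0.12 rad
  off <- c(0.07, -0.07, 0.05)
  r0 <- matrix_to_axis_angle(axis_angle_to_matrix(off) %*% R_gt)
  ref <- refine_rotation(spec, r0)
  expect_lt(rotation_error(ref$R, R_gt), 1e-9)
  expect_equal(nrow(ref$inlier_pairs), 80L)
})

test_that("excluded basins are skipped by the rotation search", {
  set.seed(69)
  X <- matrix(runif(3 * 60, -1, 1), 60, 3)
  R_gt <- rand_rotation()
  Y <- (X %*% t(R_gt)) * 2.2
  spec <- rotation_objective(X, Y, deg(10))
  r_gt <- matrix_to_axis_angle(R_gt)
  full <- bnb_rotation(spec)
  expect_equal(full$consensus, 60L)
  # excluding the true basin forces a different, lower-consensus rotation
  excl <- bnb_rotation(spec, exclude = rbind(r_gt), exclude_radius = 0.5)
  expect_gt(rotation_error(excl$R, R_gt), 0.5)  # incumbents stay outside
  expect_lte(excl$consensus, 60L)
})

test_that("least-squares direction fit solves the orthogonal Procrustes problem", {
  set.seed(68)
  Xd <- matrix(rnorm(3 * 40), 40, 3)
  Xd <- Xd / sqrt(rowSums(Xd^2))
  R_gt <- rand_rotation()
  expect_equal(fit_rotation_pairs(Xd, Xd %*% t(R_gt)), R_gt, tolerance = 1e-9)
})
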