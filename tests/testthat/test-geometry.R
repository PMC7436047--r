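test_that("angular distance matches closed-form cases and rejects degenerate input", {
  expect_equal(angular_distance(c(1, 0, 0), c(0, 1, 0)), pi / 2)
  expect_equal(angular_distance(c(2, 3, -1), c(2, 3, -1)), 0)
  expect_equal(angular_distance(c(1, 0, 0), c(-1, 0, 0)), pi)
  expect_error(angular_distance(c(0, 0, 0), c(1, 0, 0)), "zero-norm")
})

test_that("angular distance is invariant to common rotation and scaling", {
  set.seed(7)
  for (i in 1:50) {
    u <- rnorm(3); v <- rnorm(3)
    R <- rand_rotation()
    s <- runif(1, 0.1, 10)
    expect_equal(angular_distance(s * R %*% u, s * R %*% v),
                 angular_distance(u, v), tolerance = 1e-12)
    expect_equal(angular_distance(u, v), angular_distance(v, u))
  }
})

test_that("axis-angle / matrix conversions round-trip and follow Rodrigues", {
  expect_equal(axis_angle_to_matrix(c(0, 0, 0)), diag(3))
  expect_equal(as.numeric(axis_angle_to_matrix(c(0, 0, pi / 2)) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:100) {
    R <- rand_rotation()
    r <- matrix_to_axis_angle(R)
    expect_lte(sqrt(sum(r^2)), pi + 1e-12)
    expect_equal(axis_angle_to_matrix(r), R, tolerance = 1e-9)
    # matrix view is in SO(3)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("similarity transform parameterizations agree", {
  set.seed(3)
  for (i in 1:20) {
    tf <- similarity_transform(s = runif(1, 1, 5), rotation = rand_rotation(),
                               t_pre = runif(3, -1, 1))
    expect_equal(tf$t_canonical, as.numeric(tf$s * tf$R %*% tf$t_pre),
                 tolerance = 1e-9)
    x <- matrix(rnorm(3 * 50), 50, 3)
    y1 <- tf$s * x %*% t(tf$R) + matrix(tf$t_canonical, 50, 3, byrow = TRUE)
    y2 <- tf$s * (x + matrix(tf$t_pre, 50, 3, byrow = TRUE)) %*% t(tf$R)
    expect_equal(y1, y2, tolerance = 1e-9)
    expect_equal(unclass(apply_transform(tf, point_set(x))), y1,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("transforms construct from either translation and invert correctly", {
  tf <- similarity_transform(s = 2, axis_angle = c(0, 0, pi / 3),
                             t_pre = c(0.1, -0.2, 0.3))
  tf2 <- similarity_transform(s = 2, axis_angle = c(0, 0, pi / 3),
                              t_canonical = tf$t_canonical)
  expect_equal(tf2$t_pre, tf$t_pre, tolerance = 1e-12)
  inv <- invert_transform(tf)
  x <- c(0.4, 0.5, -0.6)
  expect_equal(as.numeric(apply_transform(inv, apply_transform(tf, rbind(x)))),
               x, tolerance = 1e-12)
  expect_equal(as.numeric(apply_transform(similarity_transform(), rbind(x))), x)
  expect_equal(as.numeric(apply_transform(similarity_transform(s = 2),
                                          rbind(c(1, 1, 1)))), c(2, 2, 2))
})

test_that("rotation error equals the geodesic angle of the relative rotation", {
  R <- rand_rotation()
  expect_equal(rotation_error(R, R), 0)
  Rz <- axis_angle_to_matrix(c(0, 0, 0.05))
  expect_equal(rotation_error(Rz %*% R, R), 0.05, tolerance = 1e-9)
  set.seed(11)
  for (i in 1:30) {
    R1 <- rand_rotation(); R2 <- rand_rotation()
    r_rel <- matrix_to_axis_angle(R1 %*% t(R2))
    expect_equal(rotation_error(R1, R2), sqrt(sum(r_rel^2)), tolerance = 1e-9)
  }
})

test_that("cube subdivision yields 8 disjoint children covering the parent", {
  cb <- cube(c(0.3, -0.2, 1), 0.8)
  kids <- cube_children(cb)
  expect_length(kids, 8L)
  for (k in kids) expect_equal(k$half_side, cb$half_side / 2)
  centers <- t(vapply(kids, `[[`, numeric(3), "center"))
  expect_equal(nrow(unique(centers)), 8L)
  # children tile the parent: every random point in the parent lies in
  # exactly one child
  set.seed(5)
  for (i in 1:200) {
    p <- cb$center + runif(3, -cb$half_side, cb$half_side)
    inside <- vapply(kids, function(k) all(abs(p - k$center) <= k$half_side + 1e-12),
                     logical(1))
    expect_gte(sum(inside), 1L)
  }
  expect_equal(cb$half_diagonal, 0.8 * sqrt(3))
  expect_error(cube(c(0, 0, 0), 0), "half_side")
})

test_that("point sets validate their input", {
  expect_error(point_set(matrix(1:8, 4, 2)), "3 coordinate columns")
  expect_error(point_set(rbind(c(1, 2, NaN))), "non-finite")
  ps <- point_set(rbind(c(0, 0, 0), c(1, 1, 1)), label = "reference",
                  source = "unit-test")
  expect_s3_class(ps, "point_set")
  expect_identical(attr(ps, "label"), "reference")
})
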