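test_that("RSIF angle triples match direct computation", {
  # orthonormal frame: all position angles are right angles
  f <- build_rsif(diag(3), 1:3)
  expect_equal(f$p, rep(pi / 2, 3), tolerance = 1e-12)

  # generic triple: compare against a plain-R oracle on the canonical order
  pts <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 0, 1))
  f <- build_rsif(pts, 1:3)
  ord <- pts[canonical_order(pts), ]
  expect_equal(f$p, c(ang_ref(ord[1, ], ord[2, ]), ang_ref(ord[1, ], ord[3, ]),
                      ang_ref(ord[2, ], ord[3, ])), tolerance = 1e-12)
  expect_setequal(round(f$p, 10), round(c(pi / 4, pi / 2, pi / 2), 10))
  expect_equal(f$g, c(ang_ref(ord[1, ] - ord[2, ], ord[1, ] - ord[3, ]),
                      ang_ref(ord[1, ] - ord[2, ], ord[2, ] - ord[3, ]),
                      ang_ref(ord[1, ] - ord[3, ], ord[2, ] - ord[3, ])),
               tolerance = 1e-12)
})

test_that("degenerate triples are rejected", {
  expect_error(build_rsif(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), 1:3),
               "degenerate")
  collinear <- rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(build_rsif(collinear, 1:3), "degenerate")
  expect_error(build_rsif(diag(3), c(1, 1, 2)), "distinct")
})

test_that("p and g are invariant to rotation+scale; g also to translation", {
  set.seed(21)
  for (i in 1:25) {
    pts <- matrix(runif(9, -1, 1), 3, 3)
    f0 <- tryCatch(build_rsif(pts, 1:3), error = function(e) NULL)
    if (is.null(f0)) next
    R <- rand_rotation()
    s <- runif(1, 1, 5)
    rs <- pts %*% t(R) * s
    f1 <- build_rsif(rs, 1:3)
    expect_equal(f1$p, f0$p, tolerance = 1e-9)
    expect_equal(f1$g, f0$g, tolerance = 1e-9)
    tr <- rs + matrix(runif(3, -2, 2), 3, 3, byrow = TRUE)
    f2 <- build_rsif(tr, 1:3)
    expect_equal(f2$g, f0$g, tolerance = 1e-9)
  }
})

test_that("canonical ordering is similarity-invariant, idempotent, tie-stable", {
  set.seed(31)
  for (i in 1:25) {
    pts <- matrix(runif(9, -1, 1), 3, 3)
    perm <- canonical_order(pts)
    s <- runif(1, 1, 5)
    moved <- (pts + matrix(runif(3), 3, 3, byrow = TRUE)) %*% t(rand_rotation()) * s
    expect_identical(canonical_order(moved), perm)
    expect_identical(canonical_order(pts[perm, ]), 1:3)  # idempotent
  }
  # equilateral: all sides tie; ordering falls back to original positions
  eq <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  expect_identical(canonical_order(eq), canonical_order(eq))
  expect_identical(canonical_order(eq), 1:3)
})

test_that("triple enumeration is exhaustive below the cap and seeded above it", {
  ps <- gen_random_points(4, seed = 2)
  tri <- enumerate_triples(ps, cap = 1e6)
  expect_equal(nrow(tri), 4L)  # C(4,3)
  expect_true(all(tri[, 1] < tri[, 2] & tri[, 2] < tri[, 3]))

  ps <- gen_random_points(30, seed = 3)
  t1 <- enumerate_triples(ps, cap = 100, seed = 99)
  t2 <- enumerate_triples(ps, cap = 100, seed = 99)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 100L)
  expect_equal(nrow(unique(t1)), 100L)
  expect_error(enumerate_triples(gen_random_points(3, seed = 1)[1:2, ]),
               "at least 3")
})

test_that("the full triple census of a 200-point set is enumerated", {
  ps <- gen_random_points(200, seed = 5)
  top <- rsif_top_k(ps, k = 10, cap = 2e6)
  expect_equal(top$n_enumerated, choose(200, 3))  # 1,313,400
  expect_lte(top$n_nondegenerate, top$n_enumerated)
})

test_that("top-k ranking keeps the largest difference-angle sums, stably", {
  ps <- gen_random_points(12, seed = 8)
  all_f <- rsif_top_k(ps, k = 1e6)
  expect_equal(nrow(all_f$idx), all_f$n_nondegenerate)  # k > available: all kept
  expect_equal(all_f$score, rowSums(all_f$g), tolerance = 1e-12)
  expect_true(all(diff(all_f$score) <= 1e-15))
  top5 <- rsif_top_k(ps, k = 5)
  expect_equal(top5$score, all_f$score[1:5])
  expect_equal(top5$idx, all_f$idx[1:5, ])
})

test_that("ranking scores are unchanged under a similarity transform", {
  pair <- make_clean_pair(n = 25, seed = 13)
  fX <- rsif_top_k(pair$X, k = 50)
  fY <- rsif_top_k(pair$Y, k = 50)
  expect_equal(fY$score, fX$score, tolerance = 1e-9)
  # same triples selected (indices preserved by the transform)
  expect_equal(fY$idx, fX$idx)
})

test_that("screening matches clean corresponding features and recounts brute force", {
  pair <- make_clean_pair(n = 40, seed = 17)
  P1 <- rsif_top_k(pair$X, k = 60)
  Q1 <- rsif_top_k(pair$Y, k = 60)
  scr <- screen_pairs(P1, Q1, deg(0.01))
  expect_false(scr$empty)
  # every moving feature finds its exact counterpart
  expect_equal(length(scr$P_prime), nrow(P1$idx))
  # brute-force recount of candidate pairs
  d2 <- outer(P1$g[, 1], Q1$g[, 1], "-")^2 +
    outer(P1$g[, 2], Q1$g[, 2], "-")^2 +
    outer(P1$g[, 3], Q1$g[, 3], "-")^2
  expect_equal(nrow(scr$pairs), sum(d2 <= deg(0.01)^2))

  # vanishing threshold on unrelated data: (near-)empty candidate set
  other <- gen_random_points(40, seed = 18)
  Q2 <- rsif_top_k(unclass(other), k = 60)
  scr2 <- screen_pairs(P1, Q2, 1e-12)
  expect_true(scr2$empty || nrow(scr2$pairs) < 3)
})
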