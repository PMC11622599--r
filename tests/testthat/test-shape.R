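# Sphere-overlap shape scoring: lens volumes, the normalized overlap score,
# and its invariances. Monte-Carlo rejection sampling serves as the
# independent volume oracle.

mc_overlap <- function(c1, r1, c2, r2, n = 1e6, seed = 1) {
  set.seed(seed)
  # sample inside the bounding box of sphere 1
  pts <- matrix(runif(3 * n, -r1, r1), ncol = 3)
  in1 <- rowSums(pts^2) <= r1^2
  d2 <- sweep(pts, 2, c2 - c1)
  in2 <- rowSums(d2^2) <= r2^2
  mean(in1 & in2) * (2 * r1)^3
}

test_that("two-sphere volumes: coincident, disjoint, and the lens case vs Monte Carlo", {
  r <- 1.3
  expect_equal(sphere_overlap_volume(c(0, 0, 0), r, c(0, 0, 0), r),
               4 / 3 * pi * r^3, tolerance = 1e-12)
  expect_identical(sphere_overlap_volume(c(0, 0, 0), 1, c(3, 0, 0), 1), 0)
  expect_identical(sphere_overlap_volume(c(0, 0, 0), 1, c(2, 0, 0), 1), 0)
  # full containment -> volume of the smaller sphere
  expect_equal(sphere_overlap_volume(c(0, 0, 0), 2, c(0.3, 0, 0), 0.5),
               4 / 3 * pi * 0.5^3, tolerance = 1e-12)

  # unit spheres at d = 1: analytic lens vs 10^6-sample Monte Carlo within 1%
  lens <- sphere_overlap_volume(c(0, 0, 0), 1, c(1, 0, 0), 1)
  mc <- mc_overlap(c(0, 0, 0), 1, c(1, 0, 0), 1)
  expect_lt(abs(lens - mc) / mc, 0.01)
  # and the closed form for this case: 5*pi/12
  expect_equal(lens, 5 * pi / 12, tolerance = 1e-12)

  # symmetry in the arguments
  expect_equal(sphere_overlap_volume(c(0, 0, 0), 0.8, c(1, 0.2, 0), 1.1),
               sphere_overlap_volume(c(1, 0.2, 0), 1.1, c(0, 0, 0), 0.8),
               tolerance = 1e-14)
})

test_that("the overlap score is 1 at identity and 0 when far apart", {
  confs <- conformer_fixture()
  q <- confs[[1]]
  expect_equal(galign_score(q, q), 1, tolerance = 1e-12)

  far <- q
  far$centers <- far$centers + 100
  expect_identical(galign_score(q, far), 0)
})

test_that("the overlap score is symmetric, bounded, and rigid-motion invariant", {
  confs <- conformer_fixture()
  q <- confs[[1]]; r <- confs[[2]]
  s1 <- galign_score(q, r)
  # symmetric up to floating summation order
  expect_equal(s1, galign_score(r, q), tolerance = 1e-12)
  expect_true(s1 >= 0 && s1 <= 1)

  # same rotation + translation applied to both sets leaves the score fixed
  theta <- 0.83
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  shift <- c(1.7, -2.2, 0.4)
  q2 <- q; r2 <- r
  q2$centers <- sweep(q$centers %*% t(rot), 2, shift, `+`)
  r2$centers <- sweep(r$centers %*% t(rot), 2, shift, `+`)
  expect_equal(galign_score(q2, r2), s1, tolerance = 1e-9)

  # the denominator is the larger self overlap, so all fixture pairs score <= 1
  for (a in confs) for (b in confs) {
    expect_lte(galign_score(a, b), 1)
  }
})

test_that("a 3-atom toy score matches a Monte-Carlo estimate of the same ratio", {
  Q <- sphere_set(rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0, 0)),
                  c("C", "C", "O"))
  R <- sphere_set(rbind(c(0.3, 0.2, 0), c(1.5, -0.1, 0), c(2.6, 0.3, 0.2)),
                  c("C", "N", "O"))
  s <- galign_score(Q, R)

  mc_sum <- function(A, B, n = 2e5, seed0 = 10) {
    tot <- 0
    for (i in seq_len(nrow(A$centers))) {
      for (j in seq_len(nrow(B$centers))) {
        tot <- tot + mc_overlap(A$centers[i, ], A$radii[i],
                                B$centers[j, ], B$radii[j],
                                n = n, seed = seed0 + 31 * i + j)
      }
    }
    tot
  }
  s_mc <- mc_sum(Q, R) / max(mc_sum(Q, Q), mc_sum(R, R))
  expect_lt(abs(s - s_mc) / s_mc, 0.01)
})

test_that("the SDF reader recovers the bundled conformers", {
  confs <- conformer_fixture()
  expect_gte(length(confs), 4L)
  expect_true("benzene" %in% names(confs))
  bz <- confs[["benzene"]]
  expect_equal(nrow(bz$centers), 6L)
  expect_true(all(bz$elements == "C"))
  expect_equal(bz$radii, rep(0.7 * 1.70, 6), tolerance = 1e-12)
  # benzene C-C distances ~1.39 A in the embedded geometry
  d12 <- sqrt(sum((bz$centers[1, ] - bz$centers[2, ])^2))
  expect_equal(d12, 1.39, tolerance = 0.05)
  expect_error(sphere_set(matrix(0, 0, 3), character()), "n >= 1")
})

test_that("rigid superposition aligns matched coordinates", {
  confs <- conformer_fixture()
  q <- confs[[1]]
  theta <- 1.1
  rot <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                  -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
  moved <- q
  moved$centers <- sweep(q$centers %*% t(rot), 2, c(5, -3, 2), `+`)
  back <- superpose(moved, q)
  expect_equal(back$centers, q$centers, tolerance = 1e-8)
  expect_equal(galign_score(back, q), 1, tolerance = 1e-9)
})
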