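test_that("init_centroids: random permutes points, farthest is greedy", {
  pts <- matrix(c(0, 1, 10), ncol = 1)
  # c = n random init: a permutation of the points
  perm <- init_centroids(pts, 3, method = "random", seed = 1)
  expect_setequal(as.numeric(perm), c(0, 1, 10))
  expect_identical(init_centroids(pts, 2, "random", seed = 7),
                   init_centroids(pts, 2, "random", seed = 7))
  # farthest on {0, 1, 10}: mean 11/3 -> nearest point 1, then 10
  far <- init_centroids(pts, 2, method = "farthest")
  expect_equal(as.numeric(far), c(1, 10))
  expect_error(init_centroids(pts, 4), "cannot place")
})

test_that("assignment matches a brute-force scan and ties go low", {
  # exact centroid hit
  cent <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  expect_equal(km_assign(matrix(c(5, 5), 1), cent)$cluster, 2L)
  # exactly equidistant point -> lowest cluster index
  expect_equal(km_assign(matrix(c(2.5, 2.5), 1), cent)$cluster, 1L)
  # 50 random points, 3 random centroids: equals the brute-force oracle
  set.seed(14)
  pts <- matrix(rnorm(50 * 4), 50, 4)
  cent3 <- matrix(rnorm(12), 3, 4)
  a <- km_assign(pts, cent3)
  expect_equal(a$cluster, brute_assign(pts, cent3))
  expect_equal(sum(a$sizes), 50L)
  expect_error(km_assign(pts, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("objective is the within-cluster sum of squares", {
  # forced arithmetic: points {0, 2}, centroid 1 -> J = 2
  expect_equal(km_objective(matrix(c(0, 2), 2, 1), matrix(1, 1, 1),
                            c(1L, 1L)), 2)
  # zero iff every point sits on its centroid
  pts <- matrix(c(1, 1, 3, 3), 2, 2, byrow = TRUE)
  expect_equal(km_objective(pts, pts, c(1L, 2L)), 0)
  # random instance vs double-loop oracle
  set.seed(3)
  rp <- matrix(rnorm(40), 10, 4)
  rc <- matrix(rnorm(8), 2, 4)
  cl <- km_assign(rp, rc)$cluster
  expect_equal(km_objective(rp, rc, cl), brute_objective(rp, rc, cl))
})

test_that("centroid update takes within-cluster means, reseeds empties", {
  pts <- matrix(c(0, 0, 2, 2, 7, 7), 3, 2, byrow = TRUE)
  up <- update_centroids(pts, c(1L, 1L, 2L), 2)
  expect_equal(up, matrix(c(1, 1, 7, 7), 2, 2, byrow = TRUE))
  # singleton cluster equals its point
  expect_equal(update_centroids(pts, c(1L, 2L, 3L), 3), pts)
  # per-cluster means match independent recomputation on a random instance
  set.seed(6)
  rp <- matrix(rnorm(60), 20, 3)
  cl <- sample(1:3, 20, replace = TRUE)
  up2 <- update_centroids(rp, cl, 3)
  for (k in 1:3)
    expect_equal(up2[k, ], colMeans(rp[cl == k, , drop = FALSE]))
  # empty cluster is reseeded at the worst-served point, with a message
  expect_message(up3 <- update_centroids(pts, c(1L, 1L, 1L), 2),
                 "re-seeding")
  expect_equal(up3[1L, ], c(3, 3))             # mean of all points
  expect_equal(up3[2L, ], c(7, 7))             # farthest from that mean
})

test_that("fit converges by zero reassignment with a monotone objective", {
  # all points identical: immediate convergence at J = 0
  same <- matrix(0.5, 5, 3)
  f0 <- km_fit(same, 1)
  expect_true(attr(f0$trace, "converged"))
  expect_equal(f0$trace$J[nrow(f0$trace)], 0)
  # c = 1: centroid is the global mean
  set.seed(10)
  pts <- matrix(rnorm(30), 10, 3)
  f1 <- km_fit(pts, 1)
  expect_equal(as.numeric(f1$model$centroids), colMeans(pts))
  expect_error(km_fit(pts, 11), "at least")

  # two well-separated 1-D blobs: centroids near 0 and 10, J globally optimal
  set.seed(4)
  blobs <- matrix(c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1)), ncol = 1)
  f2 <- km_fit(blobs, 2, init = "farthest")
  expect_true(attr(f2$trace, "converged"))
  expect_equal(f2$trace$n_reassigned[nrow(f2$trace)], 0L)
  cents <- sort(as.numeric(f2$model$centroids))
  expect_lt(abs(cents[1L] - 0), 0.1)
  expect_lt(abs(cents[2L] - 10), 0.1)
  # J equals the exhaustive-partition optimum on a 10-point subsample
  sub <- blobs[c(1:5, 51:55), , drop = FALSE]
  fsub <- km_fit(sub, 2, init = "farthest")
  expect_equal(fsub$trace$J[nrow(fsub$trace)], best_two_partition_J(sub),
               tolerance = 1e-12)
})

test_that("J is non-increasing and convergence is a fixed point", {
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(8:40, 1); d <- sample(1:5, 1); k <- sample(2:4, 1)
    pts <- matrix(rnorm(n * d), n, d)
    f <- suppressMessages(km_fit(pts, k, init = "random", seed = rep))
    expect_true(all(diff(f$trace$J) <= 1e-12))
    if (attr(f$trace, "converged")) {
      a <- km_predict(f$model, pts)
      up <- suppressMessages(update_centroids(pts, a, k))
      expect_equal(up, f$model$centroids)
      expect_equal(km_assign(pts, up)$cluster, a$cluster)
    }
  }
})

test_that("converged J never beats the exhaustive global optimum", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    f <- suppressMessages(km_fit(pts, 2, init = "random", seed = rep))
    expect_gte(f$trace$J[nrow(f$trace)] - best_two_partition_J(pts), -1e-9)
  }
})

test_that("point-order permutation leaves the converged J unchanged", {
  set.seed(12)
  pts <- matrix(rnorm(60), 30, 2)
  init <- init_centroids(pts, 3, "farthest")
  fit_from <- function(p) {
    cent <- init
    repeat {
      a <- km_assign(p, cent)
      new <- suppressMessages(update_centroids(p, a, 3))
      if (identical(new, cent)) return(km_objective(p, cent, a))
      cent <- new
    }
  }
  perm <- sample(nrow(pts))
  expect_equal(fit_from(pts), fit_from(pts[perm, ]))
})

test_that("agrees with stats::kmeans (Lloyd) from the same start", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
               matrix(rnorm(40, 5, 0.2), 20, 2))
  init <- init_centroids(pts, 2, "farthest")
  ours <- km_fit(pts, 2, init = "farthest")
  ref <- stats::kmeans(pts, centers = init, algorithm = "Lloyd")
  expect_equal(km_predict(ours$model, pts)$cluster, unname(ref$cluster))
  expect_equal(ours$trace$J[nrow(ours$trace)], ref$tot.withinss)
})

test_that("predict is idempotent and matches training assignment", {
  set.seed(2)
  pts <- matrix(rnorm(80), 40, 2)
  f <- km_fit(pts, 2)
  p1 <- km_predict(f$model, pts)
  p2 <- km_predict(f$model, pts)
  expect_identical(p1, p2)
  a_final <- km_assign(pts, f$model$centroids)
  expect_identical(p1$cluster, a_final$cluster)
})
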