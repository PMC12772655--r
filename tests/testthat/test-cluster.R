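test_that("rank-1 data needs a single component", {
  set.seed(1)
  t_par <- rnorm(40)
  X <- cbind(t_par * 2, -t_par, t_par * 0.5)
  p <- fit_pca(X)
  expect_equal(p$m, 1)
  expect_equal(p$var_frac[1], 1, tolerance = 1e-12)
})

test_that("an isotropic 2D Gaussian splits variance evenly", {
  set.seed(2)
  X <- matrix(rnorm(2 * 20000), ncol = 2)
  p <- fit_pca(X, standardize = FALSE)
  expect_equal(p$var_frac, c(0.5, 0.5), tolerance = 0.02)
})

test_that("the 95% rule holds by definition and constant features are dropped", {
  set.seed(3)
  X <- matrix(rnorm(50 * 8), ncol = 8) %*% diag(c(8, 4, 2, 1, 0.5, 0.25,
                                                  0.1, 0.05))
  X <- cbind(X, const = 1)
  expect_warning(p <- fit_pca(X, standardize = FALSE), "constant")
  cv <- cumsum(p$var_frac)
  expect_gte(cv[p$m], 0.95)
  if (p$m > 1) expect_lt(cv[p$m - 1], 0.95)
  expect_equal(p$dropped, "const")
})

test_that("projection is orthogonal: full-rank round trip and distances", {
  set.seed(4)
  X <- matrix(rnorm(30 * 5), ncol = 5)
  colnames(X) <- paste0("f", 1:5)
  p <- fit_pca(X)
  full <- project_pca(X, p, ncomp = 5)
  # back-projection reconstructs the standardized data
  Z <- sweep(sweep(X, 2, p$center, "-"), 2, p$scale, "/")
  expect_equal(full %*% t(p$rotation), Z, tolerance = 1e-8,
               ignore_attr = TRUE)
  # centroid of projected points is the origin
  expect_equal(colMeans(full), rep(0, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # pairwise distances preserved at full rank
  expect_equal(as.matrix(dist(full)), as.matrix(dist(Z)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(project_pca(X[, c(2:5, 1)][, 1:4], p), "feature names")
})

test_that("within-cluster distances follow hand geometry and brute force", {
  pts <- rbind(c(0, 0), c(2, 0))
  w <- within_cluster_distance(pts, c("a", "a"))
  expect_equal(w$mean_distance, 1)
  expect_equal(w$sd_distance, 0)
  w1 <- within_cluster_distance(rbind(c(5, 5)), "solo")
  expect_equal(w1$mean_distance, 0)
  set.seed(5)
  P <- matrix(rnorm(50 * 3), ncol = 3)
  w2 <- within_cluster_distance(P, rep("c", 50))
  ctr <- colMeans(P)
  d <- apply(P, 1, function(r) sqrt(sum((r - ctr)^2)))
  expect_identical(w2$mean_distance, mean(d))
  expect_identical(w2$sd_distance, sd(d))
  expect_error(within_cluster_distance(P[0, , drop = FALSE], character(0)),
               "empty cluster")
})

test_that("separability matches hand arithmetic and its invariances", {
  pts <- rbind(c(-1, 0), c(1, 0), c(3, 0), c(5, 0))
  labs <- c("a", "a", "b", "b")
  expect_equal(separability(pts, labs), 4)
  # shrinking clusters toward centroids doubles separability
  shrunk <- rbind(c(-0.5, 0), c(0.5, 0), c(3.5, 0), c(4.5, 0))
  expect_equal(separability(shrunk, labs), 8)
  # rotation/translation invariance; uniform scaling cancels
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts2 <- sweep(pts %*% R, 2, c(13, -4), "+")
  expect_equal(separability(pts2, labs), 4, tolerance = 1e-12)
  expect_equal(separability(pts * 37.5, labs), 4, tolerance = 1e-12)
  expect_error(separability(pts, rep("a", 4)), "2 clusters")
})

test_that("separability of simulated Gaussian clusters matches its expectation", {
  # three spherical 2D Gaussian clusters, SD s, centroids an equilateral
  # triangle with side L: E[within] = s * sqrt(pi / 2), E[between] = L
  set.seed(6)
  s <- 0.5; L <- 6
  ctrs <- rbind(c(0, 0), c(L, 0), c(L / 2, L * sqrt(3) / 2))
  n <- 4000
  pts <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(2 * n, sd = s), ncol = 2), 2, ctrs[k, ], "+")))
  labs <- rep(1:3, each = n)
  expected <- L / (s * sqrt(pi / 2))
  expect_equal(separability(pts, labs), expected, tolerance = 0.02)
})
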