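test_that("all five texture matrices equal exhaustive enumeration on random grids", {
  set.seed(42)
  offs <- direction_offsets_13()
  for (trial in 1:12) {
    dims <- sample(3:8, 3, replace = TRUE)
    ng <- sample(2:5, 1)
    arr <- random_level_grid(dims, ng)
    d <- as_droi(arr)
    glcm <- glcm_matrix(d)
    rl <- glrlm_matrix(d)
    maxrun <- max(dims)
    for (k in 1:13) {
      expect_equal(glcm[[k]], bf_glcm(arr, offs[k, ], d$ng))
      expect_equal(rl[[k]], bf_glrlm(arr, offs[k, ], d$ng, maxrun))
    }
    M <- glszm_matrix(d)
    B <- bf_glszm(arr, d$ng)
    expect_equal(M[, seq_len(ncol(B)), drop = FALSE], B,
                 ignore_attr = TRUE)
    if (ncol(M) > ncol(B)) expect_true(all(M[, (ncol(B) + 1):ncol(M)] == 0))
    expect_equal(unname(gldm_matrix(d)), unname(bf_gldm(arr, d$ng)))
    expect_equal(unname(ngtdm_matrix(d)), unname(bf_ngtdm(arr, d$ng)),
                 tolerance = 1e-12)
  }
})

test_that("matrix conservation laws hold on random grids", {
  set.seed(7)
  for (trial in 1:5) {
    arr <- random_level_grid(c(6, 6, 6), 4)
    d <- as_droi(arr)
    np <- d$n_voxels
    for (R in glrlm_matrix(d))
      expect_equal(sum(R %*% seq_len(ncol(R))), np)
    M <- glszm_matrix(d)
    expect_equal(sum(M %*% seq_len(ncol(M))), np)
    expect_equal(sum(gldm_matrix(d)), np)
    for (P in glcm_matrix(d)) {
      expect_true(all(P >= 0))
      expect_identical(P, t(P)) # symmetrized
    }
  }
})

test_that("degenerate single-level regions give the defined limits", {
  arr <- array(1L, dim = c(4, 4, 4))
  d <- as_droi(arr)
  g <- glcm_features(d)
  expect_equal(unname(g["JointEntropy"]), 0)
  expect_equal(unname(g["MaximumProbability"]), 1)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["Correlation"]), 1)
  n <- ngtdm_features(d)
  expect_equal(unname(n["Coarseness"]), 1e6)
  expect_equal(unname(n["Contrast"]), 0)
  expect_true(all(is.finite(glrlm_features(d))))
  expect_true(all(is.finite(glszm_features(d))))
  expect_true(all(is.finite(gldm_features(d))))
})

test_that("a two-level checkerboard has unit GLCM contrast along axes", {
  cb <- array(0L, dim = c(4, 4, 4))
  for (x in 1:4) for (y in 1:4) for (z in 1:4)
    cb[x, y, z] <- 1L + (x + y + z) %% 2L
  d <- as_droi(cb)
  mats <- glcm_matrix(d)
  offs <- direction_offsets_13()
  axis_dirs <- which(rowSums(abs(offs)) == 1)
  for (k in axis_dirs) {
    p <- mats[[k]] / sum(mats[[k]])
    expect_equal(sum((row(p) - col(p))^2 * p), 1)
  }
})

test_that("direction-averaged texture features are invariant to 90-degree rotation", {
  set.seed(11)
  arr <- random_level_grid(c(6, 6, 6), 4)
  rot <- array(0L, dim = dim(arr))
  for (z in 1:6) rot[, , z] <- t(arr[6:1, , z]) # 90 deg about z
  d1 <- as_droi(arr); d2 <- as_droi(rot)
  expect_equal(glcm_features(d1), glcm_features(d2), tolerance = 1e-6)
  expect_equal(glrlm_features(d1), glrlm_features(d2), tolerance = 1e-6)
  expect_equal(glszm_features(d1), glszm_features(d2), tolerance = 1e-12)
  expect_equal(gldm_features(d1), gldm_features(d2), tolerance = 1e-12)
  expect_equal(ngtdm_features(d1), ngtdm_features(d2), tolerance = 1e-12)
})

test_that("feature family cardinalities are 24/16/16/14/5", {
  set.seed(2)
  d <- as_droi(random_level_grid(c(5, 5, 5), 3))
  expect_length(glcm_features(d), 24)
  expect_length(glrlm_features(d), 16)
  expect_length(glszm_features(d), 16)
  expect_length(gldm_features(d), 14)
  expect_length(ngtdm_features(d), 5)
})
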