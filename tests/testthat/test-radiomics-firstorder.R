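test_that("first-order features have closed-form values on constant input", {
  vol <- ct_volume(array(5, dim = c(4, 4, 4)), c(1, 1, 1))
  m <- array(FALSE, dim = c(4, 4, 4)); m[1:2, 1:2, 1:2] <- TRUE
  f <- first_order_features(vol, m)
  expect_equal(length(f), 18)
  expect_equal(unname(f["Mean"]), 5)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Energy"]), 8 * 25)
  expect_equal(unname(f["TotalEnergy"]), 200)
  expect_equal(unname(f["Range"]), 0)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Uniformity"]), 1)
})

test_that("first-order features match hand arithmetic on {1,2,3,4}", {
  vol <- ct_volume(array(c(1, 2, 3, 4, rep(0, 23)), dim = c(3, 3, 3)),
                   c(1, 1, 1))
  m <- array(FALSE, dim = c(3, 3, 3)); m[1:4] <- TRUE
  f <- first_order_features(vol, m)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Median"]), 2.5)
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["Minimum"]), 1)
  expect_equal(unname(f["Maximum"]), 4)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(mean(c(1, 4, 9, 16))))
})

test_that("first-order features equal an independent streaming recomputation", {
  spec <- toy_phantom_spec()
  ph <- rasterize_phantom(spec, material_table(), "EIDCT", seed = 21)
  m <- fit_noise_model(data.frame(d = c(1.6, 20.4), s = c(134.4, 47.2)))
  v <- simulate_scan(ph$volume, ph$mask, m, "EIDCT", 4.9, 1, seed = 77)
  mask <- ph$mask$data == 11L
  f <- first_order_features(v, mask, bin_width = 25)

  x <- v$data[mask]
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  counts <- table(floor((x - min(x)) / 25))
  p <- as.numeric(counts) / n
  sub <- x[x >= q[1] & x <= q[5]]
  ref <- c(sum(x^2), prod(v$spacing) * sum(x^2), -sum(p * log2(p)), min(x),
           q[1], q[5], max(x), mu, q[3], q[4] - q[2], max(x) - min(x),
           sum(abs(x - mu)) / n, sum(abs(sub - mean(sub))) / length(sub),
           sqrt(sum(x^2) / n), m3 / m2^1.5, m4 / m2^2, m2, sum(p^2))
  expect_equal(unname(f), ref, tolerance = 1e-9)
})

test_that("discretization follows the anchored floor rule", {
  vol <- array(c(0, 24, 25, 49, rep(0, 23)), dim = c(3, 3, 3))
  m <- array(FALSE, dim = c(3, 3, 3)); m[1:4] <- TRUE
  d <- discretize(vol, m, bin_width = 25)
  expect_equal(d$levels[1:4], c(1L, 1L, 2L, 2L))
  expect_equal(d$ng, 2)
  # constant region: single level, flagged degenerate
  d2 <- discretize(array(7, dim = c(3, 3, 3)), array(TRUE, dim = c(3, 3, 3)),
                   25)
  expect_equal(d2$ng, 1)
  expect_true(d2$degenerate)
  expect_error(discretize(vol, m, bin_width = 0), "bin_width")
  # level count equals a brute-force recount on a synthetic lesion
  spec <- toy_phantom_spec()
  ph <- rasterize_phantom(spec, material_table(), "EIDCT", seed = 4)
  mask <- ph$mask$data == 11L
  d3 <- discretize(ph$volume$data, mask, 25)
  x <- ph$volume$data[mask]
  expect_equal(d3$ng, max(floor((x - min(x)) / 25)) + 1)
  expect_true(all(sort(unique(d3$levels[mask])) %in% 1:d3$ng))
})
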