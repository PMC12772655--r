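test_that("canonical phantoms yield 13 labeled ROIs per slice, 39 in all", {
  specs <- phantom_specs()
  mt <- material_table()
  rois <- do.call(rbind, lapply(specs, function(sp) {
    ph <- rasterize_phantom(sp, mt, "EIDCT", texture = no_texture, seed = 1)
    suppressWarnings(place_rois(ph$mask, sp))
  }))
  expect_equal(nrow(rois), 39)
  # 13 ROIs per central-slice set across the two phantoms (each phantom
  # contributes its own three central slices)
  slice_rank <- stats::ave(rois$slice, rois$phantom_id,
                           FUN = function(s) match(s, sort(unique(s))))
  expect_equal(unname(table(slice_rank)), rep(13L, 3),
               ignore_attr = TRUE)
  expect_equal(sum(rois$roi_kind == "lesion"), 18)
  expect_equal(sum(rois$roi_kind == "parenchyma"), 18)
  expect_equal(sum(rois$roi_kind == "water"), 3)
})

test_that("every ROI's voxels carry only its own label", {
  specs <- phantom_specs()
  mt <- material_table()
  for (sp in specs) {
    ph <- rasterize_phantom(sp, mt, "PCCT", texture = no_texture, seed = 1)
    rois <- suppressWarnings(place_rois(ph$mask, sp))
    for (i in seq_len(nrow(rois))) {
      idx <- roi_voxel_indices(rois[i, ], dim(ph$mask$data), ph$mask$spacing)
      expect_true(all(ph$mask$data[idx] == rois$label[i]),
                  label = sprintf("phantom %d ROI %d label purity",
                                  sp$phantom_id, i))
      expect_gte(length(idx), 20)
    }
  }
})

test_that("a single-lesion toy phantom gets 3 ROIs per slice", {
  spec <- toy_phantom_spec()
  ph <- rasterize_phantom(spec, material_table(), "EIDCT",
                          texture = no_texture, seed = 1)
  rois <- suppressWarnings(place_rois(ph$mask, spec))
  expect_equal(nrow(rois) / length(unique(rois$slice)), 3)
  expect_setequal(unique(rois$roi_kind), c("lesion", "parenchyma", "water"))
})

test_that("measure_roi matches hand arithmetic and brute force", {
  vol <- ct_volume(array(100, dim = c(9, 9, 3)), c(1, 1, 1))
  roi <- data.frame(cx = 0, cy = 0, slice = 2, radius_mm = 3)
  m <- measure_roi(vol, roi)
  expect_equal(m$mean, 100)
  expect_equal(m$sd, 0)

  # two-voxel ROI {0, 2}: mean 1, sd sqrt(2)
  vol2 <- ct_volume(array(0, dim = c(3, 3, 3)), c(1, 1, 1))
  vol2$data[1, 2, 2] <- 0; vol2$data[2, 2, 2] <- 2
  roi2 <- data.frame(cx = -0.5, cy = 0, slice = 2, radius_mm = 0.6)
  m2 <- measure_roi(vol2, roi2)
  expect_equal(m2$n_voxels, 2)
  expect_equal(m2$mean, 1)
  expect_equal(m2$sd, sqrt(2))

  # brute-force per-voxel recomputation on a random volume
  set.seed(8)
  vol3 <- ct_volume(array(rnorm(9 * 9 * 3), dim = c(9, 9, 3)), c(1, 1, 1))
  roi3 <- data.frame(cx = 1, cy = -1, slice = 3, radius_mm = 2.5)
  m3 <- measure_roi(vol3, roi3)
  ax <- lapply(1:2, function(a) (1:9 - 5))
  vals <- c()
  for (i in 1:9) for (j in 1:9)
    if ((ax[[1]][i] - 1)^2 + (ax[[2]][j] + 1)^2 <= 2.5^2)
      vals <- c(vals, vol3$data[i, j, 3])
  expect_identical(m3$mean, mean(vals))
  expect_identical(m3$sd, sd(vals))
})

test_that("pooled material stats follow hand arithmetic", {
  meas <- data.frame(material = "lung_parenchyma", mean = c(-870, -878))
  p <- pool_material_stats(meas, "lung_parenchyma")
  expect_equal(p$mean_hu, -874)
  expect_equal(p$se_hu, sd(c(-870, -878)) / sqrt(2))
  expect_equal(p$n_rois, 2)

  one <- pool_material_stats(data.frame(material = "water", mean = -3),
                             "water")
  expect_equal(one$mean_hu, -3)
  expect_equal(one$se_hu, 0)
  expect_true(isTRUE(attr(one, "single_roi")))
  expect_error(pool_material_stats(meas, "solid"), "no measurements")
})

test_that("pooling is invariant to measurement order", {
  set.seed(3)
  meas <- data.frame(material = "solid", mean = rnorm(40, -90, 4))
  p1 <- pool_material_stats(meas, "solid")
  p2 <- pool_material_stats(meas[sample(40), , drop = FALSE], "solid")
  expect_equal(p1$mean_hu, p2$mean_hu)
  expect_equal(p1$se_hu, p2$se_hu)
})

test_that("CNR follows the printed formula and its homogeneity", {
  les <- data.frame(mean = -100, sd = 50)
  bg <- data.frame(mean = -870, sd = 30)
  expect_equal(compute_cnr(les, bg), 15.4)
  expect_equal(compute_cnr(data.frame(mean = -870, sd = 50), bg), 0)
  les2 <- les; les2$sd <- 100
  expect_equal(compute_cnr(les2, bg), compute_cnr(les, bg) / 2)
  expect_warning(cnr0 <- compute_cnr(data.frame(mean = 0, sd = 0), bg),
                 "undefined")
  expect_true(is.nan(cnr0))
})

test_that("coefficient of variation matches hand arithmetic and flags instability", {
  expect_equal(as.numeric(coefficient_of_variation(c(2, 2, 2))), 0)
  expect_equal(as.numeric(coefficient_of_variation(c(1, 3))), sqrt(2) / 2)
  cv <- coefficient_of_variation(c(-1, 1.2))
  expect_true(isTRUE(attr(cv, "unstable")))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("percent change reproduces the printed noise reductions", {
  expect_equal(round(percent_change(134.4, 116.9), 1), 13.0)
  expect_equal(round(percent_change(88.2, 76.8), 1), 12.9)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(100, 112, "increase"), 12)
  expect_error(percent_change(0, 1), "zero reference")
})
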