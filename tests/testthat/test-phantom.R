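test_that("material table enforces attenuation ordering and completeness", {
  mt <- material_table()
  expect_setequal(unique(mt$scanner), c("EIDCT", "PCCT"))
  for (sc in c("EIDCT", "PCCT")) {
    hu <- vapply(c("lung_parenchyma", "ground_glass", "part_solid", "solid",
                   "water"), function(m) material_hu(mt, sc, m), numeric(1))
    expect_true(all(diff(hu) > 0))
  }
  bad <- material_table()
  bad$mean_hu[bad$material == "solid" & bad$scanner == "EIDCT"] <- -900
  expect_error(material_table(bad), "ordering")
  expect_error(material_hu(mt, "EIDCT", "bone"), "unknown material")
})

test_that("canonical lesion specs carry the printed diameters and intensities", {
  ls <- lesion_specs()
  expect_equal(nrow(ls), 6)
  small_ps <- ls[ls$lesion_type == "part_solid" & ls$size_class == "small", ]
  expect_equal(small_ps$max_3d_diameter, 36.2)
  expect_equal(small_ps$mean_intensity, -560.9)
  large_gg <- ls[ls$lesion_type == "ground_glass" & ls$size_class == "large", ]
  expect_equal(large_gg$max_3d_diameter, 48.6)
  expect_equal(large_gg$mean_intensity, -734.6)
  expect_equal(table(ls$phantom_id), table(c(1, 1, 1, 1, 2, 2)),
               ignore_attr = TRUE)
})

test_that("rasterized lesions match their target mean HU within 2 HU", {
  sp <- phantom_specs()[[1]]
  ph <- rasterize_phantom(sp, material_table(), "PCCT", seed = 11)
  for (i in seq_len(nrow(sp$lesions))) {
    les <- sp$lesions[i, ]
    mm <- mean(ph$volume$data[ph$mask$data == 10L + les$lesion_id])
    expect_lt(abs(mm - les$mean_intensity), 2)
  }
  # large solid lesion specifically
  expect_lt(abs(mean(ph$volume$data[ph$mask$data == 14L]) - (-94.8)), 2)
  # legend covers parenchyma, water and all four lesions
  expect_setequal(ph$mask$legend,
                  sort(unique(as.integer(ph$mask$data))))
})

test_that("zero-texture cylinder is exactly piecewise constant", {
  spec <- toy_phantom_spec()
  spec$lesions <- spec$lesions[0, ] # no lesions
  ph <- rasterize_phantom(spec, material_table(), "EIDCT",
                          texture = no_texture, seed = 1)
  inside <- ph$mask$data == 1L
  expect_true(all(ph$volume$data[inside] ==
                    material_hu(material_table(), "EIDCT", "lung_parenchyma")))
  expect_true(all(ph$volume$data[ph$mask$data == 0L] == -1000))
})

test_that("lesion voxel count is within 5% of the analytic ellipsoid volume", {
  sp <- phantom_specs()[[2]]
  ph <- rasterize_phantom(sp, material_table(), "EIDCT",
                          texture = no_texture, seed = 1)
  les <- sp$lesions[sp$lesions$size_class == "large", ]
  axes <- lesion_axes(les, sp$height)
  analytic <- 4 / 3 * pi * prod(axes)
  count <- sum(ph$mask$data == 10L + les$lesion_id) * prod(c(0.5, 0.5, 1))
  expect_lt(abs(count / analytic - 1), 0.05)
})

test_that("oversized lesions trigger geometry errors", {
  spec <- toy_phantom_spec(diameter = 60, lesion_diameter = 70)
  expect_error(rasterize_phantom(spec, material_table(), "EIDCT", seed = 1),
               "sector|radius")
})

test_that("every lesion mask component is nonempty and volumes are finite", {
  sp <- phantom_specs()[[2]]
  ph <- rasterize_phantom(sp, material_table(), "PCCT", seed = 3)
  for (id in sp$lesions$lesion_id)
    expect_gt(sum(ph$mask$data == 10L + id), 0)
  expect_true(all(is.finite(ph$volume$data)))
  expect_identical(dim(ph$volume$data), dim(ph$mask$data))
})
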