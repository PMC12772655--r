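printed_eidct <- data.frame(dose = c(1.6, 2.4, 4.9, 9.8, 20.4),
                            sigma = c(134.4, 117.2, 88.2, 65.9, 47.2))
printed_pcct <- data.frame(dose = c(1.6, 2.4, 4.9, 9.8, 20.4),
                           sigma = c(116.9, 103.5, 76.8, 57.9, 45.8))

test_that("noise model recovers exact parameters from consistent pairs", {
  d <- c(2, 5, 10)
  m <- fit_noise_model(data.frame(d, sqrt(20000 / d + 100)))
  expect_equal(m$a, 20000, tolerance = 1e-6)
  expect_equal(m$b, 100, tolerance = 1e-6)
})

test_that("fitted sigma(D) reproduces both scanners' calibration points within 5%", {
  for (pts in list(printed_eidct, printed_pcct)) {
    m <- fit_noise_model(pts)
    expect_true(all(abs(m$calibration$rel_residual) < 0.05))
    # strictly decreasing and positive over the dose range
    dd <- seq(1.6, 20.4, length.out = 50)
    s <- noise_sigma(m, dd)
    expect_true(all(s > 0))
    expect_true(all(diff(s) < 0))
  }
})

test_that("the photon-counting fit is the closer one to its own low-dose point", {
  m_eid <- fit_noise_model(printed_eidct)
  m_pcc <- fit_noise_model(printed_pcct)
  expect_lt(abs(noise_sigma(m_pcc, 1.6) - 116.9),
            abs(noise_sigma(m_eid, 1.6) - 116.9))
})

test_that("noise model rejects invalid input", {
  expect_error(fit_noise_model(data.frame(d = c(2, 2), s = c(10, 10))),
               "distinct")
  expect_error(fit_noise_model(data.frame(d = c(-1, 2), s = c(10, 10))),
               "positive")
})

test_that("simulated scans are deterministic and mean-preserving", {
  spec <- toy_phantom_spec()
  ph <- rasterize_phantom(spec, material_table(), "EIDCT", seed = 5)
  rois <- suppressWarnings(place_rois(ph$mask, spec))
  m <- fit_noise_model(printed_eidct)
  v1 <- simulate_scan(ph$volume, ph$mask, m, "EIDCT", 4.9, 1, seed = 99,
                      rois = rois)
  v2 <- simulate_scan(ph$volume, ph$mask, m, "EIDCT", 4.9, 1, seed = 99,
                      rois = rois)
  expect_identical(v1$data, v2$data)
  # zero-mean noise: volume mean changes by < 0.5 HU
  expect_lt(abs(mean(v1$data) - mean(ph$volume$data)), 0.5)
  # different repetition seeds give different fields
  v3 <- simulate_scan(ph$volume, ph$mask, m, "EIDCT", 4.9, 2, seed = 100,
                      rois = rois)
  expect_false(identical(v1$data, v3$data))
})

test_that("zero-noise limit returns the truth volume unchanged", {
  spec <- toy_phantom_spec()
  ph <- rasterize_phantom(spec, material_table(), "EIDCT", seed = 5)
  m <- structure(list(a = 1e-12, b = 0,
                      calibration = data.frame()), class = "noise_model")
  v <- simulate_scan(ph$volume, ph$mask, m, "EIDCT", 4.9, 1, seed = 99)
  expect_equal(v$data, ph$volume$data, tolerance = 1e-6)
})

test_that("measured parenchyma SD recovers the high-dose calibration point", {
  # EIDCT at 20.4 mGy: repeated noise draws, mean measured SD within 3 HU
  # of the printed 47.2 HU
  spec <- toy_phantom_spec()
  ph <- rasterize_phantom(spec, material_table(), "EIDCT", seed = 5)
  rois <- suppressWarnings(place_rois(ph$mask, spec))
  par_rois <- rois[rois$roi_kind == "parenchyma", ]
  m <- fit_noise_model(printed_eidct)
  sds <- c()
  for (s in 1:17) { # 17 draws x 3 parenchyma ROIs > 50 ROI measurements
    v <- simulate_scan(ph$volume, ph$mask, m, "EIDCT", 20.4, 1, seed = 1000 + s,
                       rois = rois)
    mm <- measure_rois(v, par_rois)
    sds <- c(sds, mm$sd)
  }
  expect_lt(abs(mean(sds) - 47.2), 3)
})

test_that("mismatched grids are rejected", {
  spec <- toy_phantom_spec()
  ph <- rasterize_phantom(spec, material_table(), "EIDCT", seed = 5)
  bad_mask <- ct_mask(array(0L, dim = c(4, 4, 4)), c(1, 1, 1), c(air = 0L))
  m <- fit_noise_model(printed_eidct)
  expect_error(simulate_scan(ph$volume, bad_mask, m, "EIDCT", 4.9, 1, 1),
               "do not match")
})
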