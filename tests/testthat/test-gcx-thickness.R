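test_that("threshold follows the histogram formula with exact endpoints", {
  patch <- matrix(c(0L, 255L, 10L, 100L), 2, 2)
  expect_equal(as.numeric(compute_threshold(patch, F = 0.7)), 178.5)
  expect_equal(as.numeric(compute_threshold(patch, F = 1)), 255)
  expect_equal(as.numeric(compute_threshold(patch, F = 0)), 0)
  flat <- matrix(37L, 4, 4)
  th <- compute_threshold(flat, F = 0.7)
  expect_equal(as.numeric(th), 37)
  expect_true(attr(th, "degenerate"))
  expect_error(compute_threshold(patch, F = 1.2), "0, 1")
})

test_that("supra-threshold counting matches a per-pixel loop oracle", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      patch <- matrix(sample(0:255, 40 * 50, replace = TRUE), 40, 50)
      th <- compute_threshold(patch, F = runif(1))
      expect_identical(binarize_and_count(patch, th),
                       oracle_count_at_threshold(patch, as.numeric(th)))
      expect_identical(binarize_and_count(patch, th, strict = TRUE),
                       oracle_count_at_threshold(patch, as.numeric(th),
                                                 strict = TRUE))
    }
  })
})

test_that("a uniform 5-row band over dark background counts 5 x 200 pixels", {
  patch <- matrix(0L, 40, 200)
  patch[18:22, ] <- 255L
  th <- compute_threshold(patch, F = 0.7)
  expect_identical(binarize_and_count(patch, th), 1000L)
})

test_that("count is non-increasing in F on any fixed patch", {
  withr::with_seed(7, {
    patch <- matrix(sample(0:255, 40 * 200, replace = TRUE), 40, 200)
    counts <- vapply(seq(0, 1, by = 0.05), function(F)
      binarize_and_count(patch, compute_threshold(patch, F)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("ROI extraction is the identity at angle 0 and transpose at 90", {
  m <- matrix(sample(0:255, 40 * 200, replace = TRUE), 40, 200)
  f <- image_frame(m)
  patch0 <- extract_roi(f, oriented_roi(1, 1, 0))
  expect_identical(patch0, unclass(f)[, ])
  m2 <- matrix(sample(0:255, 200 * 40, replace = TRUE), 200, 40)
  f2 <- image_frame(m2)
  # axis down the rows, width axis pointing left: anchor at the top-right
  patch90 <- extract_roi(f2, oriented_roi(40, 1, 90))
  expect_identical(patch90[1, ], unclass(f2)[, 40])
  expect_identical(dim(patch90), c(40L, 200L))
  expect_error(extract_roi(f, oriented_roi(100, 1, 0)), "outside")
})

test_that("nonstandard ROI sizes require an explicit override", {
  expect_error(oriented_roi(1, 1, 0, width_px = 20), "override")
  expect_silent(oriented_roi(1, 1, 0, width_px = 20, allow_nonstandard = TRUE))
})

test_that("TI recovers the true band thickness on noise-free scenes", {
  sc <- render_vessel_scene(scene_spec(noise_sd = 0, gcx_thickness_true = 1.885,
                                       seed = 2))
  ti <- compute_ti(sc$frame, wall_roi(sc))
  expect_equal(ti$ti_px, 5)
  expect_equal(ti$ti_um, 1.885)
  expect_false(ti$degenerate)
  # threshold sits between band and the brighter of lumen/background
  expect_lt(ti$threshold_used, 200)
  expect_gt(ti$threshold_used, 60)
  # lower wall gives the same answer by symmetry
  expect_equal(compute_ti(sc$frame, wall_roi(sc, "lower"))$ti_px, 5)
})

test_that("oblique scenes recover the band within one pixel after ROI rotation", {
  for (ang in c(15, 30, 60, 135)) {
    sc <- render_vessel_scene(scene_spec(noise_sd = 0, gcx_thickness_true = 3.016,
                                         vessel_axis_angle = ang, seed = 3))
    ti <- compute_ti(sc$frame, wall_roi(sc))
    expect_lt(abs(ti$ti_px - 8), 1 + 1e-9, label = paste("angle", ang))
  }
})

test_that("a bandless uniform field yields only noise exceedances", {
  sc <- render_vessel_scene(scene_spec(noise_sd = 5, gcx_thickness_true = 0,
                                       lumen_intensity = 40,
                                       background_intensity = 40,
                                       band_intensity = 200, seed = 4))
  ti <- compute_ti(sc$frame, wall_roi(sc))
  # without a band, only the upper noise tail exceeds the relative threshold:
  # a small fraction of the 40-px ROI width, far below any structured band
  expect_lt(ti$ti_px, 0.1 * 40)
  expect_gt(ti$ti_px, 0)
})

test_that("a flat ROI is flagged degenerate with missing TI", {
  f <- image_frame(matrix(37L, 60, 220))
  ti <- compute_ti(f, oriented_roi(1, 1, 0))
  expect_true(ti$degenerate)
  expect_true(is.na(ti$ti_px))
  expect_true(is.na(ti$ti_um))
})

test_that("TI is monotone in true thickness and covariant in pixel size", {
  tis <- vapply(c(0.5, 1, 1.5, 2, 3), function(th) {
    sc <- render_vessel_scene(scene_spec(noise_sd = 5, gcx_thickness_true = th,
                                         seed = 21))
    compute_ti(sc$frame, wall_roi(sc))$ti_um
  }, numeric(1))
  expect_true(all(diff(tis) >= 0))
  # doubling pixel_size doubles ti_um and leaves ti_px unchanged
  sc <- render_vessel_scene(scene_spec(noise_sd = 0, gcx_thickness_true = 1.885,
                                       seed = 2))
  ti1 <- compute_ti(sc$frame, wall_roi(sc))
  f2 <- image_frame(unclass(sc$frame)[, ], pixel_size = 2 * 0.377)
  ti2 <- compute_ti(f2, wall_roi(sc))
  expect_equal(ti2$ti_px, ti1$ti_px)
  expect_equal(ti2$ti_um, 2 * ti1$ti_um)
})

test_that("vessel summaries match a two-pass mean/SD oracle", {
  withr::with_seed(33, {
    df <- data.frame(ti_um = c(rep(1.3, 21), rnorm(21, 1.8, 0.6)),
                     vessel_class = "arteriole",
                     hour = rep(c(0, 24), each = 21))
  })
  s <- summarize_vessels(df)
  expect_equal(s$n, c(21L, 21L))
  expect_equal(s$mean[s$hour == 0], 1.3)
  expect_equal(s$sd[s$hour == 0], 0)
  o <- oracle_mean_sd(df$ti_um[df$hour == 24])
  expect_equal(s$mean[s$hour == 24], o$mean, tolerance = 1e-12)
  expect_equal(s$sd[s$hour == 24], o$sd, tolerance = 1e-12)
  expect_error(summarize_vessels(df[0, ]), "no non-missing")
  expect_error(summarize_vessels(df[c(1, 22), ]), "fewer than 2")
})
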