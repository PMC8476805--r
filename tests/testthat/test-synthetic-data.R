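test_that("scene spec enforces the bright-band invariant and diameter range", {
  expect_error(scene_spec(band_intensity = 50, lumen_intensity = 60),
               "band_intensity")
  expect_error(scene_spec(band_intensity = 50, background_intensity = 60),
               "band_intensity")
  expect_warning(scene_spec(vessel_diameter = 60), "20-50")
  expect_warning(scene_spec(vessel_diameter = 10), "20-50")
  expect_silent(scene_spec(vessel_diameter = 35))
})

test_that("rendered band is exactly the requested pixel thickness on each wall", {
  # 1.885 um at 0.377 um/px is 5 px by construction
  for (ang in c(0, 90)) {
    sc <- render_vessel_scene(scene_spec(noise_sd = 0,
                                         gcx_thickness_true = 1.885,
                                         vessel_axis_angle = ang, seed = 1))
    per_line <- if (ang == 0) colSums(sc$band_mask) else rowSums(sc$band_mask)
    expect_true(all(per_line == 10), label = paste("angle", ang))
    # ground-truth consistency: mask count / axis length * pixel_size = 2 walls
    axis_len <- if (ang == 0) ncol(sc$band_mask) else nrow(sc$band_mask)
    expect_equal(sum(sc$band_mask) / axis_len * sc$spec$pixel_size,
                 2 * 5 * 0.377, tolerance = 1e-12)
  }
})

test_that("zero thickness gives an empty band mask and a two-level image", {
  sc <- render_vessel_scene(scene_spec(noise_sd = 0, gcx_thickness_true = 0,
                                       seed = 1))
  expect_false(any(sc$band_mask))
  expect_setequal(unique(as.vector(unclass(sc$frame))),
                  c(sc$spec$lumen_intensity, sc$spec$background_intensity))
})

test_that("scene rendering is bit-identical under a fixed seed", {
  sp <- scene_spec(noise_sd = 8, seed = 42)
  a <- render_vessel_scene(sp)
  b <- render_vessel_scene(sp)
  expect_identical(a$frame, b$frame)
  c <- render_vessel_scene(scene_spec(noise_sd = 8, seed = 43))
  expect_false(identical(a$frame, c$frame))
})

test_that("a vessel larger than the image is a sizing error", {
  expect_error(render_vessel_scene(
    suppressWarnings(scene_spec(vessel_diameter = 49, image_shape = c(64, 64)))),
    "too small")
})

test_that("track cohorts have the configured sampling and class kinematics", {
  sp <- track_spec(n_adhering = 3, n_rolling = 3, n_flowing = 0,
                   frame_rate = 2, window = 15, centerline_speed = 100,
                   rolling_speed_fraction = 0.2, jitter_sd = 0.5,
                   segment_length = 1e4, seed = 5)
  co <- simulate_tracks(sp)
  # 2 Hz over 15 s, t = 0 inclusive: 31 samples for full-window tracks
  expect_true(all(vapply(co$tracks, function(tr) nrow(tr$samples), 1L) == 31L))
  # adhering: max pairwise displacement bounded by the uniform jitter bound
  for (i in which(co$labels == "adhering")) {
    s <- co$tracks[[i]]$samples
    expect_lte(max(dist(cbind(s$x_um, s$y_um))), 3 * sp$jitter_sd)
  }
  # rolling: mean along-axis speed recomputed from coordinates ~ 20 um/s
  for (i in which(co$labels == "rolling")) {
    s <- co$tracks[[i]]$samples
    speed <- (s$x_um[nrow(s)] - s$x_um[1]) / (s$t_s[nrow(s)] - s$t_s[1])
    expect_equal(speed, 0.2 * 100, tolerance = 0.02)
  }
})

test_that("moving tracks stay inside the vessel segment", {
  co <- simulate_tracks(track_spec(n_adhering = 0, n_rolling = 10,
                                   n_flowing = 10, segment_length = 100,
                                   jitter_sd = 0.5, seed = 11))
  for (tr in co$tracks) {
    expect_gte(min(tr$samples$x_um), -3 * 0.5)
    expect_lte(max(tr$samples$x_um), 100 + 3 * 0.5)
    expect_true(all(diff(tr$samples$t_s) > 0))
    expect_gte(nrow(tr$samples), 2L)
  }
})

test_that("track simulation is deterministic and classes have separated speeds", {
  sp <- track_spec(seed = 9)
  expect_identical(tracks_to_df(simulate_tracks(sp)),
                   tracks_to_df(simulate_tracks(sp)))
  co <- simulate_tracks(track_spec(n_adhering = 20, n_rolling = 20,
                                   n_flowing = 20, seed = 13))
  speeds <- vapply(co$tracks, function(tr) {
    s <- tr$samples
    abs(s$x_um[nrow(s)] - s$x_um[1]) / (s$t_s[nrow(s)] - s$t_s[1])
  }, numeric(1))
  expect_lt(max(speeds[co$labels == "adhering"]),
            min(speeds[co$labels == "rolling"]))
  expect_lt(max(speeds[co$labels == "rolling"]),
            min(speeds[co$labels == "flowing"]))
})

test_that("leak series obeys its linear expectation", {
  # noise-free null: every ROI mean equals baseline at every time
  se0 <- simulate_leak_series(leak_spec(leak_rate = 0, noise_sd = 0, seed = 1))
  for (f in se0$frames)
    for (r in se0$rois)
      expect_identical(roi_mean_intensity(f$frame, r), 30)
  # noise-free leak: +60 gray levels after 120 min at 0.5/min
  se <- simulate_leak_series(leak_spec(leak_rate = 0.5, noise_sd = 0, seed = 1))
  last <- se$frames[[length(se$frames)]]
  expect_identical(roi_mean_intensity(last$frame, se$rois[[1]]), 90)
  # with noise, the ensemble regression slope recovers the leak rate
  means <- do.call(rbind, lapply(1:100, function(s) {
    ser <- simulate_leak_series(leak_spec(leak_rate = 0.5, noise_sd = 10,
                                          seed = s))
    data.frame(t = vapply(ser$frames, `[[`, numeric(1), "t_min"),
               m = vapply(ser$frames, function(f)
                 roi_mean_intensity(f$frame, ser$rois[[1]]), numeric(1)))
  }))
  slope <- coef(lm(m ~ t, data = means))[["t"]]
  expect_equal(slope, 0.5, tolerance = 0.02)
})

test_that("leak spec validates its time grid", {
  expect_error(leak_spec(times = c(30, 60)), "include 0")
  expect_error(leak_spec(times = c(0, 60, 30)), "increasing")
  expect_error(leak_spec(times = c(0, -30)), "non-negative")
})

test_that("cohort draws match the configured group parameters", {
  # zero SD: every subject equals the group mean
  tab <- simulate_cohort(cohort_spec("sdc1", group_sds = c(0, 0, 0, 0),
                                     seed = 3))
  expect_true(all(tab$value[tab$hour == 0] == 1.85))
  expect_true(all(tab$value[tab$hour == 24] == 3.83))
  # large n recovers the configured 24-h mean within Monte-Carlo error
  big <- simulate_cohort(cohort_spec("sdc1", n_per_time = 1e4, seed = 4))
  expect_equal(mean(big$value[big$hour == 24]), 3.83,
               tolerance = 3 * 1.09 / sqrt(1e4) / 3.83)
  # determinism
  expect_identical(as.data.frame(simulate_cohort(cohort_spec("sdc1", seed = 8))),
                   as.data.frame(simulate_cohort(cohort_spec("sdc1", seed = 8))))
  # truncation: thickness/concentration cohorts never go negative
  low <- simulate_cohort(cohort_spec("sdc1", group_means = c(0.1, 0.1, 0.1, 0.1),
                                     n_per_time = 200, seed = 5))
  expect_gte(min(low$value), 0)
})

test_that("cohort spec rejects off-grid schedules and missing parameters", {
  expect_error(cohort_spec("sdc1", schedule = c(0, 12)), "protocol grid")
  expect_error(cohort_spec("sdc1", schedule = c(0, 72)), "every")
  expect_error(cohort_spec("sdc1", n_per_time = 1), ">= 2")
})
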