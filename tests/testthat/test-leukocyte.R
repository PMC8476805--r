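make_track <- function(x, y, t = seq(0, 15, by = 0.5), id = "t1",
                       axis = c(1, 0)) {
  leukocyte_track(id, data.frame(t_s = t, x_um = x, y_um = y),
                  vessel = list(diameter_um = 30, segment_length_um = 100,
                                axis = axis))
}

test_that("stationary, slow and fast tracks get their defining classes", {
  t <- seq(0, 15, by = 0.5)
  still <- make_track(rep(5, 31), rep(0, 31))
  expect_identical(classify_track(still, reference_speed = 100), "adhering")
  # exactly at the reference speed: flowing under any rolling fraction < 1
  fast <- make_track(100 * t, rep(0, 31), t = t)
  expect_identical(classify_track(fast, reference_speed = 100), "flowing")
  # 0.3 x reference with rolling_fraction 0.5: rolling; speed recomputed
  slow <- make_track(30 * t, rep(0, 31), t = t)
  speed <- (slow$samples$x_um[31] - slow$samples$x_um[1]) / 15
  expect_lt(speed, 0.5 * 100)
  expect_identical(classify_track(slow, reference_speed = 100), "rolling")
})

test_that("short or low-coverage tracks are indeterminate", {
  # a 1-s glimpse of a stationary cell cannot be called adhering
  glimpse <- make_track(rep(5, 3), rep(0, 3), t = c(0, 0.5, 1))
  expect_identical(classify_track(glimpse, reference_speed = 100),
                   "indeterminate")
  # below the minimum coverage nothing is classified
  blip <- make_track(c(0, 10), c(0, 0), t = c(0, 0.1))
  expect_identical(classify_track(blip, reference_speed = 100,
                                  params = classify_params(min_coverage = 0.05)),
                   "indeterminate")
})

test_that("classification is invariant to rigid rotation of coordinates", {
  co <- simulate_tracks(track_spec(n_adhering = 5, n_rolling = 5,
                                   n_flowing = 5, seed = 17))
  theta <- 37 * pi / 180
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rotated <- lapply(co$tracks, function(tr) {
    xy <- as.matrix(tr$samples[, c("x_um", "y_um")]) %*% t(R)
    v <- tr$vessel
    v$axis <- as.vector(R %*% v$axis)
    leukocyte_track(tr$track_id,
                    data.frame(t_s = tr$samples$t_s,
                               x_um = xy[, 1] + 40, y_um = xy[, 2] - 13),
                    v, window = tr$window)
  })
  orig <- vapply(co$tracks, classify_track, character(1), reference_speed = 100)
  rot <- vapply(rotated, classify_track, character(1), reference_speed = 100)
  expect_identical(rot, orig)
})

test_that("counts normalize to the 100 um x 100 um reference vessel", {
  t <- seq(0, 15, by = 0.5)
  tracks <- list(make_track(rep(1, 31), rep(0, 31), id = "a1"),
                 make_track(rep(2, 31), rep(1, 31), id = "a2"),
                 make_track(rep(3, 31), rep(-1, 31), id = "a3"))
  # 3 adhering on a 50-um segment of 25-um diameter: 3 x 2 x 4 = 24
  cc <- count_and_normalize(tracks, reference_speed = 100,
                            vessel = list(diameter_um = 25,
                                          segment_length_um = 50))
  expect_identical(cc$n_adhering, 3L)
  expect_equal(cc$normalized_adhering, 24)
  # identity calibration at 100 x 100
  cc100 <- count_and_normalize(tracks, reference_speed = 100,
                               vessel = list(diameter_um = 100,
                                             segment_length_um = 100))
  expect_equal(cc100$normalized_adhering, 3)
  # halving segment length doubles normalized counts
  cc50 <- count_and_normalize(tracks, reference_speed = 100,
                              vessel = list(diameter_um = 100,
                                            segment_length_um = 50))
  expect_equal(cc50$normalized_adhering, 2 * cc100$normalized_adhering)
  # length-only calibration drops the diameter factor and is labelled
  cl <- count_and_normalize(tracks, reference_speed = 100,
                            vessel = list(diameter_um = 25,
                                          segment_length_um = 50),
                            normalization = "length_only")
  expect_equal(cl$normalized_adhering, 6)
  expect_identical(cl$normalization, "length_only")
  expect_error(count_and_normalize(tracks, reference_speed = 100,
                                   vessel = list(diameter_um = 0,
                                                 segment_length_um = 50)),
               "positive")
  # no tracks: all counts zero
  none <- count_and_normalize(list(), reference_speed = 100)
  expect_identical(none$n_adhering + none$n_rolling + none$n_flowing, 0L)
})

test_that("dual-stain matching separates tight adherence from transit", {
  pts <- data.frame(x_um = c(10, 50, 90), y_um = c(5, 5, 5))
  same <- dual_stain_adherence(pts, pts, match_radius = 5)
  expect_true(all(same$status == "tight_adherent"))
  far <- dual_stain_adherence(pts, pts + 40, match_radius = 5)
  expect_true(all(far$status == "transient"))
  none <- dual_stain_adherence(pts, pts[0, ], match_radius = 5)
  expect_true(all(none$status == "transient"))
  empty <- dual_stain_adherence(pts[0, ], pts, match_radius = 5)
  expect_identical(nrow(empty), 0L)
})

test_that("dual-stain test recovers adhering vs rolling populations", {
  # adhering cells stay within jitter over the 8-s lag; rolling cells are
  # displaced by >= lag x rolling speed, well beyond the match radius; cell
  # density is the realistic few-per-field regime so chance coincidences
  # between unrelated cells stay rare
  withr::with_seed(29, {
    n <- 12
    adh0 <- data.frame(x_um = runif(n, 0, 200), y_um = runif(n, -15, 15))
    adh1 <- adh0 + matrix(runif(2 * n, -0.5, 0.5), n, 2)
    rol0 <- data.frame(x_um = runif(n, 0, 200), y_um = runif(n, -15, 15))
    rol1 <- rol0
    rol1$x_um <- rol1$x_um + 8 * 20  # 8 s at 20 um/s >> 2 x match radius
  })
  res <- dual_stain_adherence(rbind(adh0, rol0), rbind(adh1, rol1),
                              match_radius = 2)
  truth <- rep(c("tight_adherent", "transient"), each = 12)
  expect_gte(mean(res$status == truth), 0.95)
})
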