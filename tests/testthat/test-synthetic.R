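test_that("plane-wave scenes follow the closed-form activation profile", {
  spec <- quick_scene(n = 30)
  sim <- make_movie(spec)
  expected <- spec$baseline_ms +
    (col(sim$truth$lat_ms) - 1) * spec$pixel_size_mm / spec$base_speed_mps
  expect_equal(sim$truth$lat_ms, expected, tolerance = 1e-9,
               ignore_attr = TRUE)
  # monotone non-decreasing along the propagation axis
  expect_true(all(diff(t(sim$truth$lat_ms)) >= -1e-9))
  expect_equal(sim$truth$percent_sc, 0)
})

test_that("point-source activation matches the Euclidean travel-time oracle", {
  spec <- scene_spec(grid_rows = 50, grid_cols = 50, pixel_size_mm = 0.17,
                     base_speed_mps = 0.4, source = c(25, 25),
                     noise_sd = 0, drift_per_s = 0)
  sim <- make_movie(spec)
  d_mm <- sqrt((row(sim$truth$lat_ms) - 25)^2 +
               (col(sim$truth$lat_ms) - 25)^2) * spec$pixel_size_mm
  err <- abs(sim$truth$lat_ms - spec$baseline_ms - d_mm / 0.4)
  one_pixel_ms <- spec$pixel_size_mm / 0.4
  expect_lt(max(err), one_pixel_ms)
  # monotone with distance from the source
  ord <- order(c(d_mm))
  lat_sorted <- c(sim$truth$lat_ms)[ord]
  expect_true(all(diff(lat_sorted) > -one_pixel_ms))
})

test_that("ground-truth SC mask is exactly the thresholded speed field", {
  spec <- quick_scene(n = 40, patches = list(
    list(shape = "rect", rows = c(1, 40), cols = c(16, 25), speed_mps = 0.1)
  ))
  sim <- make_movie(spec)
  expect_equal(sim$truth$percent_sc, 25)
  expect_identical(sim$truth$sc_mask,
                   !is.na(sim$truth$speed_mps) & sim$truth$speed_mps < 0.2)
  # property: holds for arbitrary random patch layouts
  for (s in 1:8) {
    set.seed(s)
    patches <- replicate(sample(1:3, 1), list(
      shape = "disc", center = c(sample(5:35, 1), sample(5:35, 1)),
      radius_px = sample(2:6, 1),
      speed_mps = runif(1, 0.05, 0.6)
    ), simplify = FALSE)
    tr <- make_movie(quick_scene(n = 40, patches = patches,
                                 duration_ms = 60))$truth
    expect_identical(tr$sc_mask,
                     !is.na(tr$speed_mps) & tr$speed_mps < tr$sc_threshold_mps)
  }
})

test_that("block segments stop the front and unreached pixels are flagged", {
  blocked <- scene_spec(
    grid_rows = 30, grid_cols = 30, frame_rate_hz = 1000,
    base_speed_mps = 0.5, source = "left", noise_sd = 0, drift_per_s = 0,
    block_segments = list(list(from = c(1, 15), to = c(22, 15)))
  )
  sim_b <- make_movie(blocked)
  sim_o <- make_movie(quick_scene(n = 30))
  # behind the block (same row as the blocked span) the wave must detour
  expect_gt(sim_b$truth$lat_ms[5, 20], sim_o$truth$lat_ms[5, 20] + 1)
  # block pixels themselves never activate and are flagged, not truncated
  expect_true(all(is.na(sim_b$truth$lat_ms[1:22, 15])))
  expect_true(all(sim_b$truth$unreached[1:22, 15]))
  # a movie cut short flags late pixels as unreached
  short <- make_movie(quick_scene(n = 30, duration_ms = 12))
  expect_true(any(short$truth$unreached))
  expect_false(any(short$truth$unreached[, 1:2]))
})

test_that("movie generation is seeded and reproducible", {
  spec <- quick_scene(n = 12, noise_sd = 0.05, drift_per_s = 0.1, seed = 11)
  m1 <- make_movie(spec)$movie
  m2 <- make_movie(spec)$movie
  expect_identical(m1$data, m2$data)
  spec2 <- quick_scene(n = 12, noise_sd = 0.05, drift_per_s = 0.1, seed = 12)
  expect_false(identical(make_movie(spec2)$movie$data, m1$data))
})

test_that("invalid scene parameters are rejected", {
  expect_error(scene_spec(grid_rows = 4), "at least 8")
  expect_error(scene_spec(source = c(200, 3)), "outside the grid")
  expect_error(scene_spec(source = "center"), "top/bottom/left/right")
  expect_error(scene_spec(base_speed_mps = -1), "positive")
  expect_error(scene_spec(patches = list(list(shape = "rect",
                                              rows = c(1, 5), cols = c(1, 5)))),
               "speed_mps")
})

test_that("study tables have the factorial layout minus declared missing cells", {
  tab <- make_study_table(study_design(seed = 5))
  expect_equal(nrow(tab), 55)  # 7 x 4 x 2 - 1
  expect_equal(length(unique(tab$animal)), 7)
  # class constant within animal
  expect_true(all(tapply(tab$class, tab$animal,
                         function(x) length(unique(x))) == 1))
  # unique cells
  expect_false(any(duplicated(tab[c("animal", "position", "train")])))
  # determinism
  expect_identical(tab, make_study_table(study_design(seed = 5)))
  # missing cell must exist in the factorial
  expect_error(study_design(missing = list(list(animal = "C9",
                                                position = "top",
                                                train = "S1"))),
               "not part of the full factorial")
})

test_that("the generator's ICC is recovered by the package's own estimator", {
  target_icc <- 0.42
  resid_sd <- 5
  animal_sd <- sqrt(target_icc / (1 - target_icc)) * resid_sd
  iccs <- vapply(1:200, function(s) {
    tab <- make_study_table(study_design(animal_sd = animal_sd,
                                         resid_sd = resid_sd, seed = s))
    fit_mixed(tab, marginal = FALSE)$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs) - target_icc), 0.05)
})
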