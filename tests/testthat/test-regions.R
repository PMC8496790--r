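test_that("slow classification is strict at the threshold", {
  speed <- matrix(c(0.19, 0.20, 0.21, NA), 2, 2)
  cv <- as_cv_map(speed)
  sc <- classify_slow(cv, 0.2)
  expect_equal(sc$state[1, 1], "slow")     # 0.19 < 0.2
  expect_equal(sc$state[2, 1], "normal")   # 0.20 is not slow
  expect_equal(sc$state[1, 2], "normal")
  expect_equal(sc$state[2, 2], "excluded")
  expect_error(classify_slow(as_cv_map(matrix(NA_real_, 2, 2))), "valid")
})

test_that("component labeling matches the flood-fill oracle on fixed cases", {
  # 4x4 case with an L-shape, a domino, and two singletons
  slow <- matrix(FALSE, 4, 4)
  for (p in list(c(1, 1), c(1, 2), c(2, 2), c(1, 4), c(2, 4), c(4, 1), c(4, 4)))
    slow[p[1], p[2]] <- TRUE
  lab <- label_components(slow)
  expect_equal(sort(lab$sizes), c(1, 1, 2, 3))
  expect_equal(sort(lab$sizes), sort(flood_fill_oracle(slow)))
  expect_true(all(lab$labels[slow] > 0))
  expect_true(all(lab$labels[!slow] == 0))
  # diagonal contact does not connect
  diag2 <- matrix(FALSE, 3, 3); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_equal(label_components(diag2)$sizes, c(1L, 1L))
  # a fully slow grid is one component
  full <- label_components(matrix(TRUE, 5, 7))
  expect_equal(full$sizes, 35L)
})

test_that("component labeling equals the oracle on random maps", {
  set.seed(42)
  for (rep in 1:60) {
    slow <- matrix(runif(400) < runif(1, 0.15, 0.6), 20, 20)
    lab <- label_components(slow)
    expect_equal(sort(lab$sizes), sort(flood_fill_oracle(slow)))
    expect_equal(sum(lab$sizes), sum(slow))
  }
})

test_that("component statistics are invariant to labeling order", {
  set.seed(8)
  slow <- matrix(runif(900) < 0.4, 30, 30)
  a <- label_components(slow)
  b <- label_components(t(slow))   # different scan order over the same map
  expect_equal(sort(a$sizes), sort(b$sizes))
})

test_that("region reports apply the counting and area rules", {
  px <- 0.0289
  roi <- matrix(TRUE, 6, 6)
  # one 10-pixel component
  slow <- matrix(FALSE, 6, 6); slow[2, 1:5] <- TRUE; slow[3, 1:5] <- TRUE
  rep10 <- region_report(label_components(slow), px, roi)
  expect_equal(rep10$component_areas_mm2, 0.289)
  expect_equal(rep10$n_components, 1)
  # sizes {3,2,1,1}: singletons counted in percent but not in components
  slow2 <- matrix(FALSE, 6, 6)
  slow2[1, 1:3] <- TRUE          # 3
  slow2[3, 1:2] <- TRUE          # 2
  slow2[5, 1] <- TRUE; slow2[5, 6] <- TRUE  # singletons
  rep2 <- region_report(label_components(slow2), px, roi)
  expect_equal(rep2$n_components, 2)
  expect_equal(sort(rep2$component_areas_mm2), c(2, 3) * px)
  expect_equal(rep2$mean_area_mm2, 0.07225)
  expect_equal(rep2$percent_sc, 100 * 7 / 36)
  # no slow pixels: percent 0, undefined mean area (never 0)
  rep0 <- region_report(label_components(matrix(FALSE, 6, 6)), px, roi)
  expect_equal(rep0$percent_sc, 0)
  expect_equal(rep0$n_components, 0)
  expect_true(is.na(rep0$mean_area_mm2))
  expect_error(region_report(label_components(slow), px,
                             matrix(FALSE, 6, 6)), "empty ROI")
})

test_that("raising the speed threshold never decreases percent SC", {
  set.seed(13)
  speed <- matrix(runif(400, 0.05, 0.8), 20, 20)
  cv <- as_cv_map(speed)
  roi <- matrix(TRUE, 20, 20)
  pct <- vapply(c(0.1, 0.2, 0.3, 0.5), function(th) {
    region_report(label_components(classify_slow(cv, th)), 0.0289, roi)$percent_sc
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("the pipeline resolves two disjoint slow patches deterministically", {
  spec <- quick_scene(n = 40, patches = list(
    list(shape = "rect", rows = c(6, 12), cols = c(16, 22), speed_mps = 0.1),
    list(shape = "rect", rows = c(28, 34), cols = c(16, 22), speed_mps = 0.1)
  ))
  sim <- make_movie(spec)
  expect_equal(sim$truth$component_count, 2)
  res1 <- run_pipeline(sim$movie, default_config())
  expect_equal(res1$report$n_components, 2)
  # bit-identical on a re-run
  res2 <- run_pipeline(sim$movie, default_config())
  expect_identical(res1$report, res2$report)
  # stage errors carry the stage name
  broken <- default_config()
  broken$preprocess$snr_threshold <- 1e9
  expect_error(run_pipeline(sim$movie, broken), "\\[preprocess\\]")
})
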