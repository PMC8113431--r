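test_that("uniform phantom paints the background level everywhere", {
  spec <- phantom_spec(shape = c(16, 16, 8), background_suv = 1.0,
                       liver = NULL)
  act <- build_phantom(spec)
  expect_true(all(act == 1.0))
  expect_length(phantom_masks(act), 0)
})

test_that("lesion SUV is painted exactly and masks match the painted voxels", {
  les <- lesion_spec(center = c(24, 24, 16), diameter_mm = 18, suv = 3.8)
  spec <- phantom_spec(shape = c(48, 48, 31), background_suv = 0.7,
                       liver = NULL, lesions = list(les))
  act <- build_phantom(spec)
  m <- phantom_masks(act)$lesion_1
  expect_equal(max(act[m]), 3.8)
  expect_equal(min(act[m]), 3.8)
  expect_true(all(act[-m] == 0.7))
})

test_that("lesion rasterization matches a brute-force voxel-centre scan", {
  vs <- c(2.7, 2.7, 2.8)
  center <- c(30, 28, 35)
  spec <- phantom_spec(shape = c(64, 64, 71), background_suv = 0.7,
                       liver = NULL,
                       lesions = list(lesion_spec(center, 20, 4)))
  act <- build_phantom(spec)
  # independent oracle: exhaustive scan of all voxel centres
  cnt <- 0L
  c_mm <- (center - 1) * vs
  for (x in 1:64) for (y in 1:64) for (z in 1:71) {
    d2 <- sum((c(x, y, z) - 1) * vs - c_mm)^0  # keep loop simple
    d2 <- ((x - 1) * vs[1] - c_mm[1])^2 + ((y - 1) * vs[2] - c_mm[2])^2 +
      ((z - 1) * vs[3] - c_mm[3])^2
    if (d2 <= 10^2) cnt <- cnt + 1L
  }
  expect_equal(length(phantom_masks(act)$lesion_1), cnt)
})

test_that("geometry violations are rejected", {
  expect_error(build_phantom(
    phantom_spec(shape = c(20, 20, 10), liver = NULL,
                 lesions = list(lesion_spec(c(2, 2, 2), 30, 4)))),
    "outside the grid")
  expect_error(phantom_spec(liver = NULL,
                            lesions = list(lesion_spec(c(5, 5, 5), 10,
                                                       suv = 0.5))),
               "hotspot")
})

test_that("random phantoms have disjoint masks and lesions in range", {
  spec <- random_phantom_spec(3, shape = c(64L, 64L, 71L))
  act <- build_phantom(spec)
  masks <- phantom_masks(act)
  expect_length(masks, 4)  # liver + 3 lesions
  all_idx <- unlist(masks)
  expect_equal(length(all_idx), length(unique(all_idx)))
  for (l in spec$lesions) {
    expect_gte(l$suv, 2); expect_lte(l$suv, 8)
    expect_gte(l$diameter_mm, 10); expect_lte(l$diameter_mm, 25)
  }
  expect_identical(random_phantom_spec(3, shape = c(64L, 64L, 71L)), spec)
})

test_that("zero-duration frames contain no counts", {
  act <- uniform_activity()
  fr <- simulate_frame(act, 0, tiny_calib(), seed = 1)
  expect_true(all(fr == 0))
})

test_that("frame counts follow the Poisson mean activity x time x sensitivity", {
  act <- uniform_activity(level = 1, shape = c(24, 24, 24))  # 13824 voxels
  fr6 <- simulate_frame(act, 6, tiny_calib(100), seed = 2)
  n <- length(fr6)
  expect_gte(n, 1e4)
  se <- sqrt(600 / n)
  expect_lt(abs(mean(fr6) - 600), 5 * se)
  # doubling duration doubles the mean within sampling tolerance
  fr12 <- simulate_frame(act, 12, tiny_calib(100), seed = 3)
  se12 <- sqrt(1200 / n)
  expect_lt(abs(mean(fr12) - 2 * mean(fr6)), 5 * sqrt(se^2 * 4 + se12^2))
  # determinism
  expect_identical(as.numeric(simulate_frame(act, 6, tiny_calib(100), 2)),
                   as.numeric(fr6))
})

test_that("split_frame with one interval is the identity", {
  fr <- simulate_frame(uniform_activity(), 6, tiny_calib(), seed = 4)
  out <- split_frame(fr, 1, seed = 5)
  expect_length(out, 1)
  expect_identical(as.numeric(out[[1]]), as.numeric(fr))
  expect_error(split_frame(fr, 0, seed = 1), ">= 1")
})

test_that("split_frame conserves counts exactly and divides the duration", {
  fr <- simulate_frame(uniform_activity(level = 3), 6, tiny_calib(),
                       seed = 6)
  parts <- split_frame(fr, 4, seed = 7)
  expect_length(parts, 4)
  total <- Reduce(`+`, lapply(parts, as.numeric))
  expect_identical(total, as.numeric(fr))
  for (p in parts) expect_equal(frame_duration(p), 1.5)
  # determinism
  parts2 <- split_frame(fr, 4, seed = 7)
  expect_identical(as.numeric(parts2[[2]]), as.numeric(parts[[2]]))
})

test_that("split counts match the exact binomial law", {
  # 10^4 iid replicates of splitting 1000 counts into 4: one interval's
  # count is Binomial(1000, 1/4); chi-square test against exact
  # probabilities
  shape <- c(25, 20, 20)  # 10^4 voxels
  fr <- count_volume <- pet_volume(array(1000L, shape), c(2.7, 2.7, 2.8),
                                   units = "counts")
  attr(fr, "duration_min") <- 6; attr(fr, "sensitivity") <- 1
  x <- as.numeric(split_frame(fr, 4, seed = 8)[[1]])
  ks <- 170:330  # covers essentially all mass of Binomial(1000, .25)
  p <- dbinom(ks, 1000, 0.25)
  breaks <- c(-Inf, ks[p > 5 / length(x)], Inf)
  probs <- diff(pbinom(breaks, 1000, 0.25))
  obs <- table(cut(x, breaks))
  chi <- suppressWarnings(chisq.test(as.numeric(obs), p = probs))
  expect_gt(chi$p.value, 1e-4)
})

test_that("binomial thinning yields the requested sub-frame duration", {
  fr <- simulate_frame(uniform_activity(level = 2), 4, tiny_calib(),
                       seed = 9)
  sub <- subframe(fr, 1.5, seed = 10)
  expect_equal(frame_duration(sub), 1.5)
  expect_true(all(as.numeric(sub) <= as.numeric(fr)))
  expect_error(subframe(fr, 5, seed = 1), "duration")
})

test_that("reconstruction preserves a constant field and total mass", {
  shape <- c(24, 24, 12)
  fr <- pet_volume(array(50L, shape), c(2.7, 2.7, 2.8), units = "counts")
  attr(fr, "duration_min") <- 1; attr(fr, "sensitivity") <- 100
  suv <- emulate_reconstruction(fr, beta = 500, tiny_calib(100),
                                weight_kg = 70, injected_MBq = 280)
  expect_equal(dim(suv), shape)
  # constant in, constant out: counts/(t*sens) = 50/100 = 0.5 SUV
  expect_equal(as.numeric(suv), rep(0.5, prod(shape)), tolerance = 1e-12)
  # mass conservation on a noisy field
  fr2 <- simulate_frame(uniform_activity(), 1, tiny_calib(100), seed = 11)
  suv2 <- emulate_reconstruction(fr2, 500, tiny_calib(100))
  expect_equal(sum(suv2), sum(fr2) / (1 * 100), tolerance = 1e-9)
})

test_that("liver COV decreases as beta increases (more regularization)", {
  spec <- small_phantom_spec()
  act <- build_phantom(spec)
  fr <- simulate_frame(act, 1, tiny_calib(20), seed = 12)
  rois <- liver_rois_from_phantom(act)
  covs <- vapply(c(100, 200, 300, 500, 700), function(beta) {
    cov_liver(emulate_reconstruction(fr, beta, tiny_calib(20)), rois)
  }, 1.0)
  expect_true(all(diff(covs) <= 0))
})

test_that("liver COV decreases monotonically with acquisition time", {
  spec <- small_phantom_spec()
  act <- build_phantom(spec)
  rois <- liver_rois_from_phantom(act)
  calib <- tiny_calib(20)
  # average over seeded replicates to stabilise the ordering
  cov_at <- function(dur) {
    mean(vapply(1:3, function(r) {
      fr <- simulate_frame(act, dur, calib, seed = 100 * r + dur * 10)
      cov_liver(emulate_reconstruction(fr, 500, calib), rois)
    }, 1.0))
  }
  covs <- vapply(c(1, 1.5, 4, 6), cov_at, 1.0)
  expect_true(all(diff(covs) < 0))
})
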