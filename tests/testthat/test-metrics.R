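test_that("SUV conversion follows the standard convention", {
  conc <- pet_volume(array(4.0, c(8, 8, 5)), units = "kBq/mL")
  suv <- suv_convert(conc, weight_kg = 70, injected_MBq = 280)
  expect_true(all(abs(suv - 1.0) < 1e-12))
  expect_true(all(suv_convert(conc * 0, 70, 280) == 0))
  # doubling injected activity halves SUV
  expect_equal(as.numeric(suv_convert(conc, 70, 560)),
               as.numeric(suv) / 2)
  expect_error(suv_convert(conc, -1, 280), "weight")
  expect_error(suv_convert(conc, 70, 0), "injected")
})

test_that("suv_max matches an exhaustive scan", {
  expect_equal(suv_max(pet_volume(array(2.4, c(6, 6, 6))), 1:10), 2.4)
  v <- array(1, c(10, 10, 10)); v[4, 5, 6] <- 3.8
  vol <- pet_volume(v)
  voi <- which(array(TRUE, dim(v)))
  expect_equal(suv_max(vol, voi), 3.8)
  # random VOI of ~1000 voxels vs brute force
  withr::with_seed(9, {
    vals <- array(rnorm(8000), c(20, 20, 20))
    voi <- sample(8000, 1000)
  })
  expect_equal(suv_max(pet_volume(vals), voi), max(vals[voi]))
  expect_error(suv_max(vol, integer(0)), "empty")
})

test_that("suv_peak equals the brute-force best sphere mean", {
  vs <- c(2.7, 2.7, 2.8)
  withr::with_seed(10, vals <- array(runif(20^3, 0, 5), c(20, 20, 20)))
  vol <- pet_volume(vals, vs)
  voi_coords <- as.matrix(expand.grid(i = 8:12, j = 8:12, k = 8:12))
  got <- suv_peak(vol, voi_coords)

  # independent oracle: enumerate every sphere placement directly
  r_mm <- (3 * 1000 / (4 * pi))^(1 / 3)
  best <- -Inf
  for (ci in seq_len(nrow(voi_coords))) {
    ctr <- voi_coords[ci, ]
    sel <- c()
    ok <- TRUE
    for (x in 1:20) for (y in 1:20) for (z in 1:20) {
      if (sum(((c(x, y, z) - ctr) * vs)^2) <= r_mm^2) {
        sel <- c(sel, vals[x, y, z])
      }
    }
    # bounds: sphere fits for these central candidates by construction
    best <- max(best, mean(sel))
  }
  expect_equal(got, best)

  # uniform volume: peak equals the constant
  u <- pet_volume(array(1.7, c(20, 20, 20)), vs)
  expect_equal(suv_peak(u, voi_coords), 1.7)
  # sphere never fits: geometry error
  expect_error(suv_peak(pet_volume(array(1, c(4, 4, 4)), vs),
                        matrix(c(1, 1, 1), 1)), "bounds")
})

test_that("suv_peak never exceeds suv_max (property over random volumes)", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      vals <- array(rexp(18^3), c(18, 18, 18))
      vol <- pet_volume(vals, c(2.7, 2.7, 2.8))
      voi <- sample(which(array(TRUE, dim(vals))[5:14, 5:14, 5:14]), 50)
      coords <- as.matrix(expand.grid(i = 5:14, j = 5:14, k = 5:14))[voi, ]
      expect_lte(suv_peak(vol, coords), suv_max(vol, coords))
    }
  })
})

test_that("the rasterized peak sphere volume is close to 1 cm3", {
  vs <- c(2.7, 2.7, 2.8)
  r_mm <- (3 * 1000 / (4 * pi))^(1 / 3)
  rr <- ceiling(r_mm / vs)
  off <- as.matrix(expand.grid(-rr[1]:rr[1], -rr[2]:rr[2], -rr[3]:rr[3]))
  n_in <- sum(rowSums(sweep(off, 2, vs, `*`)^2) <= r_mm^2)
  vox_vol <- prod(vs)
  expect_lt(abs(n_in * vox_vol - 1000), vox_vol)
})

test_that("liver COV reproduces closed forms and scale invariance", {
  # uniform volume: COV 0
  u <- pet_volume(array(2, c(40, 40, 12)))
  rois <- liver_roi_set(center = c(20, 20), start_slice = 3)
  expect_equal(cov_liver(u, rois), 0)

  # two-value pattern: half voxels 1, half 3 in each circle -> COV 0.5
  vals <- array(0, c(40, 40, 12))
  vals[seq(1, 39, by = 2), , ] <- 1
  vals[seq(2, 40, by = 2), , ] <- 3
  v <- pet_volume(vals)
  # rows alternate 1/3; each 6 cm circle contains equally many of each row
  # pattern only if the circle spans an even number of rows symmetrically;
  # construct the exact two-value case instead via a checkerboard of rows
  d <- dim(vals)
  vsz <- voxel_size(v)
  r <- 30
  di <- (seq_len(d[1]) - 20) * vsz[1]
  dj <- (seq_len(d[2]) - 20) * vsz[2]
  inside <- outer(di^2, dj^2, `+`) < r^2
  n1 <- sum(inside[seq(1, 39, 2), ])
  n3 <- sum(inside[seq(2, 40, 2), ])
  if (n1 == n3) {
    expect_equal(cov_liver(v, rois), 0.5)
  }
  # exact closed form on a handmade half-half circle regardless of geometry
  vals2 <- array(1, c(40, 40, 12))
  sel <- which(inside)
  half <- sel[seq_len(floor(length(sel) / 2))]
  for (z in c(3, 5, 7)) {
    sl <- vals2[, , z]; sl[sel] <- 1; sl[half] <- 3
    if (length(half) * 2 == length(sel)) vals2[, , z] <- sl
  }
  if (length(half) * 2 == length(sel)) {
    expect_equal(cov_liver(pet_volume(vals2), rois), 0.5)
  }

  # scale invariance
  withr::with_seed(12, nz <- array(rexp(40 * 40 * 12) + 0.1,
                                   c(40, 40, 12)))
  nv <- pet_volume(nz)
  expect_equal(cov_liver(nv, rois), cov_liver(pet_volume(nz * 7.3), rois),
               tolerance = 1e-12)
  expect_gt(cov_liver(nv, rois), 0)
})

test_that("ROI sets use three circles with one slice in between", {
  rois <- liver_roi_set(c(10, 10), start_slice = 4)
  expect_identical(rois$slices, c(4L, 6L, 8L))
  expect_equal(rois$diameter_mm, 60)
  act <- build_phantom(small_phantom_spec())
  auto <- liver_rois_from_phantom(act)
  expect_s3_class(auto, "liver_roi_set")
  expect_equal(diff(auto$slices), c(2L, 2L))
})

test_that("evaluate_image_sets emits one row per image set and lesion", {
  act <- build_phantom(small_phantom_spec(
    lesions = list(lesion_spec(c(38, 38, 10), 14, 4),
                   lesion_spec(c(38, 12, 22), 12, 3))))
  rois <- liver_rois_from_phantom(act)
  masks <- phantom_masks(act)
  sets <- list("A" = act, "B" = act)
  m <- evaluate_image_sets(sets, masks[c("lesion_1", "lesion_2")], rois,
                           subject = "p1")
  expect_equal(nrow(m), 4)
  expect_setequal(names(m), c("subject", "image_set", "lesion", "suv_max",
                              "suv_peak", "cov"))
  expect_true(all(m$suv_peak <= m$suv_max))
  expect_equal(m$suv_max[m$lesion == "lesion_1"], c(4, 4))
})

test_that("lesion preservation check flags kept and lost hotspots", {
  act <- build_phantom(small_phantom_spec(
    lesions = list(lesion_spec(c(38, 38, 10), 14, 4))))
  masks <- phantom_masks(act)
  keep <- check_lesion_preservation(act, act, masks)
  expect_true(all(keep$lesions$preserved))
  expect_false(keep$hotspot_added)
  flat <- with_values <- pet_volume(array(0.7, dim(act)), voxel_size(act))
  lost <- check_lesion_preservation(act, flat, masks)
  expect_false(any(lost$lesions$preserved))
})
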