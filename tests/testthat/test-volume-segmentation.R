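test_that("NIfTI volumes load with calibration, clamping and cropping", {
  path <- write_tmp_nifti(array(-1000, dim = c(8, 8, 8)), c(0.5, 0.5, 0.5))
  vol <- read_hu_volume(path)
  expect_s3_class(vol, "hu_volume")
  expect_true(all(vol$data == -1000))
  expect_equal(vol$spacing, c(0.5, 0.5, 0.5))

  # CT rescale definition: stored 0, slope 1, intercept -1024 -> -1024 HU
  expect_equal(hu_rescale(0, 1, -1024), -1024)
  expect_equal(hu_rescale(c(100, 2000), 2, -1024), c(-824, 2976))

  # clamping to the 12-bit CT range on construction
  v2 <- hu_volume(array(c(-4000, 5000, 0), dim = c(3, 1, 1)), 1)
  expect_equal(range(v2$data), c(-1024, 3071))

  expect_error(read_hu_volume(tempfile()), "cannot read")
})

test_that("crop extracts the requested voxel box and preserves coordinates", {
  arr <- array(seq_len(64^3), dim = c(64, 64, 64))
  vol <- hu_volume(pmin(arr, 3071), spacing = 0.5, clamp = FALSE)
  roi <- crop_volume(vol, lo = c(11, 11, 11), hi = c(20, 20, 20))
  expect_equal(dim(roi$data), c(10, 10, 10))
  expect_equal(roi$data[1, 1, 1], vol$data[11, 11, 11])
  expect_equal(roi$origin, vol$origin + 10 * 0.5)
  expect_error(crop_volume(vol, c(0, 1, 1), c(10, 10, 10)), "outside")
  expect_error(crop_volume(vol, c(60, 1, 1), c(65, 10, 10)), "outside")
})

test_that("isotropic resampling conserves extent and affine fields", {
  vol <- hu_volume(array(7, dim = c(10, 10, 10)), spacing = 0.5,
                   clamp = FALSE)
  out <- resample_isotropic(vol, 0.1)
  expect_equal(dim(out$data), c(50, 50, 50))
  expect_equal(out$spacing, rep(0.1, 3))
  # constant stays constant whatever the shape
  expect_true(all(abs(out$data - 7) < 1e-12))

  # linear HU ramp is reproduced by trilinear interpolation (interior)
  n <- 12
  ramp <- array(0, dim = c(n, n, n))
  for (i in seq_len(n)) ramp[i, , ] <- 10 * i
  rv <- hu_volume(ramp, spacing = 0.5, clamp = FALSE)
  rr <- resample_isotropic(rv, 0.25)
  # expected ramp value at output voxel centres, in HU per mm
  centers <- (seq_len(dim(rr$data)[1]) - 0.5) * 0.25
  expected <- 10 * (centers / 0.5 + 0.5)
  interior <- centers > 0.5 & centers < (n - 0.5) * 0.5
  err <- abs(sweep(rr$data[interior, , ], 1, expected[interior]))
  expect_lt(max(err), 1)

  expect_error(resample_isotropic(vol, 0), "positive")
  expect_error(resample_isotropic(vol, -1), "positive")
})

test_that("HU thresholding assigns the unique band of each voxel", {
  vals <- c(-400, 5, -800, 0, -750, -300.0001, -500, -1000, 150)
  vol <- hu_volume(array(vals, dim = c(length(vals), 1, 1)), 1,
                   clamp = FALSE)
  lab <- threshold_classes(vol)
  # core (>0), gg1 (-300,0], gg2 (-500,-300], gg3 [-750,-500]
  expect_equal(as.vector(lab$labels), c(3L, 1L, 0L, 2L, 4L, 3L, 4L, 0L, 1L))

  # masked voxels go to background
  mask <- array(TRUE, dim = dim(vol$data)); mask[1] <- FALSE
  labm <- threshold_classes(vol, mask = mask)
  expect_equal(labm$labels[1], 0L)

  bad <- list(hu_class("a", -100, 0), hu_class("b", -50, 50))
  expect_error(threshold_classes(vol, bad), "overlap")
})

test_that("default bands tile (-750, Inf) exactly once", {
  classes <- default_hu_classes()
  hu <- seq(-760, 200, by = 7.77)
  n_match <- vapply(hu, function(h)
    sum(vapply(classes, function(cl) nodulefab:::in_class(cl, h), TRUE)), 0L)
  expect_true(all(n_match[hu >= -750] == 1L))
  expect_true(all(n_match[hu < -750] == 0L))
  # boundary values are assignable exactly once
  one_class <- function(h)
    sum(vapply(classes, function(cl) nodulefab:::in_class(cl, h), TRUE))
  expect_equal(one_class(-750), 1L)
  expect_equal(one_class(0), 1L)
  expect_equal(one_class(-750 - 1e-9), 0L)
})

test_that("class meshes are watertight and volume-faithful", {
  # digitized ball, radius 3 mm at 0.1 mm spacing
  n <- 70
  ax <- (seq_len(n) - (n + 1) / 2) * 0.1
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  hu <- array(-1000, dim = c(n, n, n))
  hu[r <= 3] <- 100
  vol <- hu_volume(hu, 0.1, clamp = FALSE)
  lab <- threshold_classes(vol)
  mesh <- class_mesh(lab, "core")
  expect_true(is_watertight(mesh))
  analytic <- 4 / 3 * pi * 27
  expect_lt(abs(mesh_volume(mesh) - analytic) / analytic, 0.05)

  # axis-aligned cuboid: mesh volume equals voxel count x voxel volume
  hu2 <- array(-1000, dim = c(12, 12, 12))
  hu2[3:8, 2:11, 4:6] <- 50
  lab2 <- threshold_classes(hu_volume(hu2, 0.25, clamp = FALSE))
  m2 <- class_mesh(lab2, "core")
  v_expect <- 6 * 10 * 3 * 0.25^3
  expect_lt(abs(mesh_volume(m2) - v_expect) / v_expect, 0.01)

  expect_error(class_mesh(lab2, "gg2"), "empty")
  expect_error(class_mesh(lab2, "nonexistent"), "unknown")
})

test_that("mesh volume error against the continuum shrinks with spacing", {
  ball_mesh <- function(sp) {
    n <- ceiling(8 / sp)
    ax <- (seq_len(n) - (n + 1) / 2) * sp
    r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
    hu <- array(-1000, dim = c(n, n, n)); hu[r <= 3] <- 100
    class_mesh(threshold_classes(hu_volume(hu, sp, clamp = FALSE)), "core")
  }
  analytic <- 4 / 3 * pi * 27
  err <- vapply(c(0.4, 0.1), function(sp)
    abs(mesh_volume(ball_mesh(sp)) - analytic), 0)
  expect_lt(err[2], err[1])
})

test_that("ROI statistics match closed forms and are resampling-invariant", {
  vol <- hu_volume(array(-350, dim = c(20, 20, 20)), 0.5, clamp = FALSE)
  st <- measure_roi_hu(vol, c(5, 5, 5), 2)
  expect_equal(st$mean, -350)
  expect_equal(st$sd, 0)
  expect_gt(st$n, 1)

  # equal halves of a and b: mean (a+b)/2, population sd |a-b|/2
  half <- array(-200, dim = c(20, 20, 20)); half[11:20, , ] <- -600
  vh <- hu_volume(half, 0.5, clamp = FALSE)
  sh <- measure_roi_hu(vh, c(0.5 * 19 / 2, 4, 4), 5)
  expect_equal(sh$mean, -400)
  expect_equal(sh$sd, 200)

  # i.i.d. Gaussian field, large ROI
  set.seed(11)
  g <- array(rnorm(40^3, mean = -500, sd = 30), dim = c(40, 40, 40))
  vg <- hu_volume(g, 0.5, clamp = FALSE)
  sg <- measure_roi_hu(vg, c(10, 10, 10), 8)
  expect_lt(abs(sg$mean + 500), 5)
  expect_lt(abs(sg$sd - 30), 5)

  # disc mode restricts to one slab
  sd_ <- measure_roi_hu(vh, c(4, 4, 4), 3, mode = "disc")
  expect_equal(sd_$n, sum(outer((0:19 * 0.5 - 4)^2,
                                (0:19 * 0.5 - 4)^2, "+") <= 9))

  # constant volume: ROI stats invariant under isotropic resampling
  rs <- resample_isotropic(vol, 0.3)
  st2 <- measure_roi_hu(rs, c(5, 5, 5), 2)
  expect_equal(st2$mean, st$mean, tolerance = 1e-12)
  expect_equal(st2$sd, 0)

  expect_error(measure_roi_hu(vol, c(50, 50, 50), 2), "ROI")
})
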