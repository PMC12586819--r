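test_that("partial-volume prediction is the linear mixing law", {
  m <- partial_volume_model(120)
  expect_equal(predict_hu(m, 0), -1000)
  expect_equal(predict_hu(m, 1), 120)
  expect_equal(predict_hu(m, 0.5), -440)
  expect_equal(predict(m, c(0, 1)), c(-1000, 120))
  expect_error(predict_hu(m, 1.2), "\\[0, 1\\]")
  expect_error(predict_hu(m, -0.1), "\\[0, 1\\]")
  expect_error(partial_volume_model(-1500), "exceed")

  # affine and strictly increasing in f
  f <- seq(0, 1, by = 0.05)
  p <- predict_hu(m, f)
  expect_true(all(diff(p) > 0))
  expect_equal(max(abs(diff(p) - diff(p)[1])), 0, tolerance = 1e-9)
})

test_that("material HU is recovered from calibration records", {
  g <- design_grid()
  truth <- partial_volume_model(120)
  recs <- data.frame(t_um = g$t_um, g_um = g$g_um,
                     mean_hu = predict_hu(truth, g$fill))
  fit <- fit_material_hu(recs)
  expect_lt(abs(coef(fit)["hu_material"] - 120), 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-9)

  # Gaussian measurement noise: estimator stays near the truth
  set.seed(1)
  recs$mean_hu <- predict_hu(truth, g$fill) + rnorm(18, sd = 10)
  fitn <- fit_material_hu(recs)
  expect_lt(abs(coef(fitn)["hu_material"] - 120), 15)

  # a single design is not identifiable
  one <- data.frame(t_um = rep(680, 3), g_um = rep(680, 3),
                    mean_hu = c(-440, -445, -438))
  expect_error(fit_material_hu(one), "identifiable")
  expect_error(fit_material_hu(recs[0, ]), "at least two")
})

test_that("calibration CSV schema is validated on read", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(t_um = 340, g_um = 680, kv = 120, ctdi_mgy = 1.5,
                   algorithm = "FBP", kernel = "hard",
                   mean_hu = -700, sd_hu = 25)
  write.csv(df, path, row.names = FALSE)
  expect_silent(recs <- read_calibration(path))
  expect_equal(recs$mean_hu, -700)
  write.csv(df[, -8], path, row.names = FALSE)
  expect_error(read_calibration(path), "sd_hu")
})

test_that("lattice selection reproduces the published band mapping", {
  pick <- function(lo, hi) select_lattice(c(lo, hi))
  s3 <- pick(-750, -500)
  expect_equal(c(s3$t_um, s3$g_um), c(340, 1020))
  s2 <- pick(-500, -300)
  expect_equal(c(s2$t_um, s2$g_um), c(510, 850))
  s1 <- pick(-300, 0)
  expect_equal(c(s1$t_um, s1$g_um), c(680, 680))
})

test_that("model-based selection picks the nearest feasible prediction", {
  grid <- design_grid()
  model <- partial_volume_model(120)
  rules <- default_visibility_rules()
  target <- c(-800, -600)
  sel <- select_lattice(target, grid, model, rules, anchors = NULL)
  # independent oracle: brute-force nearest-to-midpoint over feasible specs
  feas <- Filter(function(s)
    !any(rules$t_um == s$t_um & s$g_um >= rules$g_min_visible_um),
    grid_specs(grid))
  d <- vapply(feas, function(s)
    abs(predict_hu(model, fill_fraction(s)) - mean(target)), 0)
  cand <- which(d < min(d) + 1e-9)
  best <- feas[[cand[which.max(vapply(feas[cand], `[[`, 0, "t_um"))]]]
  expect_equal(c(sel$t_um, sel$g_um), c(best$t_um, best$g_um))

  # visibility exclusion removes large voids; all-excluded errors out
  harsh <- data.frame(t_um = c(340, 510, 680),
                      g_min_visible_um = c(680, 680, 680),
                      kernel_scope = "both")
  expect_error(
    select_lattice(target, grid, model, harsh, anchors = NULL),
    "no feasible design")

  # ties break toward thicker beams: two specs share r = 1/3
  tie_grid <- design_grid(c(340, 680), c(680, 1360))
  sel_tie <- select_lattice(c(-712, -706), tie_grid, model, rules = NULL,
                            anchors = NULL)
  expect_equal(sel_tie$t_um, 680)
})

test_that("occupancy voxelization resolves containment and partial layers", {
  cube <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  for (meth in c("exact", "sampling")) {
    occ <- voxelize_occupancy(cube, 0.25, supersample = 4, method = meth)
    expect_equal(dim(occ$data), c(4, 4, 4))
    expect_true(all(abs(occ$data - 1) < 1e-12))

    # a box ending mid-layer: top layer half filled
    slab <- box_mesh(c(0, 0, 0), c(1, 1, 0.625))
    occ2 <- voxelize_occupancy(slab, 0.25, supersample = 4, method = meth)
    expect_equal(dim(occ2$data)[3], 3L)
    expect_true(all(abs(occ2$data[, , 1:2] - 1) < 1e-12))
    expect_true(all(abs(occ2$data[, , 3] - 0.5) < 1e-12))
  }

  # sampled lattice occupancy matches the closed-form fill fraction
  spec <- lattice_spec(510, 850)
  m <- build_lattice_mesh(spec, 8)
  occ3 <- voxelize_occupancy(m, 0.2, supersample = 4, method = "sampling")
  expect_lt(abs(mean(occ3$data) - fill_fraction(spec)), 0.01)
  # total volume consistency
  expect_lt(abs(mean(occ3$data) * 512 - mesh_volume(m)) / mesh_volume(m),
            0.02)
  # the exact path integrates the lattice to closed form
  occ4 <- voxelize_occupancy(m, 0.2, method = "exact")
  expect_lt(abs(mean(occ4$data) - fill_fraction(spec)), 1e-9)

  open_mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3)))
  expect_error(voxelize_occupancy(open_mesh, 0.25), "watertight")
})

test_that("virtual CT reproduces the mixing law under blur and noise", {
  m <- partial_volume_model(120)
  occ1 <- structure(list(data = array(1, dim = c(6, 6, 6)),
                         spacing = rep(0.5, 3), origin = rep(0.25, 3)),
                    class = "occ_volume")
  ct1 <- simulate_ct(occ1, m, psf_sigma = 0, noise_sd = 0)
  expect_true(all(ct1$data == 120))
  occ0 <- occ1; occ0$data[] <- 0
  expect_true(all(simulate_ct(occ0, m, 0, 0)$data == -1000))

  # sigma = 0: whole-cube mean equals the closed form within 5 HU
  spec <- lattice_spec(680, 680)
  occ <- voxelize_occupancy(build_lattice_mesh(spec, 10), 0.25, 4)
  ct <- simulate_ct(occ, m, psf_sigma = 0, noise_sd = 0)
  roi <- measure_roi_hu(ct, c(5, 5, 5), 20)
  expect_lt(abs(roi$mean - predict_hu(m, fill_fraction(spec))), 5)

  # heavy blur preserves the mean over a central ROI
  ctb <- simulate_ct(occ, m, psf_sigma = 2 * spec$p_um / 1000, noise_sd = 0)
  roib <- measure_roi_hu(ctb, c(5, 5, 5), 2.5)
  expect_lt(abs(roib$mean - predict_hu(m, fill_fraction(spec))), 5)

  # noise requires a seed and is reproducible
  expect_error(simulate_ct(occ1, m, 0, noise_sd = 20), "seed")
  n1 <- simulate_ct(occ1, m, 0, noise_sd = 20, seed = 3)
  n2 <- simulate_ct(occ1, m, 0, noise_sd = 20, seed = 3)
  expect_identical(n1$data, n2$data)
})

test_that("visibility score separates resolved from blurred lattices", {
  m <- partial_volume_model(120)
  # constant volume: no structure, score 0
  flat <- hu_volume(array(-440, dim = c(30, 30, 30)), 0.25, clamp = FALSE)
  v0 <- lattice_visibility_score(flat, lattice_spec(680, 680))
  expect_equal(v0$score, 0)
  expect_false(v0$visible)

  spec <- lattice_spec(680, 1020)
  occ <- voxelize_occupancy(build_lattice_mesh(spec, 10), 0.25, 2)
  sharp <- lattice_visibility_score(simulate_ct(occ, m, 0, 0), spec)
  expect_true(sharp$visible)
  blurred <- lattice_visibility_score(
    simulate_ct(occ, m, psf_sigma = 2 * spec$p_um / 1000, noise_sd = 0),
    spec)
  expect_false(blurred$visible)
  expect_gt(sharp$score, blurred$score)

  tiny <- hu_volume(array(-440, dim = c(4, 4, 4)), 0.25, clamp = FALSE)
  expect_error(lattice_visibility_score(tiny, spec), "three lattice periods")
})

test_that("visibility grows with void size once the pattern is resolvable", {
  m <- partial_volume_model(120)
  voids <- c(680, 850, 1020, 1360, 1700, 2040)
  for (t in c(340, 680)) {
    res <- lapply(voids, function(g) {
      spec <- lattice_spec(t, g)
      occ <- voxelize_occupancy(build_lattice_mesh(spec, 10), 0.25, 2)
      list(
        score = lattice_visibility_score(
          simulate_ct(occ, m, psf_sigma = 0.3, noise_sd = 0), spec)$score,
        flag = lattice_visibility_score(
          simulate_ct(occ, m, psf_sigma = 0.6, noise_sd = 0), spec)$visible)
    })
    # score monotone where the PSF leaves the pattern resolvable
    expect_true(all(diff(vapply(res, `[[`, 0, "score")) >= 0))
    # at the clinical-resolution default PSF the visible flag switches
    # on at most once as voids grow
    flags <- vapply(res, `[[`, TRUE, "flag")
    expect_true(all(diff(as.integer(flags)) >= 0))
  }
})

test_that("fitting inverts prediction exactly on model-generated records", {
  g <- design_grid()
  for (hm in c(60, 120, 300)) {
    truth <- partial_volume_model(hm)
    recs <- data.frame(t_um = g$t_um, g_um = g$g_um,
                       mean_hu = predict_hu(truth, g$fill))
    expect_equal(unname(coef(fit_material_hu(recs))["hu_material"]), hm,
                 tolerance = 1e-9)
  }
})
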