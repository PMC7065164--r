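# Generator ground truth: mask discretization, dual-echo forward model,
# population variability, determinism.

test_that("constant-CSA tube discretizes to the requested area per slice", {
  spec <- const_spec(50, 40)
  g <- make_grid(c(52, 48, 48), c(1, 1, 1))
  m <- make_mask(spec, g, "left")
  inner <- m$truth[m$truth$u_mm > 1 & m$truth$u_mm < 39, ]
  expect_true(all(abs(inner$csa_frac_mm2 - 50) <= 1))
  expect_true(all(abs(inner$csa_mm2 - 50) <= 2))
})

test_that("ellipsoid mode reproduces the analytic central cross-section", {
  spec <- phantom_spec(shape = "ellipsoid", ellipsoid_semiaxes = c(25, 10, 8),
                      lateral_offset_mm = 0)
  g <- make_grid(c(48, 60, 48), c(1, 1, 1))
  m <- make_mask(spec, g, "left")
  central <- m$truth[which.min(abs(m$truth$u_mm - 25)), ]
  expect_lt(abs(central$csa_frac_mm2 - pi * 10 * 8), 2)
})

test_that("atrophic lesions halve the CSA inside their band only", {
  g <- small_t1_grid()
  les <- list(centre_mm = 30, extent_mm = 6, atrophy_fraction = 0.5,
              delta_t2 = 0)
  m0 <- make_mask(phantom_spec(), g, "left")
  m1 <- make_mask(phantom_spec(lesion = les), g, "left")
  tr <- merge(m0$truth, m1$truth, by = "slice", suffixes = c("_0", "_1"))
  inside <- tr$u_mm_0 >= 28 & tr$u_mm_0 <= 32
  outside <- tr$u_mm_0 < 26 | tr$u_mm_0 > 34
  ratio <- tr$csa_frac_mm2_1[inside] / tr$csa_frac_mm2_0[inside]
  expect_true(all(abs(ratio - 0.5) < 0.05))
  expect_equal(tr$csa_frac_mm2_1[outside], tr$csa_frac_mm2_0[outside])
})

test_that("dual-echo signals follow the mono-exponential forward model", {
  spec <- straight_spec(noise_sd = 0, t2_tissue = 115)
  e <- make_dual_echo(spec)
  tissue <- e$t2$data == 115
  ratio <- e$echo1$data[tissue] / e$echo2$data[tissue]
  expect_lt(max(abs(ratio - exp(89 / 115))), 1e-10)
})

test_that("degenerate echo spacing is rejected", {
  spec <- phantom_spec(te = c(30, 30))
  expect_error(make_dual_echo(spec), "TE2 > TE1")
})

test_that("identical spec and seed reproduce the phantom bit for bit", {
  a <- make_phantom_subject(phantom_spec(seed = 99), with_t1 = TRUE)
  b <- make_phantom_subject(phantom_spec(seed = 99), with_t1 = TRUE)
  expect_identical(a$echo1$data, b$echo1$data)
  expect_identical(a$t1$data, b$t1$data)
  expect_identical(a$mask_left$data, b$mask_left$data)
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(31)
  before <- runif(1)
  set.seed(31)
  invisible(make_phantom_subject(phantom_spec(seed = 5), with_t1 = FALSE))
  expect_identical(runif(1), before)
})

test_that("population draws honour the requested variability", {
  # zero variance: all truth profiles identical
  pop0 <- make_population(
    3, phantom_spec(),
    variability = list(csa_scale_sd = 0, t2_sd = 0, tiv_sd_ml = 0),
    pose_range = list(angles_deg = 0, translation_mm = 0),
    seed = 3, images = FALSE)
  expect_equal(pop0[[1]]$csa_scale, pop0[[2]]$csa_scale)
  expect_equal(pop0[[1]]$t2_tissue, pop0[[3]]$t2_tissue)

  # csa_scale_sd is reflected in the spread of whole volumes (TIV held fixed)
  pop <- make_population(
    111, phantom_spec(),
    variability = list(csa_scale_sd = 0.08, t2_sd = 0, tiv_sd_ml = 0),
    seed = 17, images = FALSE)
  u <- seq(0.25, 44.75, by = 0.5)
  vols <- vapply(pop, function(s) sum(base_csa_profile(s)(u)) * 0.5,
                 numeric(1))
  rel_sd <- sd(vols) / mean(vols)
  expect_lt(abs(rel_sd - 0.08), 0.25 * 0.08)

  # different seeds give different poses
  pop_b <- make_population(3, phantom_spec(), seed = 18, images = FALSE)
  pop_c <- make_population(3, phantom_spec(), seed = 19, images = FALSE)
  expect_false(isTRUE(all.equal(pop_b[[1]]$pose$angles_deg,
                                pop_c[[1]]$pose$angles_deg)))
})

test_that("integrating the truth profile reproduces the mask volume", {
  g <- small_t1_grid()
  m <- make_mask(phantom_spec(seed = 2), g, "left")
  integral <- sum(m$truth$csa_frac_mm2) * 1 # 1-mm slices
  # identity pose: the posed mask is the truth mask
  mask_vol <- sum(m$seg$data) * voxel_volume(m$seg)
  expect_lt(abs(integral - mask_vol) / mask_vol, 0.01)
})

test_that("lesion spec validation rejects impossible fractions", {
  expect_error(phantom_spec(lesion = list(centre_mm = 30, extent_mm = 6,
                                          atrophy_fraction = 1.5)))
})
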