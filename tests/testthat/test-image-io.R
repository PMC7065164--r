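# NIfTI round trips, voxel geometry and resampling.

test_that("NIfTI write/read round-trips voxels exactly and affine closely", {
  set.seed(7)
  arr <- array(rnorm(10 * 12 * 8), c(10, 12, 8))
  aff <- rigid_transform(c(10, -5, 20), c(3, -2, 1))$matrix %*%
    diag(c(1, 1, 2, 1))
  vol <- image_volume(arr, aff, "T1")
  f <- tempfile(fileext = ".nii.gz")
  save_volume(vol, f)
  back <- load_volume(f)
  expect_identical(back$data, arr)
  expect_lt(max(abs(back$affine - aff)), 1e-5)
})

test_that("voxel spacings and volumes match the acquisition geometries", {
  t1 <- make_grid(c(8, 8, 8), c(1, 1, 1))
  expect_equal(voxel_spacing(t1), c(1, 1, 1))
  expect_equal(voxel_volume(t1), 1.00)
  pd <- make_grid(c(8, 8, 8), c(0.43, 0.43, 4.00))
  expect_equal(voxel_spacing(pd), c(0.43, 0.43, 4.00))
  expect_equal(round(voxel_volume(pd), 2), 0.74)
  # brute force: voxel volume equals total volume over voxel count
  expect_equal(voxel_volume(pd),
               prod(dim(pd$data)) * voxel_volume(pd) / prod(dim(pd$data)))
})

test_that("voxel_volume is invariant under rigid transforms of the affine", {
  g <- make_grid(c(6, 6, 6), c(0.43, 0.43, 4.0))
  R <- rigid_transform(c(25, -40, 10), c(5, 6, 7))$matrix
  rotated <- image_volume(g$data, R %*% g$affine, "T1")
  expect_equal(voxel_volume(rotated), voxel_volume(g))
})

test_that("degenerate or 4-D inputs are rejected", {
  expect_error(image_volume(array(0, c(4, 4, 4)), matrix(0, 4, 4)),
               "geometry error")
  f <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(rnorm(4^4), c(4, 4, 4, 4)))
  RNifti::writeNifti(img, f)
  expect_error(load_volume(f), "unsupported-input")
  # singleton 4th axis is accepted
  f2 <- tempfile(fileext = ".nii.gz")
  img2 <- RNifti::asNifti(array(rnorm(4^3), c(4, 4, 4, 1)))
  RNifti::writeNifti(img2, f2)
  expect_equal(dim(load_volume(f2)$data), c(4L, 4L, 4L))
})

test_that("identity resampling is exact and voxel shifts relabel the grid", {
  set.seed(1)
  vol <- image_volume(array(rnorm(8^3), c(8, 8, 8)))
  same <- resample(vol, identity_transform(), vol, "nearest")
  expect_identical(same$data, vol$data)
  shifted <- resample(vol, rigid_transform(translation = c(1, 0, 0)), vol,
                      "nearest", fill = 0)
  expect_equal(shifted$data[2:8, , ], vol$data[1:7, , ])
  expect_true(all(shifted$data[1, , ] == 0))
})

test_that("rotation round trip on a smooth volume stays within tolerance", {
  vol <- blob_volume()
  th <- 17
  fwd <- resample(vol, rigid_transform(c(0, 0, th)), vol, "linear", fill = 0)
  back <- resample(fwd, rigid_transform(c(0, 0, -th)), vol, "linear",
                   fill = 0)
  interior <- back$data[8:25, 8:25, 8:25] - vol$data[8:25, 8:25, 8:25]
  expect_lt(max(abs(interior)), 0.02)
})

test_that("transform composition and inversion behave as a group", {
  t1 <- rigid_transform(c(10, 20, 30), c(1, -2, 3))
  t2 <- world_transform(hippoaxis:::params_to_affine(
    c(5, -5, 10, 2, 1, 0, 0.05, -0.02, 0.01, 0.01, 0, 0)), "affine")
  comp <- compose_transforms(t1, t2)
  expect_lt(max(abs(compose_transforms(comp, invert_transform(comp))$matrix -
                      diag(4))), 1e-6)
  # associativity
  t3 <- rigid_transform(c(0, 0, 45))
  a <- compose_transforms(compose_transforms(t1, t2), t3)
  b <- compose_transforms(t1, compose_transforms(t2, t3))
  expect_lt(max(abs(a$matrix - b$matrix)), 1e-9)
  # rigid constructor rejects improper rotations
  bad <- diag(4); bad[1, 1] <- 2
  expect_error(world_transform(bad, "rigid"), "proper rotation")
})
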