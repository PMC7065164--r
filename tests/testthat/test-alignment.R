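# Long-axis estimation, reorientation, distance maps, majority masks.

box_segmentation <- function(half = c(20, 4, 4), rot_deg = NULL,
                             dims = c(56, 56, 56)) {
  g <- make_grid(dims, c(1, 1, 1))
  w <- hippoaxis:::grid_world_coords(g)
  if (!is.null(rot_deg)) w <- w %*% hippoaxis:::rot3(rot_deg) # inverse rot
  # box elongated along y
  inc <- abs(w[, 2]) <= half[1] & abs(w[, 1]) <= half[2] &
    abs(w[, 3]) <= half[3]
  segmentation(array(as.numeric(inc), dims), g$affine, "left")
}

test_that("the principal axis of an elongated box is its long axis", {
  seg <- box_segmentation()
  pa <- principal_axis(seg)
  expect_lt(max(abs(pa$axis - c(0, 1, 0))), 1e-6)

  rot <- box_segmentation(rot_deg = c(0, 0, 30))
  pa2 <- principal_axis(rot)
  truth <- hippoaxis:::rot3(c(0, 0, 30)) %*% c(0, 1, 0)
  ang <- acos(min(1, abs(sum(pa2$axis * truth)))) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("isotropic masks are rejected as degenerate", {
  g <- make_grid(c(32, 32, 32), c(1, 1, 1))
  w <- hippoaxis:::grid_world_coords(g)
  sph <- segmentation(array(as.numeric(rowSums(w^2) <= 100), c(32, 32, 32)),
                      g$affine, "left")
  expect_error(principal_axis(sph), "degenerate-axis")
  tiny <- segmentation(array(c(rep(1, 5), rep(0, 27 - 5)), c(3, 3, 3)),
                       diag(4), "left")
  expect_error(principal_axis(tiny), ">= 10")
})

test_that("reorientation is the identity on an AP-aligned phantom", {
  s <- make_phantom_subject(straight_spec(), with_t1 = FALSE)
  r <- reorient_to_ap(NULL, s$mask_left, s$mask_right)
  expect_lt(max(abs(r$matrix - diag(4))), 1e-6)
})

test_that("reorientation recovers a known rigid pose within a degree", {
  pose <- list(angles_deg = c(9, -7, 12), translation = c(2, -1, 3))
  spec <- straight_spec(pose = pose)
  s <- make_phantom_subject(spec, with_t1 = FALSE)
  r <- reorient_to_ap(NULL, s$mask_left, s$mask_right)
  resid <- r$matrix[1:3, 1:3] %*% hippoaxis:::rot3(pose$angles_deg)
  ang <- acos(pmin(1, (sum(diag(resid)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
  # post-transform long axes are on the AP axis
  for (side in c("mask_left", "mask_right")) {
    seg_r <- resample(s[[side]], r, s[[side]], "linear")
    pa <- principal_axis(seg_r)
    expect_lt(acos(min(1, abs(pa$axis[2]))) * 180 / pi, 2)
  }
})

test_that("strongly disagreeing long axes raise an alignment failure", {
  a <- box_segmentation()
  b <- box_segmentation(rot_deg = c(0, 0, 60))
  b$side <- "right"
  expect_error(reorient_to_ap(NULL, a, b), "alignment-failure")
})

test_that("the template distance map counts millimetres from posterior", {
  tpl <- make_grid(c(4, 218, 4), c(1, 1, 1))
  dm <- build_distance_map(tpl)
  expect_equal(dm$data[1, , 1], as.numeric(1:218))
  expect_equal(range(dm$data), c(1, 218))
  tpl2 <- make_grid(c(4, 30, 4), c(1, 2, 1))
  expect_equal(build_distance_map(tpl2)$data[1, , 1], seq(2, 60, by = 2))
})

test_that("distance propagation is exact for identity, shift and scale", {
  tpl <- make_grid(c(10, 60, 10), c(1, 1, 1))
  dm <- build_distance_map(tpl)
  seg <- segmentation(array(0, dim(tpl$data)), tpl$affine, "left")
  seg$data[4:7, 10:49, 4:7] <- 1

  tab <- slice_distance_table(propagate_distance_map(
    dm, identity_transform(), tpl), seg)
  expect_equal(tab$distance_mm, as.numeric(10:49))

  # anatomy shifted anteriorly by t: mask shifted with it reads the same
  # distances; the fixed mask reads distances lower by t
  t_mm <- 5
  shift <- rigid_transform(translation = c(0, t_mm, 0))
  prop <- propagate_distance_map(dm, shift, tpl)
  tab_fixed <- slice_distance_table(prop, seg)
  expect_equal(tab_fixed$distance_mm, as.numeric(10:49) - t_mm)
  seg_shift <- segmentation(array(0, dim(tpl$data)), tpl$affine, "left")
  seg_shift$data[4:7, 15:54, 4:7] <- 1
  expect_equal(slice_distance_table(prop, seg_shift)$distance_mm,
               as.numeric(10:49))

  # AP scaling about the grid centre
  s <- 1.2
  centre_y <- 0
  sc <- world_transform(diag(c(1, s, 1, 1)), "affine")
  tab_s <- slice_distance_table(propagate_distance_map(dm, sc, tpl), seg)
  y <- hippoaxis:::slice_ap_position(tpl, 10:49)
  y0 <- hippoaxis:::slice_ap_position(tpl, 1)
  analytic <- (centre_y + (y - centre_y) / s - y0) + 1
  expect_lt(max(abs(tab_s$distance_mm - analytic)), 0.5)
  expect_true(all(diff(tab_s$distance_mm) > 0))
})

test_that("majority masks equal brute-force per-voxel counting", {
  set.seed(5)
  d <- c(7, 6, 5)
  g <- make_grid(d, c(1, 1, 1))
  segs <- lapply(1:7, function(i) {
    segmentation(array(as.numeric(runif(prod(d)) > 0.5), d), g$affine,
                 "left")
  })
  mm <- majority_mask(segs)
  counts <- Reduce(`+`, lapply(segs, function(s) s$data >= 0.5))
  expect_identical(mm$data >= 0.5, counts / 7 >= 0.5)

  # exactly half of an even stack is included
  half <- lapply(1:4, function(i) {
    v <- array(0, d); if (i <= 2) v[1, 1, 1] <- 1
    segmentation(v, g$affine, "left")
  })
  expect_equal(majority_mask(half)$data[1, 1, 1], 1)
  # unanimity and absence
  expect_equal(majority_mask(segs[1])$data, segs[[1]]$data)
  expect_error(majority_mask(list()), "empty-input")
})
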