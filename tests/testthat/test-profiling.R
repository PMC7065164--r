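# CSA/qT2 profile construction, TIV correction, region partitioning and
# regional metrics.

# minimal synthetic segmentation + distance table on its own grid
flat_seg <- function(counts) {
  dims <- c(max(counts) + 2, length(counts) + 4, 8)
  g <- make_grid(dims, c(1, 1, 1))
  arr <- array(0, dims)
  for (j in seq_along(counts)) {
    if (counts[j] > 0) {
      arr[seq_len(counts[j]), j + 2, 4] <- 1
    }
  }
  segmentation(arr, g$affine, "left")
}

test_that("a single occupied slice yields a single CSA point", {
  seg <- flat_seg(c(50))
  tab <- slice_distance_table(build_distance_map(seg), seg)
  p <- csa_profile(seg, tab, tiv = 1400, tiv_ref = 1400)
  expect_equal(length(p$values), 1L)
  expect_equal(p$values, 50)
})

test_that("TIV ratio correction is exactly homogeneous", {
  seg <- flat_seg(c(30, 40, 50, 40, 30))
  tab <- slice_distance_table(build_distance_map(seg), seg)
  p1 <- csa_profile(seg, tab, tiv = 1400, tiv_ref = 1400)
  p2 <- csa_profile(seg, tab, tiv = 2800, tiv_ref = 1400)
  expect_equal(p2$values, p1$values / 2)
})

test_that("profiles on an integer grid are reproduced exactly", {
  counts <- c(20, 35, 50, 45, 30, 25)
  seg <- flat_seg(counts)
  tab <- slice_distance_table(build_distance_map(seg), seg)
  p <- csa_profile(seg, tab, tiv = 1400, tiv_ref = 1400)
  expect_equal(p$values, as.numeric(counts))
  expect_equal(diff(p$positions), rep(1, length(counts) - 1))
})

test_that("the ellipsoid phantom CSA profile matches the analytic ellipse", {
  spec <- phantom_spec(shape = "ellipsoid",
                      ellipsoid_semiaxes = c(20, 9, 6),
                      lateral_offset_mm = 10)
  g <- make_grid(c(48, 48, 40), c(1, 1, 1))
  m <- make_mask(spec, g, "left")
  tab <- slice_distance_table(build_distance_map(m$seg), m$seg)
  p <- csa_profile(m$seg, tab, tiv = 1400, tiv_ref = 1400)
  central <- p$values[which.min(abs(p$positions - mean(p$positions)))]
  expect_lt(abs(central - pi * 9 * 6), 2)
})

test_that("region partitioning recovers a constructed plateau", {
  x <- 0:45
  mu <- ifelse(x < 15, 60 * x / 15, ifelse(x <= 30, 60, 60 - 2.7 * (x - 30)))
  model <- list(grid = x, mu = mu, side = "left")
  part <- partition_regions(model, slope_threshold = 2)
  expect_lte(abs(part$tail_body - 15), 1)
  expect_lte(abs(part$body_head - 30), 1)
  expect_equal(unname(sum(part$lengths)), 45)
  expect_false(part$degenerate)

  # brute-force slope scan agrees with the partition rule
  slope <- c(diff(mu)[1], (mu[3:46] - mu[1:44]) / 2, diff(mu)[45])
  inside <- x >= part$tail_body & x <= part$body_head
  expect_true(all(abs(slope[inside]) < 2))
  expect_true(all(abs(slope[x == part$tail_body - 2]) >= 2))
})

test_that("flat profiles degenerate to an all-body partition", {
  model <- list(grid = 0:30, mu = rep(55, 31), side = "left")
  part <- partition_regions(model)
  expect_true(part$degenerate)
  expect_equal(unname(part$lengths[c("tail", "head")]), c(0, 0))
  steep <- list(grid = 0:30, mu = 10 * (0:30), side = "left")
  expect_error(partition_regions(steep), "no-body")
})

test_that("regional metrics integrate CSA and weight qT2 by slice volume", {
  # uniform 50 mm^2 body of 15 mm: 0.75 mL
  p <- new_profile(0:29, rep(50, 30), "CSA", "left")
  part <- structure(list(side = "left", tail_body = 5, body_head = 20,
                         lengths = c(tail = 5, body = 15, head = 9),
                         degenerate = FALSE),
                    class = "region_partition")
  q <- new_profile(c(10, 14), c(110, 120), "qT2", "left",
                   sampling = "discrete-slice")
  m <- region_metrics(p, part, q, qt2_weights = c(300, 100), tiv = 1400)
  expect_equal(unname(m$regional_volumes_ml["body"]), 15 * 50 / 1000)
  expect_equal(unname(m$regional_qt2_ms["body"]),
               (110 * 300 + 120 * 100) / 400)
  expect_true(is.na(m$regional_qt2_ms["tail"])) # no qT2 slice there
  # volume conservation
  expect_lt(abs(sum(m$regional_volumes_ml) - m$whole_volume_ml) /
              m$whole_volume_ml, 0.01)
})

test_that("qT2 profile points require a minimum of valid voxels", {
  slices <- data.frame(slice = 1:4, qt2_ms = c(110, 112, 115, NA),
                       n_valid = c(20, 3, 8, 0),
                       seg_volume_mm3 = c(400, 60, 200, 0))
  tab <- data.frame(slice = 1:4, distance_mm = c(10, 14, 18, 22),
                    n_voxels = c(20, 3, 8, 1))
  p <- qt2_profile(slices, tab, "left", min_voxels = 5)
  expect_equal(p$positions, c(10, 18)) # slice 2 omitted, not zeroed
  expect_equal(attr(p, "weights"), c(400, 200))
  empty <- data.frame(slice = 1, qt2_ms = NA_real_, n_valid = 0,
                      seg_volume_mm3 = 0)
  expect_error(qt2_profile(empty, tab, "left"), "empty-input")
})
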