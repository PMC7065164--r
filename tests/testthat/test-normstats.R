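# Normative model construction, individual comparison, group statistics,
# scan-rescan variability and abnormality percentages.

test_that("identical control profiles give sigma zero and mu the profile", {
  pos <- 1:40
  vals <- 40 + 0.8 * pos # locally linear, as CSA profiles are piecewise
  profs <- lapply(1:12, function(i) new_profile(pos, vals, "CSA", "left"))
  m <- build_normative(profs)
  expect_equal(m$mu, vals[match(m$grid, pos)], tolerance = 1e-9)
  expect_lt(max(m$sigma), 1e-5)
  expect_equal(m$z, 1.96)
})

test_that("vanishing bandwidth degenerates to per-point sample moments", {
  pos <- 1:30
  profs <- simulate_profile_cohort(25, pos, 60, noise_sd = 4, seed = 3)
  m <- build_normative(profs, bandwidth = 1e-4)
  mat <- do.call(rbind, lapply(profs, `[[`, "values"))
  expect_equal(m$mu, colMeans(mat), tolerance = 1e-8)
  expect_equal(m$sigma, apply(mat, 2, sd), tolerance = 1e-8)
  expect_equal(m$n_eff, rep(25, 30), tolerance = 1e-6)
})

test_that("the kernel estimator recovers generative mean and sd", {
  pos <- 1:45
  mu0 <- function(x) 60 + 0.5 * x
  sd0 <- 5
  profs <- simulate_profile_cohort(111, pos, mu0, noise_sd = sd0, seed = 8)
  m <- build_normative(profs)
  interior <- m$grid > 5 & m$grid < 40
  expect_lt(max(abs(m$mu[interior] - mu0(m$grid[interior]))),
            3 * sd0 / sqrt(111))
  expect_lt(max(abs(m$sigma[interior] - sd0) / sd0), 0.15)
})

test_that("minimum cohort and support rules are enforced", {
  pos <- 1:20
  profs <- simulate_profile_cohort(5, pos, 50, noise_sd = 1, seed = 1)
  expect_error(build_normative(profs), ">= 10")
  m <- group_average_profiles(profs[1:3])
  expect_s3_class(m, "normative_model")
  expect_error(group_average_profiles(profs[1]), ">= 2")
})

test_that("individual comparison flags one-sided departures only", {
  pos <- 1:40
  profs <- simulate_profile_cohort(20, pos, 60, noise_sd = 3, seed = 5)
  m <- build_normative(profs)
  centred <- new_profile(m$grid, m$mu, "CSA", "left")
  r0 <- compare_individual(centred, m)
  expect_equal(attr(r0, "fraction_abnormal"), 0)
  low <- new_profile(m$grid, m$mu - 2 * m$sigma, "CSA", "left")
  expect_equal(attr(compare_individual(low, m), "fraction_abnormal"), 1)
  # high CSA is not "abnormal" under the atrophy rule
  high <- new_profile(m$grid, m$mu + 3 * m$sigma, "CSA", "left")
  expect_equal(attr(compare_individual(high, m), "fraction_abnormal"), 0)
})

test_that("flags are invariant under a common offset of profile and model", {
  pos <- 1:30
  profs <- simulate_profile_cohort(15, pos, 55, noise_sd = 4, seed = 9)
  m <- build_normative(profs)
  subj <- simulate_profile_cohort(1, pos, 55, noise_sd = 4, seed = 99)[[1]]
  r1 <- compare_individual(subj, m)
  m2 <- m; m2$mu <- m$mu + 20
  subj2 <- new_profile(subj$positions, subj$values + 20, "CSA", "left")
  r2 <- compare_individual(subj2, m2)
  expect_identical(r1$flag, r2$flag)
})

test_that("discrete qT2 points are compared against the interpolated band", {
  pos <- 1:40
  profs <- simulate_profile_cohort(20, pos, 115, noise_sd = 2,
                                   modality = "qT2", seed = 11)
  m <- build_normative(profs)
  pts <- new_profile(c(10.5, 20.5, 30.5), c(115, 140, 115), "qT2", "left",
                     sampling = "discrete-slice")
  r <- compare_individual(pts, m)
  expect_equal(nrow(r), 3L)
  expect_equal(r$flag, c(FALSE, TRUE, FALSE))
})

test_that("pointwise group tests detect an implanted shift with Bonferroni", {
  pos <- 1:40
  cs <- simulate_profile_cohort(30, pos, 50, noise_sd = 5, seed = 21)
  ps <- simulate_profile_cohort(
    30, pos, function(x) 50 - 15 * (x >= 16 & x <= 25),
    noise_sd = 5, seed = 22)
  res <- group_pointwise_test(cs, ps)
  expect_true(all(res$flag[res$position >= 16 & res$position <= 25]))
  expect_equal(attr(res, "m_tested"), 40L)
  expect_equal(attr(res, "fraction_significant"), mean(res$flag))
  # threshold really is alpha / m
  expect_true(all(res$p[res$flag] < 0.01 / 40))
})

test_that("regional comparisons use the three-way Bonferroni level", {
  set.seed(4)
  ctrl <- data.frame(tail = rnorm(30, 0.4, 0.05),
                     body = rnorm(30, 0.8, 0.05),
                     head = rnorm(30, 1.5, 0.1))
  pat <- ctrl
  pat$head <- pat$head - 0.4
  res <- group_region_test(ctrl, pat)
  expect_equal(res$flag, c(FALSE, FALSE, TRUE))
  expect_true(res$p[3] < 0.01 / 3)
})

test_that("a control group averaged with the same machinery equals its norm", {
  pos <- 1:30
  profs <- simulate_profile_cohort(15, pos, 60, noise_sd = 3, seed = 30)
  m1 <- build_normative(profs, min_profiles = 10, min_support = 2)
  m2 <- group_average_profiles(profs)
  expect_equal(m1$mu, m2$mu)
  expect_equal(m1$sigma, m2$sigma)
})

test_that("scan-rescan variability recovers the difference sd", {
  pos <- 1:45
  s <- 3
  pairs <- lapply(1:20, function(i) list(
    simulate_profile_cohort(1, pos, 60, noise_sd = s, seed = 100 + i)[[1]],
    simulate_profile_cohort(1, pos, 60, noise_sd = s, seed = 300 + i)[[1]]))
  v <- scan_rescan_variability(pairs)
  expect_lt(abs(mean(v$sd_diff) - s * sqrt(2)) / (s * sqrt(2)), 0.2)
  # identical repeats: zero everywhere
  same <- lapply(1:5, function(i) {
    p <- simulate_profile_cohort(1, pos, 60, noise_sd = s,
                                 seed = 40 + i)[[1]]
    list(p, p)
  })
  expect_lt(max(scan_rescan_variability(same)$sd_diff), 1e-9)
  expect_error(scan_rescan_variability(same[1:3]), ">= 5")
})

test_that("abnormality percentages count flagged individuals per point", {
  pos <- 1:30
  profs <- simulate_profile_cohort(20, pos, 60, noise_sd = 3, seed = 50)
  m <- build_normative(profs)
  deficient <- lapply(1:6, function(i) {
    new_profile(m$grid, m$mu - 3 * m$sigma, "CSA", "left")
  })
  pa <- percent_abnormal(lapply(deficient, compare_individual, model = m))
  expect_true(all(pa$fraction == 1))
  expect_true(all(pa$n == 6))
  expect_error(percent_abnormal(list()), "empty-input")
})

test_that("whole-structure scalars are flagged against the control range", {
  set.seed(2)
  ctrl <- rnorm(100, 2.9, 0.25)
  expect_true(compare_whole(2.0, ctrl, "low")$flag)
  expect_false(compare_whole(2.9, ctrl, "low")$flag)
  expect_true(compare_whole(3.9, ctrl, "high")$flag)
})
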