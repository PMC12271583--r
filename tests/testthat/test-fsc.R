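test_that("self-FSC is 1 and negation-FSC is -1 in every shell", {
  g <- random_grid(c(12, 12, 12), voxel = 1, seed = 21)
  cur <- compute_fsc(g, g)
  expect_true(all(abs(cur$fsc - 1) < 1e-10))
  neg <- voxel_grid(-g$values, g$origin, g$voxel)
  expect_true(all(abs(compute_fsc(g, neg)$fsc + 1) < 1e-10))
  expect_true(all(cur$freq <= 0.5 + 1e-12)) # Nyquist at 1 A voxels
  expect_true(all(cur$n_voxels > 0))
})

test_that("FFT-based FSC matches the naive direct-DFT oracle per shell", {
  for (seed in c(1, 2)) {
    ga <- random_grid(c(16, 16, 16), voxel = 1, seed = seed)
    gb <- random_grid(c(16, 16, 16), voxel = 1, seed = seed + 100)
    w <- 1 / 16
    got <- compute_fsc(ga, gb, shell_width = w)
    ref <- oracle_fsc(ga$values, gb$values, voxel = 1, shell_width = w)
    expect_equal(length(got$fsc), length(ref))
    expect_equal(got$fsc, unname(ref), tolerance = 1e-8)
  }
  # non-cubic box
  ga <- random_grid(c(8, 6, 10), voxel = 1, seed = 3)
  gb <- random_grid(c(8, 6, 10), voxel = 1, seed = 4)
  w <- 1 / 10
  expect_equal(compute_fsc(ga, gb, shell_width = w)$fsc,
               unname(oracle_fsc(ga$values, gb$values, 1, w)),
               tolerance = 1e-8)
})

test_that("independent white-noise maps decorrelate at the expected scale", {
  ga <- random_grid(c(32, 32, 32), voxel = 1, seed = 7)
  gb <- random_grid(c(32, 32, 32), voxel = 1, seed = 8)
  cur <- compute_fsc(ga, gb)
  expect_true(all(abs(cur$fsc) < 1)) # strictly inside [-1, 1]
  z <- abs(cur$fsc) * sqrt(cur$n_voxels)
  expect_lt(mean(abs(cur$fsc)), mean(3 / sqrt(cur$n_voxels)))
  expect_true(all(z < 6)) # no wildly correlated shell
})

test_that("FSC is symmetric and scale-invariant", {
  ga <- random_grid(c(10, 10, 10), seed = 31)
  gb <- random_grid(c(10, 10, 10), seed = 32)
  ab <- compute_fsc(ga, gb)
  ba <- compute_fsc(gb, ga)
  expect_equal(ab$fsc, ba$fsc, tolerance = 1e-12)
  scaled <- voxel_grid(3.7 * gb$values, gb$origin, gb$voxel)
  expect_equal(compute_fsc(ga, scaled)$fsc, ab$fsc, tolerance = 1e-10)
})

test_that("mismatched or anisotropic grids are rejected", {
  a <- random_grid(c(8, 8, 8))
  b <- random_grid(c(8, 8, 6))
  expect_error(compute_fsc(a, b), "share")
  c1 <- voxel_grid(a$values, a$origin, c(1, 1, 1.2))
  expect_error(compute_fsc(c1, c1), "anisotropic")
})

test_that("threshold resolution interpolates linearly between shells", {
  cur <- fsc_curve(freq = c(0.20, 0.25), fsc = c(0.8, 0.2))
  # crossing 0.5 at 0.20 + (0.3/0.6)*0.05 = 0.225 -> 4.444 A
  expect_equal(resolution_at(cur, 0.5), 1 / 0.225, tolerance = 1e-12)
  # never drops below 0.143 within the curve -> Nyquist-limited: 1/0.25
  expect_equal(resolution_at(cur, 0.143), 4.0)
  # below from the first shell -> unresolved
  expect_equal(resolution_at(fsc_curve(c(0.1, 0.2), c(0.1, 0.05)), 0.5), Inf)
  # identical maps at 1 A voxels resolve to the 2 A Nyquist limit
  g <- random_grid(c(12, 12, 12), voxel = 1, seed = 41)
  expect_equal(resolution_at(compute_fsc(g, g), 0.5), 2.0)
})

test_that("map-model FSC of a map against its own model hits Nyquist", {
  h <- make_helix(10)
  sim <- simulate_map(h, kernel = kernel_spec(2.0))
  res <- map_model_fsc(sim, h, kernel_spec(2.0))
  expect_equal(res$resolution, 2.0)
  expect_true(all(res$curve$fsc > 0.99))
  # clean self-consistent map resolves at least as well as the kernel
  expect_lte(res$resolution, 2.0)
})

test_that("increasing noise never improves the reported resolution", {
  h <- make_helix(10)
  sim <- simulate_map(h, kernel = kernel_spec(2.0))
  res_at_sigma <- vapply(c(0, 0.05, 0.2), function(sig) {
    r <- vapply(1:3, function(seed) {
      noisy <- make_noisy_map(sim, noise_spec(gaussian_sigma = sig,
                                              blob_count = 0, seed = seed))
      map_model_fsc(noisy, h, kernel_spec(2.0))$resolution
    }, numeric(1))
    stats::median(r)
  }, numeric(1))
  expect_true(all(diff(res_at_sigma) >= 0))
})

test_that("map_model_fsc demands overlap and exposes tidy/glance/autoplot", {
  h <- make_helix(5)
  far <- voxel_grid(array(1, c(8, 8, 8)), origin = c(500, 500, 500), voxel = 1)
  expect_error(map_model_fsc(far, h), "overlap")
  sim <- simulate_map(h, kernel = kernel_spec(2.0))
  res <- map_model_fsc(sim, h, kernel_spec(2.0))
  td <- tidy(res)
  expect_true(all(c("freq", "fsc", "n_voxels") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$resolution, res$resolution)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("improvement percent follows its closed form", {
  expect_equal(improvement_percent(10, 5), 50)
  expect_equal(improvement_percent(3.3, 3.3), 0)
  expect_equal(improvement_percent(4.01, 3.33), 100 * 0.68 / 4.01)
  expect_error(improvement_percent(0, 1), "positive")
  expect_error(improvement_percent(-2, 1), "positive")
})

test_that("manifest summary aggregates means and improvement", {
  man <- data.frame(resolution_before = c(4, 3), resolution_after = c(3, 2))
  s <- summarize_manifest(man)
  expect_equal(s$mean_before, 3.5)
  expect_equal(s$mean_after, 2.5)
  expect_equal(s$improvement_percent, 100 * 1 / 3.5)
  expect_equal(s$n, 2L)
})
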