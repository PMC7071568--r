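test_that("theta -> 0 collapses every set onto its group mean", {
  gm <- tibble::tibble(rsid = c("v1", "v2", "v3"),
                       mean_EUR = c(0.2, 0.5, 0.8),
                       mean_EAS = c(0.5, 0.8, 0.2),
                       mean_AFR = c(0.8, 0.2, 0.5))
  cfg <- simulation_config(sets = tiny_sets(), group_means = gm, theta = 1e-12)
  sim <- simulate_sample_sets(cfg, seed = 1)
  joined <- dplyr::inner_join(sim$frequencies, tiny_sets()[c("id", "group")],
                              by = c(sample_set_id = "id"))
  truth <- tidyr::pivot_longer(gm, -rsid, names_to = "group",
                               values_to = "p", names_prefix = "mean_")
  joined <- dplyr::inner_join(joined, truth, by = c("rsid", "group"))
  expect_lt(max(abs(joined$freq - joined$p)), 1e-4)
})

test_that("identical seeds give identical collections, different seeds differ", {
  cfg <- simulation_config(theta = 0.05)
  s1 <- simulate_sample_sets(cfg, seed = 9)
  s2 <- simulate_sample_sets(cfg, seed = 9)
  s3 <- simulate_sample_sets(cfg, seed = 10)
  expect_identical(s1, s2)
  expect_false(identical(s1$frequencies$freq, s3$frequencies$freq))
  r1 <- simulate_uvb_raster(cfg, seed = 9)
  r2 <- simulate_uvb_raster(cfg, seed = 9)
  expect_identical(r1, r2)
})

test_that("generated frequencies stay in [0,1] and variance grows with theta", {
  gm <- tibble::tibble(rsid = "v1", mean_EUR = 0.5, mean_EAS = 0.5, mean_AFR = 0.5)
  spread <- vapply(c(0.01, 0.05, 0.2), function(th) {
    cfg <- simulation_config(group_means = gm, theta = th)
    f <- simulate_sample_sets(cfg, seed = 4)$frequencies$freq
    expect_true(all(f >= 0 & f <= 1))
    var(f)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("degenerate group means 0 and 1 stay fixed under drift", {
  gm <- tibble::tibble(rsid = "v1", mean_EUR = 0, mean_EAS = 1, mean_AFR = 0.5)
  cfg <- simulation_config(sets = tiny_sets(), group_means = gm, theta = 0.3)
  f <- simulate_sample_sets(cfg, seed = 2)
  joined <- dplyr::inner_join(f$frequencies, tiny_sets()[c("id", "group")],
                              by = c(sample_set_id = "id"))
  expect_true(all(joined$freq[joined$group == "EUR"] == 0))
  expect_true(all(joined$freq[joined$group == "EAS"] == 1))
})

test_that("generator recovers group means and drift-implied differentiation", {
  # Monte-Carlo parameter recovery: one group, 20 sets of n = 100, theta = 0.05.
  # Across replicates the mean frequency should be nearly unbiased and the
  # within-group Wright FST (relative to the group mean) close to theta.
  sets <- validate_sample_sets(tibble::tibble(
    id = sprintf("S%02d", 1:20), name = as.character(1:20), group = "EUR",
    n = 100L, lat_min = 50, lat_max = 50, lon = 10, source = "SYNTHETIC"))
  gm <- tibble::tibble(rsid = "v1", mean_EUR = 0.3)
  cfg <- simulation_config(sets = sets, group_means = gm, theta = 0.05)
  stats <- vapply(1:200, function(s) {
    f <- simulate_sample_sets(cfg, seed = s)$frequencies$freq
    c(mean(f), wright_fst(f))
  }, numeric(2))
  expect_lt(abs(mean(stats[1, ]) - 0.3), 0.02)
  expect_lt(abs(mean(stats[2, ]) / 0.05 - 1), 0.30)
})

test_that("synthetic raster follows the deterministic lattice and clamps at zero", {
  sets <- tiny_sets()
  cfg <- simulation_config(sets = sets, uvb_base = 100, uvb_decay = 1,
                           uvb_sd = 0, uvb_days = 10)
  raster <- simulate_uvb_raster(cfg, seed = 1)
  cell40 <- raster[abs(raster$lat_cell - 40.25) < 1e-9, ]
  expect_true(all(abs(cell40$irradiance - (100 - 40.25)) < 1e-9))

  far <- validate_sample_sets(tibble::tibble(
    id = "X", name = "polar", group = "EUR", n = 10L,
    lat_min = 89, lat_max = 89, lon = 0, source = "SYNTHETIC"))
  cfg2 <- simulation_config(sets = far, group_means = tibble::tibble(
    rsid = "v", mean_EUR = 0.5), uvb_base = 50, uvb_decay = 1,
    uvb_sd = 0, uvb_days = 5)
  r2 <- simulate_uvb_raster(cfg2, seed = 1)
  expect_true(all(r2$irradiance == 0))
})

test_that("default raster reproduces the AFR > EAS > EUR mean annual UVB ordering", {
  cfg <- simulation_config()
  for (seed in 1:5) {
    raster <- simulate_uvb_raster(cfg, seed = seed)
    per_set <- suppressWarnings(uvb_by_sample_set(cfg$sets, raster))
    grp <- suppressWarnings(compare_group_uvb(per_set))$summary
    ord <- grp$mean_uvb[match(c("AFR", "EAS", "EUR"), grp$group)]
    expect_true(all(diff(ord) < 0))
  }
})

test_that("write_simulation materialises readable pipeline inputs", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(sets = tiny_sets(), group_means = tibble::tibble(
    rsid = c("v1", "v2"), mean_EUR = c(0.1, 0.9), mean_EAS = c(0.5, 0.5),
    mean_AFR = c(0.9, 0.1)), uvb_days = 5)
  paths <- write_simulation(cfg, dir, seed = 6)
  expect_equal(nrow(read_sample_sets(paths[["sample_sets"]])), 6)
  expect_equal(nrow(read_frequency_matrix(paths[["frequencies"]])), 12)
  expect_equal(nrow(read_variant_annotations(paths[["annotations"]])), 2)
  expect_gt(nrow(read_uvb_raster(paths[["raster"]])), 0)
})
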