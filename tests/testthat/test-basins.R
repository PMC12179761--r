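test_that("Boltzmann inversion gives closed-form bin free energies", {
  proj <- c(rep(1, 60), rep(2, 30), rep(3, 10), rep(4, 10))
  fel <- build_landscape(proj, dims = 1, n_bins = 4)
  expect_identical(as.vector(fel$counts), c(60L, 30L, 10L, 10L))
  expect_equal(as.vector(fel$deltaG), c(0, log(2), log(6), log(6)),
               tolerance = 1e-12)
  expect_identical(fel$frame_bin, rep(1:4, c(60, 30, 10, 10)))
})

test_that("empty bins carry the finite cap and the range is expanded 5%", {
  proj <- c(rep(0, 60), rep(5, 30), rep(10, 10))
  fel <- build_landscape(proj, dims = 1, n_bins = 4)
  expect_identical(as.vector(fel$counts)[2], 0L)
  expect_equal(fel$cap, log(6) + 1, tolerance = 1e-12)
  expect_equal(as.vector(fel$deltaG)[2], fel$cap)
  expect_equal(range(fel$edges[[1]]), c(-0.25, 10.25), tolerance = 1e-12)
})

test_that("a 2D histogram matches an independently binned oracle", {
  set.seed(61)
  P <- cbind(rnorm(500), rnorm(500, sd = 2))
  fel <- build_landscape(P, dims = 1:2, n_bins = 8)
  expect_identical(sum(fel$counts), 500L)
  oracle <- matrix(0L, 8, 8)
  for (f in 1:500) {
    i <- min(max(findInterval(P[f, 1], fel$edges[[1]],
                              rightmost.closed = TRUE), 1L), 8L)
    j <- min(max(findInterval(P[f, 2], fel$edges[[2]],
                              rightmost.closed = TRUE), 1L), 8L)
    oracle[i, j] <- oracle[i, j] + 1L
  }
  expect_identical(unname(fel$counts), unname(oracle))
})

test_that("a constant projection degenerates with a warning", {
  expect_warning(build_landscape(rep(1, 50), dims = 1), "degenerate")
})

test_that("well-separated minima give distinct basins with exact weights", {
  # bins 1 and 3 are local minima (ln6 walls on both sides of bin 3), with
  # a ln3 > 1 kT depth, so the default min_depth keeps them separate
  proj <- c(rep(1, 60), rep(2, 10), rep(3, 30), rep(4, 10))
  fel <- build_landscape(proj, dims = 1, n_bins = 4)
  bs <- detect_basins(fel)
  expect_s3_class(bs, "basin_set")
  expect_identical(nrow(bs$basins), 2L)
  expect_equal(bs$retained_fraction, 1)
  expect_equal(bs$basins$probability, c(70, 40) / 110, tolerance = 1e-12)
  expect_identical(bs$basins$n_frames, c(70L, 40L))
})

test_that("shallow basins merge across their lowest saddle", {
  proj <- c(rep(1, 100), rep(2, 80), rep(3, 90), rep(4, 85))
  fel <- build_landscape(proj, dims = 1, n_bins = 4)
  # bins 1 and 3 are local minima; basin at bin 3 is only ~0.12 kT deep
  no_merge <- detect_basins(fel, min_depth = 0)
  expect_identical(nrow(no_merge$basins), 2L)
  merged <- detect_basins(fel, min_depth = 1)
  expect_identical(nrow(merged$basins), 1L)
  expect_equal(merged$basins$probability, 1, tolerance = 1e-12)
})

test_that("a two-Gaussian projection recovers the planted 0.7/0.3 weights", {
  set.seed(62)
  proj <- c(rnorm(7000, -3, 0.5), rnorm(3000, 3, 0.5))
  fel <- build_landscape(proj, dims = 1, n_bins = 64)
  bs <- detect_basins(fel, renormalize = TRUE)
  expect_identical(nrow(bs$basins), 2L)
  expect_lt(abs(bs$basins$probability[1] - 0.7), 0.02)
  expect_lt(abs(bs$basins$probability[2] - 0.3), 0.02)
  # representative frames belong to their own basins, near the modes
  expect_identical(bs$frame_basin[bs$basins$representative_frame[1]], 1L)
  expect_lt(proj[bs$basins$representative_frame[1]], 0)
  expect_gt(proj[bs$basins$representative_frame[2]], 0)
})

test_that("frames above g_cut stay unassigned", {
  set.seed(63)
  proj <- c(rnorm(5000, 0, 0.3), seq(4, 8, length.out = 25))
  fel <- build_landscape(proj, dims = 1, n_bins = 64)
  bs <- detect_basins(fel, g_cut = 3)
  expect_lt(bs$retained_fraction, 1)
  expect_equal(bs$retained_fraction, mean(!is.na(bs$frame_basin)),
               tolerance = 1e-12)
  expect_equal(sum(bs$basins$probability), bs$retained_fraction,
               tolerance = 1e-12)
  # renormalized probabilities sum to 1 instead
  bs_rn <- detect_basins(fel, g_cut = 3, renormalize = TRUE)
  expect_equal(sum(bs_rn$basins$probability), 1, tolerance = 1e-12)
})

test_that("an all-excluded landscape warns and returns an empty basin set", {
  proj <- c(rep(1, 60), rep(2, 30), rep(3, 10))
  fel <- build_landscape(proj, dims = 1, n_bins = 4)
  expect_warning(bs <- detect_basins(fel, g_cut = -1), "no occupied bin")
  expect_identical(nrow(bs$basins), 0L)
  expect_true(all(is.na(bs$frame_basin)))
})

test_that("combine_weights multiplies solute and cluster weights", {
  proj <- c(rnorm(700, -3, 0.4), rnorm(300, 3, 0.4))
  fel <- build_landscape(proj, dims = 1, n_bins = 32)
  bs <- detect_basins(fel, renormalize = TRUE)
  w <- combine_weights(c(solA = 0.6, solB = 0.4), bs)
  expect_identical(nrow(w), 2L * nrow(bs$basins))
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_equal(w$weight[w$solute_state == "solA"],
               0.6 * bs$basins$probability, tolerance = 1e-12)
  expect_error(combine_weights(c(0.5, 0.7), list(bs)), "one basin set")
  expect_error(combine_weights(1.2, bs), "\\[0, 1\\]")
})

test_that("write_landscape emits a re-readable grid table", {
  set.seed(64)
  fel <- build_landscape(cbind(rnorm(200), rnorm(200)), n_bins = 8)
  path <- tempfile(fileext = ".txt")
  write_landscape(fel, path)
  tab <- read.table(path, header = TRUE)
  expect_identical(nrow(tab), 64L)
  expect_identical(names(tab), c("x", "y", "deltaG"))
  expect_equal(min(tab$deltaG), 0)
})

test_that("convergence_check requires enough frames and reports deviations", {
  tr <- one_particle_traj(rep(c(-3, 3), 150) + rnorm(300, sd = 0.2))
  expect_error(convergence_check(tr, n_splits = 200), "too few frames")
  cv <- convergence_check(tr, n_splits = 3, dims = 1, n_bins = 32)
  expect_false(cv$count_mismatch)
  expect_identical(dim(cv$matched), c(3L, 2L))
  expect_lt(cv$max_deviation, 0.05)
})
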