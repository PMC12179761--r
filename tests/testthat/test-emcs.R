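# symmetric 4-point solute: geometric center at the origin, isotropic
# gyration tensor (unit variance per coordinate)
tetra_solute <- function() {
  matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4, 3, byrow = TRUE)
}

test_that("a single-atom solute yields a padding sphere", {
  e <- build_ellipsoid(c(2, -1, 5), padding = 3)
  expect_equal(e$center, c(2, -1, 5))
  expect_equal(e$semi_axes, rep(3, 3))
  expect_equal(ellipsoid_metric(c(5, -1, 5), e), 1, tolerance = 1e-12)
  expect_lt(ellipsoid_metric(c(3, -1, 5), e), 1)
})

test_that("a collinear solute gets padding on the degenerate axes", {
  line <- cbind(0, 0, c(-1, 0, 1))
  e <- build_ellipsoid(line, padding = 3)
  expect_equal(sort(e$semi_axes), sort(c(1 + 3, 3, 3)), tolerance = 1e-12)
  # the endpoints sit on the ellipsoid shrunk back by the padding
  e_bare <- e
  e_bare$semi_axes <- e$semi_axes - 3
  e_bare$semi_axes[e_bare$semi_axes == 0] <- 1  # degenerate: no solute extent
  expect_equal(max(ellipsoid_metric(line, e_bare)), 1, tolerance = 1e-12)
})

test_that("ellipsoid axes diagonalize the gyration tensor (closed-form oracle)", {
  set.seed(31)
  X <- matrix(rnorm(60, sd = c(3, 1.5, 0.5)), 20, 3, byrow = TRUE)
  e <- build_ellipsoid(X, padding = 0)
  Xc <- sweep(X, 2, colMeans(X))
  gyr <- crossprod(Xc) / nrow(Xc)
  D <- t(e$axes) %*% gyr %*% e$axes
  vals <- eig3_closed_form(gyr)
  expect_lt(max(abs(D - diag(vals))), 1e-9)
  expect_equal(det(e$axes), 1, tolerance = 1e-12)
  # every solute atom is enclosed by the bare ellipsoid
  expect_lte(max(ellipsoid_metric(X, e)), 1 + 1e-12)
})

test_that("ellipsoid metric classification matches a rotate-and-test oracle", {
  set.seed(32)
  X <- matrix(rnorm(45, sd = c(2, 1, 0.6)), 15, 3, byrow = TRUE)
  e <- build_ellipsoid(X, padding = 1.5)
  pts <- matrix(rnorm(90, sd = 4), 30, 3)
  m <- ellipsoid_metric(pts, e)
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    p <- as.vector((pts[i, ] - e$center) %*% e$axes)
    sum((p / e$semi_axes)^2)
  }, numeric(1))
  expect_lt(max(abs(m - oracle)), 1e-12)
})

test_that("determine_M summarizes the per-frame inside counts", {
  near <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0), c(0, -1, 0))
  far <- function(i) c(60 + 5 * i, 0, 0)
  frame_pos <- function(n_in) rbind(near[seq_len(n_in), , drop = FALSE],
                                    t(vapply(seq_len(6 - n_in), far,
                                             numeric(3))))
  tr <- toy_water_traj(tetra_solute(), lapply(c(3, 4, 4, 5), frame_pos))
  M <- determine_M(tr)
  expect_identical(as.integer(M), 4L)
  expect_identical(attr(M, "counts"), c(3L, 4L, 4L, 5L))
  expect_identical(as.integer(determine_M(tr, statistic = "mode")), 4L)
  expect_identical(as.integer(determine_M(tr, statistic = "min")), 3L)
})

test_that("inside counts grow monotonically with padding", {
  set.seed(33)
  pos <- lapply(1:3, function(f) matrix(rnorm(18, sd = 5), 6, 3))
  tr <- toy_water_traj(tetra_solute(), pos)
  c_small <- attr(determine_M(tr, padding = 2), "counts")
  c_large <- attr(determine_M(tr, padding = 5), "counts")
  expect_true(all(c_large >= c_small))
})

test_that("an empty shell raises the empty-shell error", {
  pos <- list(rbind(c(100, 0, 0), c(0, 100, 0), c(0, 0, 100)))
  tr <- toy_water_traj(tetra_solute(), pos)
  expect_error(determine_M(tr, padding = 1), "empty-shell")
})

test_that("emcs_extract keeps the M nearest molecules in metric-rank order", {
  pos <- list(rbind(c(1, 0, 0), c(0, 40, 0), c(-1.2, 0.4, 0), c(50, 0, 0)))
  tr <- toy_water_traj(tetra_solute(), pos)
  cl <- emcs_extract(tr, M = 2)
  expect_s3_class(cl, "cluster_trajectory")
  expect_identical(cl$M, 2L)
  # molecule ids are 2..5 in input order; the nearest (by center-of-geometry
  # metric, template offset included) is molecule 4, then molecule 2
  expect_identical(cl$slot_ids[1, ], c(4L, 2L))
  expect_identical(n_atoms(cl), 4L + 2L * 3L)
  # slot coordinates equal the source molecules' coordinates, in rank order
  xyz <- frame_coords(tr, 1)
  expect_equal(frame_coords(cl, 1)[5:7, ], xyz[11:13, ])  # molecule 4
  expect_equal(frame_coords(cl, 1)[8:10, ], xyz[5:7, ])   # molecule 2
})

test_that("exact metric ties break toward the lower molecule id", {
  # two exactly superposed waters give a bit-identical metric tie
  pos <- list(rbind(c(2, 0, 0), c(2, 0, 0), c(70, 0, 0)))
  tr <- toy_water_traj(tetra_solute(), pos)
  cl <- emcs_extract(tr, M = 2)
  expect_identical(cl$slot_ids[1, ], c(2L, 3L))
})

test_that("extraction is invariant under a global rigid motion", {
  spec <- synthetic_spec(n_frames = 10L, seed = 13L)
  tr <- generate_trajectory(spec)
  set.seed(34)
  R <- random_rotation()
  rot <- tr
  for (f in seq_len(n_frames(tr)))
    rot$coords[, , f] <- tr$coords[, , f] %*% t(R) +
      matrix(c(5, -2, 9), n_atoms(tr), 3, byrow = TRUE)
  expect_identical(emcs_extract(tr, M = 8)$slot_ids,
                   emcs_extract(rot, M = 8)$slot_ids)
})

test_that("emcs_extract validates M and solvent homogeneity", {
  pos <- list(rbind(c(1, 0, 0), c(0, 2, 0), c(3, 0, 0)))
  tr <- toy_water_traj(tetra_solute(), pos)
  expect_error(emcs_extract(tr, M = 0), "M must be >= 1")
  expect_error(emcs_extract(tr, M = 3), "smaller than the solvent count")
  topo2 <- rbind(tr$topology,
                 data.frame(element = "O", name = "OX", resname = "ION",
                            resno = 9L, molecule_id = 9L, role = "solvent",
                            stringsAsFactors = FALSE))
  hetero <- trajectory(topo2, array(rbind(tr$coords[, , 1], c(30, 30, 30)),
                                    c(n_atoms(tr) + 1L, 3L, 1L)))
  expect_error(emcs_extract(hetero, M = 2), "one solvent species")
})

test_that("minimum-image wrapping brings periodic images into the shell", {
  # a water at x = 29 in a 30 A box is 1 A from the solute center
  pos <- list(rbind(c(29, 0, 0), c(0, 12, 0), c(0, 0, 12)))
  tr0 <- toy_water_traj(tetra_solute(), pos)
  tr <- trajectory(tr0$topology, tr0$coords, box = c(30, 30, 30))
  M <- determine_M(tr, padding = 3)
  expect_identical(attr(M, "counts"), 1L)
  cl <- emcs_extract(tr, M = 1)
  expect_identical(cl$slot_ids[1, ], 2L)
  # the stored O-atom coordinate is the wrapped (nearby) image
  expect_lt(max(abs(frame_coords(cl, 1)[5, ] - c(-1, 0, 0))), 1e-9)
})
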