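test_that("aggregation_center validates its fields", {
  ac <- aggregation_center(c(8, 9), 4, "COO")
  expect_s3_class(ac, "aggregation_center")
  expect_identical(ac$n_retain, 4L)
  expect_error(aggregation_center(integer(0), 1, "X"), "empty atom set")
  expect_error(aggregation_center(1, -1, "X"), "n_retain")
})

test_that("the alanine fixture reduces to 4 + 3 = 7 waters in center order", {
  spec <- synthetic_spec(n_frames = 20L, seed = 3L)
  tr <- generate_trajectory(spec)
  cl <- emcs_extract(tr, M = 10L)
  rd <- remcs_reduce(cl, alanine_centers(cl$topology))
  expect_s3_class(rd, "reduced_cluster_trajectory")
  expect_identical(rd$k, 7L)
  expect_identical(n_atoms(rd), 13L + 7L * 3L)
  # slots are grouped by center in the given order
  expect_identical(unique(rd$assignment[1, ]), c("COO", "NH3"))
  expect_identical(sum(rd$assignment[1, ] == "COO"), 4L)
  expect_identical(sum(rd$assignment[1, ] == "NH3"), 3L)
  # within a center, slots are in ascending nearest-atom distance order
  # (slot ids are source-trajectory molecule ids: map them back through the
  # EMCS cluster's own slot table)
  xyz <- frame_coords(cl, 1)
  centers <- alanine_centers(cl$topology)
  groups <- remcs:::solvent_molecules(cl$topology)
  d_coo <- vapply(rd$slot_ids[1, 1:4], function(id) {
    ix <- groups[[match(id, cl$slot_ids[1, ])]]
    sqrt(min(as.matrix(stats::dist(rbind(xyz[centers[[1]]$atoms, ],
                                         xyz[ix, ])))[1:2, 3:5]))
  }, numeric(1))
  expect_true(all(diff(d_coo) >= 0))
})

test_that("zero-retention centers give a solute-only reduced cluster", {
  spec <- synthetic_spec(n_frames = 3L, seed = 5L)
  tr <- generate_trajectory(spec)
  cl <- emcs_extract(tr, M = 10L)
  centers <- alanine_centers(cl$topology, n_carboxylate = 0L, n_ammonium = 0L)
  rd <- remcs_reduce(cl, centers)
  expect_identical(rd$k, 0L)
  expect_identical(n_atoms(rd), 13L)
  expect_identical(n_solvent(rd), 0L)
})

test_that("reduction is invariant to the solvent molecule order", {
  spec <- synthetic_spec(n_frames = 5L, seed = 9L)
  tr <- generate_trajectory(spec)
  # permute whole solvent molecules in topology and coordinates
  set.seed(41)
  groups <- remcs:::solvent_molecules(tr$topology)
  perm <- sample(length(groups))
  idx <- c(which(tr$topology$role == "solute"),
           unlist(groups[perm], use.names = FALSE))
  topo2 <- tr$topology[idx, , drop = FALSE]
  rownames(topo2) <- NULL
  tr2 <- trajectory(topo2, tr$coords[idx, , , drop = FALSE])
  rd1 <- remcs_reduce(emcs_extract(tr, M = 10L),
                      alanine_centers(tr$topology))
  rd2 <- remcs_reduce(emcs_extract(tr2, M = 10L),
                      alanine_centers(topo2))
  # the retained coordinates are identical regardless of input order
  expect_equal(rd1$coords, rd2$coords, tolerance = 1e-12)
  expect_identical(rd1$assignment, rd2$assignment)
})

test_that("conflicts are resolved by the global ascending-distance pass", {
  # two centers, one water nearest to both: the closer center wins,
  # the other takes the next available molecule
  solute_xyz <- matrix(c(0, 0, 0, 4, 0, 0, 2, 2, 0, 2, -1, 1.5),
                       4, 3, byrow = TRUE)
  wpos <- rbind(c(1.4, -3, 0), c(-4, 0, 0), c(8.5, 0, 0))
  tt <- toy_water_traj(solute_xyz, list(wpos))
  centers <- list(aggregation_center(1L, 1L, "A"),
                  aggregation_center(2L, 1L, "B"))
  rd <- remcs_reduce(tt, centers)
  # molecule 2 (first water) is nearest to both centers but closer to A;
  # B falls back to molecule 4
  expect_identical(rd$slot_ids[1, ], c(2L, 4L))
  expect_identical(rd$assignment[1, ], c("A", "B"))
})

test_that("greedy assignment matches the scan oracle on random inputs", {
  set.seed(42)
  for (r in 1:25) {
    nc <- sample(2:4, 1)
    ns <- sample(5:9, 1)
    D <- matrix(runif(nc * ns), nc, ns)
    nr <- 1L + as.integer(rmultinom(1, ns - 1L - nc, rep(1, nc)))
    expect_identical(remcs:::greedy_assign(D, nr), scan_greedy(D, nr))
  }
})

test_that("reduction validates feasibility and center atoms", {
  spec <- synthetic_spec(n_frames = 2L, seed = 6L)
  tr <- generate_trajectory(spec)
  cl <- emcs_extract(tr, M = 5L)
  expect_error(remcs_reduce(cl, alanine_centers(cl$topology)),
               "infeasible-reduction")
  bad <- list(aggregation_center(14L, 1L, "W"))  # atom 14 is solvent
  expect_error(remcs_reduce(cl, bad), "non-solute")
  expect_error(remcs_reduce(cl, list()), "nonempty")
})

test_that("centroid distance mode runs and can differ from nearest-atom", {
  spec <- synthetic_spec(n_frames = 5L, seed = 8L)
  tr <- generate_trajectory(spec)
  cl <- emcs_extract(tr, M = 10L)
  rd <- remcs_reduce(cl, alanine_centers(cl$topology),
                     distance_mode = "com")
  expect_identical(rd$k, 7L)
})

test_that("suggest_centers groups the alanine N/O sites", {
  spec <- synthetic_spec(n_frames = 1L, seed = 2L)
  tr <- generate_trajectory(spec)
  cs <- suggest_centers(tr$topology)
  expect_identical(length(cs), 2L)
  sizes <- sort(vapply(cs, function(c) length(c$atoms), integer(1)))
  expect_identical(sizes, c(1L, 2L))                 # N and the O/OXT pair
  expect_true(all(vapply(cs, `[[`, integer(1), "n_retain") == 0L))
})

test_that("running rEMCS on more frames never changes earlier assignments", {
  spec <- synthetic_spec(n_frames = 30L, seed = 10L)
  tr <- generate_trajectory(spec)
  cl <- emcs_extract(tr, M = 10L)
  rd_full <- remcs_reduce(cl, alanine_centers(cl$topology))
  short <- cl
  short$coords <- cl$coords[, , 1:10, drop = FALSE]
  short$slot_ids <- cl$slot_ids[1:10, , drop = FALSE]
  rd_short <- remcs_reduce(short, alanine_centers(cl$topology))
  expect_identical(rd_short$slot_ids, rd_full$slot_ids[1:10, ])
  expect_equal(rd_short$coords, rd_full$coords[, , 1:10, drop = FALSE])
})
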