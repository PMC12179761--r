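qm_fixture <- function() {
  solute_xyz <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0, 0.4, 0.4, 1.3),
                       4, 3, byrow = TRUE)
  wpos <- rbind(c(3, 0.5, 0), c(-2, 1, 1.5))
  toy_water_traj(solute_xyz, list(wpos))
}

test_that("water clusters get spherical triples and orientation torsions only", {
  cl <- qm_fixture()
  spec <- build_constraints(cl, frame = 1)
  expect_s3_class(spec, "constraint_spec")
  expect_identical(nrow(spec$frozen_spherical), 2L)
  tab <- table(spec$frozen_torsions$type)
  expect_identical(unname(tab["orientation"]), 6L)   # 3 per solvent molecule
  expect_false("solvent_internal" %in% names(tab))
  expect_false("solute" %in% names(tab))
})

test_that("the spherical encoding round-trips the solvent centers of mass", {
  cl <- qm_fixture()
  spec <- build_constraints(cl, frame = 1)
  centers <- constraint_centers(spec)
  # oracle: mass-weighted water COMs straight from the coordinates
  xyz <- frame_coords(cl, 1)
  topo <- cl$topology
  groups <- remcs:::solvent_molecules(topo)
  m <- c(O = 15.999, H = 1.008)
  oracle <- t(vapply(groups, function(ix) {
    w <- m[topo$element[ix]]
    colSums(xyz[ix, , drop = FALSE] * w) / sum(w)
  }, numeric(3)))
  expect_lt(max(abs(centers - oracle)), 1e-9)
  expect_true(all(spec$frozen_spherical$r > 0))
  expect_true(all(spec$frozen_spherical$theta >= 0 &
                    spec$frozen_spherical$theta <= pi))
})

test_that("spherical radii are invariant under a global rigid motion", {
  cl <- qm_fixture()
  set.seed(71)
  R <- random_rotation()
  rot <- trajectory(cl$topology,
                    cl$coords[, , 1] %*% t(R) +
                      matrix(c(4, -2, 6), n_atoms(cl), 3, byrow = TRUE))
  s1 <- build_constraints(cl, 1)$frozen_spherical
  s2 <- build_constraints(rot, 1)$frozen_spherical
  expect_equal(s1$r, s2$r, tolerance = 1e-9)
})

test_that("solute and solvent torsions are emitted and validated", {
  cl <- qm_fixture()
  spec <- build_constraints(cl, 1, solute_torsions = list(c(1, 2, 3, 4)))
  expect_identical(sum(spec$frozen_torsions$type == "solute"), 1L)
  expect_error(build_constraints(cl, 1, solute_torsions = list(c(1, 2))),
               "4 valid atom indices")
  expect_error(build_constraints(cl, 1, solute_torsions = list(c(1, 2, 3, 99))),
               "4 valid atom indices")
  expect_error(build_constraints(cl, 1,
                                 solute_torsions = list(c(1, 2, 3, 4),
                                                        c(1, 2, 3, 4))),
               "duplicate torsion")
  # a 4-atom solvent gets its declared internal torsion per molecule
  topo <- rbind(cl$topology[1:4, ],
                data.frame(element = c("C", "O", "H", "H"),
                           name = c("C1", "O1", "H1", "H2"), resname = "MEO",
                           resno = 2L, molecule_id = 2L, role = "solvent",
                           stringsAsFactors = FALSE))
  xyz <- rbind(frame_coords(cl, 1)[1:4, ],
               matrix(c(3, 0, 0, 4.2, 0.3, 0, 2.6, 0.9, 0.4, 2.7, -0.8, 0.2),
                      4, 3, byrow = TRUE))
  meo <- trajectory(topo, xyz)
  spec2 <- build_constraints(meo, 1, solvent_torsions = list(c(3, 1, 2, 4)))
  expect_identical(sum(spec2$frozen_torsions$type == "solvent_internal"), 1L)
  # local indices are mapped to global atom numbers
  row <- spec2$frozen_torsions[spec2$frozen_torsions$type ==
                                 "solvent_internal", ]
  expect_identical(as.integer(c(row$i, row$j, row$k, row$l)),
                   c(7L, 5L, 6L, 8L))
})

test_that("single-atom solvent molecules are rejected", {
  tr <- one_particle_traj(c(0, 1))
  expect_error(build_constraints(tr, 1), "cannot define")
})

test_that("write_constraints produces the documented plain-text layout", {
  cl <- qm_fixture()
  spec <- build_constraints(cl, 1)
  path <- tempfile(fileext = ".txt")
  write_constraints(spec, path)
  lines <- readLines(path)
  expect_identical(sum(grepl("^torsion orientation", lines)), 6L)
  expect_identical(sum(grepl("^spherical ", lines)), 2L)
  expect_true(any(grepl("^#", lines)))
})

test_that("parse_sticks reads both dialects and flags bad input", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "1300.5  2.25", "1250,-1.5", "", "1400 0.75"),
             path)
  st <- parse_sticks(path)
  expect_identical(st$lines$wavenumber, c(1250, 1300.5, 1400))
  expect_identical(st$lines$strength, c(-1.5, 2.25, 0.75))
  expect_identical(st$label, tools::file_path_sans_ext(basename(path)))

  lab <- tempfile(fileext = ".tsv")
  writeLines(c("1300 1.0 confA", "1310 -0.5 confA"), lab)
  expect_identical(parse_sticks(lab, dialect = "labeled")$label, "confA")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("1300 1.0", "oops 2.0"), bad)
  expect_error(parse_sticks(bad), "line 2")
  neg <- tempfile(fileext = ".tsv")
  writeLines("-10 1.0", neg)
  expect_error(parse_sticks(neg), "negative wavenumber")
  empty <- tempfile(fileext = ".tsv")
  writeLines("# nothing here", empty)
  expect_warning(st0 <- parse_sticks(empty), "no stick lines")
  expect_identical(nrow(st0$lines), 0L)
})
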