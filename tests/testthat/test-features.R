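test_that("PDB files round-trip through the reader", {
  s <- new_structure(atom = c("N", "CA", "C"), resname = "ALA",
                     resid = c(1L, 1L, 1L), chain = "A",
                     xyz = rbind(c(1.5, 2, 3), c(2.25, 3, 4),
                                 c(3.125, 4, 5)))
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  write_structure_pdb(s, path)
  r <- read_structure(path)
  expect_equal(nrow(r), 3)
  expect_equal(r$atom, c("N", "CA", "C"))
  expect_equal(r$x, c(1.5, 2.25, 3.125))
  expect_equal(r$resid, rep(1L, 3))
})

test_that("alternate locations resolve to the highest occupancy, ties alphabetically", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA AGLY A   2       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2       8.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CA ASER A   3       2.000   0.000   0.000  0.30  0.00           C",
    "ATOM      6  CA BSER A   3       7.000   0.000   0.000  0.70  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  writeLines(lines, path)
  r <- read_structure(path)
  expect_equal(nrow(r), 3)
  expect_equal(r$x[r$resid == 1], 0)    # occupancy 0.6 wins
  expect_equal(r$x[r$resid == 2], 1)    # tie -> altloc A
  expect_equal(r$x[r$resid == 3], 7)    # occupancy 0.7 wins over altloc A
})

test_that("model selection picks the requested MODEL block", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       5.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END")
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  writeLines(lines, path)
  expect_equal(read_structure(path, model = 1)$x, 0)
  expect_equal(read_structure(path, model = 2)$x, 5)
  expect_error(read_structure(path, model = 3), "model")
})

test_that("a missing chain error names the available chains", {
  s <- new_structure(atom = "CA", resname = "ALA", resid = 1L, chain = "B",
                     xyz = rbind(c(0, 0, 0)))
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  write_structure_pdb(s, path)
  expect_error(read_structure(path, chain = "Q"), "B")
})

test_that("center of mass weights by standard atomic masses", {
  s <- new_structure(atom = c("CA", "CA"), resname = "GLY",
                     resid = c(1L, 1L), xyz = rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(center_of_mass(s, 1), c(1, 0, 0))
  co <- new_structure(atom = c("C", "O"), resname = "GLY", resid = 1L,
                      xyz = rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(center_of_mass(co, 1)[1], 15.999 / (12.011 + 15.999),
               tolerance = 1e-12)
  shifted <- s
  shifted$x <- shifted$x + 3; shifted$y <- shifted$y - 1
  expect_equal(center_of_mass(shifted, 1), c(4, -1, 0))
  expect_error(center_of_mass(s, 99), "empty selection")
})

test_that("the interlid distance converts Angstrom geometry to nm and is rigid-body invariant", {
  collapsed <- new_structure(
    atom = rep("CA", 15), resname = "GLY",
    resid = c(142:146, 278:287),
    xyz = rbind(matrix(rep(c(0, 0, 0), 5), ncol = 3, byrow = TRUE),
                matrix(rep(c(30, 0, 0), 10), ncol = 3, byrow = TRUE)))
  expect_equal(interlid_distance(collapsed), 3.0)
  zero <- collapsed
  zero$x <- 0
  expect_equal(interlid_distance(zero), 0)
  # rigid rotation about z by 71 degrees plus a translation
  th <- 71 * pi / 180
  rot <- collapsed
  rot$x <- collapsed$x * cos(th) - collapsed$y * sin(th) + 4
  rot$y <- collapsed$x * sin(th) + collapsed$y * cos(th) - 2
  expect_equal(interlid_distance(rot), 3.0, tolerance = 1e-9)
  expect_error(interlid_distance(collapsed[collapsed$resid != 144, ]),
               "144")
})

test_that("lid distances come from the named Calpha pairs", {
  s <- make_crystal_standin(dist2_A = 12.0, salt_NO_A = 8, dist1_A = 25)
  lf <- lid_distances(s)
  expect_equal(lf$dist2, 1.2, tolerance = 1e-12)
  expect_equal(lf$dist1, 2.5, tolerance = 1e-12)
  expect_gt(lf$d, 0)
  expect_error(lid_distances(s[s$resid != 309, ]), "309")
})

test_that("conformation classification applies the stated boundary conventions", {
  expect_equal(classify_conformation(0.98), "closed")
  expect_equal(classify_conformation(1.55), "semiopen")
  expect_equal(classify_conformation(1.0), "closed")
  expect_equal(classify_conformation(2.0), "open")
  expect_error(classify_conformation(-0.1), "non-negative")
  # partition: every value gets exactly one label
  grid <- seq(0, 4, by = 0.01)
  expect_true(all(classify_conformation(grid) %in%
                    c("closed", "semiopen", "open")))
})
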