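# small helper: a two-residue frame with the salt-bridge pair at a chosen
# N-O distance
sb_frame <- function(no_dist) {
  new_structure(atom = c("OD1", "OD2", "NZ"),
                resname = c("ASP", "ASP", "LYS"),
                resid = c(145L, 145L, 290L),
                xyz = rbind(c(0, 0, 0), c(1.2, 0, 0), c(no_dist, 0, 0)))
}

test_that("contact detection applies the strict distance cutoff symmetrically", {
  s <- make_structure_ensemble(synthetic_structure_spec(
    planted_contacts = data.frame(resid_i = 140, resid_j = 280,
                                  distance = 4.9)))[[1]]
  expect_equal(nrow(residue_contacts(s)), 1)
  s2 <- make_structure_ensemble(synthetic_structure_spec(
    planted_contacts = data.frame(resid_i = 140, resid_j = 280,
                                  distance = 5.0)))[[1]]
  expect_equal(nrow(residue_contacts(s2)), 0)
  # pairs are reported once, ordered i < j, regardless of planting order
  s3 <- make_structure_ensemble(synthetic_structure_spec(
    planted_contacts = data.frame(resid_i = 280, resid_j = 140,
                                  distance = 4.0)))[[1]]
  c3 <- residue_contacts(s3)
  expect_equal(c3$resid_i, 140)
  expect_equal(c3$resid_j, 280)
})

test_that("macrostate probabilities are stationary-weighted microstate means", {
  expect_equal(macrostate_contact_probability(c(1, 0), c(0.25, 0.75)), 0.25)
  expect_equal(macrostate_contact_probability(c(1, 1, 1), c(0.2, 0.5, 0.3)),
               1)
  p <- c(0.2, 0.9, 0.4)
  expect_equal(macrostate_contact_probability(p, rep(1 / 3, 3)), mean(p))
  # bounds: min p <= P <= max p for any weights
  set.seed(2)
  for (i in 1:20) {
    pk <- runif(5)
    w <- runif(5)
    P <- macrostate_contact_probability(pk, w)
    expect_gte(P, min(pk))
    expect_lte(P, max(pk))
  }
  expect_error(macrostate_contact_probability(c(1, 0), c(0, 0)), "zero")
})

test_that("average interaction counts weight microstates by pi", {
  expect_equal(macrostate_average_counts(rep(7, 10), rep(1L, 10), 1), 7)
  counts <- c(rep(10, 5), rep(20, 5))
  micro <- rep(c(1L, 2L), each = 5)
  expect_equal(macrostate_average_counts(counts, micro, c(0.5, 0.5)), 15)
  expect_equal(macrostate_average_counts(counts, micro, c(0.9, 0.1)), 11)
})

test_that("planted interaction loss shows up as an average-count difference", {
  closed_spec <- synthetic_structure_spec(
    planted_contacts = data.frame(resid_i = c(140, 141, 142, 143, 144),
                                  resid_j = c(280, 281, 282, 283, 284),
                                  distance = 4.5),
    n_structures = 5)
  open_spec <- synthetic_structure_spec(
    planted_contacts = data.frame(resid_i = c(140, 141),
                                  resid_j = c(280, 281),
                                  distance = 4.5),
    n_structures = 5)
  n_closed <- vapply(make_structure_ensemble(closed_spec),
                     function(s) nrow(residue_contacts(s)), numeric(1))
  n_open <- vapply(make_structure_ensemble(open_spec),
                   function(s) nrow(residue_contacts(s)), numeric(1))
  a <- macrostate_average_counts(n_closed, rep(1L, 5), 1)
  b <- macrostate_average_counts(n_open, rep(1L, 5), 1)
  expect_equal(a - b, 3.0)
})

test_that("probability changes are screened with a strict threshold", {
  pb <- c("140-280" = 0.9, "141-281" = 0.5, "142-282" = 0.7)
  pc <- c("140-280" = 0.1, "141-281" = 0.7, "143-283" = 0.5)
  d <- delta_probability(pb, pc, threshold = 0.2)
  expect_equal(d$losses$pair, c("140-280", "142-282"))
  expect_equal(d$losses$delta[1], -0.8)
  expect_equal(d$gains$pair, "143-283")      # absent in B counts as 0
  # |delta| = 0.2 exactly is excluded
  expect_false("141-281" %in% c(d$gains$pair, d$losses$pair))
})

test_that("macrostate structure sampling is deterministic with stated resampling rules", {
  labels <- rep(1:4, times = c(40, 30, 25, 10))
  s1 <- sample_macrostate_structures(labels, members = 1:3, seed = 5)
  expect_equal(nrow(s1), 75)
  expect_false(any(s1$resampled))
  expect_true(all(tapply(s1$frame, s1$microstate, anyDuplicated) == 0))
  s2 <- sample_macrostate_structures(labels, members = 1:3, seed = 5)
  expect_identical(s1, s2)
  s3 <- sample_macrostate_structures(labels, members = 4L, seed = 5)
  expect_equal(nrow(s3), 25)
  expect_true(all(s3$resampled))
  expect_warning(sample_macrostate_structures(labels, members = c(4L, 9L),
                                              seed = 5), "no frames")
})

test_that("salt-bridge probabilities count strict sub-cutoff frames with pi weighting", {
  frames <- c(replicate(3, sb_frame(3.5), simplify = FALSE),
              replicate(97, sb_frame(8.0), simplify = FALSE))
  res <- salt_bridge_probability(frames)
  expect_equal(res$probability, 0.03)
  res0 <- salt_bridge_probability(frames,
                                  criteria = salt_bridge_criteria(cutoff = 0))
  expect_equal(res0$probability, 0)
  rare <- c(replicate(1, sb_frame(3.0), simplify = FALSE),
            replicate(999, sb_frame(9.0), simplify = FALSE))
  expect_equal(salt_bridge_probability(rare)$probability, 0.001)
  expect_error(salt_bridge_probability(list(new_structure(
    atom = "CA", resname = "GLY", resid = 1L, xyz = rbind(c(0, 0, 0))))),
    "missing")
})

test_that("probability from indicators reduces to the plain mean under uniform weights", {
  ind <- c(1, 0, 1, 1, 0)
  micro <- 1:5
  expect_equal(macrostate_average_counts(ind, micro, rep(0.2, 5)),
               mean(ind))
})
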