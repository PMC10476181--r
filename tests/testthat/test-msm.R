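test_that("k-means++ clustering separates well-separated clouds and is deterministic", {
  set.seed(1)
  clouds <- rbind(cbind(rnorm(50, 0, 0.05), rnorm(50, 0, 0.05)),
                  cbind(rnorm(50, 3, 0.05), rnorm(50, 0, 0.05)),
                  cbind(rnorm(50, 0, 0.05), rnorm(50, 3, 0.05)))
  cl <- cluster_microstates(clouds, 3, seed = 7)
  lab <- assign_microstates(cl, clouds)
  truth <- rep(1:3, each = 50)
  # purity 1: each cloud maps to exactly one cluster and vice versa
  expect_equal(sum(table(lab, truth) > 0), 3)
  cl2 <- cluster_microstates(clouds, 3, seed = 7)
  expect_identical(cl$centers, cl2$centers)
  one <- cluster_microstates(clouds, 1, seed = 7)
  expect_equal(as.numeric(one$centers), colMeans(clouds), tolerance = 1e-12)
  expect_error(cluster_microstates(clouds[1:2, ], 5, seed = 1), "distinct")
})

test_that("transition counting matches hand enumeration and respects boundaries", {
  dtraj <- c(1L, 1L, 2L, 2L, 1L, 2L)
  C1 <- count_transitions(dtraj, 1, k = 2)
  expect_equal(C1, matrix(c(1, 2, 1, 1), 2, 2, byrow = TRUE))
  C5 <- count_transitions(dtraj, 5, k = 2)
  expect_equal(C5, matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(count_transitions(list(dtraj, dtraj), 1, k = 2), 2 * C1)
  # segments shorter than the lag contribute nothing, with a warning when
  # everything is skipped
  expect_warning(count_transitions(list(c(1L, 2L)), 5, k = 2), "lag")
  # counting never crosses segment boundaries
  Csplit <- count_transitions(list(c(1L, 1L), c(2L, 2L)), 1, k = 2)
  expect_equal(Csplit, matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
})

test_that("the largest strongly connected set follows the stated tie-breaks", {
  C <- matrix(0, 5, 5)
  C[1:3, 1:3] <- 1
  C[4:5, 4:5] <- 1
  expect_equal(largest_connected_set(C), 1:3)
  expect_equal(largest_connected_set(matrix(1, 4, 4)), 1:4)
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- 1; chain[2, 3] <- 1
  expect_equal(largest_connected_set(chain), 1L)
  expect_error(largest_connected_set(matrix(0, 2, 2)), "empty")
})

test_that("transition-matrix estimation matches row normalisation and detailed balance", {
  C <- matrix(c(1, 2, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(estimate_transition_matrix(C, "nonreversible"),
               matrix(c(1 / 3, 2 / 3, 1 / 2, 1 / 2), 2, 2, byrow = TRUE))
  Csym <- matrix(c(5, 2, 3, 2, 6, 1, 3, 1, 4), 3, 3, byrow = TRUE)
  Csym <- Csym + t(Csym)
  expect_equal(estimate_transition_matrix(Csym, "reversible"),
               estimate_transition_matrix(Csym, "nonreversible"),
               tolerance = 1e-8)
  set.seed(3)
  Crand <- matrix(rpois(36, 8) + 1, 6, 6)
  Trev <- estimate_transition_matrix(Crand, "reversible")
  pi_ <- stationary_distribution(Trev)
  expect_lt(max(abs(pi_ * Trev - t(pi_ * Trev))), 1e-8)
  expect_equal(rowSums(Trev), rep(1, 6), tolerance = 1e-10)
  expect_error(estimate_transition_matrix(
    matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE), "nonreversible"),
    "zero row")
})

test_that("the stationary distribution solves the left eigenproblem", {
  expect_equal(stationary_distribution(toy_T2), c(2 / 3, 1 / 3),
               tolerance = 1e-10)
  doubly <- matrix(c(0.5, 0.3, 0.2,
                     0.2, 0.5, 0.3,
                     0.3, 0.2, 0.5), 3, 3, byrow = TRUE)
  expect_equal(stationary_distribution(doubly), rep(1 / 3, 3),
               tolerance = 1e-10)
  # permutation equivariance
  P <- matrix(0, 3, 3)
  P[cbind(1:3, c(2, 3, 1))] <- 1
  Tp <- P %*% toy_T3_biased %*% t(P)
  expect_equal(stationary_distribution(Tp),
               as.numeric(P %*% stationary_distribution(toy_T3_biased)),
               tolerance = 1e-10)
})

test_that("free energies are min-shifted negative log probabilities", {
  expect_equal(free_energy(rep(0.25, 4)), rep(0, 4))
  f <- free_energy(c(0.8, 0.2))
  expect_equal(f[2] - f[1], log(4), tolerance = 1e-12)
  expect_equal(free_energy(c(0.8, 0.2), kT = 2.5), 2.5 * f)
  expect_error(free_energy(c(0.5, 0)), "positive")
})

test_that("pi T = pi holds for the fitted model and counts converge to the truth", {
  truth <- toy_T3_biased
  sim <- function(n) {
    m0 <- structure(list(transition_matrix = truth,
                         stationary = stationary_distribution(truth)),
                    class = "markov_model")
    simulate(m0, nsim = n, seed = 11, start = 1)
  }
  m_small <- markov_model(list(sim(2000)), 1, k = 3)
  m_big <- markov_model(list(sim(60000)), 1, k = 3)
  expect_lt(max(abs(m_big$stationary %*% m_big$transition_matrix -
                      m_big$stationary)), 1e-8)
  err_small <- max(abs(m_small$transition_matrix - truth))
  err_big <- max(abs(m_big$transition_matrix - truth))
  expect_lt(err_big, err_small)
  expect_lt(err_big, 0.02)
})

test_that("implied timescales recover the spectral relaxation time and are lag-stable", {
  lam2 <- 0.7
  truth <- matrix(c(1 - (1 - lam2) / 2, (1 - lam2) / 2,
                    (1 - lam2) / 2, 1 - (1 - lam2) / 2), 2, 2, byrow = TRUE)
  m0 <- structure(list(transition_matrix = truth,
                       stationary = c(0.5, 0.5)), class = "markov_model")
  dtraj <- simulate(m0, nsim = 2e5, seed = 21, start = 1)
  its <- implied_timescales(list(dtraj), c(1L, 2L, 4L), n_timescales = 1)
  t_ref <- -1 / log(lam2)
  est <- its$its_ps[its$lag_ps == 1]
  expect_equal(est, t_ref, tolerance = 0.1)
  # a Markov chain gives lag-independent timescales (within noise)
  expect_equal(its$its_ps[its$lag_ps == 4], est, tolerance = 0.15)
})

test_that("free-energy projection masks unvisited bins and marginalises exactly", {
  centers <- rbind(c(0.5, 0.5), c(1.5, 0.5), c(1.5, 1.5))
  fel <- project_fel(c(1, 0, 0), centers,
                     xedges = c(0, 1, 2), yedges = c(0, 1, 2))
  expect_equal(fel$F2d[1, 1], 0)
  expect_true(all(is.na(fel$F2d[2, 2])))
  set.seed(5)
  pi2 <- runif(3); pi2 <- pi2 / sum(pi2)
  fel2 <- project_fel(pi2, centers, c(0, 1, 2), c(0, 1, 2))
  expect_equal(fel2$p1d, colSums(fel2$p2d), tolerance = 1e-12)
  expect_error(project_fel(pi2, centers + 5, c(0, 1, 2), c(0, 1, 2)),
               "outside")
})

test_that("an MSM from adaptive-seeding segments corrects the selection bias of the raw pool", {
  # two-well landscape: deep lower well, shallow upper well
  tw <- potential_spec(list(
    list(center = c(2.5, 0.8), depth = 7, width = 0.27),
    list(center = c(2.5, 1.6), depth = 5, width = 0.27)),
    confinement_k = c(6, 1.2), confinement_origin = c(2.5, 1.2))
  xe <- seq(1.6, 3.4, by = 0.05)
  ye <- seq(-0.2, 2.8, by = 0.05)
  pb <- suppressWarnings(reference_boltzmann(tw, xe, ye, subdiv = 4))
  ym <- (ye[-1] + ye[-length(ye)]) / 2
  ref <- c(sum(colSums(pb)[ym <= 1.2]), sum(colSums(pb)[ym > 1.2]))

  engine <- langevin_engine(tw, record_stride = 50L)
  cfg <- pacs_config(n_rep = 10, open_threshold_nm = 1.9,
                     close_threshold_nm = 0.6,
                     preliminary_length_ps = 500, max_cycles = 40,
                     seed = 11)
  camp <- run_campaign(engine, cfg = cfg, initial = c(2.5, 0.8),
                       n_opening_trials = 2, n_closing_per_opening = 2)
  pool <- campaign_frames(camp)
  clu <- cluster_microstates(pool[, c("cv1", "cv2")], 30, seed = 11)
  lab <- assign_microstates(clu, pool[, c("cv1", "cv2")])
  seg <- paste(pool$stage, pool$trial, pool$cycle, pool$replica)
  m <- markov_model(unname(split(lab, factor(seg, levels = unique(seg)))),
                    100, k = 30, dt_ps = 0.5)
  cc <- clu$centers[m$active_set, 2]
  est <- c(sum(m$stationary[cc <= 1.2]), sum(m$stationary[cc > 1.2]))
  raw <- c(mean(pool$cv2 <= 1.2), mean(pool$cv2 > 1.2))
  tv_msm <- tv_dist(est, ref)
  tv_raw <- tv_dist(raw, ref)
  expect_lt(tv_msm, 0.1)
  expect_lt(tv_msm, tv_raw)
})
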