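snap_pool <- function(cv, cycle = seq_along(cv), replica = 1L,
                      frame = seq_along(cv)) {
  data.frame(trial = 1L, cycle = cycle, replica = replica, frame = frame,
             cv1 = 0, cv2 = cv, cv = cv)
}

test_that("ranking orders by the collective variable with a stable tie-break", {
  pool <- snap_pool(c(1.2, 3.4, 2.2))
  expect_equal(rank_snapshots(pool, "opening")$cv, c(3.4, 2.2, 1.2))
  expect_equal(rank_snapshots(pool, "closing")$cv, c(1.2, 2.2, 3.4))
  ties <- data.frame(trial = 1L, cycle = c(2L, 1L, 1L),
                     replica = c(1L, 3L, 2L), frame = c(5L, 7L, 9L),
                     cv1 = 0, cv2 = 2, cv = 2)
  r <- rank_snapshots(ties, "opening")
  expect_equal(r$cycle, c(1L, 1L, 2L))
  expect_equal(r$replica, c(2L, 3L, 1L))
  expect_error(rank_snapshots(pool[0, ], "opening"), "non-empty")
})

test_that("seed selection takes the top block and recycles short rankings", {
  pool <- rank_snapshots(snap_pool(runif(40, 1, 3)), "opening")
  expect_equal(select_seeds(pool, 30)$cv, pool$cv[1:30])
  small <- rank_snapshots(snap_pool(seq(1, 2, length.out = 10)), "opening")
  picked <- select_seeds(small, 30)
  expect_equal(nrow(picked), 30)
  expect_equal(as.integer(table(picked$cv)), rep(3L, 10))
  expect_equal(select_seeds(pool, 1)$cv, max(pool$cv))
})

test_that("a deterministic drift engine terminates at the threshold with a monotone frontier", {
  # drift: cv2 increases by 0.01 nm per recorded frame, no noise
  drift_engine <- function(state, length_ps, seed) {
    n <- round(length_ps)  # one frame per ps
    frames <- cbind(state[1], state[2] + 0.01 * (0:n))
    colnames(frames) <- c("cv1", "cv2")
    structure(list(frames = frames, dt_ps = 1,
                   cfg = NULL, provenance = list()),
              class = "cv_trajectory")
  }
  cfg <- pacs_config(n_rep = 3, cycle_length_ps = 10, max_cycles = 50,
                     open_threshold_nm = 1.5, close_threshold_nm = 0.5,
                     preliminary_length_ps = 10, seed = 1)
  tr <- run_pacs_trial(drift_engine, cfg = cfg, initial = c(0, 1.0))
  expect_equal(tr$termination, "threshold")
  best <- tapply(tr$pool$cv, tr$pool$cycle, max)
  expect_true(all(diff(best) >= 0))
  # immediate satisfaction: threshold below the starting point
  cfg2 <- pacs_config(n_rep = 3, cycle_length_ps = 10, max_cycles = 50,
                      open_threshold_nm = 1.5, close_threshold_nm = 0.5,
                      preliminary_length_ps = 10, seed = 1)
  tr2 <- run_pacs_trial(drift_engine, cfg = cfg2, initial = c(0, 1.6))
  expect_equal(tr2$n_cycles, 1L)
  expect_equal(tr2$termination, "threshold")
})

test_that("with n_rep covering all candidates the selection is the identity", {
  pool <- snap_pool(runif(7, 1, 2))
  ranked <- rank_snapshots(pool, "opening")
  picked <- select_seeds(ranked, 7)
  expect_setequal(picked$cv, pool$cv)
})

test_that("campaigns count, tag and reproduce deterministically", {
  sp <- potential_spec(list(list(center = c(0, 1), depth = 4, width = 0.3)),
                       confinement_k = 3, confinement_origin = c(0, 1))
  engine <- langevin_engine(sp, record_stride = 20L)
  cfg <- pacs_config(n_rep = 4, cycle_length_ps = 20, max_cycles = 3,
                     open_threshold_nm = 1.6, close_threshold_nm = 0.6,
                     preliminary_length_ps = 40, seed = 10)
  camp <- run_campaign(engine, cfg = cfg, initial = c(0, 1),
                       n_opening_trials = 2, n_closing_per_opening = 2)
  stages <- vapply(camp, function(t) t$stage, character(1))
  expect_length(camp, 6)
  expect_equal(sum(stages == "oPaCS"), 2)
  expect_equal(sum(stages == "cPaCS"), 4)
  camp2 <- run_campaign(engine, cfg = cfg, initial = c(0, 1),
                        n_opening_trials = 2, n_closing_per_opening = 2)
  expect_identical(campaign_frames(camp), campaign_frames(camp2))
  camp3 <- run_campaign(engine, cfg = cfg, initial = c(0, 1),
                        n_opening_trials = 2, n_closing_per_opening = 0)
  expect_length(camp3, 2)
  expect_true(all(vapply(camp3, function(t) t$stage, character(1)) ==
                    "oPaCS"))
})

test_that("every pooled frame has a unique provenance and the stated frame count", {
  sp <- potential_spec(list(list(center = c(0, 1), depth = 4, width = 0.3)),
                       confinement_k = 3, confinement_origin = c(0, 1))
  engine <- langevin_engine(sp, record_stride = 20L)
  cfg <- pacs_config(n_rep = 3, cycle_length_ps = 20, max_cycles = 2,
                     open_threshold_nm = 5, close_threshold_nm = 0.1,
                     preliminary_length_ps = 40, seed = 2)
  tr <- run_pacs_trial(engine, cfg = cfg, initial = c(0, 1))
  expect_equal(tr$termination, "max_cycles")
  key <- with(tr$pool, paste(trial, cycle, replica, frame))
  expect_false(anyDuplicated(key) > 0)
  # each cycle trajectory has cycle_length / (dt * stride) + 1 frames
  per_seg <- table(with(tr$pool[tr$pool$cycle > 0, ],
                        paste(cycle, replica)))
  expect_true(all(per_seg == 20 / (0.01 * 20) + 1))
})

test_that("simulation cost bookkeeping multiplies out in microseconds", {
  expect_equal(simulation_cost(0.1, 49.6, 30), 0.1488)
  expect_equal(simulation_cost(0.1, 292.0, 30), 0.876)
  expect_equal(simulation_cost(0.1, 0, 30), 0)
  expect_error(simulation_cost(-0.1, 1, 30), "non-negative")
})

test_that("adaptive seeding reaches the open band at lower cost than plain runs", {
  sp <- preset_landscape("water_like")
  engine <- langevin_engine(sp, record_stride = 50L)
  # aggregate engine time consumed until the first frame in the open band,
  # counted in execution order for both protocols
  pacs_steps <- function(seed) {
    cfg <- pacs_config(n_rep = 20, open_threshold_nm = 2.0,
                       close_threshold_nm = 0.9,
                       preliminary_length_ps = 500, max_cycles = 20,
                       seed = seed)
    tr <- run_pacs_trial(engine, cfg = cfg, initial = c(2.6, 0.70))
    hit <- which(tr$pool$cv2 > 2.0)
    if (length(hit) == 0) return(Inf)
    hit[1] * 0.5 * 100                       # frames -> ps -> steps
  }
  plain_steps <- function(seed, budget_ps) {
    len <- budget_ps / 20
    used <- 0
    for (r in 1:20) {
      tr <- engine(c(2.6, 0.70), len, derive_seed(seed, 777L, r))
      hit <- which(tr$frames[, 2] > 2.0)
      if (length(hit) > 0) return((used + (hit[1] - 1) * 0.5) * 100)
      used <- used + len
    }
    Inf
  }
  seeds <- 1:10
  pc <- vapply(seeds, pacs_steps, numeric(1))
  budget_ps <- 2500
  pl <- vapply(seeds, function(s) plain_steps(s, budget_ps), numeric(1))
  expect_lt(median(pc), median(pl))
})
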