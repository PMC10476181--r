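## Parallel cascade selection driver, generic over any engine implementing
## propagate(state, length_ps, seed) -> cv_trajectory.
##
## A "snapshot pool" is a data.frame with one row per retained frame:
## trial, cycle, replica, frame (provenance), cv1, cv2 (engine state) and cv
## (the ranking collective variable, the interlid distance d for the lid
## system). The candidate pool for each cycle's selection is the set of
## frames from the immediately preceding cycle only.

#' PaCS protocol configuration
#'
#' Defaults follow the published lid-opening protocol: 30 replicas, 0.1 ns
#' cycles, a 1 ns preliminary run, switching thresholds of 3.0 nm (opening
#' reached) and 0.8 nm (closing reached) on the ranking variable.
#'
#' @param n_rep replicas per cycle (>= 1).
#' @param cycle_length_ps length of each replica run per cycle (ps).
#' @param max_cycles cycle cap per trial.
#' @param open_threshold_nm terminate an opening-stage trial once the ranking
#'   variable exceeds this value.
#' @param close_threshold_nm terminate a closing-stage trial once the ranking
#'   variable falls below this value.
#' @param direction `"opening"` or `"closing"`.
#' @param preliminary_length_ps length of the preliminary run feeding the
#'   first selection (ps).
#' @param seed master seed; all replica seeds are derived from it via
#'   [derive_seed()].
#' @return a list of class `pacs_config`.
#' @export
pacs_config <- function(n_rep = 30L, cycle_length_ps = 100,
                        max_cycles = 200L, open_threshold_nm = 3.0,
                        close_threshold_nm = 0.8,
                        direction = c("opening", "closing"),
                        preliminary_length_ps = 1000, seed = 1L) {
  direction <- match.arg(direction)
  if (!is_count(n_rep)) stop("'n_rep' must be a positive integer")
  stopifnot_number(cycle_length_ps, "cycle_length_ps", 0, strict = TRUE)
  if (!is_count(max_cycles)) stop("'max_cycles' must be a positive integer")
  stopifnot_number(open_threshold_nm, "open_threshold_nm", 0, strict = TRUE)
  stopifnot_number(close_threshold_nm, "close_threshold_nm", 0, strict = TRUE)
  if (open_threshold_nm <= close_threshold_nm)
    stop("open_threshold_nm must exceed close_threshold_nm")
  stopifnot_number(preliminary_length_ps, "preliminary_length_ps", 0,
                   strict = TRUE)
  structure(list(n_rep = as.integer(n_rep),
                 cycle_length_ps = cycle_length_ps,
                 max_cycles = as.integer(max_cycles),
                 open_threshold_nm = open_threshold_nm,
                 close_threshold_nm = close_threshold_nm,
                 direction = direction,
                 preliminary_length_ps = preliminary_length_ps,
                 seed = as.integer(seed)),
            class = "pacs_config")
}

#' Rank snapshots along the collective variable
#'
#' Descending order for the opening direction (longer distances first),
#' ascending for closing. Ties are broken lexicographically by
#' (cycle, replica, frame), giving a stable total order.
#'
#' @param snapshots data.frame with columns `cv`, `cycle`, `replica`, `frame`.
#' @param direction `"opening"` or `"closing"`.
#' @return the same data.frame, reordered.
#' @export
rank_snapshots <- function(snapshots, direction = c("opening", "closing")) {
  direction <- match.arg(direction)
  if (!is.data.frame(snapshots) || nrow(snapshots) == 0)
    stop("'snapshots' must be a non-empty data.frame")
  if (!all(is.finite(snapshots$cv))) stop("all cv values must be finite")
  key <- if (direction == "opening") -snapshots$cv else snapshots$cv
  snapshots[order(key, snapshots$cycle, snapshots$replica, snapshots$frame), ,
            drop = FALSE]
}

#' Select seeds for the next cycle from a ranked pool
#'
#' Takes the first `n_rep` entries; when fewer candidates exist the ranking is
#' cycled from the top so every replica still gets a seed.
#'
#' @param ranked output of [rank_snapshots()].
#' @param n_rep number of seeds required.
#' @return data.frame of `n_rep` rows.
#' @export
select_seeds <- function(ranked, n_rep) {
  if (!is.data.frame(ranked) || nrow(ranked) == 0)
    stop("'ranked' must be a non-empty data.frame")
  idx <- rep(seq_len(nrow(ranked)), length.out = n_rep)
  ranked[idx, , drop = FALSE]
}

## Flatten one trajectory into pool rows.
traj_to_pool <- function(traj, cv_extractor, trial, cycle, replica) {
  fr <- traj$frames
  data.frame(trial = trial, cycle = cycle, replica = replica,
             frame = seq_len(nrow(fr)) - 1L,
             cv1 = fr[, 1], cv2 = fr[, 2],
             cv = cv_extractor(fr))
}

#' Run one PaCS trial
#'
#' A preliminary run seeds the first selection; each subsequent cycle ranks
#' the previous cycle's frames, selects the top `n_rep` as restart points and
#' propagates each with a fresh derived noise stream (the overdamped analogue
#' of velocity reinitialisation). The trial stops once any frame's ranking
#' variable crosses the stage threshold, or at `max_cycles`.
#'
#' @param engine propagator `function(state, length_ps, seed) -> cv_trajectory`.
#' @param cv_extractor `function(frames_matrix) -> numeric` ranking variable
#'   per frame; defaults to the second collective variable (the Dist2-like
#'   axis, standing in for the interlid distance d).
#' @param cfg a [pacs_config()].
#' @param initial numeric length-2 initial engine state.
#' @param trial_id integer provenance label.
#' @return an object of class `pacs_trial`: list with `pool` (all frames with
#'   provenance; the preliminary run is cycle 0, replica 1), `termination`
#'   (`"threshold"` or `"max_cycles"`), `n_cycles`, `stage` (`"oPaCS"` or
#'   `"cPaCS"`), `cfg`, `trial_id`, and `final_state` (the best frame of the
#'   final cycle).
#' @export
run_pacs_trial <- function(engine, cv_extractor = function(x) x[, 2],
                           cfg = pacs_config(), initial,
                           trial_id = 1L) {
  stopifnot(inherits(cfg, "pacs_config"), is.function(engine),
            is.function(cv_extractor))
  if (length(initial) != 2 || !all(is.finite(initial)))
    stop("'initial' must be a finite length-2 state")
  stage <- if (cfg$direction == "opening") "oPaCS" else "cPaCS"
  crossed <- if (cfg$direction == "opening") {
    function(cv) cv > cfg$open_threshold_nm
  } else {
    function(cv) cv < cfg$close_threshold_nm
  }

  prelim <- engine(initial, cfg$preliminary_length_ps,
                   derive_seed(cfg$seed, trial_id, 0L, 0L))
  pool <- list(traj_to_pool(prelim, cv_extractor, trial_id, 0L, 1L))
  candidates <- pool[[1L]]

  termination <- "max_cycles"
  n_cycles <- cfg$max_cycles
  for (cycle in seq_len(cfg$max_cycles)) {
    seeds <- select_seeds(rank_snapshots(candidates, cfg$direction),
                          cfg$n_rep)
    cyc <- vector("list", cfg$n_rep)
    for (r in seq_len(cfg$n_rep)) {
      state <- c(seeds$cv1[r], seeds$cv2[r])
      traj <- tryCatch(
        engine(state, cfg$cycle_length_ps,
               derive_seed(cfg$seed, trial_id, cycle, r)),
        error = function(e) stop(sprintf(
          "engine failure in trial %d, cycle %d, replica %d: %s",
          trial_id, cycle, r, conditionMessage(e)), call. = FALSE))
      cyc[[r]] <- traj_to_pool(traj, cv_extractor, trial_id, cycle, r)
    }
    candidates <- do.call(rbind, cyc)
    pool[[length(pool) + 1L]] <- candidates
    if (any(crossed(candidates$cv))) {
      termination <- "threshold"
      n_cycles <- cycle
      break
    }
  }

  pool <- do.call(rbind, pool)
  rownames(pool) <- NULL
  last <- pool[pool$cycle == n_cycles, , drop = FALSE]
  best <- rank_snapshots(last, cfg$direction)[1L, ]
  structure(list(pool = pool, termination = termination,
                 n_cycles = n_cycles, stage = stage, cfg = cfg,
                 trial_id = as.integer(trial_id),
                 final_state = c(best$cv1, best$cv2)),
            class = "pacs_trial")
}

#' @export
print.pacs_trial <- function(x, ...) {
  cat(sprintf("%s trial %d: %d cycles (%s), %d frames, best cv %.3f nm\n",
              x$stage, x$trial_id, x$n_cycles, x$termination,
              nrow(x$pool),
              if (x$cfg$direction == "opening") max(x$pool$cv)
              else min(x$pool$cv)))
  invisible(x)
}

#' Run an opening/closing PaCS campaign
#'
#' Runs `n_opening_trials` opening-stage trials from `initial`; each opening
#' trial's final snapshot then seeds `n_closing_per_opening` closing-stage
#' trials with distinct derived seeds (the open-to-closed return stage).
#'
#' @inheritParams run_pacs_trial
#' @param n_opening_trials number of opening trials.
#' @param n_closing_per_opening closing trials per opening trial (>= 0).
#' @return an object of class `pacs_campaign`: list of `pacs_trial` objects
#'   with unique trial ids and stage tags.
#' @export
run_campaign <- function(engine, cv_extractor = function(x) x[, 2],
                         cfg = pacs_config(), initial,
                         n_opening_trials = 1L,
                         n_closing_per_opening = 2L) {
  stopifnot(is_count(n_opening_trials),
            is_count(n_closing_per_opening, min = 0L))
  trials <- list()
  tid <- 0L
  for (i in seq_len(n_opening_trials)) {
    tid <- tid + 1L
    ocfg <- cfg
    ocfg$direction <- "opening"
    ocfg$seed <- derive_seed(cfg$seed, 1L, tid)
    op <- run_pacs_trial(engine, cv_extractor, ocfg, initial, trial_id = tid)
    trials[[length(trials) + 1L]] <- op
    for (j in seq_len(n_closing_per_opening)) {
      tid <- tid + 1L
      ccfg <- cfg
      ccfg$direction <- "closing"
      ccfg$seed <- derive_seed(cfg$seed, 2L, tid, j)
      trials[[length(trials) + 1L]] <-
        run_pacs_trial(engine, cv_extractor, ccfg, op$final_state,
                       trial_id = tid)
    }
  }
  structure(trials, class = "pacs_campaign")
}

#' @export
print.pacs_campaign <- function(x, ...) {
  stages <- vapply(x, function(t) t$stage, character(1))
  cat(sprintf("PaCS campaign: %d trials (%d oPaCS, %d cPaCS), %d frames total\n",
              length(x), sum(stages == "oPaCS"), sum(stages == "cPaCS"),
              sum(vapply(x, function(t) nrow(t$pool), numeric(1)))))
  invisible(x)
}

#' Pool all frames of a campaign
#'
#' @param campaign a `pacs_campaign` (or a single `pacs_trial`).
#' @return data.frame of all frames with provenance columns
#'   (trial, cycle, replica, frame) plus `cv1`, `cv2`, `cv` and `stage`.
#' @export
campaign_frames <- function(campaign) {
  if (inherits(campaign, "pacs_trial")) campaign <- list(campaign)
  out <- do.call(rbind, lapply(campaign, function(t) {
    p <- t$pool
    p$stage <- t$stage
    p
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate simulation cost of a PaCS stage
#'
#' Cost per trial is cycle length (ns) x number of cycles x number of
#' replicas, reported in microseconds of aggregate simulation time.
#'
#' @param cycle_length_ns cycle length in ns.
#' @param n_cycles number of cycles (may be a per-trial average).
#' @param n_rep replicas per cycle.
#' @return cost in microseconds.
#' @examples
#' simulation_cost(0.1, 49.6, 30)  # ~0.149 us per trial
#' @export
simulation_cost <- function(cycle_length_ns, n_cycles, n_rep) {
  for (v in list(cycle_length_ns, n_cycles, n_rep)) {
    if (length(v) != 1 || !is.finite(v) || v < 0)
      stop("all arguments must be single non-negative numbers")
  }
  cycle_length_ns * n_cycles * n_rep / 1000
}
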