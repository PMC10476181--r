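## End-to-end orchestration: landscape -> PaCS campaign -> clustering ->
## MSM (+ ITS, FEL) -> PCCA+ -> MFPT/committor/TPT -> synthetic-ensemble
## interaction statistics, plus the crystal-structure geometry survey.

#' Pipeline configuration
#'
#' Defaults are scaled for a desk-size synthetic study: they keep the full
#' analysis under a couple of minutes on one CPU while preserving the
#' protocol's structure (preliminary run + ranked selection cycles, 100 ps
#' segments, 50 ps lag, k-means microstates, PCCA+ macrostates).
#'
#' @param preset `"water_like"` or `"interface_like"`, or supply `spec`.
#' @param spec optional custom [cv_potential][potential_spec].
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param timestep_ps,diffusion_nm2_ps,record_stride engine settings.
#' @param n_rep,cycle_length_ps,max_cycles,preliminary_length_ps,
#'   open_threshold_nm,close_threshold_nm PaCS settings (thresholds sit
#'   inside the synthetic landscape's reachable range).
#' @param n_opening_trials,n_closing_per_opening campaign size.
#' @param k_microstates,lag_ps,its_lags_ps,n_macro MSM/PCCA settings.
#' @param n_sample_per_microstate structures drawn per microstate for the
#'   interaction statistics.
#' @param noise_sd_A coordinate noise of the synthetic structure ensembles.
#' @param output_dir where stage outputs and the manifest are written;
#'   `NULL` disables file output.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "water_like", spec = NULL, seed = 1L,
                            timestep_ps = 0.01, diffusion_nm2_ps = 0.005,
                            record_stride = 50L,
                            n_rep = 20L, cycle_length_ps = 100,
                            max_cycles = 120L,
                            preliminary_length_ps = 500,
                            open_threshold_nm = 2.2,
                            close_threshold_nm = 0.9,
                            n_opening_trials = 4L,
                            n_closing_per_opening = 2L,
                            k_microstates = 60L, lag_ps = 50,
                            its_lags_ps = c(5, 10, 20, 30, 40, 50),
                            n_macro = 3L,
                            n_sample_per_microstate = 25L,
                            noise_sd_A = 0.3,
                            output_dir = NULL) {
  if (is.null(spec)) spec <- preset_landscape(preset)
  stopifnot(inherits(spec, "cv_potential"))
  cfg <- list(preset = spec$preset, spec = spec, seed = as.integer(seed),
              timestep_ps = timestep_ps,
              diffusion_nm2_ps = diffusion_nm2_ps,
              record_stride = as.integer(record_stride),
              n_rep = as.integer(n_rep), cycle_length_ps = cycle_length_ps,
              max_cycles = as.integer(max_cycles),
              preliminary_length_ps = preliminary_length_ps,
              open_threshold_nm = open_threshold_nm,
              close_threshold_nm = close_threshold_nm,
              n_opening_trials = as.integer(n_opening_trials),
              n_closing_per_opening = as.integer(n_closing_per_opening),
              k_microstates = as.integer(k_microstates), lag_ps = lag_ps,
              its_lags_ps = its_lags_ps, n_macro = as.integer(n_macro),
              n_sample_per_microstate = as.integer(n_sample_per_microstate),
              noise_sd_A = noise_sd_A, output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

## split a campaign frame pool into per-segment discrete trajectories
split_dtrajs <- function(pool, labels) {
  seg <- paste(pool$stage, pool$trial, pool$cycle, pool$replica, sep = "|")
  unname(split(labels, factor(seg, levels = unique(seg))))
}

## pi-weighted mean Dist2 of each macrostate's crisp members
macrostate_bands <- function(macro, centers) {
  vapply(seq_len(macro$n_macro), function(a) {
    rows <- macro$assignment == a
    if (!any(rows)) return(NA_real_)
    weighted.mean(centers[rows, 2], macro$pi_[rows])
  }, numeric(1))
}

## planted interaction sets per conformational class: contacts and hydrogen
## bonds are progressively lost as the lid opens, and the Asp145-Lys290
## salt bridge exists only in the closed class
class_structure_spec <- function(class, n, seed, noise_sd) {
  planted <- switch(
    class,
    closed = list(
      contacts = data.frame(
        resid_i = c(140, 148, 137, 145), resid_j = c(280, 292, 265, 290),
        distance = c(4.5, 4.5, 4.5, 3.4),
        atom_i = c("CG", "CG", "CG", "OD1"),
        atom_j = c("CG", "CG", "CG", "NZ")),
      hbonds = data.frame(donor_resid = c(145, 139),
                          acceptor_resid = c(150, 270),
                          distance = c(2.8, 2.8), angle = c(160, 160))),
    semiopen = list(
      contacts = data.frame(
        resid_i = c(148, 137, 145), resid_j = c(292, 265, 290),
        distance = c(4.5, 4.8, 6.5),
        atom_i = c("CG", "CG", "OD1"), atom_j = c("CG", "CG", "NZ")),
      hbonds = data.frame(donor_resid = 148, acceptor_resid = 292,
                          distance = 2.8, angle = 160)),
    open = list(
      contacts = data.frame(
        resid_i = c(148, 145), resid_j = c(292, 290),
        distance = c(5.8, 8.0),
        atom_i = c("CG", "OD1"), atom_j = c("CG", "NZ")),
      hbonds = NULL))
  make_structure_ensemble(synthetic_structure_spec(
    planted_contacts = planted$contacts, planted_hbonds = planted$hbonds,
    noise_sd = noise_sd, n_structures = n, seed = seed))
}

#' Run the full synthetic lid-dynamics pipeline
#'
#' Executes the stages in order: Langevin engine on the configured
#' landscape, PaCS opening/closing campaign, k-means microstate clustering,
#' MSM estimation with implied-timescale validation, free-energy-landscape
#' projection, PCCA+ coarse-graining, MFPT / committor / TPT flux analysis
#' between the closed-band and open-band macrostates, and macrostate-weighted
#' interaction statistics on synthetic structure ensembles keyed to each
#' microstate's conformational class. When `output_dir` is set, stage tables
#' and a JSON manifest (config, seeds, per-trial costs, file checksums) are
#' written.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `lid_pipeline`; notable elements: `campaign`,
#'   `clustering`, `msm`, `its`, `fel`, `macro`, `bands` (Dist2 band class of
#'   each macrostate), `mfpt_matrix_ps`, `committor` (per-macrostate,
#'   closed -> open), `committor_bands` (the same committor averaged over
#'   each Dist2 band of microstates), `flux`, `interactions`, `costs`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$spec
  engine <- langevin_engine(spec, config$timestep_ps,
                            config$diffusion_nm2_ps,
                            record_stride = config$record_stride)
  closed_start <- spec$centers[which.min(abs(spec$centers[, 2] - 0.75)), ]

  pcfg <- pacs_config(n_rep = config$n_rep,
                      cycle_length_ps = config$cycle_length_ps,
                      max_cycles = config$max_cycles,
                      open_threshold_nm = config$open_threshold_nm,
                      close_threshold_nm = config$close_threshold_nm,
                      preliminary_length_ps = config$preliminary_length_ps,
                      seed = derive_seed(config$seed, 11L))
  campaign <- run_campaign(engine, cfg = pcfg, initial = closed_start,
                           n_opening_trials = config$n_opening_trials,
                           n_closing_per_opening = config$n_closing_per_opening)
  pool <- campaign_frames(campaign)

  dt_ps <- config$timestep_ps * config$record_stride
  clustering <- cluster_microstates(pool[, c("cv1", "cv2")],
                                    k = config$k_microstates,
                                    seed = derive_seed(config$seed, 12L))
  labels <- assign_microstates(clustering, pool[, c("cv1", "cv2")])
  dtrajs <- split_dtrajs(pool, labels)

  lag_frames <- round(config$lag_ps / dt_ps)
  msm <- markov_model(dtrajs, lag_frames, k = config$k_microstates,
                      dt_ps = dt_ps)
  its <- implied_timescales(dtrajs, round(config$its_lags_ps / dt_ps),
                            dt_ps = dt_ps)

  centers <- clustering$centers[msm$active_set, , drop = FALSE]
  pad <- 0.05
  xedges <- seq(min(centers[, 1]) - pad, max(centers[, 1]) + pad,
                length.out = 25)
  yedges <- seq(min(centers[, 2]) - pad, max(centers[, 2]) + pad,
                length.out = 41)
  fel <- project_fel(msm$stationary, centers, xedges, yedges, kT = msm$kT)

  macro <- pcca_memberships(msm, config$n_macro)
  band_mid <- macrostate_bands(macro, centers)
  bands <- classify_conformation(pmax(band_mid, 0))

  members <- lapply(seq_len(macro$n_macro),
                    function(a) which(macro$assignment == a))
  mf <- matrix(0, macro$n_macro, macro$n_macro)
  for (a in seq_len(macro$n_macro)) {
    for (b in seq_len(macro$n_macro)) {
      if (a != b)
        mf[a, b] <- mfpt(msm, members[[a]], members[[b]])
    }
  }

  ## closed -> open committor on the microstate chain; the source/sink sets
  ## are the Dist2 bands of the microstate centers, independent of the
  ## coarse-graining
  micro_class <- classify_conformation(pmax(centers[, 2], 0))
  A <- which(micro_class == "closed")
  B <- which(micro_class == "open")
  committor_macro <- rep(NA_real_, macro$n_macro)
  committor_bands <- c(closed = NA_real_, semiopen = NA_real_,
                       open = NA_real_)
  flux <- NULL
  if (length(A) > 0 && length(B) > 0) {
    qc <- committor(msm, A, B)
    committor_macro <- vapply(members, function(mm) {
      if (length(mm) == 0) return(NA_real_)
      weighted.mean(qc$q_plus[mm], msm$stationary[mm])
    }, numeric(1))
    committor_bands <- vapply(c("closed", "semiopen", "open"), function(b) {
      mm <- which(micro_class == b)
      if (length(mm) == 0) return(NA_real_)
      weighted.mean(qc$q_plus[mm], msm$stationary[mm])
    }, numeric(1))
    flux <- tpt_network(msm, A, B)
  }

  interactions <- pipeline_interactions(msm, macro, centers, bands, config)

  stages <- vapply(campaign, function(t) t$stage, character(1))
  cycles <- vapply(campaign, function(t) t$n_cycles, numeric(1))
  costs <- data.frame(
    trial = vapply(campaign, function(t) t$trial_id, numeric(1)),
    stage = stages, n_cycles = cycles,
    cost_us = vapply(cycles, function(nc)
      simulation_cost(config$cycle_length_ps / 1000, nc, config$n_rep),
      numeric(1)))

  result <- structure(
    list(config = config, campaign = campaign, pool_size = nrow(pool),
         clustering = clustering, msm = msm, its = its, fel = fel,
         macro = macro, bands = bands, band_dist2 = band_mid,
         micro_class = micro_class, mfpt_matrix_ps = mf,
         committor = committor_macro, committor_bands = committor_bands,
         flux = flux,
         interactions = interactions, costs = costs, manifest = NULL),
    class = "lid_pipeline")
  if (!is.null(config$output_dir))
    result$manifest <- write_pipeline_outputs(result, config$output_dir)
  result
}

## interaction statistics on synthetic ensembles keyed to microstate class
pipeline_interactions <- function(msm, macro, centers, bands, config) {
  classes <- classify_conformation(pmax(centers[, 2], 0))
  n_active <- length(msm$active_set)
  per_macro <- list()
  ccrit <- contact_criteria()
  hcrit <- hbond_criteria()
  scrit <- salt_bridge_criteria()
  for (a in seq_len(macro$n_macro)) {
    mm <- which(macro$assignment == a)
    if (length(mm) == 0) next
    samp_classes <- classes[mm]
    contact_counts <- numeric(0)
    hbond_counts <- numeric(0)
    micro_id <- integer(0)
    sb_formed <- numeric(0)
    p_contact <- list()
    for (s in mm) {
      ens <- class_structure_spec(classes[s],
                                  n = config$n_sample_per_microstate,
                                  seed = derive_seed(config$seed, 31L, s),
                                  noise_sd = config$noise_sd_A)
      cc <- lapply(ens, residue_contacts, criteria = ccrit)
      hh <- lapply(ens, hydrogen_bonds, criteria = hcrit)
      contact_counts <- c(contact_counts,
                          vapply(cc, nrow, numeric(1)))
      hbond_counts <- c(hbond_counts, vapply(hh, nrow, numeric(1)))
      micro_id <- c(micro_id, rep(s, length(ens)))
      sb_formed <- c(sb_formed, vapply(ens, function(st)
        salt_bridge_distance(st, scrit) < scrit$cutoff, logical(1)))
      keys <- unlist(lapply(cc, function(d) pair_key(d$resid_i, d$resid_j)))
      allpairs <- unique(keys)
      p_contact[[as.character(s)]] <-
        vapply(allpairs, function(k) mean(vapply(cc, function(d)
          k %in% pair_key(d$resid_i, d$resid_j), logical(1))), numeric(1))
    }
    w <- msm$stationary[mm]
    pairs <- unique(unlist(lapply(p_contact, names)))
    P <- vapply(pairs, function(k) {
      pk <- vapply(as.character(mm), function(s) {
        v <- p_contact[[s]]
        if (k %in% names(v)) v[[k]] else 0
      }, numeric(1))
      macrostate_contact_probability(pk, w)
    }, numeric(1))
    per_macro[[a]] <- list(
      band = bands[a],
      avg_contacts = macrostate_average_counts(contact_counts, micro_id,
                                               setNames(w, mm)),
      avg_hbonds = macrostate_average_counts(hbond_counts, micro_id,
                                             setNames(w, mm)),
      salt_bridge_prob = macrostate_average_counts(sb_formed, micro_id,
                                                   setNames(w, mm)),
      contact_probability = P)
  }

  ## deltaP screening along the closed -> semiopen -> open band sequence
  ord <- order(match(bands, c("closed", "semiopen", "open")))
  transitions <- list()
  for (t in seq_len(length(ord) - 1)) {
    a <- ord[t]; b <- ord[t + 1]
    if (is.null(per_macro[[a]]) || is.null(per_macro[[b]])) next
    transitions[[paste0(bands[a], "->", bands[b])]] <-
      delta_probability(per_macro[[a]]$contact_probability,
                        per_macro[[b]]$contact_probability)
  }
  list(per_macro = per_macro, transitions = transitions,
       criteria = list(contact = ccrit, hbond = hcrit, salt = scrit))
}

#' @export
print.lid_pipeline <- function(x, ...) {
  cat(sprintf("lid-dynamics pipeline (%s preset, seed %d)\n",
              x$config$preset, x$config$seed))
  cat(sprintf("  %d trials, %d pooled frames, %d/%d active microstates\n",
              length(x$campaign), x$pool_size,
              length(x$msm$active_set), x$msm$k))
  imin <- which.min(x$fel$F1d)
  cat(sprintf("  FEL global minimum: Dist2 = %.2f nm (%s)\n",
              x$fel$ymid[imin], classify_conformation(max(x$fel$ymid[imin], 0))))
  for (a in seq_len(x$macro$n_macro)) {
    cat(sprintf("  macrostate %d [%s]: Pi = %.3f, F = %.2f kT, committor %.3f\n",
                a, x$bands[a], x$macro$probability[a],
                x$macro$free_energy[a], x$committor[a]))
  }
  cat(sprintf("  band committors (closed -> open): %s\n",
              paste(sprintf("%s %.3f", names(x$committor_bands),
                            x$committor_bands), collapse = ", ")))
  invisible(x)
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(obj, name, ...) {
    p <- file.path(dir, name)
    utils::write.table(obj, p, sep = "\t", row.names = FALSE,
                       quote = FALSE, ...)
    files <<- c(files, p)
    p
  }
  wr(data.frame(microstate = seq_len(nrow(result$clustering$centers)),
                result$clustering$centers), "cluster_centers.tsv")
  wr(as.data.frame(result$msm$transition_matrix), "transition_matrix.tsv")
  wr(data.frame(state = result$msm$active_set, pi = result$msm$stationary,
                free_energy_kT = result$msm$free_energy), "stationary.tsv")
  wr(as.data.frame(result$its), "implied_timescales.tsv")
  fel1 <- data.frame(dist2_mid = result$fel$ymid, F_kT = result$fel$F1d)
  wr(fel1, "fel_1d.tsv")
  wr(data.frame(macrostate = seq_len(result$macro$n_macro),
                band = result$bands,
                probability = result$macro$probability,
                free_energy_kT = result$macro$free_energy,
                committor = result$committor), "macrostates.tsv")
  wr(as.data.frame(result$mfpt_matrix_ps), "mfpt_ps.tsv")
  if (!is.null(result$flux)) wr(result$flux$edges, "flux_edges.tsv")
  wr(result$costs, "costs.tsv")
  manifest <- list(
    preset = result$config$preset, seed = result$config$seed,
    package_version = as.character(utils::packageVersion("pacsmsm")),
    n_frames = result$pool_size,
    total_cost_us = sum(result$costs$cost_us),
    files = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Survey lid geometry of crystal structures
#'
#' For each (file, chain): Dist1 and Dist2 in Angstrom, the interlid distance
#' d in nm, the conformational class and the Asp145-Lys290 minimum N-O
#' distance with the salt-bridge flag. Parse failures are reported as a
#' warning per entry and the survey continues.
#'
#' @param paths PDB file paths.
#' @param chains list (per path) of chain ids; `NULL` surveys all chains.
#' @param model model number.
#' @param salt_criteria a [salt_bridge_criteria()].
#' @return data.frame with one row per (entry, chain).
#' @export
crystal_survey <- function(paths, chains = NULL, model = 1L,
                           salt_criteria = salt_bridge_criteria()) {
  rows <- list()
  for (i in seq_along(paths)) {
    p <- paths[i]
    entry <- sub("\\.pdb$", "", basename(p), ignore.case = TRUE)
    chs <- if (is.null(chains)) NULL else chains[[i]]
    res <- tryCatch({
      if (is.null(chs)) {
        s0 <- bio3d::read.pdb(p, verbose = FALSE)
        chs <- sort(unique(s0$atom$chain[s0$atom$type == "ATOM"]))
      }
      if (length(chs) == 0) stop("no ATOM chains found")
      lapply(chs, function(ch) {
        s <- read_structure(p, chain = ch, model = model)
        lf <- lid_distances(s)
        sb <- salt_bridge_distance(s, salt_criteria, strict = FALSE)
        data.frame(entry = entry, chain = ch,
                   dist1_A = lf$dist1 * 10, dist2_A = lf$dist2 * 10,
                   d_nm = lf$d,
                   class = classify_conformation(lf$dist2),
                   salt_NO_A = sb,
                   salt_bridge = sb < salt_criteria$cutoff)
      })
    }, error = function(e) {
      warning(sprintf("entry %s skipped: %s", entry, conditionMessage(e)))
      NULL
    })
    rows <- c(rows, res)
  }
  if (length(rows) == 0) stop("no entry could be surveyed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
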