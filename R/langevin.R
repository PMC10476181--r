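## Overdamped Langevin propagation in the 2-D collective-variable plane.

#' Integrator configuration for the synthetic engine
#'
#' @param timestep_ps integration timestep (ps, > 0).
#' @param diffusion_nm2_ps diffusion coefficient (nm^2/ps, >= 0; zero gives
#'   pure deterministic drift).
#' @param kT thermal energy in kT units (fixed at 1 for the synthetic
#'   landscape; exposed for completeness).
#' @param seed integer RNG seed.
#' @param n_steps number of integration steps (>= 1).
#' @param record_stride record every `record_stride`-th frame (default 1 =
#'   every frame). Must divide `n_steps`.
#' @return a list of class `langevin_config`.
#' @export
langevin_config <- function(timestep_ps = 0.01, diffusion_nm2_ps = 0.005,
                            kT = 1, seed = 1L, n_steps = 1000L,
                            record_stride = 1L) {
  stopifnot_number(timestep_ps, "timestep_ps", 0, strict = TRUE)
  stopifnot_number(diffusion_nm2_ps, "diffusion_nm2_ps", 0)
  stopifnot_number(kT, "kT", 0, strict = TRUE)
  if (!is_count(n_steps)) stop("'n_steps' must be a positive integer")
  if (!is_count(record_stride) || n_steps %% record_stride != 0)
    stop("'record_stride' must be a positive integer dividing n_steps")
  structure(list(timestep_ps = timestep_ps,
                 diffusion_nm2_ps = diffusion_nm2_ps, kT = kT,
                 seed = as.integer(seed), n_steps = as.integer(n_steps),
                 record_stride = as.integer(record_stride)),
            class = "langevin_config")
}

#' Simulate an overdamped Langevin trajectory on a landscape
#'
#' Euler-Maruyama integration of `dx = -(D/kT) grad E dt + sqrt(2 D dt) dW`.
#' A per-step displacement larger than three times the narrowest well width
#' aborts with an integration error naming the step. Identical seed and
#' inputs give bitwise-identical output.
#'
#' @param spec a [cv_potential][potential_spec].
#' @param start numeric length-2 starting point (nm).
#' @param cfg a [langevin_config()].
#' @return an object of class `cv_trajectory`: list with `frames` (matrix,
#'   `n_steps/record_stride + 1` rows x 2 columns), `dt_ps` (frame spacing =
#'   timestep * stride), `cfg`, and `provenance` (trial/cycle/replica labels,
#'   NA outside PaCS runs).
#' @export
simulate_overdamped_langevin <- function(spec, start, cfg) {
  stopifnot(inherits(spec, "cv_potential"), inherits(cfg, "langevin_config"))
  if (length(start) != 2 || !all(is.finite(start)))
    stop("'start' must be a finite length-2 vector")
  max_disp <- 3 * min(spec$widths)
  frames <- with_seed(cfg$seed, {
    langevin_path_cpp(spec$centers, spec$depths, spec$widths,
                      spec$confinement_k, spec$confinement_origin,
                      as.numeric(start), cfg$timestep_ps,
                      cfg$diffusion_nm2_ps, cfg$kT, cfg$n_steps,
                      cfg$record_stride, max_disp)
  })
  colnames(frames) <- c("cv1", "cv2")
  structure(list(frames = frames,
                 dt_ps = cfg$timestep_ps * cfg$record_stride,
                 cfg = cfg,
                 provenance = list(trial = NA_integer_, cycle = NA_integer_,
                                   replica = NA_integer_)),
            class = "cv_trajectory")
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat(sprintf("cv_trajectory: %d frames, frame spacing %g ps (%.4g ps total)\n",
              nrow(x$frames), x$dt_ps, (nrow(x$frames) - 1) * x$dt_ps))
  invisible(x)
}

#' Write a trajectory as plain columnar CSV (time_ps, cv1, cv2)
#'
#' @param traj a `cv_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cv_trajectory"))
  d <- data.frame(time_ps = (seq_len(nrow(traj$frames)) - 1) * traj$dt_ps,
                  cv1 = traj$frames[, 1], cv2 = traj$frames[, 2])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Build a PaCS-compatible engine from a landscape
#'
#' Returns a propagator closure `function(state, length_ps, seed)` producing a
#' `cv_trajectory`, the contract expected by [run_pacs_trial()]. Any engine
#' with this signature (e.g. an adapter to a real MD backend) can be swapped
#' in.
#'
#' @param spec a `cv_potential`.
#' @param timestep_ps,diffusion_nm2_ps,kT,record_stride integrator settings,
#'   see [langevin_config()].
#' @return a function `(state, length_ps, seed) -> cv_trajectory`.
#' @export
langevin_engine <- function(spec, timestep_ps = 0.01,
                            diffusion_nm2_ps = 0.005, kT = 1,
                            record_stride = 50L) {
  stopifnot(inherits(spec, "cv_potential"))
  force(spec)
  function(state, length_ps, seed) {
    n_steps <- round(length_ps / timestep_ps)
    cfg <- langevin_config(timestep_ps, diffusion_nm2_ps, kT, seed,
                           n_steps, record_stride)
    simulate_overdamped_langevin(spec, state, cfg)
  }
}
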