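## Synthetic structure ensembles with planted geometry. These are test and
## pipeline fixtures for the interaction operators: residues are laid out far
## apart (no accidental contacts), and specific residue pairs get extra atoms
## placed at exact planted distances / hydrogen-bond geometries, optionally
## perturbed by Gaussian coordinate noise.

#' Specification of a synthetic structure ensemble
#'
#' @param resids residue numbers; default spans the lid ranges 135-151 and
#'   261-293.
#' @param resnames residue names; sensible defaults name Asp145, Ala146,
#'   Ala148, Val286, Lys290 and fill the rest with GLY.
#' @param planted_contacts data.frame with columns `resid_i`, `resid_j`,
#'   `distance` (Angstrom) and optionally `atom_i`, `atom_j` (atom names for
#'   the planted pair; default `"CG"`). Each planted pair is realised as the
#'   closest heavy-atom pair of those two residues.
#' @param planted_hbonds data.frame with columns `donor_resid`,
#'   `acceptor_resid`, `distance` (acceptor-donor heavy distance, Angstrom)
#'   and `angle` (acceptor-hydrogen-donor angle, degrees).
#' @param noise_sd Gaussian coordinate noise per axis (Angstrom, >= 0).
#' @param n_structures ensemble size.
#' @param seed RNG seed.
#' @return a list of class `synthetic_structure_spec`.
#' @export
synthetic_structure_spec <- function(resids = c(135:151, 261:293),
                                     resnames = NULL,
                                     planted_contacts = NULL,
                                     planted_hbonds = NULL,
                                     noise_sd = 0, n_structures = 1L,
                                     seed = 1L) {
  resids <- as.integer(resids)
  stopifnot(!anyDuplicated(resids))
  if (is.null(resnames)) {
    resnames <- rep("GLY", length(resids))
    resnames[resids == 145] <- "ASP"
    resnames[resids %in% c(146, 148)] <- "ALA"
    resnames[resids == 286] <- "VAL"
    resnames[resids == 290] <- "LYS"
  }
  stopifnot(length(resnames) == length(resids))
  check_pairs <- function(df, cols) {
    if (is.null(df)) return(NULL)
    stopifnot(is.data.frame(df), all(cols %in% names(df)))
    if (any(df$distance < 0)) stop("planted distances must be non-negative")
    df
  }
  planted_contacts <- check_pairs(planted_contacts,
                                  c("resid_i", "resid_j", "distance"))
  planted_hbonds <- check_pairs(planted_hbonds,
                                c("donor_resid", "acceptor_resid",
                                  "distance", "angle"))
  if (!is.null(planted_hbonds) &&
      any(planted_hbonds$angle < 0 | planted_hbonds$angle > 180))
    stop("planted angles must lie in [0, 180] degrees")
  stopifnot_number(noise_sd, "noise_sd", 0)
  if (!is_count(n_structures)) stop("'n_structures' must be positive")
  structure(list(resids = resids, resnames = resnames,
                 planted_contacts = planted_contacts,
                 planted_hbonds = planted_hbonds,
                 noise_sd = noise_sd,
                 n_structures = as.integer(n_structures),
                 seed = as.integer(seed)),
            class = "synthetic_structure_spec")
}

## place A so that |A - D| = dist and the angle A-H-D equals `angle`,
## with D at `d0` and H at `d0 + (1, 0, 0)` (1.0 A covalent N-H/O-H bond)
hbond_acceptor_position <- function(d0, dist, angle) {
  th <- angle * pi / 180
  disc <- cos(th)^2 - 1 + dist^2
  if (disc < 0)
    stop(sprintf("unrealisable hydrogen-bond geometry: %.2f A at %.1f deg",
                 dist, angle))
  s <- cos(th) + sqrt(disc)
  if (s <= 0)
    stop(sprintf("unrealisable hydrogen-bond geometry: %.2f A at %.1f deg",
                 dist, angle))
  d0 + c(1 - s * cos(th), s * sin(th), 0)
}

#' Generate a synthetic structure ensemble with planted interactions
#'
#' Backbone-like atoms (N, CA, C, O and an amide hydrogen) of each residue
#' are placed 20 Angstrom apart along a line; each planted contact or
#' hydrogen bond gets its own spatial slot 30 Angstrom away from everything
#' else, so the planted geometry is the unique interaction between the
#' involved residues. Deterministic under the spec seed.
#'
#' @param spec a [synthetic_structure_spec()].
#' @return list of [lid_structure][new_structure] objects of length
#'   `n_structures`.
#' @export
make_structure_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_structure_spec"))
  n_res <- length(spec$resids)
  atom <- character(0); resname <- character(0); resid <- integer(0)
  xyz <- matrix(numeric(0), 0, 3)
  add <- function(a, rn, ri, p) {
    atom <<- c(atom, a); resname <<- c(resname, rn)
    resid <<- c(resid, ri); xyz <<- rbind(xyz, p)
  }
  for (i in seq_len(n_res)) {
    base <- c(20 * (i - 1), 0, 0)
    rn <- spec$resnames[i]; ri <- spec$resids[i]
    add("N", rn, ri, base)
    add("H", rn, ri, base + c(-0.6, 0.8, 0))
    add("CA", rn, ri, base + c(1.46, 0, 0))
    add("C", rn, ri, base + c(2.2, 1.3, 0))
    add("O", rn, ri, base + c(2.0, 2.5, 0))
  }
  slot <- 0L
  slot_origin <- function() {
    slot <<- slot + 1L
    c(0, 30 * slot, 0)
  }
  if (!is.null(spec$planted_contacts)) {
    pc <- spec$planted_contacts
    for (r in seq_len(nrow(pc))) {
      o <- slot_origin()
      ai <- if ("atom_i" %in% names(pc)) pc$atom_i[r] else "CG"
      aj <- if ("atom_j" %in% names(pc)) pc$atom_j[r] else "CG"
      ni <- match(pc$resid_i[r], spec$resids)
      nj <- match(pc$resid_j[r], spec$resids)
      if (is.na(ni) || is.na(nj))
        stop("planted contact references a residue outside the layout")
      add(ai, spec$resnames[ni], pc$resid_i[r], o)
      add(aj, spec$resnames[nj], pc$resid_j[r], o + c(pc$distance[r], 0, 0))
    }
  }
  if (!is.null(spec$planted_hbonds)) {
    ph <- spec$planted_hbonds
    for (r in seq_len(nrow(ph))) {
      o <- slot_origin()
      ni <- match(ph$donor_resid[r], spec$resids)
      nj <- match(ph$acceptor_resid[r], spec$resids)
      if (is.na(ni) || is.na(nj))
        stop("planted hydrogen bond references a residue outside the layout")
      add("ND", spec$resnames[ni], ph$donor_resid[r], o)
      add("HD", spec$resnames[ni], ph$donor_resid[r], o + c(1, 0, 0))
      add("OA", spec$resnames[nj], ph$acceptor_resid[r],
          hbond_acceptor_position(o, ph$distance[r], ph$angle[r]))
    }
  }

  template <- xyz
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_structures), function(m) {
      co <- template
      if (spec$noise_sd > 0)
        co <- co + matrix(rnorm(length(co), sd = spec$noise_sd),
                          nrow(co), 3)
      new_structure(atom = atom, resname = resname, resid = resid,
                    chain = "A", xyz = co, model = m)
    })
  })
}
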