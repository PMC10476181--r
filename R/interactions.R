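## Residue-residue contact / hydrogen-bond / salt-bridge detection and the
## macrostate-weighted interaction statistics.

#' Contact detection criteria
#'
#' @param cutoff heavy-atom distance cutoff in Angstrom (strict `<`;
#'   default 5.0).
#' @param range_a,range_b residue ranges defining the selection (defaults:
#'   the lid ranges 135-151 and 261-293). Contacts are evaluated among all
#'   residues of the union.
#' @param min_separation minimum sequence separation |i - j| (default 1:
#'   only self-pairs excluded).
#' @return list of class `contact_criteria`.
#' @export
contact_criteria <- function(cutoff = 5.0, range_a = 135:151,
                             range_b = 261:293, min_separation = 1L) {
  stopifnot_number(cutoff, "cutoff", 0, strict = TRUE)
  structure(list(cutoff = cutoff, range_a = range_a, range_b = range_b,
                 min_separation = as.integer(min_separation)),
            class = "contact_criteria")
}

#' Hydrogen-bond detection criteria
#'
#' @param dist_cutoff acceptor-donor heavy-atom distance cutoff in Angstrom
#'   (strict `<`; default 3.0).
#' @param angle_min acceptor-hydrogen-donor angle threshold in degrees
#'   (strict `>`; default 135).
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(dist_cutoff = 3.0, angle_min = 135) {
  stopifnot_number(dist_cutoff, "dist_cutoff", 0, strict = TRUE)
  if (angle_min <= 0 || angle_min >= 180)
    stop("'angle_min' must lie in (0, 180)")
  structure(list(dist_cutoff = dist_cutoff, angle_min = angle_min),
            class = "hbond_criteria")
}

#' Salt-bridge detection criteria
#'
#' The published analysis names the Asp145-Lys290 pair but no geometric
#' criterion; the default is a 4.0 Angstrom cutoff between the aspartate
#' carboxylate oxygens and the lysine side-chain nitrogen, and the cutoff is
#' always reported alongside results.
#'
#' @param resid_asp,resid_lys residue numbers of the pair (defaults 145, 290).
#' @param asp_atoms,lys_atoms charged-group atom names.
#' @param cutoff N-O distance cutoff in Angstrom (strict `<`).
#' @return list of class `salt_bridge_criteria`.
#' @export
salt_bridge_criteria <- function(resid_asp = 145L, resid_lys = 290L,
                                 asp_atoms = c("OD1", "OD2"),
                                 lys_atoms = "NZ", cutoff = 4.0) {
  stopifnot_number(cutoff, "cutoff", 0)
  structure(list(resid_asp = as.integer(resid_asp),
                 resid_lys = as.integer(resid_lys),
                 asp_atoms = asp_atoms, lys_atoms = lys_atoms,
                 cutoff = cutoff),
            class = "salt_bridge_criteria")
}

pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "-")
}

#' Residue-residue contacts
#'
#' Two residues are in contact when any pair of their heavy atoms lies
#' strictly below the cutoff. Pairs are reported once with
#' `resid_i < resid_j`.
#'
#' @param structure a `lid_structure`.
#' @param criteria a [contact_criteria()].
#' @return data.frame with columns `resid_i`, `resid_j`, `min_dist`.
#' @export
residue_contacts <- function(structure, criteria = contact_criteria()) {
  stopifnot(inherits(criteria, "contact_criteria"))
  sel_res <- union(criteria$range_a, criteria$range_b)
  s <- select_atoms(structure, sel_res, heavy_only = TRUE)
  if (nrow(s) == 0) stop("empty selection: no heavy atoms in the lid ranges")
  co <- as.matrix(s[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(co))
  near <- which(d < criteria$cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(near) == 0)
    return(data.frame(resid_i = integer(0), resid_j = integer(0),
                      min_dist = numeric(0)))
  ri <- s$resid[near[, 1]]
  rj <- s$resid[near[, 2]]
  keep <- abs(ri - rj) >= criteria$min_separation
  ri <- ri[keep]; rj <- rj[keep]
  dd <- d[near][keep]
  if (length(ri) == 0)
    return(data.frame(resid_i = integer(0), resid_j = integer(0),
                      min_dist = numeric(0)))
  key <- pair_key(ri, rj)
  agg <- tapply(dd, key, min)
  parts <- do.call(rbind, strsplit(names(agg), "-", fixed = TRUE))
  out <- data.frame(resid_i = as.integer(parts[, 1]),
                    resid_j = as.integer(parts[, 2]),
                    min_dist = as.numeric(agg))
  out <- out[order(out$resid_i, out$resid_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hydrogen bonds by geometric criterion
#'
#' A hydrogen bond is a triple of acceptor heavy atom A, donor heavy atom D
#' and donor hydrogen H (H covalently attached to D, D and A limited to N/O,
#' in different residues) with `|A - D| < dist_cutoff` and angle
#' `A-H-D > angle_min`. Structures without hydrogens (e.g. crystal
#' structures) raise an error: this operator is simulation-side only.
#'
#' @param structure a `lid_structure` including hydrogens.
#' @param criteria an [hbond_criteria()].
#' @param covalent_cutoff D-H covalent bond cutoff (Angstrom).
#' @return data.frame with columns `donor_resid`, `acceptor_resid`,
#'   `donor_atom`, `h_atom`, `acceptor_atom`, `dist_AD`, `angle_AHD`.
#' @export
hydrogen_bonds <- function(structure, criteria = hbond_criteria(),
                           covalent_cutoff = 1.25) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  h <- structure[structure$element == "H", , drop = FALSE]
  if (nrow(h) == 0)
    stop("no hydrogens in structure: hydrogen-bond detection needs explicit ",
         "hydrogens (crystal inputs are not supported by this operator)")
  heavy <- structure[structure$element %in% c("N", "O"), , drop = FALSE]
  hco <- as.matrix(h[, c("x", "y", "z")])
  nco <- as.matrix(heavy[, c("x", "y", "z")])

  out <- list()
  for (ih in seq_len(nrow(h))) {
    dh <- sqrt(colSums((t(nco) - hco[ih, ])^2))
    don <- which(dh < covalent_cutoff & heavy$resid == h$resid[ih])
    if (length(don) == 0) next
    don <- don[which.min(dh[don])]
    D <- nco[don, ]
    da <- sqrt(colSums((t(nco) - D)^2))
    acc <- which(da < criteria$dist_cutoff & heavy$resid != heavy$resid[don])
    for (ia in acc) {
      A <- nco[ia, ]
      v1 <- A - hco[ih, ]
      v2 <- D - hco[ih, ]
      ang <- acos(pmin(pmax(sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (ang > criteria$angle_min) {
        out[[length(out) + 1L]] <- data.frame(
          donor_resid = heavy$resid[don], acceptor_resid = heavy$resid[ia],
          donor_atom = heavy$atom[don], h_atom = h$atom[ih],
          acceptor_atom = heavy$atom[ia], dist_AD = da[ia], angle_AHD = ang)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(donor_resid = integer(0), acceptor_resid = integer(0),
                      donor_atom = character(0), h_atom = character(0),
                      acceptor_atom = character(0), dist_AD = numeric(0),
                      angle_AHD = numeric(0)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sample structures per microstate of a macrostate
#'
#' Draws `n_per_microstate` frame indices uniformly without replacement from
#' each member microstate's frames (with replacement, flagged, when a
#' microstate holds fewer frames). Deterministic under the seed.
#'
#' @param microstate_labels integer microstate label per frame of the pool.
#' @param members integer vector of microstate indices forming the
#'   macrostate.
#' @param n_per_microstate sample size per microstate (default 25).
#' @param seed RNG seed.
#' @return data.frame with columns `microstate`, `frame` (pool row index)
#'   and `resampled` (logical); microstates without frames are skipped with
#'   a warning.
#' @export
sample_macrostate_structures <- function(microstate_labels, members,
                                         n_per_microstate = 25L, seed = 1L) {
  stopifnot(is_count(n_per_microstate))
  with_seed(seed, {
    out <- list()
    for (m in members) {
      idx <- which(microstate_labels == m)
      if (length(idx) == 0) {
        warning("microstate ", m, " has no frames; skipped")
        next
      }
      replace <- length(idx) < n_per_microstate
      pick <- if (replace) sample(idx, n_per_microstate, replace = TRUE)
              else sample(idx, n_per_microstate)
      out[[length(out) + 1L]] <-
        data.frame(microstate = m, frame = pick, resampled = replace)
    }
    if (length(out) == 0) stop("no member microstate has frames")
    do.call(rbind, out)
  })
}

#' Macrostate interaction probability (stationary-weighted mean)
#'
#' `P = sum_k pi_k p_k / sum_k pi_k` over the member microstates k: the
#' macrostate probability of a contact (or hydrogen bond) is the
#' stationary-weighted mean of the per-microstate probabilities.
#'
#' @param p_k per-microstate probabilities (each in `[0, 1]`), or a matrix
#'   with one row per microstate (columns = residue pairs).
#' @param pi_k stationary weights of those microstates (not all zero).
#' @return weighted probability (vector if `p_k` is a matrix).
#' @export
macrostate_contact_probability <- function(p_k, pi_k) {
  if (all(pi_k == 0)) stop("all stationary weights are zero")
  if (any(pi_k < 0)) stop("stationary weights must be non-negative")
  if (is.matrix(p_k)) {
    stopifnot(nrow(p_k) == length(pi_k))
    as.numeric(colSums(p_k * pi_k) / sum(pi_k))
  } else {
    stopifnot(length(p_k) == length(pi_k))
    sum(p_k * pi_k) / sum(pi_k)
  }
}

#' Stationary-weighted average interaction counts per macrostate
#'
#' Per-structure counts are first averaged within each microstate, then
#' combined across the macrostate's microstates with stationary weights.
#'
#' @param counts numeric interaction count per sampled structure.
#' @param microstate integer microstate label per sampled structure.
#' @param pi_k named or ordered stationary weights, one per unique
#'   microstate label (aligned with `sort(unique(microstate))` when
#'   unnamed).
#' @return the weighted average count.
#' @export
macrostate_average_counts <- function(counts, microstate, pi_k) {
  stopifnot(length(counts) == length(microstate))
  ms <- sort(unique(microstate))
  mu <- vapply(ms, function(m) mean(counts[microstate == m]), numeric(1))
  w <- if (!is.null(names(pi_k))) pi_k[as.character(ms)] else pi_k
  stopifnot(length(w) == length(mu))
  sum(mu * w) / sum(w)
}

#' Interaction probability changes across a macrostate transition
#'
#' `deltaP = P(C) - P(B)` per residue pair; pairs absent from one macrostate
#' count as probability 0 there. Only strict exceedances of the threshold
#' are reported.
#'
#' @param p_b,p_c named probability vectors (names = residue-pair keys,
#'   e.g. `"145-290"`) for the initial macrostate B and final macrostate C.
#' @param threshold significance threshold on `|deltaP|` (default 0.2,
#'   strict `>`).
#' @return list with data.frames `gains` and `losses` (columns `pair`,
#'   `delta`), and `delta` (full named vector).
#' @export
delta_probability <- function(p_b, p_c, threshold = 0.2) {
  pairs <- union(names(p_b), names(p_c))
  if (is.null(pairs)) stop("'p_b' and 'p_c' must be named by residue pair")
  b <- setNames(rep(0, length(pairs)), pairs)
  b[names(p_b)] <- p_b
  co <- setNames(rep(0, length(pairs)), pairs)
  co[names(p_c)] <- p_c
  if (any(b < 0 | b > 1 | co < 0 | co > 1))
    stop("probabilities must lie in [0, 1]")
  delta <- co - b
  gains <- delta[delta > threshold]
  losses <- delta[delta < -threshold]
  list(gains = data.frame(pair = names(gains), delta = as.numeric(gains),
                          row.names = NULL),
       losses = data.frame(pair = names(losses), delta = as.numeric(losses),
                           row.names = NULL),
       delta = delta)
}

#' Salt-bridge formation probability
#'
#' A frame forms the salt bridge when the minimum distance between the
#' aspartate carboxylate oxygens and the lysine side-chain nitrogen is
#' strictly below the cutoff. Per-microstate frequencies are aggregated with
#' stationary weights, the same scheme as the contact probabilities.
#'
#' @param structures list of `lid_structure` frames.
#' @param microstate integer microstate label per frame (default: all one
#'   microstate).
#' @param pi_k stationary weights per unique microstate label.
#' @param criteria a [salt_bridge_criteria()].
#' @return list with `probability` (weighted), `per_frame` (logical vector)
#'   and `cutoff`.
#' @export
salt_bridge_probability <- function(structures,
                                    microstate = rep(1L, length(structures)),
                                    pi_k = 1,
                                    criteria = salt_bridge_criteria()) {
  stopifnot(inherits(criteria, "salt_bridge_criteria"),
            length(structures) == length(microstate))
  formed <- vapply(structures, function(s) {
    salt_bridge_distance(s, criteria) < criteria$cutoff
  }, logical(1))
  p <- macrostate_average_counts(as.numeric(formed), microstate, pi_k)
  list(probability = p, per_frame = formed, cutoff = criteria$cutoff)
}

#' Minimum carboxylate-O to amine-N distance of the salt-bridge pair
#'
#' @param structure a `lid_structure`.
#' @param criteria a [salt_bridge_criteria()].
#' @return minimum N-O distance in Angstrom (`Inf` when either group is
#'   absent and `strict = FALSE`).
#' @param strict error (rather than `Inf`) when atoms are missing.
#' @export
salt_bridge_distance <- function(structure,
                                 criteria = salt_bridge_criteria(),
                                 strict = TRUE) {
  o <- select_atoms(structure, criteria$resid_asp, atoms = criteria$asp_atoms)
  nz <- select_atoms(structure, criteria$resid_lys, atoms = criteria$lys_atoms)
  if (nrow(o) == 0 || nrow(nz) == 0) {
    if (strict)
      stop("salt-bridge atoms missing (need ",
           paste(criteria$asp_atoms, collapse = "/"), " of residue ",
           criteria$resid_asp, " and ",
           paste(criteria$lys_atoms, collapse = "/"), " of residue ",
           criteria$resid_lys, ")")
    return(Inf)
  }
  min(sqrt(outer(o$x, nz$x, "-")^2 + outer(o$y, nz$y, "-")^2 +
             outer(o$z, nz$z, "-")^2))
}
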