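## PCCA+ coarse-graining: fuzzy memberships of microstates in metastable
## macrostates via the inner-simplex algorithm on the leading right
## eigenvectors of a reversible transition matrix.

#' PCCA+ macrostate memberships
#'
#' Computes the first `n_macro` right eigenvectors of the (reversible)
#' transition matrix through the pi-symmetrised form, locates the vertices of
#' the eigenvector simplex (inner-simplex algorithm) and maps eigenvector
#' rows to membership rows. Small negative memberships arising from the
#' linear transform are clipped and rows renormalised. Deterministic given
#' the transition matrix.
#'
#' @param model a [markov_model()] (reversible mode recommended), or a
#'   row-stochastic matrix (then `pi_` must be supplied).
#' @param n_macro number of macrostates (>= 2, <= number of active states).
#' @param pi_ stationary distribution, only when `model` is a bare matrix.
#' @param kT thermal energy for macrostate free energies.
#' @return an object of class `macrostates` with `memberships` (k x n_macro,
#'   rows sum to 1), `assignment` (crisp argmax per microstate),
#'   `probability` (`Pi_A = sum_{i in A} pi_i` from the fuzzy memberships'
#'   crisp sets), `free_energy` (`-kT log Pi_A`, min-shifted), `n_macro`.
#' @export
pcca_memberships <- function(model, n_macro, pi_ = NULL, kT = 1) {
  if (inherits(model, "markov_model")) {
    Tm <- model$transition_matrix
    pi_ <- model$stationary
    kT <- model$kT
  } else {
    Tm <- as.matrix(model)
    if (is.null(pi_)) pi_ <- stationary_distribution(Tm)
  }
  n <- nrow(Tm)
  if (!is_count(n_macro, min = 2L) || n_macro > n)
    stop("'n_macro' must be an integer in [2, number of active states]")

  ## reversible chains: D^{1/2} T D^{-1/2} is symmetric; its eigenvectors
  ## give pi-orthonormal right eigenvectors of T with real eigenvalues
  sq <- sqrt(pi_)
  S <- (sq %o% (1 / sq)) * Tm
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  if (n_macro < n && abs(lam[n_macro] - lam[n_macro + 1]) < 1e-10)
    stop("eigenvalue degeneracy at the requested cut; ",
         "choose a different n_macro")
  X <- e$vectors[, seq_len(n_macro), drop = FALSE] / sq
  ## fix the trivial eigenvector to the constant 1
  X[, 1] <- 1

  vertices <- integer(n_macro)
  G <- X
  vertices[1] <- which.max(rowSums(G^2))
  G <- sweep(G, 2, G[vertices[1], ])
  if (n_macro > 1) {
    for (j in 2:n_macro) {
      nr <- rowSums(G^2)
      vertices[j] <- which.max(nr)
      d <- G[vertices[j], ]
      nd <- sqrt(sum(d^2))
      if (nd < 1e-12)
        stop("degenerate eigenvector simplex; choose a different n_macro")
      d <- d / nd
      G <- G - (G %*% d) %*% t(d)
    }
  }
  A <- solve(X[vertices, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)

  assignment <- max.col(chi, ties.method = "first")
  prob <- vapply(seq_len(n_macro),
                 function(a) sum(pi_[assignment == a]), numeric(1))
  f <- ifelse(prob > 0, -kT * log(prob), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  structure(list(memberships = chi, assignment = assignment,
                 probability = prob, free_energy = f,
                 n_macro = as.integer(n_macro), pi_ = pi_, kT = kT),
            class = "macrostates")
}

#' @export
print.macrostates <- function(x, ...) {
  cat(sprintf("PCCA+ coarse-graining into %d macrostates\n", x$n_macro))
  tab <- data.frame(macrostate = seq_len(x$n_macro),
                    n_micro = tabulate(x$assignment, x$n_macro),
                    probability = round(x$probability, 4),
                    free_energy_kT = round(x$free_energy, 3),
                    crispness = round(vapply(seq_len(x$n_macro), function(a) {
                      rows <- x$assignment == a
                      if (!any(rows)) return(NA_real_)
                      mean(x$memberships[rows, a])
                    }, numeric(1)), 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Macrostate free energies from a stationary distribution
#'
#' `F_A = -kT log(sum_{i in A} pi_i)`, min-shifted to 0. A macrostate
#' containing the global-minimum microstate need not have the lowest free
#' energy, because macrostates can also absorb broad high-energy regions.
#' Empty macrostates are reported as `NA` (masked), never zero.
#'
#' @param pi_ stationary distribution over active microstates.
#' @param assignment integer macrostate label per microstate.
#' @param kT thermal energy.
#' @param n_macro number of macrostates (inferred when `NULL`).
#' @return numeric vector of per-macrostate free energies.
#' @export
macro_free_energy <- function(pi_, assignment, kT = 1, n_macro = NULL) {
  stopifnot(length(pi_) == length(assignment))
  if (is.null(n_macro)) n_macro <- max(assignment)
  p <- vapply(seq_len(n_macro),
              function(a) sum(pi_[assignment == a]), numeric(1))
  f <- ifelse(p > 0, -kT * log(p), NA_real_)
  f - min(f, na.rm = TRUE)
}
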