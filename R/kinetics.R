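## Coarse kinetics on the microstate chain: mean first-passage times,
## committor probabilities and the transition-path-theory flux network with
## pathway decomposition.

as_Tpi <- function(model, pi_) {
  if (inherits(model, "markov_model")) {
    list(T = model$transition_matrix, pi = model$stationary,
         lag = model$lag_ps)
  } else {
    Tm <- as.matrix(model)
    if (is.null(pi_)) pi_ <- stationary_distribution(Tm)
    list(T = Tm, pi = pi_, lag = 1)
  }
}

## states from which `target` is reachable (reverse BFS on the T > 0 graph)
reachable_from <- function(Tm, target) {
  n <- nrow(Tm)
  reach <- logical(n)
  reach[target] <- TRUE
  repeat {
    new <- which(!reach & (Tm[, reach, drop = FALSE] > 0) %*%
                   rep(1, sum(reach)) > 0)
    if (length(new) == 0) break
    reach[new] <- TRUE
  }
  which(reach)
}

#' Mean first-passage time between state sets
#'
#' Solves the absorbing linear system `h_i = tau + sum_j T_ij h_j` for states
#' outside the target (with `h = 0` on the target) and averages the hitting
#' time over the source set with stationary weights renormalised on the
#' source.
#'
#' @param model a [markov_model()] or a row-stochastic matrix.
#' @param source,target integer state sets (active-set indices).
#' @param lag_time physical duration of one step; defaults to the model's
#'   lag (ps) or 1 for a bare matrix.
#' @param pi_ stationary weights for bare matrices.
#' @return mean first-passage time in units of `lag_time`.
#' @export
mfpt <- function(model, source, target, lag_time = NULL, pi_ = NULL) {
  tp <- as_Tpi(model, pi_)
  if (is.null(lag_time)) lag_time <- tp$lag
  n <- nrow(tp$T)
  source <- unique(as.integer(source))
  target <- unique(as.integer(target))
  stopifnot(all(source >= 1 & source <= n), all(target >= 1 & target <= n))
  if (all(source %in% target)) return(0)
  reach <- reachable_from(tp$T, target)
  bad <- setdiff(source, reach)
  if (length(bad) > 0)
    stop("target unreachable from source state(s): ",
         paste(bad, collapse = ", "))

  nt <- setdiff(seq_len(n), target)
  Tnt <- tp$T[nt, nt, drop = FALSE]
  h <- numeric(n)
  h[nt] <- solve(diag(length(nt)) - Tnt, rep(lag_time, length(nt)))
  w <- tp$pi[source]
  sum(w * h[source]) / sum(w)
}

#' Forward and backward committor probabilities
#'
#' The forward committor `q+` is the probability of reaching the sink set B
#' before the source set A; it solves the discrete Laplace problem with
#' boundary values 0 on A and 1 on B. The backward committor `q-` is the
#' forward committor of the time-reversed chain
#' `Ttilde_ij = pi_j T_ji / pi_i`; for reversible chains `q- = 1 - q+`.
#'
#' @param model a [markov_model()] or row-stochastic matrix.
#' @param A,B disjoint non-empty state sets (active-set indices).
#' @param pi_ stationary distribution for bare matrices.
#' @return list with `q_plus`, `q_minus` (numeric vectors over all states).
#' @export
committor <- function(model, A, B, pi_ = NULL) {
  tp <- as_Tpi(model, pi_)
  Tm <- tp$T
  n <- nrow(Tm)
  A <- unique(as.integer(A))
  B <- unique(as.integer(B))
  if (length(A) == 0 || length(B) == 0) stop("A and B must be non-empty")
  if (length(intersect(A, B)) > 0) stop("A and B must be disjoint")
  solve_committor <- function(Tmat, src, snk) {
    q <- numeric(n)
    q[snk] <- 1
    M <- setdiff(seq_len(n), c(src, snk))
    if (length(M) > 0) {
      lhs <- diag(length(M)) - Tmat[M, M, drop = FALSE]
      rhs <- Tmat[M, snk, drop = FALSE] %*% rep(1, length(snk))
      q[M] <- solve(lhs, rhs)
    }
    q
  }
  q_plus <- solve_committor(Tm, A, B)
  # time reversal: Trev[i, j] = pi_j T[j, i] / pi_i
  Trev <- t(Tm) * ((1 / tp$pi) %o% tp$pi)
  q_minus <- solve_committor(Trev, B, A)
  list(q_plus = q_plus, q_minus = q_minus)
}

#' Transition-path-theory flux network and pathway decomposition
#'
#' Gross reactive flux `f_ij = pi_i q-_i T_ij q+_j` (i != j), net flux
#' `f+_ij = max(0, f_ij - f_ji)`, total A -> B flux as the net flux leaving
#' A, per-edge flux fractions, and a pathway decomposition by iterative
#' bottleneck removal on the net-flux graph (each extracted pathway carries
#' its bottleneck flux as fractional contribution).
#'
#' @inheritParams committor
#' @param max_paths cap on the number of decomposed pathways.
#' @return an object of class `flux_network`: `net_flux` matrix,
#'   `gross_flux`, `total_flux`, `edges` (data.frame i, j, flux, fraction),
#'   `pathways` (list of `list(states, flux, fraction)`), `q_plus`,
#'   `q_minus`, `A`, `B`.
#' @export
tpt_network <- function(model, A, B, pi_ = NULL, max_paths = 50L) {
  tp <- as_Tpi(model, pi_)
  Tm <- tp$T
  n <- nrow(Tm)
  A <- unique(as.integer(A))
  B <- unique(as.integer(B))
  qc <- committor(model, A, B, pi_)
  f <- (tp$pi * qc$q_minus) * Tm * rep(qc$q_plus, each = n)
  diag(f) <- 0
  fnet <- pmax(f - t(f), 0)
  total <- sum(fnet[A, setdiff(seq_len(n), A), drop = FALSE])
  if (total <= 0) stop("zero total flux: A and B are dynamically disconnected")

  idx <- which(fnet > 0, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2], flux = fnet[idx])
  edges$fraction <- edges$flux / total
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL

  pathways <- decompose_pathways(fnet, A, B, total, max_paths)
  structure(list(net_flux = fnet, gross_flux = f, total_flux = total,
                 edges = edges, pathways = pathways,
                 q_plus = qc$q_plus, q_minus = qc$q_minus, A = A, B = B),
            class = "flux_network")
}

## widest (maximum-bottleneck) path from A to B; deterministic tie-breaks by
## lowest state index
widest_path <- function(W, A, B) {
  n <- nrow(W)
  width <- rep(-Inf, n)
  prev <- rep(NA_integer_, n)
  width[A] <- Inf
  done <- logical(n)
  repeat {
    cand <- which(!done & width > -Inf)
    if (length(cand) == 0) return(NULL)
    u <- cand[which.max(width[cand])]
    done[u] <- TRUE
    if (u %in% B) {
      path <- u
      while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
      return(list(states = path, width = width[u]))
    }
    for (v in which(W[u, ] > 0)) {
      w <- min(width[u], W[u, v])
      if (w > width[v]) {
        width[v] <- w
        prev[v] <- u
      }
    }
  }
}

decompose_pathways <- function(fnet, A, B, total, max_paths) {
  W <- fnet
  out <- list()
  remaining <- total
  for (p in seq_len(max_paths)) {
    if (remaining <= total * 1e-10) break
    wp <- widest_path(W, A, B)
    if (is.null(wp)) break
    s <- wp$states
    for (e in seq_len(length(s) - 1))
      W[s[e], s[e + 1]] <- W[s[e], s[e + 1]] - wp$width
    remaining <- remaining - wp$width
    out[[p]] <- list(states = s, flux = wp$width,
                     fraction = wp$width / total)
  }
  out
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("TPT flux network: total A->B flux %.4g, %d net-flux edges\n",
              x$total_flux, nrow(x$edges)))
  for (p in head(x$pathways, 5)) {
    cat(sprintf("  pathway %s: fraction %.3f\n",
                paste(p$states, collapse = " -> "), p$fraction))
  }
  invisible(x)
}
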