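## Markov state model core: microstate clustering, transition counting,
## transition-matrix estimation (reversible maximum likelihood or simple row
## normalisation), stationary distribution, free energies, implied
## timescales and free-energy-landscape projection.

#' Cluster feature vectors into microstates (k-means with k-means++ seeding)
#'
#' @param features n x 2 matrix of (Dist1, Dist2) feature vectors, nm.
#' @param k number of microstates.
#' @param seed RNG seed (clustering is deterministic given the seed).
#' @param iter_max Lloyd iteration cap.
#' @return an object of class `microstates` with `centers` (k x 2) and `k`.
#' @export
cluster_microstates <- function(features, k, seed = 1L, iter_max = 100L) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == 2, all(is.finite(features)))
  ndistinct <- nrow(unique(features))
  if (ndistinct < k)
    stop(sprintf("need at least k = %d distinct feature vectors, have %d",
                 k, ndistinct))
  centers <- with_seed(seed, {
    init <- kmeanspp_init(features, k)
    if (k == 1L) {
      matrix(colMeans(features), 1, 2)
    } else {
      fit <- suppressWarnings(
        stats::kmeans(features, centers = init, iter.max = iter_max,
                      algorithm = "Lloyd"))
      fit$centers
    }
  })
  dimnames(centers) <- list(NULL, c("cv1", "cv2"))
  structure(list(centers = centers, k = as.integer(k)),
            class = "microstates")
}

## k-means++ seeding: first center uniform, subsequent centers sampled with
## probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (i in 2:k) {
    p <- d2 / sum(d2)
    idx <- sample.int(n, 1L, prob = p)
    centers[i, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[i, ])^2))
  }
  centers
}

#' @export
print.microstates <- function(x, ...) {
  cat(sprintf("microstate clustering: k = %d centers in 2-D feature space\n",
              x$k))
  invisible(x)
}

#' Assign feature vectors to the nearest microstate center
#'
#' @param model a `microstates` clustering.
#' @param features n x 2 matrix.
#' @return integer vector of microstate indices in `1..k`.
#' @export
assign_microstates <- function(model, features) {
  stopifnot(inherits(model, "microstates"))
  features <- as.matrix(features)
  cx <- model$centers
  ## nearest-center via |f|^2 - 2 f.c + |c|^2; n x k cross term
  cross <- features %*% t(cx)
  d2 <- outer(rep(1, nrow(features)), rowSums(cx^2)) - 2 * cross
  max.col(-d2, ties.method = "first")
}

#' Count microstate transitions at a lag
#'
#' Sliding-window counts at stride one within each discrete trajectory;
#' counting never crosses trajectory boundaries (PaCS segments are
#' independent pieces). Segments shorter than the lag contribute nothing.
#'
#' @param dtrajs list of integer vectors (microstate indices in `1..k`).
#' @param lag_frames lag in frames (>= 1).
#' @param k number of microstates; inferred from the data when `NULL`.
#' @return k x k count matrix `C`, `C[i, j]` = observed i -> j transitions.
#' @export
count_transitions <- function(dtrajs, lag_frames, k = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (!is_count(lag_frames)) stop("'lag_frames' must be a positive integer")
  if (is.null(k)) k <- max(vapply(dtrajs, max, numeric(1)))
  k <- as.integer(k)
  counts <- numeric(k * k)
  used <- FALSE
  for (dt in dtrajs) {
    n <- length(dt)
    if (n <= lag_frames) next
    used <- TRUE
    from <- dt[seq_len(n - lag_frames)]
    to <- dt[(lag_frames + 1):n]
    idx <- (from - 1L) * k + to  # column-major index of t(C)
    tab <- tabulate(idx, nbins = k * k)
    counts <- counts + tab
  }
  if (!used) warning("all segments shorter than the lag; count matrix empty")
  matrix(counts, k, k, byrow = TRUE)
}

#' Largest strongly connected set of a count matrix
#'
#' States i, j are connected when `C[i, j] > 0`. Among equally large strongly
#' connected components the one containing the lowest state index wins.
#'
#' @param C count matrix.
#' @return increasing integer vector of active state indices.
#' @export
largest_connected_set <- function(C) {
  C <- as.matrix(C)
  stopifnot(nrow(C) == ncol(C), all(C >= 0))
  if (sum(C) == 0) stop("empty count matrix")
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    firsts <- vapply(best, function(b) min(which(comp$membership == b)),
                     numeric(1))
    best <- best[which.min(firsts)]
  }
  sort(which(comp$membership == best))
}

#' Estimate a transition matrix from counts
#'
#' Nonreversible mode is plain row normalisation `T_ij = C_ij / sum_j C_ij`.
#' Reversible mode maximises the likelihood under detailed balance with the
#' standard fixed-point iteration on the unnormalised flux matrix
#' `x_ij = (C_ij + C_ji) / (c_i / x_i + c_j / x_j)`, iterated until the
#' largest elementwise change drops below `tol`.
#'
#' @param C count matrix restricted to a connected active set.
#' @param mode `"reversible"` (default) or `"nonreversible"`.
#' @param tol fixed-point convergence tolerance.
#' @param max_iter sweep cap.
#' @return row-stochastic transition matrix.
#' @export
estimate_transition_matrix <- function(C, mode = c("reversible",
                                                   "nonreversible"),
                                       tol = 1e-10, max_iter = 1e6) {
  mode <- match.arg(mode)
  C <- as.matrix(C)
  rs <- rowSums(C)
  if (any(rs == 0))
    stop("zero row in count matrix; restrict to largest_connected_set first")
  if (mode == "nonreversible") return(C / rs)

  Csym <- C + t(C)
  x <- Csym / sum(Csym)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(rs / xi, rs / xi, "+")
    xnew <- Csym / denom
    xnew <- xnew / sum(xnew)
    delta <- max(abs(xnew - x))
    x <- xnew
    if (delta < tol) break
  }
  Tm <- x / rowSums(x)
  Tm
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector at eigenvalue 1, normalised to a probability vector.
#'
#' @param T_ row-stochastic transition matrix, irreducible.
#' @return numeric vector `pi` with `pi >= 0`, `sum(pi) = 1`.
#' @export
stationary_distribution <- function(T_) {
  T_ <- as.matrix(T_)
  stopifnot(nrow(T_) == ncol(T_))
  if (max(abs(rowSums(T_) - 1)) > 1e-8)
    stop("transition matrix rows must sum to 1")
  e <- eigen(t(T_))
  i <- which.min(abs(e$values - 1))
  if (abs(e$values[i] - 1) > 1e-6)
    stop("no unit eigenvalue; is the chain irreducible? ",
         "(use largest_connected_set)")
  v <- Re(e$vectors[, i])
  v <- abs(v)
  pi_ <- v / sum(v)
  if (max(abs(pi_ %*% T_ - pi_)) > 1e-8)
    stop("stationary distribution check failed; ",
         "the chain may not be irreducible (use largest_connected_set)")
  as.numeric(pi_)
}

#' Free energy from a stationary distribution
#'
#' `F_i = -kT log(pi_i)`, shifted so the minimum is 0.
#'
#' @param pi_ probability vector over the active set (all entries > 0).
#' @param kT thermal energy.
#' @return free energies in the units of `kT`.
#' @export
free_energy <- function(pi_, kT = 1) {
  if (any(pi_ <= 0)) stop("pi must be strictly positive on the active set")
  f <- -kT * log(pi_)
  f - min(f)
}

#' Fit a Markov state model to discrete trajectories
#'
#' The central estimator: counts transitions at the chosen lag, restricts to
#' the largest strongly connected set, estimates the transition matrix
#' (reversible maximum likelihood by default) and computes the stationary
#' distribution and per-microstate free energies.
#'
#' @param dtrajs list of integer microstate sequences (values in `1..k`).
#' @param lag_frames lag time in frames.
#' @param k number of microstates (inferred when `NULL`).
#' @param dt_ps physical frame spacing in ps (records the lag in time units).
#' @param mode estimator mode, see [estimate_transition_matrix()].
#' @param kT thermal energy for free energies.
#' @return an object of class `markov_model` with elements `C` (counts on the
#'   active set), `transition_matrix`, `stationary` (pi), `active_set`,
#'   `free_energy`, `lag_frames`, `lag_ps`, `k`, `mode`, `kT`.
#' @seealso [implied_timescales()], [pcca_memberships()], [mfpt()],
#'   [committor()], [tpt_network()]
#' @export
markov_model <- function(dtrajs, lag_frames, k = NULL, dt_ps = 1,
                         mode = c("reversible", "nonreversible"), kT = 1) {
  mode <- match.arg(mode)
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  Cfull <- count_transitions(dtrajs, lag_frames, k)
  active <- largest_connected_set(Cfull)
  C <- Cfull[active, active, drop = FALSE]
  Tm <- estimate_transition_matrix(C, mode)
  pi_ <- stationary_distribution(Tm)
  structure(list(C = C, transition_matrix = Tm, stationary = pi_,
                 active_set = active, free_energy = free_energy(pi_, kT),
                 lag_frames = as.integer(lag_frames),
                 lag_ps = lag_frames * dt_ps, k = nrow(Cfull),
                 dt_ps = dt_ps, mode = mode, kT = kT),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("Markov state model (%s): %d/%d active microstates, lag %g ps\n",
              x$mode, length(x$active_set), x$k, x$lag_ps))
  cat(sprintf("  total counts %g, pi range [%.2e, %.2e]\n",
              sum(x$C), min(x$stationary), max(x$stationary)))
  invisible(x)
}

#' @export
summary.markov_model <- function(object, n_timescales = 5L, ...) {
  ev <- sort(Re(eigen(object$transition_matrix,
                      only.values = TRUE)$values), decreasing = TRUE)
  nts <- min(n_timescales, length(ev) - 1)
  its <- -object$lag_ps / log(pmin(pmax(ev[1 + seq_len(nts)], 0), 1))
  out <- list(n_active = length(object$active_set), k = object$k,
              lag_ps = object$lag_ps, mode = object$mode,
              eigenvalues = ev[seq_len(nts + 1)],
              implied_timescales_ps = its,
              stationary_entropy = -sum(object$stationary *
                                          log(object$stationary)))
  class(out) <- "summary.markov_model"
  out
}

#' @export
print.summary.markov_model <- function(x, ...) {
  cat(sprintf("MSM summary: %d/%d active states, lag %g ps (%s estimator)\n",
              x$n_active, x$k, x$lag_ps, x$mode))
  cat("  leading eigenvalues:",
      paste(sprintf("%.4f", x$eigenvalues), collapse = ", "), "\n")
  cat("  implied timescales (ps):",
      paste(sprintf("%.3g", x$implied_timescales_ps), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a discrete trajectory from a fitted model
#'
#' Draws a realisation of the Markov chain defined by the model's transition
#' matrix, in active-set indices. Useful as a sampling oracle for
#' first-passage statistics.
#'
#' @param object a `markov_model`.
#' @param nsim trajectory length in steps (frames at the model's lag).
#' @param seed RNG seed.
#' @param start initial active-set state index; stationary draw when `NULL`.
#' @param ... unused.
#' @return integer vector of length `nsim + 1` of active-set indices.
#' @export
simulate.markov_model <- function(object, nsim = 1000L, seed = NULL,
                                  start = NULL, ...) {
  Tm <- object$transition_matrix
  n <- nrow(Tm)
  runner <- function() {
    s <- if (is.null(start)) sample.int(n, 1L, prob = object$stationary)
         else as.integer(start)
    out <- integer(nsim + 1L)
    out[1L] <- s
    ## row-wise cumulative probabilities, one uniform draw per step
    cum <- t(apply(Tm, 1, cumsum))
    u <- runif(nsim)
    for (t in seq_len(nsim)) {
      s <- findInterval(u[t], cum[s, ], left.open = TRUE) + 1L
      out[t + 1L] <- s
    }
    out
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

#' Implied timescales over a series of lag times
#'
#' For each lag, a model is estimated and the slowest timescales
#' `t_i = -tau / log(lambda_i)` of the leading non-unit eigenvalues are
#' reported. Convergence is flagged when the slowest timescale varies by less
#' than `rel_tol` over the last two lags. Eigenvalues with an imaginary part
#' beyond `1e-8` are reported by magnitude with a warning; eigenvalues at or
#' above 1 give an `Inf` sentinel.
#'
#' @param dtrajs list of integer microstate sequences.
#' @param lags_frames increasing integer vector of lags, in frames.
#' @param n_timescales how many timescales per lag.
#' @param dt_ps physical frame spacing (ps).
#' @param mode estimator mode.
#' @param rel_tol relative tolerance of the convergence flag.
#' @return a data.frame of class `its_table` with columns `lag_ps`,
#'   `timescale_index`, `its_ps`; attribute `converged`.
#' @export
implied_timescales <- function(dtrajs, lags_frames, n_timescales = 3L,
                               dt_ps = 1, mode = "reversible",
                               rel_tol = 0.25) {
  stopifnot(all(lags_frames >= 1), !is.unsorted(lags_frames))
  rows <- list()
  slowest <- numeric(0)
  for (lag in lags_frames) {
    m <- markov_model(dtrajs, lag, dt_ps = dt_ps, mode = mode)
    ev <- eigen(m$transition_matrix, only.values = TRUE)$values
    if (any(abs(Im(ev)) > 1e-8))
      warning("complex eigenvalues at lag ", lag,
              " frames; using magnitudes")
    lam <- sort(abs(ev), decreasing = TRUE)
    lam <- lam[-1]  # drop the unit eigenvalue
    nts <- min(n_timescales, length(lam))
    its <- ifelse(lam[seq_len(nts)] >= 1, Inf,
                  -lag * dt_ps / log(lam[seq_len(nts)]))
    rows[[length(rows) + 1L]] <-
      data.frame(lag_ps = lag * dt_ps, timescale_index = seq_len(nts),
                 its_ps = its)
    slowest <- c(slowest, its[1])
  }
  out <- do.call(rbind, rows)
  n <- length(slowest)
  converged <- n >= 2 && is.finite(slowest[n]) && is.finite(slowest[n - 1]) &&
    abs(slowest[n] - slowest[n - 1]) / slowest[n] < rel_tol
  attr(out, "converged") <- converged
  class(out) <- c("its_table", "data.frame")
  out
}

#' Project a stationary distribution onto a free-energy landscape
#'
#' Each microstate's probability mass is assigned to the grid cell containing
#' its cluster center; bin free energies are `-kT log(p_bin)` shifted so the
#' minimum visited bin is 0. Unvisited bins are `NA` (masked), never zero.
#' The 1-D profile along the second (Dist2) axis is the marginal of the 2-D
#' grid.
#'
#' @param pi_ stationary distribution over active microstates.
#' @param centers matrix of cluster centers for those microstates (rows
#'   aligned with `pi_`).
#' @param xedges,yedges bin edges covering all centers (nm).
#' @param kT thermal energy.
#' @return an object of class `fel` with `F2d` (matrix, NA = unvisited),
#'   `p2d`, `F1d`, `p1d`, `xedges`, `yedges`, `xmid`, `ymid`.
#' @export
project_fel <- function(pi_, centers, xedges, yedges, kT = 1) {
  centers <- as.matrix(centers)
  stopifnot(length(pi_) == nrow(centers))
  ix <- findInterval(centers[, 1], xedges, rightmost.closed = TRUE)
  iy <- findInterval(centers[, 2], yedges, rightmost.closed = TRUE)
  if (any(ix < 1 | ix > length(xedges) - 1 | iy < 1 | iy > length(yedges) - 1))
    stop("some cluster centers fall outside the bin grid")
  p2d <- matrix(0, length(xedges) - 1, length(yedges) - 1)
  for (s in seq_along(pi_)) p2d[ix[s], iy[s]] <- p2d[ix[s], iy[s]] + pi_[s]
  F2d <- ifelse(p2d > 0, -kT * log(p2d), NA_real_)
  F2d <- F2d - min(F2d, na.rm = TRUE)
  p1d <- colSums(p2d)
  F1d <- ifelse(p1d > 0, -kT * log(p1d), NA_real_)
  F1d <- F1d - min(F1d, na.rm = TRUE)
  structure(list(F2d = F2d, p2d = p2d, F1d = F1d, p1d = p1d,
                 xedges = xedges, yedges = yedges,
                 xmid = (xedges[-1] + xedges[-length(xedges)]) / 2,
                 ymid = (yedges[-1] + yedges[-length(yedges)]) / 2,
                 kT = kT),
            class = "fel")
}

#' @export
print.fel <- function(x, ...) {
  imin <- which.min(x$F1d)
  cat(sprintf("free-energy landscape: %d x %d bins; 1-D minimum at Dist2 = %.2f nm (%s)\n",
              nrow(x$F2d), ncol(x$F2d), x$ymid[imin],
              classify_conformation(x$ymid[imin])))
  invisible(x)
}

#' @export
plot.fel <- function(x, ...) {
  graphics::image(x$xmid, x$ymid, x$F2d,
                  col = grDevices::hcl.colors(32, "viridis", rev = TRUE),
                  xlab = "Dist1 (nm)", ylab = "Dist2 (nm)",
                  main = "free-energy landscape (kT)", ...)
  invisible(x)
}
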