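## Synthetic collective-variable landscape: a 2-D potential over
## (Dist1-like, Dist2-like) coordinates in nm, built from negative isotropic
## Gaussian wells plus a weak harmonic confinement. Energies are in kT.

#' Construct a two-dimensional multi-well potential specification
#'
#' The landscape lives in a collective-variable plane whose second axis plays
#' the role of the lid-opening distance Dist2 (nm): wells centred below
#' 1.0 nm on that axis sit in the closed band, between 1.0 and 2.0 nm in the
#' semiopen band, and above 2.0 nm in the open band.
#'
#' @param wells a list of wells, each a list with elements `center` (numeric
#'   length-2, nm), `depth` (kT, > 0) and `width` (nm, > 0; isotropic Gaussian
#'   standard deviation).
#' @param confinement_k harmonic confinement strength in kT/nm^2 (>= 0);
#'   either a scalar (isotropic) or a length-2 vector of per-axis strengths
#'   (the Dist1-like axis is typically confined more stiffly than the
#'   lid-opening axis).
#' @param confinement_origin anchor point of the confinement (numeric 2).
#' @param preset tag recording provenance: `"water_like"`, `"interface_like"`
#'   or `"custom"`.
#' @return an object of class `cv_potential`.
#' @seealso [preset_landscape()], [potential_energy()], [reference_boltzmann()]
#' @export
potential_spec <- function(wells, confinement_k = 0,
                           confinement_origin = c(0, 0),
                           preset = "custom") {
  preset <- match.arg(preset, c("custom", "water_like", "interface_like"))
  if (!is.list(wells) || length(wells) == 0)
    stop("'wells' must be a non-empty list")
  centers <- matrix(NA_real_, length(wells), 2)
  depths <- widths <- numeric(length(wells))
  for (i in seq_along(wells)) {
    w <- wells[[i]]
    if (!all(c("center", "depth", "width") %in% names(w)))
      stop("each well needs 'center', 'depth' and 'width'")
    if (length(w$center) != 2 || !all(is.finite(w$center)))
      stop("well centers must be finite length-2 vectors")
    stopifnot_number(w$depth, "depth", 0, strict = TRUE)
    stopifnot_number(w$width, "width", 0, strict = TRUE)
    centers[i, ] <- w$center
    depths[i] <- w$depth
    widths[i] <- w$width
  }
  if (anyDuplicated(centers) > 0)
    stop("well centers must be distinct")
  if (!length(confinement_k) %in% c(1L, 2L) || any(!is.finite(confinement_k)) ||
      any(confinement_k < 0))
    stop("'confinement_k' must be one or two finite non-negative numbers")
  confinement_k <- rep(as.numeric(confinement_k), length.out = 2)
  stopifnot(length(confinement_origin) == 2, all(is.finite(confinement_origin)))

  deepest <- centers[which.max(depths), 2]
  if (preset == "water_like" && deepest >= 1.0)
    stop("water_like requires the deepest well's Dist2 center < 1.0 nm")
  if (preset == "interface_like" && (deepest <= 1.0 || deepest >= 2.0))
    stop("interface_like requires the deepest well's Dist2 center in (1, 2) nm")

  structure(
    list(centers = centers, depths = depths, widths = widths,
         confinement_k = confinement_k,
         confinement_origin = as.numeric(confinement_origin),
         preset = preset),
    class = "cv_potential"
  )
}

#' @export
print.cv_potential <- function(x, ...) {
  cat(sprintf("2-D multi-well potential (%s): %d wells, confinement k = (%g, %g) kT/nm^2\n",
              x$preset, length(x$depths), x$confinement_k[1],
              x$confinement_k[2]))
  tab <- data.frame(cv1 = x$centers[, 1], cv2 = x$centers[, 2],
                    depth_kT = x$depths, width_nm = x$widths)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Canned landscapes emulating the aqueous and interfacial systems
#'
#' Both presets place three wells in the closed / semiopen / open Dist2 bands.
#' `water_like` makes the closed well the global minimum, with a lower barrier
#' towards the semiopen well than from semiopen to open; `interface_like`
#' makes the semiopen well the global minimum and its open well shallower and
#' narrower than in `water_like`, while the path from semiopen to open is
#' easier than back to closed. The magnitudes are package defaults (depths in
#' the 4-8 kT range); only the orderings are meaningful.
#'
#' @param tag `"water_like"` or `"interface_like"`.
#' @return a `cv_potential` object with three wells.
#' @export
preset_landscape <- function(tag = c("water_like", "interface_like")) {
  tag <- match.arg(tag)
  if (tag == "water_like") {
    potential_spec(
      wells = list(
        list(center = c(2.60, 0.70), depth = 8.0, width = 0.27), # closed
        list(center = c(2.45, 1.50), depth = 6.2, width = 0.27), # semiopen
        list(center = c(2.25, 2.50), depth = 5.5, width = 0.27)  # open
      ),
      confinement_k = c(6, 1.2), confinement_origin = c(2.50, 1.50),
      preset = "water_like"
    )
  } else {
    potential_spec(
      wells = list(
        list(center = c(2.55, 0.70), depth = 4.5, width = 0.23), # closed
        list(center = c(2.40, 1.55), depth = 8.0, width = 0.24), # semiopen
        list(center = c(2.30, 2.25), depth = 4.0, width = 0.23)  # open
      ),
      confinement_k = c(8, 2.0), confinement_origin = c(2.40, 1.55),
      preset = "interface_like"
    )
  }
}

#' Potential energy of a landscape at one or many points
#'
#' @param spec a `cv_potential`.
#' @param point numeric length-2 vector, or an n x 2 matrix of points (nm).
#' @return energy in kT (vector of length n).
#' @export
potential_energy <- function(spec, point) {
  stopifnot(inherits(spec, "cv_potential"))
  x <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  if (ncol(x) != 2 || !all(is.finite(x)))
    stop("'point' must be finite with two columns (cv1, cv2)")
  e <- 0.5 * spec$confinement_k[1] *
    (x[, 1] - spec$confinement_origin[1])^2 +
    0.5 * spec$confinement_k[2] *
    (x[, 2] - spec$confinement_origin[2])^2
  for (m in seq_along(spec$depths)) {
    r2 <- (x[, 1] - spec$centers[m, 1])^2 + (x[, 2] - spec$centers[m, 2])^2
    e <- e - spec$depths[m] * exp(-r2 / (2 * spec$widths[m]^2))
  }
  e
}

#' Analytic gradient of the potential (matches the integrator's force)
#'
#' @inheritParams potential_energy
#' @return n x 2 matrix of dE/dcv in kT/nm.
#' @export
potential_gradient <- function(spec, point) {
  stopifnot(inherits(spec, "cv_potential"))
  x <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  g1 <- spec$confinement_k[1] * (x[, 1] - spec$confinement_origin[1])
  g2 <- spec$confinement_k[2] * (x[, 2] - spec$confinement_origin[2])
  for (m in seq_along(spec$depths)) {
    w2 <- spec$widths[m]^2
    d1 <- x[, 1] - spec$centers[m, 1]
    d2 <- x[, 2] - spec$centers[m, 2]
    e <- spec$depths[m] * exp(-(d1^2 + d2^2) / (2 * w2))
    g1 <- g1 + e * d1 / w2
    g2 <- g2 + e * d2 / w2
  }
  cbind(g1, g2, deparse.level = 0)
}

#' Boltzmann reference distribution on a grid, by numerical quadrature
#'
#' Integrates `exp(-E/kT)` over each grid cell with a midpoint rule on a fine
#' subgrid. Serves as the independent equilibrium oracle for trajectory
#' occupancies and MSM stationary distributions.
#'
#' @param spec a `cv_potential`.
#' @param xedges,yedges strictly increasing bin edges (nm) on the two axes.
#' @param kT thermal energy (kT units; default 1).
#' @param subdiv midpoint subdivisions per cell and axis.
#' @return a matrix `p` of bin probabilities (rows = x bins, cols = y bins)
#'   summing to 1, with attributes `xedges`, `yedges`.
#' @export
reference_boltzmann <- function(spec, xedges, yedges, kT = 1, subdiv = 8) {
  stopifnot(inherits(spec, "cv_potential"),
            length(xedges) >= 2, length(yedges) >= 2,
            all(diff(xedges) > 0), all(diff(yedges) > 0))
  nx <- length(xedges) - 1L
  ny <- length(yedges) - 1L
  p <- matrix(0, nx, ny)
  ## midpoints of the fine subgrid within each cell, vectorised per x-slab
  for (i in seq_len(nx)) {
    xs <- seq(xedges[i], xedges[i + 1], length.out = subdiv + 1)
    xm <- (xs[-1] + xs[-length(xs)]) / 2
    dx <- diff(xs)[1]
    for (j in seq_len(ny)) {
      ys <- seq(yedges[j], yedges[j + 1], length.out = subdiv + 1)
      ym <- (ys[-1] + ys[-length(ys)]) / 2
      dy <- diff(ys)[1]
      pts <- cbind(rep(xm, times = subdiv), rep(ym, each = subdiv))
      p[i, j] <- sum(exp(-potential_energy(spec, pts) / kT)) * dx * dy
    }
  }
  ## coverage check: coarse quadrature of exp(-E/kT) on a halo extending
  ## 2 nm beyond the grid estimates the excluded mass
  hx <- seq(xedges[1] - 2, xedges[length(xedges)] + 2, by = 0.1)
  hy <- seq(yedges[1] - 2, yedges[length(yedges)] + 2, by = 0.1)
  hpts <- cbind(rep(hx, times = length(hy)), rep(hy, each = length(hx)))
  inside <- hpts[, 1] >= xedges[1] & hpts[, 1] <= xedges[length(xedges)] &
    hpts[, 2] >= yedges[1] & hpts[, 2] <= yedges[length(yedges)]
  halo <- sum(exp(-potential_energy(spec, hpts[!inside, , drop = FALSE]) / kT)) * 0.01
  if (halo / (halo + sum(p)) > 1e-6)
    warning("grid may exclude non-negligible Boltzmann mass; widen the edges")
  p <- p / sum(p)
  attr(p, "xedges") <- xedges
  attr(p, "yedges") <- yedges
  p
}

#' Serialize / deserialize a potential specification (JSON)
#'
#' @param spec a `cv_potential`.
#' @param path file path.
#' @return `write_potential_spec` returns `path` invisibly;
#'   `read_potential_spec` returns a `cv_potential`.
#' @export
write_potential_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cv_potential"))
  obj <- list(
    preset = spec$preset,
    wells = lapply(seq_along(spec$depths), function(m) {
      list(center = spec$centers[m, ], depth = spec$depths[m],
           width = spec$widths[m])
    }),
    confinement_k = spec$confinement_k,
    confinement_origin = spec$confinement_origin
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_potential_spec
#' @export
read_potential_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  wells <- if (is.data.frame(obj$wells)) {
    lapply(seq_len(nrow(obj$wells)), function(i)
      list(center = unlist(obj$wells$center[i]), depth = obj$wells$depth[i],
           width = obj$wells$width[i]))
  } else {
    obj$wells
  }
  potential_spec(wells, obj$confinement_k, obj$confinement_origin, obj$preset)
}
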