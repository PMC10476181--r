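## Collective variables of the lid system and the open/close classification.
##
## d      : centre-of-mass distance between the alpha5 helix (residues
##          142-146) and the outer half of the alpha10 helix (residues
##          278-287), nm.
## Dist1  : Calpha-Calpha distance Arg309-Leu144, nm.
## Dist2  : Calpha-Calpha distance Ala146-Val286, nm; measures lid opening.

LID_ALPHA5 <- 142:146
LID_ALPHA10_HALF <- 278:287

#' Interlid centre-of-mass distance d
#'
#' @param structure a `lid_structure` containing residues 142-146 and
#'   278-287.
#' @return d in nm.
#' @export
interlid_distance <- function(structure) {
  for (rng in list(LID_ALPHA5, LID_ALPHA10_HALF)) {
    missing <- setdiff(rng, unique(structure$resid))
    if (length(missing) > 0)
      stop("missing residues for interlid distance: ",
           paste(missing, collapse = ", "))
  }
  a <- center_of_mass(structure, LID_ALPHA5)
  b <- center_of_mass(structure, LID_ALPHA10_HALF)
  sqrt(sum((a - b)^2)) / 10
}

#' Lid collective variables (d, Dist1, Dist2)
#'
#' Dist1 is the Calpha-Calpha distance between residues 309 and 144; Dist2
#' between residues 146 and 286. Both are reported in nm along with the
#' interlid distance d.
#'
#' @param structure a `lid_structure` with the required Calpha atoms.
#' @return a list of class `lid_features` with elements `d`, `dist1`,
#'   `dist2` (nm).
#' @export
lid_distances <- function(structure) {
  ca <- function(res) {
    sel <- select_atoms(structure, res, atoms = "CA")
    if (nrow(sel) == 0) stop("missing Calpha atom for residue ", res)
    c(sel$x[1], sel$y[1], sel$z[1])
  }
  d12 <- function(a, b) sqrt(sum((a - b)^2)) / 10
  structure(list(d = interlid_distance(structure),
                 dist1 = d12(ca(309), ca(144)),
                 dist2 = d12(ca(146), ca(286))),
            class = "lid_features")
}

#' @export
print.lid_features <- function(x, ...) {
  cat(sprintf("d = %.3f nm, Dist1 = %.3f nm, Dist2 = %.3f nm (%s)\n",
              x$d, x$dist1, x$dist2, classify_conformation(x$dist2)))
  invisible(x)
}

#' Classify a conformation from Dist2
#'
#' Closed: Dist2 <= 1.0 nm; semiopen: 1.0 < Dist2 < 2.0 nm; open:
#' Dist2 >= 2.0 nm. The boundaries belong to closed and open respectively.
#'
#' @param dist2 numeric vector of Dist2 values (nm, >= 0).
#' @return character vector of `"closed"`, `"semiopen"` or `"open"`.
#' @export
classify_conformation <- function(dist2) {
  if (any(!is.finite(dist2)) || any(dist2 < 0))
    stop("'dist2' must be finite and non-negative")
  ifelse(dist2 <= 1.0, "closed", ifelse(dist2 >= 2.0, "open", "semiopen"))
}

#' Dist2 band limits of a conformational class
#'
#' @param class `"closed"`, `"semiopen"` or `"open"`.
#' @return numeric length-2 `(lower, upper)` in nm.
#' @export
conformation_band <- function(class = c("closed", "semiopen", "open")) {
  switch(match.arg(class),
         closed = c(0, 1.0), semiopen = c(1.0, 2.0), open = c(2.0, Inf))
}
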