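## Structure container and PDB I/O. Parsing goes through bio3d; the
## container is a plain data.frame (class "lid_structure") with one row per
## atom, coordinates in Angstrom.

STRUCTURE_COLS <- c("atom", "element", "resname", "resid", "insert", "chain",
                    "x", "y", "z", "occupancy", "altloc")

#' Construct a structure from atom fields
#'
#' @param atom atom names (e.g. `"CA"`, `"OD1"`).
#' @param element element symbols; derived from the atom name when `NULL`.
#' @param resname residue names.
#' @param resid integer residue numbers.
#' @param chain chain identifiers.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param occupancy,altloc,insert optional PDB fields.
#' @param model integer model id, stored as an attribute.
#' @return a data.frame of class `lid_structure`.
#' @export
new_structure <- function(atom, resname, resid, chain = "A", xyz,
                          element = NULL, occupancy = 1, altloc = "",
                          insert = "", model = 1L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(atom),
            all(is.finite(xyz)))
  if (is.null(element)) {
    element <- vapply(atom, function(a) {
      a <- gsub("[0-9']", "", a)
      substr(a, 1, 1)
    }, character(1))
  }
  out <- data.frame(atom = atom, element = toupper(element),
                    resname = resname, resid = as.integer(resid),
                    insert = insert, chain = chain,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    occupancy = occupancy, altloc = altloc,
                    stringsAsFactors = FALSE)
  attr(out, "model") <- as.integer(model)
  class(out) <- c("lid_structure", "data.frame")
  out
}

#' Read a structure from a PDB file
#'
#' Wraps [bio3d::read.pdb()]. One structure per requested (model, chain) is
#' returned; alternate locations are resolved to the highest occupancy
#' (ties broken alphabetically by altloc id). Atoms with insertion codes are
#' retained but excluded from plain numeric residue ranges by the selection
#' helpers.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; `NULL` keeps all chains.
#' @param model model number (default 1).
#' @return a `lid_structure`.
#' @export
read_structure <- function(path, chain = NULL, model = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  nmod <- nrow(pdb$xyz)
  if (model > nmod)
    stop(sprintf("model %d requested but file has %d model(s)", model, nmod))
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  atom_idx <- which(pdb$atom$type == "ATOM")
  co <- xyz[atom_idx, , drop = FALSE]

  if (!is.null(chain)) {
    keep <- !is.na(at$chain) & at$chain == chain
    if (!any(keep))
      stop(sprintf("chain '%s' not found; available: %s", chain,
                   paste(sort(unique(at$chain)), collapse = ", ")))
    at <- at[keep, , drop = FALSE]
    co <- co[keep, , drop = FALSE]
  }

  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  ins <- ifelse(is.na(at$insert), "", at$insert)
  elesy <- if ("elesy" %in% names(at)) at$elesy else NA
  element <- ifelse(is.na(elesy) | elesy == "",
                    substr(gsub("[0-9']", "", at$elety), 1, 1), elesy)

  s <- new_structure(atom = at$elety, element = element, resname = at$resid,
                     resid = at$resno, chain = ifelse(is.na(at$chain), "",
                                                      at$chain),
                     xyz = co, occupancy = occ, altloc = alt, insert = ins,
                     model = model)
  resolve_altloc(s)
}

## Keep, per (chain, resid, insert, atom), the altloc with highest occupancy;
## ties go to the alphabetically first altloc id.
resolve_altloc <- function(s) {
  key <- paste(s$chain, s$resid, s$insert, s$atom, sep = "|")
  if (!anyDuplicated(key)) return(s)
  ord <- order(key, -s$occupancy, s$altloc)
  s2 <- s[ord, , drop = FALSE]
  s2 <- s2[!duplicated(paste(s2$chain, s2$resid, s2$insert, s2$atom,
                             sep = "|")), , drop = FALSE]
  s2 <- s2[order(as.integer(rownames(s2))), , drop = FALSE]
  rownames(s2) <- NULL
  attr(s2, "model") <- attr(s, "model")
  class(s2) <- class(s)
  s2
}

#' Write a structure as PDB ATOM records
#'
#' Minimal fixed-width writer used to emit synthetic text fixtures; round
#' trips through [read_structure()].
#'
#' @param structure a `lid_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "lid_structure"))
  s <- structure
  name <- vapply(seq_len(nrow(s)), function(i) {
    a <- s$atom[i]
    ## PDB convention: atom name starts in column 14 unless 4 chars long
    if (nchar(a) >= 4) substr(a, 1, 4) else sprintf(" %-3s", a)
  }, character(1))
  lines <- sprintf(
    "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(s)), name, substr(s$altloc, 1, 1), substr(s$resname, 1, 3),
    substr(s$chain, 1, 1), s$resid, substr(s$insert, 1, 1),
    s$x, s$y, s$z, s$occupancy, 0, s$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## Select atoms by numeric residue range (insertion-coded residues excluded
## unless `insert` matches exactly), optional atom-name filter and
## heavy-atom restriction.
select_atoms <- function(structure, resids, atoms = NULL, heavy_only = TRUE,
                         insert = "") {
  keep <- structure$resid %in% resids & structure$insert == insert
  if (!is.null(atoms)) keep <- keep & structure$atom %in% atoms
  if (heavy_only) keep <- keep & structure$element != "H"
  structure[keep, , drop = FALSE]
}

#' Mass-weighted centre of mass of a residue selection
#'
#' Uses standard atomic masses over the heavy atoms of the selection (crystal
#' structures generally lack hydrogens; excluding them keeps crystal and
#' simulation pipelines consistent).
#'
#' @param structure a `lid_structure`.
#' @param resids integer vector of residue numbers.
#' @param atoms optional atom-name filter (e.g. `"CA"`).
#' @param heavy_only drop hydrogens before weighting (default TRUE).
#' @return numeric length-3 centre of mass (Angstrom).
#' @export
center_of_mass <- function(structure, resids, atoms = NULL,
                           heavy_only = TRUE) {
  sel <- select_atoms(structure, resids, atoms, heavy_only)
  if (nrow(sel) == 0)
    stop("empty selection: no atoms for residues ",
         paste(range(resids), collapse = "-"))
  m <- atomic_mass(sel$element)
  c(weighted.mean(sel$x, m), weighted.mean(sel$y, m),
    weighted.mean(sel$z, m))
}
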