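# Core domain types: topology, frame ensemble, atom selection.
#
# A topology is the static atom/residue bookkeeping of one molecular system;
# a frame ensemble holds F aligned coordinate frames (nm) over the same
# atoms. Atom order is identical between the two by construction.

# Backbone atom names (N-/C-terminal variants included).
.backbone_names <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2", "H", "H1",
                     "H2", "H3", "HA", "HN")
.backbone_heavy <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

# Residues treated as purely hydrophobic for contact typing.
.hydrophobic_residues <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "PRO",
                           "TRP")

#' Construct a molecular topology
#'
#' @param name atom names (character)
#' @param resid residue numbers as given by the source file (integer; source
#'   numbering is preserved, never re-indexed)
#' @param resname residue names (character)
#' @param chain chain identifiers (character; default all "A")
#' @param element element symbols; inferred from atom names when `NULL`
#' @return an object of class `topology`: a list with an `atoms` data.frame
#'   (name, element, resid, resname, chain, mass, backbone, heavy,
#'   hydrophobic) and a `residues` data.frame (resid, resname, chain)
#' @export
topology <- function(name, resid, resname, chain = NULL, element = NULL) {
  n <- length(name)
  if (n == 0) stop("topology must contain at least one atom")
  if (length(resid) != n || length(resname) != n)
    stop("name, resid and resname must have equal length")
  chain <- chain %||% rep("A", n)
  element <- element %||% infer_element(name)
  atoms <- data.frame(
    name = trimws(as.character(name)),
    element = as.character(element),
    resid = as.integer(resid),
    resname = trimws(as.character(resname)),
    chain = as.character(chain),
    stringsAsFactors = FALSE
  )
  atoms$mass <- element_mass(atoms$element)
  atoms$backbone <- atoms$name %in% .backbone_heavy
  atoms$heavy <- atoms$element != "H"
  atoms$hydrophobic <- atoms$resname %in% .hydrophobic_residues
  # one residue per unique (chain, resid) in order of first appearance
  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  first <- !duplicated(key)
  residues <- data.frame(
    resid = atoms$resid[first],
    resname = atoms$resname[first],
    chain = atoms$chain[first],
    stringsAsFactors = FALSE
  )
  # within a chain residue indices must be non-decreasing at first appearance
  for (ch in unique(residues$chain)) {
    r <- residues$resid[residues$chain == ch]
    if (is.unsorted(r)) stop("residue indices within chain '", ch,
                             "' are not non-decreasing")
  }
  structure(list(atoms = atoms, residues = residues), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,", nrow(x$residues), "residues,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a `topology`
#' @return integer atom count
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Construct a frame ensemble
#'
#' @param top a `topology`
#' @param coords numeric array `F x A x 3` of coordinates in nm, or an
#'   `A x 3` matrix for a single frame
#' @param time optional per-frame times in ps
#' @return an object of class `frame_ensemble`
#' @export
frame_ensemble <- function(top, coords, time = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be an F x A x 3 array")
  if (dim(coords)[2] != n_atoms(top))
    stop("coordinate atom count (", dim(coords)[2],
         ") does not match topology (", n_atoms(top), ")")
  if (dim(coords)[1] < 1) stop("ensemble must contain at least one frame")
  if (!is.null(time) && length(time) != dim(coords)[1])
    stop("time must have one entry per frame")
  structure(list(topology = top, coords = coords, time = time),
            class = "frame_ensemble")
}

#' @export
print.frame_ensemble <- function(x, ...) {
  cat("frame_ensemble:", n_frames(x), "frames x", n_atoms(x$topology),
      "atoms (nm)\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens a `frame_ensemble`
#' @return integer frame count
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' Extract one frame as an A x 3 coordinate matrix (nm)
#' @param ens a `frame_ensemble`
#' @param i frame index
#' @return numeric matrix A x 3
#' @export
get_frame <- function(ens, i) {
  if (i < 1 || i > n_frames(ens)) stop("frame index out of range")
  matrix(ens$coords[i, , ], ncol = 3)
}

#' Concatenate frame ensembles over the same topology
#' @param ... `frame_ensemble` objects sharing an atom count
#' @return merged `frame_ensemble`
#' @export
merge_ensembles <- function(...) {
  ens <- list(...)
  if (length(ens) == 1 && is.list(ens[[1]]) &&
      !inherits(ens[[1]], "frame_ensemble")) ens <- ens[[1]]
  a <- n_atoms(ens[[1]]$topology)
  for (e in ens) {
    if (n_atoms(e$topology) != a) stop("atom counts differ between ensembles")
  }
  coords <- do.call(abind3, lapply(ens, function(e) e$coords))
  times <- lapply(ens, function(e) e$time)
  time <- if (all(!vapply(times, is.null, logical(1)))) unlist(times) else NULL
  frame_ensemble(ens[[1]]$topology, coords, time)
}

#' Bind F x A x 3 arrays along the frame axis
#' @keywords internal
abind3 <- function(...) {
  xs <- list(...)
  ftot <- sum(vapply(xs, function(x) dim(x)[1], numeric(1)))
  a <- dim(xs[[1]])[2]
  out <- array(NA_real_, dim = c(ftot, a, 3))
  at <- 0
  for (x in xs) {
    f <- dim(x)[1]
    out[at + seq_len(f), , ] <- x
    at <- at + f
  }
  out
}

#' Construct an atom selection from explicit indices
#' @param indices integer atom indices (1-based, unique, in range)
#' @param top the `topology` the indices refer to
#' @param expression provenance string
#' @return an object of class `atom_selection`
#' @export
atom_selection <- function(indices, top, expression = "<manual>") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  if (length(indices) && (min(indices) < 1 || max(indices) > n_atoms(top)))
    stop("selection index out of range")
  structure(list(indices = indices, expression = expression),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection:", length(x$indices), "atoms  [", x$expression, "]\n")
  invisible(x)
}

#' @export
length.atom_selection <- function(x) length(x$indices)
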