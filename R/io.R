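# Structure and trajectory I/O.
#
# Internal units are nm (and ps): PDB angstroms are converted on read/write,
# GRO files are already nm. DCD coordinates are treated as angstroms
# (CHARMM/NAMD convention). Supported formats: PDB and GRO read/write for
# structures; DCD and multi-model PDB read/write for trajectories.

#' Read a structure file into a topology and frame ensemble
#'
#' @param path path to a PDB or GRO file
#' @param format "auto" (by extension), "pdb" or "gro"
#' @return list with `topology` and `ensemble` (one frame per PDB MODEL /
#'   GRO frame), coordinates in nm
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", ent = "pdb", gro = "gro",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "pdb") .read_pdb(path) else .read_gro(path)
}

.read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms in ", path)
  elt <- at$elesy
  if (is.null(elt) || all(is.na(elt)) || all(trimws(elt) == "")) elt <- NULL
  if (!is.null(elt)) {
    elt <- trimws(elt)
    elt[elt == ""] <- infer_element(at$elety[elt == ""])
  }
  top <- topology(name = at$elety, resid = at$resno, resname = at$resid,
                  chain = ifelse(is.na(at$chain), "A", at$chain),
                  element = elt)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  f <- nrow(xyz)
  coords <- array(NA_real_, dim = c(f, n_atoms(top), 3))
  for (i in seq_len(f)) {
    coords[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) *
      .const$nm_per_angstrom
  }
  list(topology = top, ensemble = frame_ensemble(top, coords))
}

.read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  top <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (i + 1 > length(lines)) break
    natom <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(natom) || natom < 1) stop("unparseable GRO atom count at line ",
                                        i + 1)
    if (i + 1 + natom + 1 > length(lines)) stop("truncated GRO frame")
    body <- lines[i + 1 + seq_len(natom)]
    resid <- as.integer(substr(body, 1, 5))
    resname <- trimws(substr(body, 6, 10))
    name <- trimws(substr(body, 11, 15))
    x <- as.numeric(substr(body, 21, 28))
    y <- as.numeric(substr(body, 29, 36))
    z <- as.numeric(substr(body, 37, 44))
    if (anyNA(c(x, y, z))) stop("unparseable GRO coordinate record")
    if (is.null(top)) {
      top <- topology(name = name, resid = resid, resname = resname)
    }
    frames[[length(frames) + 1]] <- cbind(x, y, z)
    i <- i + 1 + natom + 2   # title + count + atoms + box line
  }
  if (is.null(top)) stop("no frames in ", path)
  coords <- array(NA_real_, dim = c(length(frames), n_atoms(top), 3))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  list(topology = top, ensemble = frame_ensemble(top, coords))
}

#' Write a structure (or multi-frame ensemble) to PDB or GRO
#'
#' @param ens a `frame_ensemble`
#' @param path output path
#' @param format "auto", "pdb" or "gro"
#' @return `path`, invisibly
#' @export
write_structure <- function(ens, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", gro = "gro",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "pdb") .write_pdb(ens, path) else .write_gro(ens, path)
  invisible(path)
}

.write_pdb <- function(ens, path) {
  at <- ens$topology$atoms
  f <- n_frames(ens)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(f)) {
    if (f > 1) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- get_frame(ens, k) / .const$nm_per_angstrom
    rec <- sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)) %% 100000,
      ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name),
      at$resname, substr(at$chain, 1, 1), at$resid %% 10000,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element
    )
    writeLines(rec, con)
    if (f > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

.write_gro <- function(ens, path) {
  at <- ens$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(ens))) {
    xyz <- get_frame(ens, k)
    writeLines(sprintf("frame %d", k), con)
    writeLines(sprintf("%5d", nrow(at)), con)
    rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   at$resid %% 100000, at$resname, at$name,
                   seq_len(nrow(at)) %% 100000,
                   xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(rec, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", 100, 100, 100), con)
  }
}

#' Read a coordinate trajectory against an existing topology
#'
#' @param top the `topology` the trajectory belongs to (atom counts must
#'   match)
#' @param path path to a DCD or multi-model PDB file
#' @param format "auto", "dcd" or "pdb"
#' @return a `frame_ensemble` (nm), frames in file order
#' @export
read_trajectory <- function(top, path, format = c("auto", "dcd", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     dcd = "dcd", pdb = "pdb",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "pdb") {
    out <- .read_pdb(path)
    if (n_atoms(out$topology) != n_atoms(top))
      stop("trajectory atom count (", n_atoms(out$topology),
           ") does not match topology (", n_atoms(top), ")")
    return(frame_ensemble(top, out$ensemble$coords))
  }
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  a <- ncol(xyz) / 3
  if (a != n_atoms(top))
    stop("trajectory atom count (", a, ") does not match topology (",
         n_atoms(top), ")")
  coords <- array(NA_real_, dim = c(nrow(xyz), a, 3))
  for (i in seq_len(nrow(xyz))) {
    coords[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) *
      .const$nm_per_angstrom
  }
  frame_ensemble(top, coords)
}

#' Write a trajectory to DCD or multi-model PDB
#'
#' @param ens a `frame_ensemble`
#' @param path output path
#' @param format "auto", "dcd" or "pdb"
#' @return `path`, invisibly
#' @export
write_trajectory <- function(ens, path, format = c("auto", "dcd", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     dcd = "dcd", pdb = "pdb",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "pdb") return(.write_pdb(ens, path))
  .write_dcd(ens, path)
  invisible(path)
}

# Minimal CHARMM-style DCD writer (little-endian, no unit cell). Matches the
# record layout expected by standard readers: header, title, natom, then
# x/y/z float records per frame.
.write_dcd <- function(ens, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  f <- n_frames(ens)
  a <- n_atoms(ens$topology)
  wr_marker <- function(n) writeBin(as.integer(n), con, size = 4,
                                    endian = "little")
  # header record: "CORD" + 20 int slots (icntrl)
  wr_marker(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- f        # number of frames
  icntrl[2] <- 1        # first step
  icntrl[3] <- 1        # save stride
  icntrl[4] <- f        # total steps
  icntrl[20] <- 24      # CHARMM version stamp
  writeBin(as.integer(icntrl), con, size = 4, endian = "little")
  wr_marker(84)
  # title record
  title <- sprintf("%-80s", "written by allonet")
  wr_marker(84 + 4 - 4)   # 4 (ntitle) + 80 chars
  writeBin(1L, con, size = 4, endian = "little")
  writeChar(title, con, nchars = 80, eos = NULL)
  wr_marker(84)
  # natom record
  wr_marker(4)
  writeBin(as.integer(a), con, size = 4, endian = "little")
  wr_marker(4)
  # frames (angstrom floats)
  for (k in seq_len(f)) {
    xyz <- get_frame(ens, k) / .const$nm_per_angstrom
    for (d in 1:3) {
      wr_marker(4 * a)
      writeBin(as.numeric(xyz[, d]), con, size = 4, endian = "little")
      wr_marker(4 * a)
    }
  }
}
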