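#' Read a binary DCD trajectory
#'
#' Reads the CHARMM/X-PLOR DCD dialect (little-endian, Fortran record
#' markers, no unit-cell records).  The atom count must match the supplied
#' topology; malformed record markers raise a structural error and no
#' partial trajectory is returned.
#'
#' @param path DCD file.
#' @param topology An [md_topology] describing the atoms.
#' @return An [md_trajectory].
#' @export
read_dcd <- function(path, topology) {
  top <- as_topology(topology)
  if (!file.exists(path)) abort(paste0("DCD file not found: ", path))
  con <- file(path, open = "rb")
  on.exit(close(con))
  rint <- function(n = 1) readBin(con, "integer", n = n, size = 4, endian = "little")

  len <- rint()
  if (!identical(len, 84L)) abort("malformed DCD: header record is not 84 bytes")
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "CORD") abort("malformed DCD: missing CORD magic")
  icntrl <- rint(20)
  if (!identical(rint(), 84L)) abort("malformed DCD: unterminated header record")
  nframes_hdr <- icntrl[1]
  has_cell <- icntrl[11] != 0

  tlen <- rint()
  ntitle <- rint()
  if (tlen != 4 + 80 * ntitle) abort("malformed DCD: title record size mismatch")
  readBin(con, "raw", 80 * ntitle)
  if (!identical(rint(), tlen)) abort("malformed DCD: unterminated title record")

  if (!identical(rint(), 4L)) abort("malformed DCD: natom record size mismatch")
  natom <- rint()
  if (!identical(rint(), 4L)) abort("malformed DCD: unterminated natom record")
  if (natom != nrow(top)) {
    abort(paste0("DCD atom count (", natom, ") does not match topology (",
                 nrow(top), ")"))
  }

  frames <- list()
  repeat {
    len <- rint()
    if (length(len) == 0) break
    if (has_cell && identical(len, 48L)) {  # skip unit-cell record
      readBin(con, "raw", 48)
      if (!identical(rint(), 48L)) abort("malformed DCD: unterminated cell record")
      next
    }
    xyz <- matrix(NA_real_, natom, 3)
    for (d in 1:3) {
      if (d > 1) len <- rint()
      if (length(len) == 0 || len != 4L * natom) {
        abort(paste0("malformed DCD: coordinate block of ",
                     if (length(len)) len else 0, " bytes in frame ",
                     length(frames) + 1, "; expected ", 4L * natom))
      }
      vals <- readBin(con, "double", n = natom, size = 4, endian = "little")
      if (length(vals) != natom) {
        abort(paste0("malformed DCD: truncated coordinate block in frame ",
                     length(frames) + 1))
      }
      xyz[, d] <- vals
      if (!identical(rint(), 4L * natom)) {
        abort(paste0("malformed DCD: unterminated coordinate block in frame ",
                     length(frames) + 1))
      }
    }
    frames[[length(frames) + 1]] <- xyz
  }
  if (length(frames) == 0) abort("malformed DCD: no frames")
  if (nframes_hdr > 0 && length(frames) != nframes_hdr) {
    abort(paste0("malformed DCD: header promises ", nframes_hdr,
                 " frames but file holds ", length(frames)))
  }
  coords <- array(unlist(frames), dim = c(natom, 3, length(frames)))
  md_trajectory(top, coords)
}

#' Write a trajectory as a binary DCD file
#'
#' Coordinates are stored as little-endian 32-bit floats (the format's
#' precision); a read-back therefore agrees with the written values to
#' single precision and is bitwise stable under further round trips.
#'
#' @param traj An [md_trajectory].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  nf <- n_frames(traj); natom <- n_atoms(traj)

  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  wint(84L); writeBin(charToRaw("CORD"), con); wint(icntrl); wint(84L)
  title <- sprintf("%-80s", "Created by trajan")
  wint(4L + 80L); wint(1L); writeBin(charToRaw(title), con); wint(4L + 80L)
  wint(4L); wint(natom); wint(4L)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    for (d in 1:3) {
      wint(4L * natom)
      writeBin(m[, d], con, size = 4, endian = "little")
      wint(4L * natom)
    }
  }
  invisible(path)
}

#' Read or write a trajectory in a standard format
#'
#' Thin dispatcher over the PDB and DCD readers/writers.  Format `"auto"`
#' uses the file extension.
#'
#' @param path File path.
#' @param topology Topology, required for reading DCD.
#' @param format `"auto"`, `"pdb"` or `"dcd"`.
#' @return An [md_trajectory].
#' @export
read_trajectory <- function(path, topology = NULL, format = c("auto", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  if (format == "pdb") {
    tr <- read_pdb_trajectory(path)
    if (!is.null(topology)) tr$topology <- as_topology(topology)
    tr
  } else {
    if (is.null(topology)) abort("reading DCD requires a topology")
    read_dcd(path, topology)
  }
}

#' @rdname read_trajectory
#' @param traj Trajectory to write.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  if (format == "pdb") write_pdb_trajectory(traj, path) else write_dcd(traj, path)
}
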