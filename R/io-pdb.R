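#' Read a (multi-model) PDB file as a trajectory
#'
#' Parses `ATOM`/`HETATM` records with fixed PDB columns; `MODEL`/`ENDMDL`
#' blocks become frames.  Occupancy and B-factor columns are tolerated and
#' ignored.  Files without `MODEL` records yield a single-frame trajectory.
#'
#' @param path PDB file.
#' @return An [md_trajectory].  Parameter columns are `NA`; attach them with
#'   [set_parameters()].
#' @export
read_pdb_trajectory <- function(path) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model_end <- trimws(rec) == "ENDMDL"
  if (!any(is_atom)) abort(paste0("no ATOM/HETATM records in ", path))

  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad)) {
    abort(paste0("truncated ATOM record at line ", bad[1], " of ", path))
  }

  # frame id per atom line: number of ENDMDL seen before it
  frame_of <- cumsum(is_model_end)[is_atom] + 1L
  al <- lines[is_atom]
  parse_frame <- function(ls) {
    cbind(as.numeric(substr(ls, 31, 38)),
          as.numeric(substr(ls, 39, 46)),
          as.numeric(substr(ls, 47, 54)))
  }
  first <- al[frame_of == 1L]
  natom <- length(first)
  elem <- trimws(substr(first, 77, 78))
  name <- trimws(substr(first, 13, 16))
  elem[elem == ""] <- toupper(substr(name[elem == ""], 1, 1))
  top <- md_topology(tibble(
    atom_id = as.integer(substr(first, 7, 11)),
    name = name,
    element = elem,
    resid = as.integer(substr(first, 23, 26)),
    resname = trimws(substr(first, 18, 20)),
    chain = substr(first, 22, 22)
  ))
  nf <- max(frame_of)
  counts <- tabulate(frame_of, nbins = nf)
  if (any(counts != natom)) {
    abort(paste0("frame ", which(counts != natom)[1], " has ",
                 counts[counts != natom][1], " atoms; expected ", natom))
  }
  xyz <- parse_frame(al)
  if (anyNA(xyz)) {
    abort(paste0("unparsable coordinate field in ATOM record of ", path))
  }
  coords <- array(NA_real_, dim = c(natom, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- xyz[frame_of == f, , drop = FALSE]
  md_trajectory(top, coords)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj An [md_trajectory].
#' @param path Output file.
#' @param frames Frames to write (default all).
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path, frames = seq_len(n_frames(traj))) {
  top <- traj$topology
  nm <- ifelse(nchar(top$name) < 4, paste0(" ", top$name), top$name)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in frames) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- frame_coords(traj, f)
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       top$atom_id %% 100000L, nm, top$resname, top$chain,
                       top$resid %% 10000L, m[, 1], m[, 2], m[, 3], 1, 0,
                       top$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
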