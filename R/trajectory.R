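#' Molecular-dynamics trajectory container
#'
#' A lightweight in-memory trajectory: a `frames x atoms x 3` coordinate array
#' (Å) plus a topology table. The topology carries one row per atom with the
#' residue index (construct numbering, 1-based), residue name, atom name and
#' element. `numbering_offset` maps construct numbering to full-protein
#' numbering (`construct = full + numbering_offset`), so that region
#' selections can be written in full-protein residue numbers even when the
#' simulated construct omits disordered termini.
#'
#' @param coords Numeric array `n_frames x n_atoms x 3`, or a single
#'   `n_atoms x 3` matrix for a one-frame "trajectory".
#' @param topology Data frame with columns `resid`, `resname`, `atom`,
#'   `element` (one row per atom, same order as `coords`).
#' @param frame_interval_ps Time between stored frames, picoseconds.
#' @param replica Replica identifier.
#' @param numbering_offset Integer added to full-protein residue numbers to
#'   obtain construct numbering (e.g. `-68` when construct residue 1 is
#'   full-protein residue 69).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, topology, frame_interval_ps = 100,
                          replica = 1L, numbering_offset = 0L) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  topology <- as_tibble(topology)
  need <- c("resid", "resname", "atom", "element")
  if (!all(need %in% names(topology))) {
    stop_hd("Topology must have columns resid, resname, atom, element.",
            "topology_error")
  }
  if (nrow(topology) != dim(coords)[2]) {
    stop_hd("Topology rows must match the number of atoms in `coords`.",
            "topology_error")
  }
  structure(
    list(coords = coords, topology = topology,
         frame_interval_ps = frame_interval_ps,
         replica = replica,
         numbering_offset = as.integer(numbering_offset)),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d frames x %d atoms (%d residues), %g ps/frame, replica %s\n",
    n_frames(x), dim(x$coords)[2], length(unique(x$topology$resid)),
    x$frame_interval_ps, format(x$replica)))
  invisible(x)
}

#' @export
dim.md_trajectory <- function(x) dim(x$coords)

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

# One frame as an atoms x 3 matrix.
frame_coords <- function(traj, i = 1L) {
  if (i < 1L || i > n_frames(traj)) {
    stop_hd(sprintf("Frame %d out of range (1..%d).", i, n_frames(traj)),
            "frame_error")
  }
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(traj$topology$atom, c("x", "y", "z")))
}

#' Region selection in full-protein numbering
#'
#' @param residues Integer vector of residue numbers (full-protein numbering).
#' @param atoms Character vector of atom names to keep (`NULL` = all atoms).
#' @return A `region_selection` object.
#' @export
region_selection <- function(residues, atoms = "CA") {
  structure(list(residues = as.integer(residues), atoms = atoms),
            class = "region_selection")
}

# Resolve a selection to atom row indices of a trajectory topology.
resolve_selection <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(nrow(traj$topology)))
  stopifnot(inherits(selection, "region_selection"))
  construct <- selection$residues + traj$numbering_offset
  keep <- traj$topology$resid %in% construct
  if (!is.null(selection$atoms)) {
    keep <- keep & traj$topology$atom %in% selection$atoms
  }
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop_hd("Selection resolves to no atoms in this topology.",
            "selection_error")
  }
  idx
}

# Frame indices sampled every `stride_ps`, after discarding `equilibration_ns`
# from the start of the trajectory.
sampled_frames <- function(traj, stride_ps = NULL, equilibration_ns = 0) {
  dt <- traj$frame_interval_ps
  stride_ps <- stride_ps %||% dt
  if (stride_ps < dt) {
    stop_hd("Stride is finer than the stored frame interval.",
            "sampling_error")
  }
  if (abs(stride_ps / dt - round(stride_ps / dt)) > 1e-9) {
    stop_hd("Stride must be a multiple of the frame interval.",
            "sampling_error")
  }
  step <- as.integer(round(stride_ps / dt))
  first_frame <- floor(equilibration_ns * 1000 / dt) + 1
  idx <- seq.int(first_frame, n_frames(traj), by = step)
  if (length(idx) == 0L || first_frame > n_frames(traj)) {
    stop_hd("No frames remain after the equilibration cut.",
            "empty_window_error")
  }
  idx
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj An `md_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  topo <- traj$topology
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    name4 <- ifelse(nchar(topo$atom) < 4L,
                    sprintf(" %-3s", topo$atom), topo$atom)
    lines <- sprintf(
      "ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(topo)) %% 100000L, name4, topo$resname, topo$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], topo$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param path PDB file with one MODEL block per frame.
#' @param frame_interval_ps,replica,numbering_offset Stored as trajectory
#'   metadata (see [md_trajectory()]).
#' @return An `md_trajectory`.
#' @export
read_trajectory_pdb <- function(path, frame_interval_ps = 100, replica = 1L,
                                numbering_offset = 0L) {
  lines <- readLines(path)
  atom <- grepl("^ATOM  |^HETATM", lines)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (max(model_id) == 0L) model_id <- rep(1L, length(lines))
  al <- lines[atom]
  fid <- model_id[atom]
  nf <- length(unique(fid))
  per <- length(al) / nf
  if (per != round(per)) {
    stop_hd("Models in the PDB file differ in atom count.", "topology_error")
  }
  first <- al[fid == fid[1]]
  topology <- tibble(
    resid = as.integer(substr(first, 23, 26)),
    resname = trimws(substr(first, 18, 21)),
    atom = trimws(substr(first, 13, 16)),
    element = trimws(substr(first, 77, 78))
  )
  xyz <- cbind(as.numeric(substr(al, 31, 38)),
               as.numeric(substr(al, 39, 46)),
               as.numeric(substr(al, 47, 54)))
  coords <- array(0, dim = c(nf, per, 3L))
  for (f in seq_len(nf)) coords[f, , ] <- xyz[(f - 1) * per + seq_len(per), ]
  md_trajectory(coords, topology, frame_interval_ps, replica, numbering_offset)
}
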