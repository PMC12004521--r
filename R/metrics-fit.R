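#' Rigid-body superposition of one frame onto a reference
#'
#' Least-squares optimal (Kabsch) superposition computed on the atoms of
#' `selection`; the returned coordinates contain the whole mobile frame after
#' the fitted rotation/translation, along with the post-fit RMSD over the
#' selection.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices sharing a
#'   topology, or `md_trajectory` objects (first frame used).
#' @param traj Trajectory supplying the topology used to resolve `selection`
#'   when `mobile` is a bare matrix.
#' @param selection A [region_selection()] (`NULL` = all atoms).
#' @return List with `coords` (transformed mobile frame) and `rmsd` (Å).
#' @export
superpose <- function(mobile, reference, selection = NULL, traj = NULL) {
  if (inherits(mobile, "md_trajectory")) {
    traj <- traj %||% mobile
    mobile <- frame_coords(mobile, 1)
  }
  if (inherits(reference, "md_trajectory")) {
    traj <- traj %||% reference
    reference <- frame_coords(reference, 1)
  }
  idx <- if (is.null(selection)) seq_len(nrow(mobile)) else {
    if (is.null(traj)) stop_hd("Need a trajectory to resolve the selection.",
                               "selection_error")
    resolve_selection(traj, selection)
  }
  if (nrow(mobile) != nrow(reference)) {
    stop_hd("Mobile and reference differ in atom count.", "selection_error")
  }
  fitted <- kabsch_transform(mobile, reference, idx)
  list(coords = fitted,
       rmsd = coord_rmsd(fitted[idx, , drop = FALSE],
                         reference[idx, , drop = FALSE]))
}

#' RMSD time series over a trajectory
#'
#' Per-sampled-frame RMSD of `selection` relative to a reference frame, after
#' aligning each frame on `align_selection` (typically the rigid protein
#' core, excluding mobile regions).
#'
#' @param traj An [md_trajectory()].
#' @param reference Reference coordinates (`n_atoms x 3`) or an
#'   `md_trajectory` whose first frame is used.
#' @param selection Region the RMSD is computed over.
#' @param align_selection Region used for the superposition (default:
#'   `selection`).
#' @param stride_ps Sampling interval (must be a multiple of the stored frame
#'   interval).
#' @param equilibration_ns Initial time span to discard.
#' @return Tibble with `frame`, `time_ns`, `rmsd`.
#' @export
rmsd_series <- function(traj, reference, selection = NULL,
                        align_selection = selection, stride_ps = 200,
                        equilibration_ns = 0) {
  if (inherits(reference, "md_trajectory")) {
    reference <- frame_coords(reference, 1)
  }
  frames <- sampled_frames(traj, stride_ps, equilibration_ns)
  sel <- if (is.null(selection)) seq_len(nrow(traj$topology)) else
    resolve_selection(traj, selection)
  fit <- if (is.null(align_selection)) sel else
    resolve_selection(traj, align_selection)
  vals <- vapply(frames, function(f) {
    fitted <- kabsch_transform(frame_coords(traj, f), reference, fit)
    coord_rmsd(fitted[sel, , drop = FALSE], reference[sel, , drop = FALSE])
  }, numeric(1))
  tibble(frame = frames,
         time_ns = (frames - 1) * traj$frame_interval_ps / 1000,
         rmsd = vals)
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each selected atom about the trajectory-average structure, after
#' aligning every sampled frame on `align_selection`. Replicas are analyzed
#' separately with [rmsf()] and combined with [replica_mean_sem()].
#'
#' @inheritParams rmsd_series
#' @param selection Atoms to report (default alpha-carbons of all residues).
#' @return Tibble with `resid`, `atom`, `rmsf`.
#' @export
rmsf <- function(traj, selection = NULL, align_selection = NULL,
                 stride_ps = 200, equilibration_ns = 0) {
  frames <- sampled_frames(traj, stride_ps, equilibration_ns)
  if (length(frames) < 2) {
    stop_hd("RMSF needs at least two sampled frames.",
            "undefined_fluctuation_error")
  }
  sel <- if (is.null(selection)) which(traj$topology$atom == "CA") else
    resolve_selection(traj, selection)
  fit <- if (is.null(align_selection)) sel else
    resolve_selection(traj, align_selection)
  ref <- frame_coords(traj, frames[1])
  aligned <- array(0, dim = c(length(frames), nrow(ref), 3))
  for (k in seq_along(frames)) {
    aligned[k, , ] <- kabsch_transform(frame_coords(traj, frames[k]), ref, fit)
  }
  avg <- apply(aligned, c(2, 3), mean)
  # realign onto the average structure, then fluctuation about it
  for (k in seq_along(frames)) {
    aligned[k, , ] <- kabsch_transform(aligned[k, , ], avg, fit)
  }
  avg <- apply(aligned, c(2, 3), mean)
  dev2 <- vapply(seq_along(frames), function(k) {
    rowSums((aligned[k, sel, , drop = FALSE][1, , ] - avg[sel, ])^2)
  }, numeric(length(sel)))
  vals <- sqrt(rowMeans(matrix(dev2, nrow = length(sel))))
  tibble(resid = traj$topology$resid[sel],
         atom = traj$topology$atom[sel], rmsf = vals)
}

#' Kink angle at a residue triple
#'
#' Planar angle (degrees) at the middle residue formed by three named
#' residues, measured on one atom per residue (alpha-carbon by default).
#' Reported per sampled frame.
#'
#' @param traj An [md_trajectory()].
#' @param residues Ordered integer triple, full-protein numbering.
#' @param atom_name Atom measured at each residue.
#' @param stride_ps,equilibration_ns Sampling controls.
#' @return Tibble with `frame`, `time_ns`, `angle` (degrees).
#' @export
kink_angle <- function(traj, residues, atom_name = "CA", stride_ps = NULL,
                       equilibration_ns = 0) {
  if (length(residues) != 3) {
    stop_hd("`residues` must be an ordered triple.", "selection_error")
  }
  idx <- vapply(residues, function(r) {
    i <- which(traj$topology$resid == r + traj$numbering_offset &
                 traj$topology$atom == atom_name)
    if (length(i) != 1) {
      stop_hd(sprintf("Atom %s of residue %d not found.", atom_name, r),
              "topology_error")
    }
    i
  }, integer(1))
  frames <- sampled_frames(traj, stride_ps, equilibration_ns)
  vals <- vapply(frames, function(f) {
    xyz <- frame_coords(traj, f)
    angle_at(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ])
  }, numeric(1))
  tibble(frame = frames,
         time_ns = (frames - 1) * traj$frame_interval_ps / 1000,
         angle = vals)
}

#' Average pairwise-distance change map
#'
#' For every pair of selected atoms (alpha-carbons by default), the mean over
#' sampled frames of `d_ij(frame) - d_ij(reference)`. Positive entries mean
#' the pair moved apart relative to the reference structure. The matrix is
#' symmetric with a zero diagonal.
#'
#' @inheritParams rmsd_series
#' @return Numeric `n_sel x n_sel` matrix with residue numbers as dimnames.
#' @export
displacement_map <- function(traj, reference, selection = NULL,
                             stride_ps = NULL, equilibration_ns = 0) {
  if (inherits(reference, "md_trajectory")) {
    reference <- frame_coords(reference, 1)
  }
  sel <- if (is.null(selection)) which(traj$topology$atom == "CA") else
    resolve_selection(traj, selection)
  frames <- sampled_frames(traj, stride_ps, equilibration_ns)
  dref <- as.matrix(stats::dist(reference[sel, , drop = FALSE]))
  acc <- matrix(0, length(sel), length(sel))
  for (f in frames) {
    acc <- acc + as.matrix(stats::dist(frame_coords(traj, f)[sel, , drop = FALSE]))
  }
  out <- acc / length(frames) - dref
  lab <- traj$topology$resid[sel] - traj$numbering_offset
  dimnames(out) <- list(lab, lab)
  out
}
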