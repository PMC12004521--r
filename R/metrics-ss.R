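# Simplified three-state secondary-structure assignment.
#
# Hydrogen bonds are detected with the classic electrostatic model
#   E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)  [kcal/mol]
# between the carbonyl group (C=O) of residue i and the amide group (N-H) of
# residue j, with a bond whenever E < -0.5 kcal/mol and |i - j| >= 3.
# Helix: two consecutive (i, i+3) or (i, i+4) turns. Strand: exact parallel /
# antiparallel bridge patterns only, so beta-bulges fall through to loop.
# Residues without an amide hydrogen (prolines, the N-terminus) are never
# donors.

.hbond_q <- 0.084 * 332
.hbond_cutoff <- -0.5

# Hydrogen-bond map for one frame: logical nres x nres matrix, entry [i, j]
# TRUE when CO(i) accepts from NH(j).
hbond_map <- function(N, H, C, O) {
  nres <- nrow(N)
  has_h <- !is.na(H[, 1])
  dmat <- function(A, B) {
    # pairwise distances between rows of A and rows of B
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  }
  safe_sqrt <- function(m) sqrt(pmax(m, 1e-12))
  d_on <- safe_sqrt(dmat(O, N))
  d_cn <- safe_sqrt(dmat(C, N))
  Hf <- H
  Hf[!has_h, ] <- 1e6  # sentinel far away; masked below
  d_oh <- safe_sqrt(dmat(O, Hf))
  d_ch <- safe_sqrt(dmat(C, Hf))
  E <- .hbond_q * (1 / d_on + 1 / d_ch - 1 / d_oh - 1 / d_cn)
  hb <- E < .hbond_cutoff
  hb[, !has_h] <- FALSE
  sep <- abs(outer(seq_len(nres), seq_len(nres), "-"))
  hb[sep < 3] <- FALSE
  hb
}

assign_ss_frame <- function(N, H, C, O) {
  nres <- nrow(N)
  hb <- hbond_map(N, H, C, O)
  hbat <- function(i, j) {
    ok <- i >= 1 & i <= nres & j >= 1 & j <= nres
    out <- logical(length(i))
    out[ok] <- hb[cbind(i[ok], j[ok])]
    out
  }
  i <- seq_len(nres)
  turn3 <- hbat(i, i + 3)
  turn4 <- hbat(i, i + 4)
  prev <- function(x) c(FALSE, x[-length(x)])
  helix <- (prev(turn3) & turn3) | (prev(turn4) & turn4)
  strand <- logical(nres)
  if (any(hb)) {
    for (ii in i) {
      jj <- which(hb[ii, ] | hb[, ii])
      jj <- jj[abs(jj - ii) >= 3]
      for (j in jj) {
        p_br <- (hbat(ii - 1, j) && hbat(j, ii + 1)) ||
          (hbat(j - 1, ii) && hbat(ii, j + 1))
        a_br <- (hbat(ii, j) && hbat(j, ii)) ||
          (hbat(ii - 1, j + 1) && hbat(j - 1, ii + 1))
        if (p_br || a_br) {
          strand[ii] <- TRUE
          break
        }
      }
    }
  }
  out <- rep("loop", nres)
  out[strand] <- "strand"
  out[helix] <- "helix"
  out
}

# Pull per-residue backbone atom coordinate matrices out of one frame.
backbone_frames <- function(traj, f) {
  topo <- traj$topology
  xyz <- frame_coords(traj, f)
  resids <- sort(unique(topo$resid))
  pick <- function(atom_name) {
    m <- matrix(NA_real_, length(resids), 3)
    idx <- which(topo$atom == atom_name)
    m[match(topo$resid[idx], resids), ] <- xyz[idx, , drop = FALSE]
    m
  }
  list(resids = resids, N = pick("N"), H = pick("H"),
       CA = pick("CA"), C = pick("C"), O = pick("O"))
}

#' Assign secondary structure over trajectory frames
#'
#' Three-state (`helix` / `strand` / `loop`) assignment per residue and frame
#' using an electrostatic hydrogen-bond criterion with explicitly provided
#' amide hydrogens. Beta-bulges are assigned `loop` (only exact bridge
#' patterns count as strand).
#'
#' @param traj An [md_trajectory()] whose topology carries backbone atoms
#'   `N`, `H`, `CA`, `C`, `O` (`H` may be absent at prolines / the
#'   N-terminus, where the residue is then never a hydrogen-bond donor).
#' @param frames Frame indices to assign (default: all).
#' @return Character matrix `length(frames) x n_residues`, with residue
#'   numbers (construct numbering) as column names.
#' @export
assign_ss <- function(traj, frames = seq_len(n_frames(traj))) {
  bb0 <- backbone_frames(traj, frames[1])
  if (anyNA(bb0$N) || anyNA(bb0$C) || anyNA(bb0$O) || anyNA(bb0$CA)) {
    stop_hd("Backbone atoms N, CA, C, O must be present for every residue.",
            "topology_error")
  }
  out <- matrix("", length(frames), length(bb0$resids),
                dimnames = list(NULL, bb0$resids))
  for (k in seq_along(frames)) {
    bb <- if (k == 1) bb0 else backbone_frames(traj, frames[k])
    out[k, ] <- assign_ss_frame(bb$N, bb$H, bb$C, bb$O)
  }
  out
}

#' Fraction of ordered residues in a region
#'
#' Mean over frames of the fraction of region residues assigned `helix` or
#' `strand`. The uncertainty is a moving-block-bootstrap SEM of the per-frame
#' series with block length set by its autocorrelation time.
#'
#' @param labels Character matrix from [assign_ss()] (frames x residues).
#' @param region A [region_selection()] or integer residue numbers
#'   (construct numbering, matching `labels` column names); `NULL` = all.
#' @param numbering_offset Offset applied to `region` residue numbers when a
#'   plain integer vector in full-protein numbering is given.
#' @param n_boot,seed Bootstrap replicates and seed for the uncertainty.
#' @return A one-row tibble: `ordered_fraction`, `sem`, `tau`,
#'   `block_length`, `n_frames`.
#' @export
ordered_fraction <- function(labels, region = NULL, numbering_offset = 0L,
                             n_boot = 500L, seed = 1L) {
  resids <- as.integer(colnames(labels))
  keep <- if (is.null(region)) {
    rep(TRUE, length(resids))
  } else {
    want <- if (inherits(region, "region_selection")) region$residues else region
    resids %in% (as.integer(want) + numbering_offset)
  }
  if (!any(keep)) stop_hd("Region selects no residues.", "selection_error")
  ordered <- matrix(labels[, keep, drop = FALSE] %in% c("helix", "strand"),
                    nrow = nrow(labels))
  series <- rowMeans(ordered)
  if (length(series) >= 10 && sd(series) > 0) {
    tau <- autocorrelation_time(series)
    bs <- moving_block_bootstrap_sem(series, block_length = ceiling(tau),
                                     n_boot = n_boot, seed = seed)
    sem <- bs$sem
    bl <- bs$block_length
  } else {
    tau <- NA_real_
    sem <- if (sd(series) == 0) 0 else NA_real_
    bl <- NA_integer_
  }
  tibble(ordered_fraction = mean(series), sem = sem, tau = tau,
         block_length = bl, n_frames = length(series))
}

#' Per-frame fraction of residues whose assignment changed
#'
#' Compares each frame's secondary-structure labels with a reference
#' assignment (typically the starting structure).
#'
#' @param labels Character matrix from [assign_ss()].
#' @param reference_labels Character vector, one label per residue.
#' @return Tibble with `frame` and `changed_fraction`.
#' @export
ss_change_fraction <- function(labels, reference_labels) {
  if (length(reference_labels) != ncol(labels)) {
    stop_hd("Reference labels must cover the same residue set.",
            "selection_error")
  }
  ref <- matrix(reference_labels, nrow(labels), ncol(labels), byrow = TRUE)
  tibble(frame = seq_len(nrow(labels)),
         changed_fraction = rowMeans(labels != ref))
}
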