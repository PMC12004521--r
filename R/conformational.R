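# Essential-dynamics comparison: PCA of alpha-carbon motion and the RMSIP
# subspace-overlap statistic; dihedral and interface-map featurizations for
# conformational clustering.

#' Essential subspace from alpha-carbon PCA
#'
#' Aligns every sampled frame to a reference on the alpha-carbons outside an
#' excluded (mobile) region, then eigendecomposes the covariance of the
#' aligned alpha-carbon coordinates. The top `D` orthonormal components span
#' the essential subspace compared across trajectories via [rmsip()].
#'
#' @param traj An [md_trajectory()].
#' @param align_reference Reference coordinates (`n_atoms x 3` matrix or
#'   `md_trajectory`, first frame); default: the first sampled frame.
#' @param exclude Residue numbers (full-protein numbering) left out of the
#'   alignment fit (still included in the PCA).
#' @param stride_ps Sampling interval (default 500 ps = 0.5 ns).
#' @param equilibration_ns Initial time span to discard.
#' @param D Number of components to keep.
#' @return An `essential_subspace`: list with `basis` (`3N x D`, orthonormal
#'   columns), `eigenvalues` (all variances, non-increasing), `D`,
#'   `total_variance`, `n_frames`.
#' @export
pca_essential <- function(traj, align_reference = NULL, exclude = NULL,
                          stride_ps = 500, equilibration_ns = 0, D = 30) {
  frames <- sampled_frames(traj, stride_ps, equilibration_ns)
  if (length(frames) < D) {
    stop_hd(sprintf("Need at least D = %d sampled frames, have %d.",
                    D, length(frames)), "rank_error")
  }
  ca <- which(traj$topology$atom == "CA")
  fit_ca <- ca
  if (!is.null(exclude)) {
    drop_resid <- as.integer(exclude) + traj$numbering_offset
    fit_ca <- ca[!(traj$topology$resid[ca] %in% drop_resid)]
  }
  ref <- if (is.null(align_reference)) {
    frame_coords(traj, frames[1])
  } else if (inherits(align_reference, "md_trajectory")) {
    frame_coords(align_reference, 1)
  } else align_reference
  X <- matrix(0, length(frames), 3 * length(ca))
  for (k in seq_along(frames)) {
    fitted <- kabsch_transform(frame_coords(traj, frames[k]), ref, fit_ca)
    X[k, ] <- as.vector(t(fitted[ca, , drop = FALSE]))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  eigenvalues <- pc$sdev^2
  structure(list(basis = pc$rotation[, seq_len(D), drop = FALSE],
                 eigenvalues = eigenvalues, D = as.integer(D),
                 total_variance = sum(eigenvalues),
                 n_frames = length(frames)),
            class = "essential_subspace")
}

#' @export
print.essential_subspace <- function(x, ...) {
  cat(sprintf("<essential_subspace> D = %d over %d coordinates; top component %.1f%% of variance\n",
              x$D, nrow(x$basis), 100 * x$eigenvalues[1] / x$total_variance))
  invisible(x)
}

#' Root mean square inner product of two essential subspaces
#'
#' `sqrt( (1/D) * sum_ij (u_i . v_j)^2 )` over the first `D` components of
#' each subspace: 1 for identical subspaces, 0 for mutually orthogonal ones.
#'
#' @param U,V `essential_subspace` objects (or bare basis matrices with
#'   orthonormal columns) on the same ambient dimension and same `D`.
#' @return Overlap in \[0, 1\].
#' @export
rmsip <- function(U, V) {
  bu <- if (inherits(U, "essential_subspace")) U$basis else U
  bv <- if (inherits(V, "essential_subspace")) V$basis else V
  if (nrow(bu) != nrow(bv)) {
    stop_hd("Subspaces live in different ambient dimensions.",
            "dimension_error")
  }
  if (ncol(bu) != ncol(bv)) {
    stop_hd("Subspaces keep different numbers of components.",
            "dimension_error")
  }
  sqrt(sum((t(bu) %*% bv)^2) / ncol(bu))
}

#' Backbone dihedral features of a trajectory region
#'
#' Extracts per-frame phi/psi backbone dihedrals (degrees, in (-180, 180\])
#' of the region's residues. Phi is undefined at the chain N-terminus and
#' psi at the C-terminus; only residues with both dihedrals defined
#' contribute, giving `2 x n_complete` features per frame. Pair with the
#' periodic-angular metric in [adp_cluster()].
#'
#' @param traj An [md_trajectory()].
#' @param region Residue numbers (full-protein numbering; `NULL` = all).
#' @param stride_ps,equilibration_ns Sampling controls.
#' @return Numeric matrix `frames x features` with a `metric = "periodic"`
#'   attribute and feature names `phi_<res>` / `psi_<res>`.
#' @export
dihedral_features <- function(traj, region = NULL, stride_ps = NULL,
                              equilibration_ns = 0) {
  frames <- sampled_frames(traj, stride_ps, equilibration_ns)
  topo <- traj$topology
  resids <- sort(unique(topo$resid))
  row_of <- function(res, atom) {
    i <- which(topo$resid == res & topo$atom == atom)
    if (length(i) != 1) NA_integer_ else i
  }
  want <- if (is.null(region)) resids else
    intersect(resids, as.integer(region) + traj$numbering_offset)
  # residues with both dihedrals defined: need prev C and next N
  quads <- list()
  for (res in want) {
    idx <- c(Cm = row_of(res - 1, "C"), N = row_of(res, "N"),
             CA = row_of(res, "CA"), C = row_of(res, "C"),
             Np = row_of(res + 1, "N"))
    if (!anyNA(idx)) quads[[as.character(res)]] <- idx
  }
  if (length(quads) == 0) {
    stop_hd("No region residue has a full backbone with both neighbours.",
            "topology_error")
  }
  out <- matrix(NA_real_, length(frames), 2 * length(quads))
  colnames(out) <- as.vector(rbind(paste0("phi_", names(quads)),
                                   paste0("psi_", names(quads))))
  for (k in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[k])
    for (q in seq_along(quads)) {
      id <- quads[[q]]
      out[k, 2 * q - 1] <- dihedral_angle(xyz[id["Cm"], ], xyz[id["N"], ],
                                          xyz[id["CA"], ], xyz[id["C"], ])
      out[k, 2 * q] <- dihedral_angle(xyz[id["N"], ], xyz[id["CA"], ],
                                      xyz[id["C"], ], xyz[id["Np"], ])
    }
  }
  attr(out, "metric") <- "periodic"
  out
}

#' Flatten interface contact maps into clustering features
#'
#' Stacks a series of integer residue-by-nucleotide contact maps (all the
#' same shape) into an observations-by-cells matrix tagged with the
#' Manhattan (L1) metric, the natural distance between integer contact maps.
#'
#' @param maps List of integer matrices from [dna_contact_map()].
#' @return Numeric matrix `length(maps) x cells` with
#'   `metric = "manhattan"`.
#' @export
interface_map_features <- function(maps) {
  dims <- map(maps, dim)
  if (length(unique(map_chr(dims, paste, collapse = "x"))) != 1) {
    stop_hd("All contact maps must share the same shape.", "shape_error")
  }
  out <- t(vapply(maps, as.vector, numeric(length(maps[[1]]))))
  attr(out, "metric") <- "manhattan"
  out
}

# pairwise distance under the supported metrics
feature_dist <- function(X, metric = c("euclidean", "periodic", "manhattan")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") return(as.matrix(stats::dist(X)))
  if (metric == "manhattan") {
    return(as.matrix(stats::dist(X, method = "manhattan")))
  }
  # periodic-angular: per-coordinate minimal angular difference (degrees),
  # combined as Euclidean
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    d <- abs(sweep(X[(i + 1):n, , drop = FALSE], 2, X[i, ]))
    d <- pmin(d, 360 - d)
    v <- sqrt(rowSums(d^2))
    D[i, (i + 1):n] <- v
    D[(i + 1):n, i] <- v
  }
  D
}
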