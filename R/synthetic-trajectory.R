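# Canonical backbone internal coordinates (Å, degrees). Engh & Huber-style
# values; the generator promises these exactly when noise_sd = 0.
.bb <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.010,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180
)

.helix_phi <- -57
.helix_psi <- -47

#' Specification for a synthetic helix/coil trajectory
#'
#' Bundles every knob of the synthetic backbone-trajectory generator. Frames
#' are drawn independently: with probability `helix_probability` a frame is an
#' ideal alpha-helix (phi = -57 deg, psi = -47 deg), otherwise every residue
#' gets coil dihedrals drawn uniformly from the beta/PPII basin
#' (phi in \[-180, -60\], psi in \[60, 180\]), which never satisfies the
#' helical hydrogen-bond pattern — so the planted helix probability is the
#' exact ordered-fraction ground truth.
#'
#' @param seed Integer RNG seed; same spec + seed gives bit-identical output.
#' @param n_frames Number of frames (>= 1).
#' @param n_residues Number of residues (>= 6).
#' @param helix_probability Per-frame probability of the helical state.
#' @param noise_sd Isotropic Gaussian positional noise, Å.
#' @param planted_contacts List of contact plants, each a list with fields
#'   `i`, `j` (atom row indices), `occurrence` in \[0,1\], `contact_dist` and
#'   `open_dist` (Å). Realized by rigidly displacing atom `j` only.
#' @param ar1_rho Lag-1 autocorrelation used by [gen_ar1()] companions.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_frames = 100L, n_residues = 12L,
                           helix_probability = 0.6, noise_sd = 0,
                           planted_contacts = list(), ar1_rho = 0.9) {
  check_scalar_number(helix_probability, "helix_probability", 0, 1)
  check_scalar_number(noise_sd, "noise_sd", 0)
  check_scalar_number(ar1_rho, "ar1_rho", -1, 1, strict = TRUE)
  if (n_frames < 1) stop_hd("n_frames must be >= 1.", "invalid_spec_error")
  for (pc in planted_contacts) {
    check_scalar_number(pc$occurrence, "planted contact occurrence", 0, 1)
  }
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 n_residues = as.integer(n_residues),
                 helix_probability = helix_probability, noise_sd = noise_sd,
                 planted_contacts = planted_contacts, ar1_rho = ar1_rho),
            class = "synthetic_spec")
}

# Build backbone Cartesian coordinates for one frame from per-residue
# (phi, psi) by sequential internal-coordinate (NeRF) chain construction.
# Returns an atoms x 3 matrix ordered N, H, CA, C, O per residue
# (residue 1 has no amide H).
build_backbone <- function(phi, psi) {
  nres <- length(phi)
  stopifnot(length(psi) == nres, nres >= 2)
  g <- .bb
  N <- CA <- C <- O <- matrix(NA_real_, nres, 3)
  # residue 1 seeded in a canonical local frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  a <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(nres - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                             g$c_n, g$ang_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                              g$n_ca, g$ang_c_n_ca, g$omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                             g$ca_c, g$ang_n_ca_c, phi[i + 1])
    # carbonyl O of residue i: anti to the next amide N across the C=O plane
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$c_o, g$ang_ca_c_o, psi[i] + 180)
  }
  O[nres, ] <- place_atom(N[nres, ], CA[nres, ], C[nres, ],
                          g$c_o, g$ang_ca_c_o, psi[nres] + 180)
  # amide H on the in-plane bisector of the two N bonds, opposite them
  H <- matrix(NA_real_, nres, 3)
  for (i in 2:nres) {
    u <- unit(C[i - 1, ] - N[i, ]) + unit(CA[i, ] - N[i, ])
    H[i, ] <- N[i, ] - g$n_h * unit(u)
  }
  out <- NULL
  for (i in seq_len(nres)) {
    rows <- rbind(N = N[i, ], H = if (i > 1) H[i, ], CA = CA[i, ],
                  C = C[i, ], O = O[i, ])
    out <- rbind(out, rows)
  }
  out
}

backbone_topology <- function(nres, resname = "ALA") {
  rows <- purrr::map(seq_len(nres), function(i) {
    at <- if (i == 1) c("N", "CA", "C", "O") else c("N", "H", "CA", "C", "O")
    tibble(resid = i, resname = resname, atom = at,
           element = substr(at, 1, 1))
  })
  bind_rows(rows)
}

#' Generate a helix/coil backbone trajectory with planted contacts
#'
#' Emits an [md_trajectory()] whose frames switch between an ideal
#' alpha-helical state and a disordered coil state with known probability,
#' optionally carrying planted atom-pair contacts realized at a target
#' occurrence rate. Ground truth (per-frame state and per-contact indicator)
#' is stored in the `ground_truth` attribute for parameter-recovery tests.
#'
#' @param spec A [synthetic_spec()].
#' @param frame_interval_ps Metadata for the resulting trajectory.
#' @return An `md_trajectory` with a `ground_truth` attribute (list with
#'   `helix_state` logical vector and `contact_state` logical matrix).
#' @export
gen_helix_coil_trajectory <- function(spec, frame_interval_ps = 100) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nres <- spec$n_residues
  if (nres < 6) {
    stop_hd("Need at least 6 residues for a meaningful chain.",
            "too_short_error")
  }
  topo <- backbone_topology(nres)
  natoms <- nrow(topo)
  with_seed(spec$seed, {
    helix_state <- runif(spec$n_frames) < spec$helix_probability
    coords <- array(0, dim = c(spec$n_frames, natoms, 3))
    for (f in seq_len(spec$n_frames)) {
      if (helix_state[f]) {
        phi <- rep(.helix_phi, nres)
        psi <- rep(.helix_psi, nres)
      } else {
        phi <- runif(nres, -180, -60)
        psi <- runif(nres, 60, 180)
      }
      coords[f, , ] <- build_backbone(phi, psi)
    }
    if (spec$noise_sd > 0) {
      coords <- coords + array(rnorm(length(coords), 0, spec$noise_sd),
                               dim = dim(coords))
    }
    npc <- length(spec$planted_contacts)
    contact_state <- matrix(FALSE, spec$n_frames, max(1L, npc))
    if (npc > 0) {
      for (k in seq_len(npc)) {
        pc <- spec$planted_contacts[[k]]
        closed <- runif(spec$n_frames) < pc$occurrence
        contact_state[, k] <- closed
        for (f in seq_len(spec$n_frames)) {
          pi_ <- coords[f, pc$i, ]
          pj <- coords[f, pc$j, ]
          dir <- pj - pi_
          if (vnorm(dir) == 0) dir <- c(1, 0, 0)
          d <- if (closed[f]) pc$contact_dist else pc$open_dist
          coords[f, pc$j, ] <- pi_ + d * unit(dir)
        }
      }
    }
    traj <- md_trajectory(coords, topo, frame_interval_ps = frame_interval_ps)
    attr(traj, "ground_truth") <- list(
      helix_state = helix_state,
      contact_state = contact_state[, seq_len(max(1L, npc)), drop = FALSE])
    traj
  })
}
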