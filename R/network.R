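# Frame-wise noncovalent interaction detection, occurrence-weighted protein
# structure networks, network comparison, and protein-DNA interface maps.

#' Geometric parameters for contact and interaction detection
#'
#' @param inner_cutoff Distance (Å) below which an atomic contact counts
#'   fully (weight 1).
#' @param outer_cutoff Distance (Å) beyond which the contact weight is 0; the
#'   weight ramps down smoothly in between.
#' @param salt_bridge_cutoff Distance (Å) between oppositely charged
#'   side-chain group atoms.
#' @param hbond_distance Donor--acceptor heavy-atom distance (Å).
#' @param hbond_angle Minimum donor-H-acceptor angle (degrees).
#' @param hydrophobic_cutoff Distance (Å) between apolar side-chain centers
#'   of mass.
#' @param occurrence_cutoff Fraction of frames above which an edge survives
#'   binarization (strict `>`).
#' @param network_stride_ps Frame sampling interval for network construction.
#' @param switch_fun Smooth switching function used between the inner and
#'   outer cutoffs; any strictly decreasing continuous map of the scaled
#'   distance `t in [0,1]` with `f(0)=1`, `f(1)=0`. Default: cosine ramp.
#' @return A `contact_params` list.
#' @export
contact_params <- function(inner_cutoff = 4, outer_cutoff = 5,
                           salt_bridge_cutoff = 4.5, hbond_distance = 3.5,
                           hbond_angle = 120, hydrophobic_cutoff = 5,
                           occurrence_cutoff = 0.2, network_stride_ps = 100,
                           switch_fun = NULL) {
  if (inner_cutoff >= outer_cutoff) {
    stop_hd("inner_cutoff must be smaller than outer_cutoff.",
            "invalid_spec_error")
  }
  for (v in c(inner_cutoff, outer_cutoff, salt_bridge_cutoff, hbond_distance,
              hydrophobic_cutoff)) {
    check_scalar_number(v, "cutoff", 0, Inf, strict = FALSE)
  }
  check_scalar_number(occurrence_cutoff, "occurrence_cutoff", 0, 1)
  structure(list(inner_cutoff = inner_cutoff, outer_cutoff = outer_cutoff,
                 salt_bridge_cutoff = salt_bridge_cutoff,
                 hbond_distance = hbond_distance, hbond_angle = hbond_angle,
                 hydrophobic_cutoff = hydrophobic_cutoff,
                 occurrence_cutoff = occurrence_cutoff,
                 network_stride_ps = network_stride_ps,
                 switch_fun = switch_fun %||%
                   function(t) 0.5 * (1 + cos(pi * t))),
            class = "contact_params")
}

#' Smooth contact weight of an atomic distance
#'
#' 1 at or below the inner cutoff, 0 at or beyond the outer cutoff, and a
#' continuous strictly decreasing switch in between (cosine ramp by default,
#' so the midpoint distance maps to weight 0.5).
#'
#' @param d Distance(s), Å (non-negative).
#' @param params A [contact_params()].
#' @return Weight(s) in \[0, 1\].
#' @export
contact_weight <- function(d, params = contact_params()) {
  if (any(d < 0)) stop_hd("Distances must be non-negative.", "invalid_spec_error")
  t <- (d - params$inner_cutoff) /
    (params$outer_cutoff - params$inner_cutoff)
  w <- ifelse(t <= 0, 1, ifelse(t >= 1, 0, params$switch_fun(pmin(pmax(t, 0), 1))))
  as.numeric(w)
}

# residue classification tables -------------------------------------------

.charged_groups <- list(
  ARG = list(sign = +1, atoms = c("NH1", "NH2", "NE", "CZ")),
  LYS = list(sign = +1, atoms = "NZ"),
  HIS = list(sign = +1, atoms = c("ND1", "NE2")),
  ASP = list(sign = -1, atoms = c("OD1", "OD2", "CG")),
  GLU = list(sign = -1, atoms = c("OE1", "OE2", "CD"))
)

# representative single atoms of the charged groups, for pairwise
# distance-occurrence queries (Arg zeta carbon, Asp gamma carbon, ...)
.charged_representative <- c(ARG = "CZ", LYS = "NZ", ASP = "CG", GLU = "CD",
                             HIS = "NE2")

.hydrophobic_res <- c("ALA", "VAL", "LEU", "ILE", "PHE", "TRP", "MET", "PRO")

.backbone_atoms <- c("N", "H", "CA", "C", "O", "HA", "OXT")

#' Detect noncovalent interaction edges in one frame
#'
#' Residue-level edges by interaction type, using side-chain geometric
#' criteria: salt bridges are oppositely charged side-chain group atoms
#' within `salt_bridge_cutoff`; hydrogen bonds require a donor--acceptor
#' distance within `hbond_distance` and a donor-H-acceptor angle of at least
#' `hbond_angle` (donors are N/O atoms with an attached hydrogen, acceptors
#' are O atoms or hydrogen-free side-chain nitrogens); hydrophobic contacts
#' are apolar side-chain centers of mass within `hydrophobic_cutoff`.
#' Sequence-adjacent residue pairs are excluded for every type.
#'
#' @param traj An [md_trajectory()].
#' @param frame Frame index.
#' @param type One of `"salt-bridge"`, `"hydrogen-bond"`, `"hydrophobic"`.
#' @param params A [contact_params()].
#' @return Tibble of edges: `i`, `j` (residue ids, construct numbering,
#'   `i < j`), `type`.
#' @export
detect_edges <- function(traj, frame = 1L, type, params = contact_params()) {
  topo <- traj$topology
  xyz <- frame_coords(traj, frame)
  edges <- switch(
    type,
    "salt-bridge" = {
      rows <- which(topo$resname %in% names(.charged_groups) &
                      mapply(function(rn, at) at %in% .charged_groups[[rn]]$atoms,
                             topo$resname, topo$atom))
      if (length(rows) < 2) return(empty_edges(type))
      sign_of <- vapply(topo$resname[rows],
                        function(r) .charged_groups[[r]]$sign, numeric(1))
      pair_edges(xyz[rows, , drop = FALSE], topo$resid[rows],
                 params$salt_bridge_cutoff,
                 compatible = outer(sign_of, sign_of, "*") < 0)
    },
    "hydrogen-bond" = detect_hbond_edges(topo, xyz, params),
    "hydrophobic" = {
      sc <- which(topo$resname %in% .hydrophobic_res &
                    !(topo$atom %in% .backbone_atoms) &
                    topo$element != "H")
      if (length(sc) == 0) return(empty_edges(type))
      coms <- rowsum(xyz[sc, , drop = FALSE], topo$resid[sc]) /
        as.vector(table(topo$resid[sc]))
      resids <- as.integer(rownames(coms))
      if (length(resids) < 2) return(empty_edges(type))
      pair_edges(coms, resids, params$hydrophobic_cutoff)
    },
    stop_hd(sprintf("Unknown interaction type '%s'.", type), "type_error")
  )
  edges$type <- type
  edges
}

empty_edges <- function(type = character(0)) {
  tibble(i = integer(0), j = integer(0),
         type = character(0))
}

# residue pairs whose minimum inter-group atom distance is <= cutoff
pair_edges <- function(xyz, resid, cutoff, compatible = NULL) {
  d <- as.matrix(stats::dist(xyz))
  same <- outer(resid, resid, "==")
  adjacent <- abs(outer(resid, resid, "-")) == 1
  ok <- d <= cutoff & !same & !adjacent
  if (!is.null(compatible)) ok <- ok & compatible
  hit <- which(ok, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_edges())
  pairs <- tibble(i = pmin(resid[hit[, 1]], resid[hit[, 2]]),
                  j = pmax(resid[hit[, 1]], resid[hit[, 2]])) |>
    distinct()
  pairs
}

detect_hbond_edges <- function(topo, xyz, params) {
  heavy <- which(topo$element %in% c("N", "O"))
  hyd <- which(topo$element == "H")
  if (length(heavy) < 2) return(empty_edges())
  # attach hydrogens to their nearest heavy N/O within covalent range
  donors <- list()
  for (h in hyd) {
    dd <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2))
    k <- which.min(dd)
    if (dd[k] <= 1.25) donors[[length(donors) + 1L]] <- c(heavy[k], h)
  }
  if (length(donors) == 0) return(empty_edges())
  don <- do.call(rbind, donors)
  has_h <- unique(don[, 1])
  acceptors <- heavy[topo$element[heavy] == "O" |
                       (topo$element[heavy] == "N" & !(heavy %in% has_h))]
  if (length(acceptors) == 0) return(empty_edges())
  out_i <- integer(0); out_j <- integer(0)
  for (r in seq_len(nrow(don))) {
    dA <- don[r, 1]; hA <- don[r, 2]
    dd <- sqrt(colSums((t(xyz[acceptors, , drop = FALSE]) - xyz[dA, ])^2))
    cand <- acceptors[dd <= params$hbond_distance]
    cand <- cand[topo$resid[cand] != topo$resid[dA] &
                   abs(topo$resid[cand] - topo$resid[dA]) != 1]
    for (a in cand) {
      ang <- angle_at(xyz[dA, ], xyz[hA, ], xyz[a, ])
      if (ang >= params$hbond_angle) {
        out_i <- c(out_i, topo$resid[dA])
        out_j <- c(out_j, topo$resid[a])
      }
    }
  }
  if (length(out_i) == 0) return(empty_edges())
  distinct(tibble(i = pmin(out_i, out_j), j = pmax(out_i, out_j)))
}

#' Occurrence-weighted interaction network over a trajectory
#'
#' Detects the chosen interaction type in every sampled equilibrated frame
#' and weights each residue--residue edge by its occurrence: the fraction of
#' sampled frames in which the interaction is present.
#'
#' @param traj An [md_trajectory()].
#' @param type Interaction type (see [detect_edges()]).
#' @param params A [contact_params()].
#' @param equilibration_ns Initial time span to discard.
#' @return An `interaction_network`: tibble of edges `i`, `j`, `type`,
#'   `occurrence`, with the node set and frame count as attributes.
#' @export
occurrence_network <- function(traj, type, params = contact_params(),
                               equilibration_ns = 0) {
  frames <- sampled_frames(traj, params$network_stride_ps, equilibration_ns)
  counts <- list()
  for (f in frames) {
    e <- detect_edges(traj, f, type, params)
    if (nrow(e) > 0) {
      key <- paste(e$i, e$j, sep = "-")
      for (k in key) counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  nodes <- sort(unique(traj$topology$resid))
  if (length(counts) == 0) {
    edges <- tibble(i = integer(0), j = integer(0), type = character(0),
                    occurrence = numeric(0))
  } else {
    ij <- do.call(rbind, strsplit(names(counts), "-", fixed = TRUE))
    edges <- tibble(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    type = type,
                    occurrence = unname(unlist(counts)) / length(frames)) |>
      arrange(.data$i, .data$j)
  }
  new_interaction_network(edges, nodes, length(frames))
}

new_interaction_network <- function(edges, nodes, n_frames = NA_integer_) {
  structure(edges, nodes = nodes, n_frames = n_frames,
            class = c("interaction_network", class(tibble())))
}

#' Combine per-type networks by maximum occurrence
#'
#' Union of edges over the supplied networks; each edge gets the maximum
#' occurrence among the interaction types in which it appears, and the
#' winning type is recorded.
#'
#' @param ... `interaction_network` objects on the same node set (or one
#'   list of them).
#' @return A combined `interaction_network`.
#' @export
combine_max <- function(...) {
  nets <- list(...)
  if (length(nets) == 1 && !inherits(nets[[1]], "interaction_network")) {
    nets <- nets[[1]]
  }
  node_sets <- map(nets, ~ attr(.x, "nodes"))
  if (length(unique(map_chr(node_sets, paste, collapse = ","))) != 1) {
    stop_hd("Networks must share the same node set.", "merge_error")
  }
  all_edges <- bind_rows(map(nets, as_tibble))
  if (nrow(all_edges) == 0) {
    return(new_interaction_network(all_edges, node_sets[[1]]))
  }
  combined <- all_edges |>
    group_by(.data$i, .data$j) |>
    summarise(type = .data$type[which.max(.data$occurrence)],
              occurrence = max(.data$occurrence),
              .groups = "drop") |>
    select("i", "j", "type", "occurrence") |>
    arrange(.data$i, .data$j)
  new_interaction_network(combined, node_sets[[1]],
                          attr(nets[[1]], "n_frames"))
}

#' Binarize a weighted network at an occurrence cutoff
#'
#' Keeps edges whose occurrence is strictly greater than the cutoff.
#'
#' @param net An `interaction_network`.
#' @param cutoff Occurrence threshold (default 0.2).
#' @return An `interaction_network` whose surviving edges all have
#'   occurrence above the cutoff (weights retained for reference).
#' @export
binarize <- function(net, cutoff = 0.2) {
  out <- filter(as_tibble(net), .data$occurrence > cutoff)
  new_interaction_network(out, attr(net, "nodes"), attr(net, "n_frames"))
}

edge_keys <- function(net) {
  if (nrow(net) == 0) return(character(0))
  paste(pmin(net$i, net$j), pmax(net$i, net$j), sep = "-")
}

#' Jaccard similarity of two unweighted networks
#'
#' Number of common edges divided by the number of edges present in either
#' network. Two empty networks are defined to be identical (similarity 1).
#'
#' @param g1,g2 Binarized `interaction_network` objects (or any edge tibbles
#'   with `i`, `j` columns).
#' @return Similarity in \[0, 1\].
#' @export
jaccard <- function(g1, g2) {
  e1 <- unique(edge_keys(g1))
  e2 <- unique(edge_keys(g2))
  if (length(e1) == 0 && length(e2) == 0) return(1)
  length(intersect(e1, e2)) / length(union(e1, e2))
}

#' Signed occurrence differences between two networks
#'
#' For every edge touching `focus_nodes` (all nodes if `NULL`), the
#' occurrence in `netA` minus the occurrence in `netB`; an edge absent from
#' one network contributes occurrence 0 there.
#'
#' @param netA,netB `interaction_network` objects on the same node labels.
#' @param focus_nodes Optional integer residue ids restricting the edges.
#' @return Tibble: `i`, `j`, `occurrence_a`, `occurrence_b`, `difference`.
#' @export
occurrence_difference <- function(netA, netB, focus_nodes = NULL) {
  a <- as_tibble(netA)[, c("i", "j", "occurrence")]
  b <- as_tibble(netB)[, c("i", "j", "occurrence")]
  merged <- dplyr::full_join(a, b, by = c("i", "j"),
                             suffix = c("_a", "_b")) |>
    mutate(occurrence_a = dplyr::coalesce(.data$occurrence_a, 0),
           occurrence_b = dplyr::coalesce(.data$occurrence_b, 0),
           difference = .data$occurrence_a - .data$occurrence_b) |>
    arrange(.data$i, .data$j)
  if (!is.null(focus_nodes)) {
    merged <- filter(merged, .data$i %in% focus_nodes |
                       .data$j %in% focus_nodes)
  }
  merged
}

#' Fraction of frames in which an atom pair is within a distance
#'
#' @param traj An [md_trajectory()].
#' @param atom_pair List of two `c(resid, atom_name)` pairs (construct
#'   numbering), e.g. `list(c(133, "CZ"), c(47, "CG"))`.
#' @param threshold Distance threshold, Å (strict `<`).
#' @param stride_ps,equilibration_ns Sampling controls.
#' @return Fraction in \[0, 1\].
#' @export
pair_distance_occurrence <- function(traj, atom_pair, threshold,
                                     stride_ps = NULL, equilibration_ns = 0) {
  idx <- vapply(atom_pair, function(p) {
    i <- which(traj$topology$resid == as.integer(p[1]) &
                 traj$topology$atom == p[2])
    if (length(i) != 1) {
      stop_hd(sprintf("Atom %s of residue %s not resolvable.", p[2], p[1]),
              "topology_error")
    }
    i
  }, integer(1))
  frames <- sampled_frames(traj, stride_ps, equilibration_ns)
  d <- vapply(frames, function(f) {
    xyz <- frame_coords(traj, f)
    vnorm(xyz[idx[1], ] - xyz[idx[2], ])
  }, numeric(1))
  mean(d < threshold)
}

#' Protein--DNA interface contact map for one frame
#'
#' Atom-pair contact weights (via [contact_weight()]) summed per
#' residue--nucleotide pair and rounded to the nearest integer.
#'
#' @param traj An [md_trajectory()] containing both molecules.
#' @param frame Frame index.
#' @param protein_resids,nucleotide_resids Residue ids of the two molecules.
#' @param params A [contact_params()].
#' @param common_atoms Optional character vector restricting protein atoms to
#'   those shared across compared systems (mutated residues).
#' @return Integer matrix `protein residues x nucleotides`.
#' @export
dna_contact_map <- function(traj, frame = 1L, protein_resids,
                            nucleotide_resids, params = contact_params(),
                            common_atoms = NULL) {
  topo <- traj$topology
  xyz <- frame_coords(traj, frame)
  p_rows <- which(topo$resid %in% protein_resids & topo$element != "H")
  n_rows <- which(topo$resid %in% nucleotide_resids & topo$element != "H")
  if (!is.null(common_atoms)) {
    p_rows <- p_rows[topo$atom[p_rows] %in% common_atoms |
                       topo$atom[p_rows] %in% .backbone_atoms]
  }
  if (length(p_rows) == 0 || length(n_rows) == 0) {
    stop_hd("Empty protein or nucleotide selection.", "selection_error")
  }
  d2 <- outer(rowSums(xyz[p_rows, , drop = FALSE]^2),
              rowSums(xyz[n_rows, , drop = FALSE]^2), "+") -
    2 * xyz[p_rows, , drop = FALSE] %*% t(xyz[n_rows, , drop = FALSE])
  w <- contact_weight(sqrt(pmax(d2, 0)), params)
  w <- matrix(w, length(p_rows), length(n_rows))
  pr <- sort(unique(topo$resid[p_rows]))
  nr <- sort(unique(topo$resid[n_rows]))
  out <- matrix(0L, length(pr), length(nr), dimnames = list(pr, nr))
  for (a in seq_along(p_rows)) {
    for (b in seq_along(n_rows)) {
      ri <- match(topo$resid[p_rows[a]], pr)
      ci <- match(topo$resid[n_rows[b]], nr)
      out[ri, ci] <- out[ri, ci] + w[a, b]
    }
  }
  round(out)
}
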