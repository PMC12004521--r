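test_that("contact weight is a continuous monotone switch with exact endpoints", {
  p <- contact_params()
  expect_equal(contact_weight(3, p), 1)
  expect_equal(contact_weight(6, p), 0)
  expect_equal(contact_weight(4.5, p), 0.5)
  d <- seq(0, 7, by = 0.01)
  w <- contact_weight(d, p)
  expect_true(all(diff(w) <= 1e-12))
  expect_lt(max(abs(diff(w))), 0.02)  # no jumps: continuity at the cutoffs
  expect_error(contact_weight(-1, p), class = "invalid_spec_error")
  expect_error(contact_params(inner_cutoff = 5, outer_cutoff = 4),
               class = "invalid_spec_error")
})

test_that("DNA contact maps sum atomic weights per residue-nucleotide pair", {
  mk <- function(extra) {
    df <- tibble::tibble(
      resid = c(1L, rep(50L, nrow(extra))),
      resname = c("ALA", rep("DA", nrow(extra))),
      atom = c("CB", sprintf("P%d", seq_len(nrow(extra)))),
      element = c("C", rep("P", nrow(extra))),
      x = c(0, extra$x), y = c(0, extra$y), z = c(0, extra$z))
    frame_from_atoms(df)
  }
  one <- mk(tibble::tibble(x = 3, y = 0, z = 0))
  m <- dna_contact_map(one, 1, protein_resids = 1, nucleotide_resids = 50)
  expect_equal(unname(m[1, 1]), 1)
  three <- mk(tibble::tibble(x = c(3, 0, 0), y = c(0, 3, 0), z = c(0, 0, 3)))
  m3 <- dna_contact_map(three, 1, protein_resids = 1, nucleotide_resids = 50)
  expect_equal(unname(m3[1, 1]), 3)
  far <- mk(tibble::tibble(x = 8, y = 0, z = 0))
  mf <- dna_contact_map(far, 1, protein_resids = 1, nucleotide_resids = 50)
  expect_equal(unname(mf[1, 1]), 0)
  expect_error(dna_contact_map(one, 1, protein_resids = 99,
                               nucleotide_resids = 50),
               class = "selection_error")
})

salt_frame <- function(d) {
  frame_from_atoms(tibble::tibble(
    resid = c(10L, 30L), resname = c("ARG", "ASP"),
    atom = c("CZ", "CG"), element = c("C", "C"),
    x = c(0, d), y = 0, z = 0))
}

test_that("salt bridges obey the 4.5 Å side-chain criterion", {
  e <- detect_edges(salt_frame(4.0), type = "salt-bridge")
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$i, e$j), c(10L, 30L))
  expect_equal(nrow(detect_edges(salt_frame(4.6), type = "salt-bridge")), 0L)
  # like charges never bridge
  same <- frame_from_atoms(tibble::tibble(
    resid = c(10L, 30L), resname = c("ARG", "LYS"),
    atom = c("CZ", "NZ"), element = c("C", "N"),
    x = c(0, 3), y = 0, z = 0))
  expect_equal(nrow(detect_edges(same, type = "salt-bridge")), 0L)
  expect_error(detect_edges(salt_frame(4), type = "pi-stack"),
               class = "type_error")
})

test_that("hydrophobic edges need apolar side chains", {
  gly <- frame_from_atoms(tibble::tibble(
    resid = c(1L, 5L), resname = "GLY", atom = "CA", element = "C",
    x = c(0, 4), y = 0, z = 0))
  expect_equal(nrow(detect_edges(gly, type = "hydrophobic")), 0L)
  leu <- frame_from_atoms(tibble::tibble(
    resid = c(1L, 5L), resname = "LEU", atom = "CD1", element = "C",
    x = c(0, 4), y = 0, z = 0))
  expect_equal(nrow(detect_edges(leu, type = "hydrophobic")), 1L)
})

test_that("hydrogen bonds require distance and angle", {
  hb_frame <- function(dev_deg, r = 1.9) {
    # donor O at origin, H at 1 Å along +x; acceptor at distance r from H,
    # deviating from the straight D-H...A line by dev_deg
    # (donor-H-acceptor angle = 180 - dev_deg)
    a <- dev_deg * pi / 180
    frame_from_atoms(tibble::tibble(
      resid = c(2L, 2L, 40L), resname = c("SER", "SER", "GLU"),
      atom = c("OG", "HG", "OE1"), element = c("O", "H", "O"),
      x = c(0, 1, 1 + r * cos(a)), y = c(0, 0, r * sin(a)), z = 0))
  }
  straight <- detect_edges(hb_frame(0), type = "hydrogen-bond")
  expect_equal(nrow(straight), 1L)
  bent <- detect_edges(hb_frame(120), type = "hydrogen-bond")
  expect_equal(nrow(bent), 0L)
  far <- detect_edges(hb_frame(0, r = 3.2), type = "hydrogen-bond")
  expect_equal(nrow(far), 0L)
})

alternating_traj <- function(n_frames = 10) {
  coords <- array(0, c(n_frames, 2, 3))
  for (f in seq_len(n_frames)) {
    coords[f, 2, 1] <- if (f %% 2 == 0) 4 else 9
  }
  md_trajectory(coords, tibble::tibble(
    resid = c(10L, 30L), resname = c("ARG", "ASP"),
    atom = c("CZ", "CG"), element = "C"), frame_interval_ps = 100)
}

test_that("occurrence networks average detection over sampled frames", {
  tr <- alternating_traj(10)
  net <- occurrence_network(tr, "salt-bridge",
                            contact_params(network_stride_ps = 100))
  expect_equal(net$occurrence, 0.5)
  # contact present in every frame
  always <- tr
  always$coords[, 2, 1] <- 4
  net1 <- occurrence_network(always, "salt-bridge",
                             contact_params(network_stride_ps = 100))
  expect_equal(net1$occurrence, 1.0)
  # networks invariant to frame-order permutation
  perm <- tr
  perm$coords <- tr$coords[sample(10), , , drop = FALSE]
  netp <- occurrence_network(perm, "salt-bridge",
                             contact_params(network_stride_ps = 100))
  expect_equal(netp$occurrence, net$occurrence)
})

mini_net <- function(edges, nodes = 1:10) {
  haplodyn:::new_interaction_network(
    tibble::tibble(i = edges$i, j = edges$j,
                   type = edges$type %||% "salt-bridge",
                   occurrence = edges$occurrence), nodes)
}

test_that("combine_max keeps the maximum occurrence and winning type", {
  n1 <- mini_net(tibble::tibble(i = 1L, j = 5L, occurrence = 0.3,
                                type = "salt-bridge"))
  n2 <- mini_net(tibble::tibble(i = 1L, j = 5L, occurrence = 0.5,
                                type = "hydrogen-bond"))
  n3 <- mini_net(tibble::tibble(i = 1L, j = 5L, occurrence = 0.2,
                                type = "hydrophobic"))
  cm <- combine_max(n1, n2, n3)
  expect_equal(cm$occurrence, 0.5)
  expect_equal(cm$type, "hydrogen-bond")
  # edge present in one network only is preserved
  n4 <- mini_net(tibble::tibble(i = 2L, j = 7L, occurrence = 0.4,
                                type = "hydrophobic"))
  cm2 <- combine_max(n1, n4)
  expect_equal(nrow(cm2), 2L)
  # idempotent
  expect_equal(as.data.frame(combine_max(n1, n1, n1)), as.data.frame(n1))
  # occurrence conservation: combined weight >= every component weight
  expect_true(all(cm$occurrence >= n1$occurrence))
  bad <- haplodyn:::new_interaction_network(tibble::tibble(
    i = 1L, j = 2L, type = "salt-bridge", occurrence = 0.1), nodes = 1:3)
  expect_error(combine_max(n1, bad), class = "merge_error")
})

test_that("binarization keeps only occurrences strictly above the cutoff", {
  net <- mini_net(tibble::tibble(i = c(1L, 2L, 3L), j = c(5L, 6L, 7L),
                                 occurrence = c(0.19, 0.20, 0.21),
                                 type = "salt-bridge"))
  b <- binarize(net, 0.2)
  expect_equal(nrow(b), 1L)
  expect_equal(b$occurrence, 0.21)
  expect_equal(nrow(binarize(net, 0)), 3L)
  empty <- mini_net(tibble::tibble(i = integer(0), j = integer(0),
                                   occurrence = numeric(0),
                                   type = character(0)))
  expect_equal(nrow(binarize(empty)), 0L)
})

test_that("Jaccard similarity follows set identities", {
  g <- function(pairs) mini_net(tibble::tibble(
    i = pairs[, 1], j = pairs[, 2], occurrence = 1, type = "salt-bridge"))
  ab <- g(cbind(1:3, 4:6))
  expect_equal(jaccard(ab, ab), 1)
  cd <- g(cbind(7:8, 9:10))
  expect_equal(jaccard(ab, cd), 0)
  # {a,b,c} vs {b,c,d}: 2 common / 4 union
  g1 <- g(cbind(c(1, 2, 3), c(4, 5, 6)))
  g2 <- g(cbind(c(2, 3, 7), c(5, 6, 8)))
  expect_equal(jaccard(g1, g2), 0.5)
  expect_equal(jaccard(g1, g2), jaccard(g2, g1))
  expect_gte(jaccard(g1, g2), 0)
  expect_lte(jaccard(g1, g2), 1)
  empty <- g(cbind(integer(0), integer(0)))
  expect_equal(jaccard(empty, empty), 1)
})

test_that("occurrence differences use zero-fill and antisymmetry", {
  a <- mini_net(tibble::tibble(i = c(1L, 2L), j = c(5L, 6L),
                               occurrence = c(0.7, 0.4),
                               type = "salt-bridge"))
  b <- mini_net(tibble::tibble(i = 2L, j = 6L, occurrence = 0.1,
                               type = "salt-bridge"))
  d <- occurrence_difference(a, b)
  expect_equal(d$difference[d$i == 1], 0.7)
  expect_equal(d$difference[d$i == 2], 0.3)
  dd <- occurrence_difference(b, a)
  expect_equal(d$difference, -dd$difference)
  expect_equal(occurrence_difference(a, a)$difference, c(0, 0))
  # focus restriction
  df <- occurrence_difference(a, b, focus_nodes = 1L)
  expect_equal(nrow(df), 1L)
})

test_that("pair distance occurrence recovers a planted rate", {
  pc <- list(i = 2L, j = 43L, occurrence = 0.705, contact_dist = 3.5,
             open_dist = 9)
  spec <- synthetic_spec(seed = 12, n_frames = 3000, n_residues = 10,
                         helix_probability = 0.5, noise_sd = 0,
                         planted_contacts = list(pc))
  tr <- gen_helix_coil_trajectory(spec)
  atom_i <- tr$topology[2, ]
  atom_j <- tr$topology[43, ]
  occ <- pair_distance_occurrence(
    tr, list(c(atom_i$resid, atom_i$atom), c(atom_j$resid, atom_j$atom)),
    threshold = 4.5)
  se <- sqrt(0.705 * 0.295 / 3000)
  expect_lt(abs(occ - 0.705), 3 * se)
  # trivial: always below threshold
  expect_equal(pair_distance_occurrence(
    tr, list(c(atom_i$resid, atom_i$atom), c(atom_j$resid, atom_j$atom)),
    threshold = 100), 1.0)
  expect_error(pair_distance_occurrence(tr, list(c(99, "XX"), c(1, "CA")), 4),
               class = "topology_error")
})
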