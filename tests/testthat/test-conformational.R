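oscillating_traj <- function(n_frames = 100, n_res = 8, amp = 2, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(3 * n_res, sd = 4), n_res, 3)
  # a single internal mode: random displacement pattern with the six
  # rigid-body modes (translations, rotations about the centroid) projected
  # out, so superposition cannot absorb the motion
  ctr <- sweep(base, 2, colMeans(base))
  rigid <- cbind(
    rep(c(1, 0, 0), each = n_res), rep(c(0, 1, 0), each = n_res),
    rep(c(0, 0, 1), each = n_res),
    c(rep(0, n_res), -ctr[, 3], ctr[, 2]),
    c(ctr[, 3], rep(0, n_res), -ctr[, 1]),
    c(-ctr[, 2], ctr[, 1], rep(0, n_res)))
  q <- qr.Q(qr(rigid))
  v <- rnorm(3 * n_res)
  v <- v - q %*% (t(q) %*% v)
  v <- v / sqrt(sum(v^2))
  mode <- matrix(v, n_res, 3)
  coords <- array(0, c(n_frames, n_res, 3))
  for (f in seq_len(n_frames)) {
    disp <- amp * sin(2 * pi * f / n_frames)
    coords[f, , ] <- base + disp * mode +
      matrix(rnorm(3 * n_res, sd = 0.005), n_res)
  }
  md_trajectory(coords, tibble::tibble(
    resid = seq_len(n_res), resname = "ALA", atom = "CA", element = "C"),
    frame_interval_ps = 100)
}

test_that("PCA finds a single dominant mode in a 1D oscillation", {
  tr <- oscillating_traj()
  # no alignment fit: pass the first frame as its own reference
  es <- pca_essential(tr, stride_ps = 100, D = 5)
  expect_gt(es$eigenvalues[1] / es$total_variance, 0.99)
  # orthonormal basis
  gram <- t(es$basis) %*% es$basis
  expect_equal(gram, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalues non-increasing
  expect_true(all(diff(es$eigenvalues) <= 1e-12))
  expect_error(pca_essential(tr, stride_ps = 100, D = 200),
               class = "rank_error")
})

test_that("PCA total variance equals the coordinate covariance trace", {
  tr <- oscillating_traj(n_frames = 60, seed = 7)
  es <- pca_essential(tr, stride_ps = 100, D = 3)
  frames <- seq_len(60)
  ref <- matrix(tr$coords[1, , ], ncol = 3)
  X <- t(vapply(frames, function(f) {
    fitted <- haplodyn:::kabsch_transform(matrix(tr$coords[f, , ], ncol = 3),
                                          ref, seq_len(8))
    as.vector(t(fitted))
  }, numeric(24)))
  expect_equal(es$total_variance, sum(apply(X, 2, var)), tolerance = 1e-8)
})

test_that("RMSIP reproduces its analytic values", {
  U <- diag(40)[, 1:30]
  expect_equal(rmsip(U, U), 1)
  V <- diag(40)[, c(31:40, 1:20)]
  # shares exactly 20 axes of 30 -> sqrt(20/30); build the exact 15/30 case
  U15 <- diag(60)[, 1:30]
  V15 <- diag(60)[, 16:45]
  expect_equal(rmsip(U15, V15), sqrt(15 / 30))
  W <- diag(60)[, 31:60]
  expect_equal(rmsip(U15, W), 0)
  expect_equal(rmsip(U15, V15), rmsip(V15, U15))
  expect_error(rmsip(U, diag(42)[, 1:30]), class = "dimension_error")
  expect_error(rmsip(U, diag(40)[, 1:10]), class = "dimension_error")
})

test_that("RMSIP is invariant under re-basis within the span", {
  set.seed(3)
  U <- qr.Q(qr(matrix(rnorm(40 * 10), 40)))[, 1:10]
  V <- qr.Q(qr(matrix(rnorm(40 * 10), 40)))[, 1:10]
  base <- rmsip(U, V)
  R <- qr.Q(qr(matrix(rnorm(100), 10)))  # random orthonormal rotation
  expect_equal(rmsip(U %*% R, V), base, tolerance = 1e-10)
  expect_equal(rmsip(U, V %*% R), base, tolerance = 1e-10)
})

test_that("dihedral features recover planted angles with periodic metric", {
  spec <- synthetic_spec(seed = 4, n_frames = 3, n_residues = 8,
                         helix_probability = 1, noise_sd = 0)
  tr <- gen_helix_coil_trajectory(spec)
  feats <- dihedral_features(tr)
  # interior residues 2..7 have both dihedrals: 12 features
  expect_equal(ncol(feats), 12L)
  phis <- feats[, grepl("^phi", colnames(feats))]
  psis <- feats[, grepl("^psi", colnames(feats))]
  expect_equal(as.numeric(phis), rep(-57, length(phis)), tolerance = 1e-6)
  expect_equal(as.numeric(psis), rep(-47, length(psis)), tolerance = 1e-6)
  expect_equal(attr(feats, "metric"), "periodic")
  # periodic distance: 179 vs -179 differ by 2 degrees, not 358
  X <- rbind(c(179, 0), c(-179, 0))
  D <- haplodyn:::feature_dist(X, "periodic")
  expect_equal(D[1, 2], 2)
})

test_that("interface map features use the Manhattan metric", {
  m1 <- matrix(0L, 2, 3)
  m2 <- m1; m2[1, 1] <- 1L; m2[2, 3] <- 1L
  feats <- interface_map_features(list(m1, m2, m2))
  D <- haplodyn:::feature_dist(feats, "manhattan")
  expect_equal(D[1, 2], 2)
  expect_equal(D[2, 3], 0)
  # triangle inequality on random integer triples
  set.seed(2)
  for (k in 1:20) {
    maps <- lapply(1:3, function(i) matrix(sample(0:3, 6, TRUE), 2))
    Dk <- haplodyn:::feature_dist(interface_map_features(maps), "manhattan")
    expect_lte(Dk[1, 3], Dk[1, 2] + Dk[2, 3] + 1e-12)
  }
  expect_error(interface_map_features(list(m1, matrix(0, 3, 2))),
               class = "shape_error")
})
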