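rand_frame <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 5), n, 3)
}

rigid_motion <- function(xyz, angle = 90, shift = c(5, 5, 5)) {
  th <- angle * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  sweep(xyz %*% t(R), 2, shift, "+")
}

test_that("superposition removes rigid motions exactly", {
  ref <- rand_frame(20)
  expect_equal(superpose(ref, ref)$rmsd, 0)
  moved <- rigid_motion(ref)
  fit <- superpose(moved, ref)
  expect_lt(fit$rmsd, 1e-8)
  # 1 Å displacement on one of N selected atoms -> RMSD = 1/sqrt(N)
  pert <- ref
  pert[1, 1] <- pert[1, 1] + 1
  d <- sqrt(mean(rowSums((pert - ref)^2)))
  expect_equal(d, 1 / sqrt(20))
  # superposition RMSD invariant to rigid motion of the mobile frame
  f1 <- superpose(pert, ref)$rmsd
  f2 <- superpose(rigid_motion(pert, 37, c(-3, 2, 9)), ref)$rmsd
  expect_equal(f1, f2, tolerance = 1e-9)
})

static_traj <- function(n_frames, n_atoms = 10, seed = 2, jitter = 0) {
  base <- rand_frame(n_atoms, seed)
  coords <- array(0, c(n_frames, n_atoms, 3))
  set.seed(seed + 1)
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- base + if (jitter > 0)
      matrix(rnorm(3 * n_atoms, sd = jitter), n_atoms) else 0
  }
  md_trajectory(coords, tibble::tibble(
    resid = seq_len(n_atoms), resname = "ALA", atom = "CA", element = "C"),
    frame_interval_ps = 100)
}

test_that("RMSD series is zero for a static trajectory and exact for known displacement", {
  tr <- static_traj(5)
  ref <- matrix(tr$coords[1, , ], ncol = 3)
  s <- rmsd_series(tr, ref, stride_ps = 100)
  expect_equal(s$rmsd, rep(0, 5), tolerance = 1e-9)
  expect_error(rmsd_series(tr, ref, stride_ps = 50), class = "sampling_error")
  # known displacement: every atom moved by d along x after fit has RMSD 0;
  # instead displace half the atoms by 2 Å and fit on the other half
  coords <- tr$coords
  for (f in 1:5) coords[f, 1:5, 1] <- coords[f, 1:5, 1] + 2
  tr2 <- md_trajectory(coords, tr$topology, frame_interval_ps = 100)
  s2 <- rmsd_series(tr2, ref, selection = region_selection(1:5, "CA"),
                    align_selection = region_selection(6:10, "CA"),
                    stride_ps = 100)
  expect_equal(s2$rmsd, rep(2, 5), tolerance = 1e-9)
})

test_that("RMSF vanishes on static input and recovers isotropic jitter", {
  tr <- static_traj(4)
  expect_error(rmsf(static_traj(1)), class = "undefined_fluctuation_error")
  r <- rmsf(tr, stride_ps = 100)
  expect_true(all(r$rmsf < 1e-9))
  sigma <- 0.3
  trj <- static_traj(600, n_atoms = 20, jitter = sigma)
  rj <- rmsf(trj, stride_ps = 100)
  # isotropic gaussian jitter -> RMSF -> sigma * sqrt(3)
  expect_equal(mean(rj$rmsf), sigma * sqrt(3), tolerance = 0.1)
  # identical replicas -> zero SEM across replicas
  means <- rep(mean(rj$rmsf), 3)
  expect_equal(replica_mean_sem(means)$sem, 0)
})

test_that("kink angle reproduces analytic cases", {
  df <- tibble::tibble(
    resid = 1:3, resname = "ALA", atom = "CA", element = "C",
    x = c(1, 0, 0), y = c(0, 0, 1), z = c(0, 0, 0))
  tr <- frame_from_atoms(df)
  expect_equal(kink_angle(tr, c(1, 2, 3))$angle, 90)
  df2 <- df
  df2$x <- c(-1, 0, 1); df2$y <- 0
  expect_equal(kink_angle(frame_from_atoms(df2), c(1, 2, 3))$angle, 180)
  expect_error(kink_angle(tr, c(1, 2)), class = "selection_error")
  expect_error(kink_angle(tr, c(1, 2, 9)), class = "topology_error")
})

test_that("displacement maps are symmetric, zero-diagonal and constructive", {
  tr <- static_traj(4)
  ref <- matrix(tr$coords[1, , ], ncol = 3)
  m <- displacement_map(tr, ref)
  expect_equal(max(abs(m)), 0, tolerance = 1e-9)
  # move atom 1 away from all others by +2 along its outward direction
  coords <- tr$coords
  others <- colMeans(ref[-1, ])
  dir <- (ref[1, ] - others) / sqrt(sum((ref[1, ] - others)^2))
  for (f in 1:4) coords[f, 1, ] <- coords[f, 1, ] + 40 * dir
  tr2 <- md_trajectory(coords, tr$topology, frame_interval_ps = 100)
  m2 <- displacement_map(tr2, ref)
  expect_true(all(m2[1, -1] > 0))
  expect_equal(m2, t(m2))
  expect_equal(unname(diag(m2)), rep(0, 10))
})
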