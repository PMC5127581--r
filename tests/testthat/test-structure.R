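test_that("superposition handles the identity, pure translation and a hand-built case", {
  set.seed(3)
  ref <- matrix(rnorm(12), 4, 3)
  fit <- kabsch_superpose(ref, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  fit2 <- kabsch_superpose(ref, sweep(ref, 2, c(5, 0, 0), "+"))
  expect_equal(fit2$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit2$translation, c(-5, 0, 0), tolerance = 1e-9)
  expect_equal(fit2$rotation, diag(3), tolerance = 1e-9)

  # rotated copy with one displaced point: agree with the numerical oracle
  mobile <- sweep(ref %*% t(rotation_z(90)), 2, c(1, -2, 0), "+")
  mobile[2, ] <- mobile[2, ] + c(1, 0, 0)
  fit3 <- kabsch_superpose(ref, mobile)
  expect_equal(fit3$rmsd, oracle_rigid_rmsd(ref, mobile), tolerance = 1e-6)
  expect_equal(det(fit3$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition never reflects even when a mirror fit would be better", {
  set.seed(4)
  P <- matrix(rnorm(12), 4, 3)
  fit <- kabsch_superpose(P, -P)           # mirrored set
  o <- oracle_superpose(P, -P)             # bio3d, independent
  expect_equal(fit$rmsd, o$rmsd, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.01)
})

test_that("rmsd series is zero for static or rigidly drifting trajectories", {
  base <- matrix(rnorm(18), 6, 3) * 3
  static <- generate_trajectory(base, n_frames = 5, sigma = 0, seed = 1)
  expect_equal(rmsd_series(static), rep(0, 5), tolerance = 1e-9)
  drifting <- generate_trajectory(base, n_frames = 5, sigma = 0,
                                  drift = list(translation = c(1, 0.5, 0),
                                               angle_deg = 10), seed = 1)
  expect_equal(rmsd_series(drifting), rep(0, 5), tolerance = 1e-6)
  expect_error(rmsd_series(static, selection = "XX"), "empty")
})

test_that("rmsd of a one-atom displacement matches the brute-force rigid oracle", {
  base <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  frames <- list(base, base, base, base)
  frames[[2]][1, 1] <- frames[[2]][1, 1] + 1
  frames[[4]][1, 1] <- frames[[4]][1, 1] - 1
  traj <- trajectory(frames, data.frame(resno = 1:4, resname = "GLY",
                                        atom = "CA"))
  got <- rmsd_series(traj)
  expect_equal(got[c(1, 3)], c(0, 0), tolerance = 1e-9)
  for (f in c(2, 4)) {
    expect_equal(got[f], oracle_rigid_rmsd(base, frames[[f]]),
                 tolerance = 1e-6)
  }
  expect_gt(got[2], 0.3)   # displacement is genuinely penalised
  expect_lt(got[2], 0.5)   # but the best fit beats the no-fit value d/sqrt(n)
})

test_that("rmsd series is invariant to a global rigid transform of all frames", {
  base <- matrix(rnorm(24), 8, 3) * 2
  traj <- generate_trajectory(base, n_frames = 6, sigma = 0.4, seed = 8)
  s0 <- rmsd_series(traj)
  R <- rotation_z(33); t_ <- c(3, 3, -3)
  moved <- traj
  for (f in 1:6)
    moved$xyz[f, , ] <- sweep(matrix(traj$xyz[f, , ], ncol = 3) %*% t(R), 2,
                              t_, "+")
  expect_equal(rmsd_series(moved), s0, tolerance = 1e-6)
})

test_that("rmsf recovers the generating sigma*sqrt(3) and scales linearly", {
  # one probe atom near the centroid of a wide static scaffold: the rigid fit
  # is anchored, so the probe's fluctuation is reported almost unreduced
  set.seed(60)
  anchors <- matrix(rnorm(39 * 3), 39, 3) * 8
  base <- rbind(colMeans(anchors), anchors)
  sig <- c(0.5, rep(0, 39))
  traj <- generate_trajectory(base, n_frames = 2000, sigma = sig, seed = 6)
  rmsf <- rmsf_per_residue(traj, selection = "CA")
  expect_equal(unname(rmsf[1]), 0.5 * sqrt(3), tolerance = 0.05)
  expect_lt(max(rmsf[-1]), 0.1)

  static <- generate_trajectory(base[1:5, ], n_frames = 5, sigma = 0,
                                seed = 1)
  expect_equal(max(rmsf_per_residue(static, "CA")), 0, tolerance = 1e-9)

  # doubling the jitter doubles the fluctuation on the same seed
  small <- base[1:5, ]
  t1 <- generate_trajectory(small, n_frames = 200, sigma = 0.3, seed = 12)
  t2 <- generate_trajectory(small, n_frames = 200, sigma = 0.6, seed = 12)
  r1 <- rmsf_per_residue(t1, "CA")
  r2 <- rmsf_per_residue(t2, "CA")
  expect_equal(unname(r2 / r1), rep(2, 5), tolerance = 2e-2)

  expect_error(rmsf_per_residue(traj, "CA", equilibration_cut = 1999),
               "at least 2 frames")
})

test_that("the equilibration cut discards leading frames", {
  base <- matrix(rnorm(9), 3, 3) * 4
  early <- generate_trajectory(base + 50, n_frames = 3, sigma = 0, seed = 2)
  late <- generate_trajectory(base, n_frames = 10, sigma = 0.2, seed = 2)
  joined <- trajectory(array(c(early$xyz, late$xyz) , c(13, 3, 3)),
                       early$labels)
  joined$xyz[1:3, , ] <- early$xyz
  joined$xyz[4:13, , ] <- late$xyz
  r_cut <- rmsf_per_residue(joined, "CA", equilibration_cut = 3)
  r_ref <- rmsf_per_residue(late, "CA")
  expect_equal(r_cut, r_ref, tolerance = 1e-9)
})

test_that("hydrogen-bond detection follows the distance and angle criteria", {
  labels <- data.frame(resno = c(1, 1, 2), resname = c("SER", "SER", "ASP"),
                       atom = c("OG", "HG", "OD1"))
  # donor O, its H, acceptor 2.8 A away, nearly linear D-H...A
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.8, 0.15, 0))
  ev <- detect_hbonds(xyz, labels, donors = data.frame(donor = "SER1:OG",
                                                       h = "SER1:HG"),
                      acceptors = "ASP2:OD1")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$distance, sqrt(2.8^2 + 0.15^2), tolerance = 1e-9)
  expect_false(ev$h_inferred)

  far <- xyz; far[3, 1] <- 4.5
  expect_equal(nrow(detect_hbonds(far, labels,
                                  data.frame(donor = "SER1:OG",
                                             h = "SER1:HG"),
                                  "ASP2:OD1")), 0L)
  # 90-degree D-H-A angle fails the angle rule even at 3.0 A
  bent <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(0.96, 3.0, 0))
  expect_equal(nrow(detect_hbonds(bent, labels,
                                  data.frame(donor = "SER1:OG",
                                             h = "SER1:HG"),
                                  "ASP2:OD1")), 0L)
  # without the hydrogen: stricter distance-only cutoff, flagged
  ev2 <- detect_hbonds(xyz, labels, donors = "SER1:OG",
                       acceptors = "ASP2:OD1")
  expect_equal(nrow(ev2), 1L)
  expect_true(ev2$h_inferred)
  expect_equal(nrow(detect_hbonds(far, labels, "SER1:OG", "ASP2:OD1")), 0L)
  expect_error(detect_hbonds(xyz, labels, "SER9:XX", "ASP2:OD1"),
               "unknown atom label")
})

test_that("hydrogen-bond occupancy counts the toggling fraction of frames", {
  labels <- data.frame(resno = c(1, 2), resname = c("SER", "ASP"),
                       atom = c("OG", "OD1"))
  near <- rbind(c(0, 0, 0), c(2.8, 0, 0))
  far <- rbind(c(0, 0, 0), c(6, 0, 0))
  frames <- rep(list(near, far), 5)
  traj <- trajectory(frames, labels)
  occ <- hbond_occupancy(traj, data.frame(donor = "SER1:OG",
                                          acceptor = "ASP2:OD1"))
  expect_equal(occ$occupancy, 0.5)
  always <- trajectory(rep(list(near), 4), labels)
  expect_equal(hbond_occupancy(always, data.frame(
    donor = "SER1:OG", acceptor = "ASP2:OD1"))$occupancy, 1.0)
  never <- trajectory(rep(list(far), 4), labels)
  expect_equal(hbond_occupancy(never, data.frame(
    donor = "SER1:OG", acceptor = "ASP2:OD1"))$occupancy, 0.0)
})

test_that("multi-model PDB round-trips a trajectory", {
  base <- matrix(rnorm(15), 5, 3) * 5
  traj <- generate_trajectory(base, n_frames = 4, sigma = 0.3, seed = 44)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(dim(back$xyz), dim(traj$xyz))
  expect_lt(max(abs(back$xyz - traj$xyz)), 1e-3 + 1e-9)
  expect_equal(back$labels$resno, traj$labels$resno)
})
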