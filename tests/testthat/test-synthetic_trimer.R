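# Trimer builder and planted-motion generators.

test_that("build_trimer: counts, determinism, three-fold symmetry", {
  spec <- trimer_spec(beads_per_subdomain = 12, seed = 5)
  built <- build_trimer(spec)
  expect_identical(n_atoms(built$model), 21L * 12L)
  expect_identical(nrow(partition_units(built$partition)), 21L)
  # deterministic
  built2 <- build_trimer(spec)
  expect_identical(built$model$xyz, built2$model$xyz)
  # monomer B = monomer A rotated 120 degrees about z
  iA <- which(built$model$monomer == "A")
  iB <- which(built$model$monomer == "B")
  rotA <- built$model$xyz[iA, ] %*% t(rot_z(120))
  expect_lt(sqrt(mean(rowSums((rotA - built$model$xyz[iB, ])^2))), 1e-6)
  # membrane convention: TM below z = 0, porter/docking above
  tm <- partition_atoms(built$partition, built$model, "TM")
  expect_true(all(built$model$xyz[tm, 3] < 0))
  expect_true(all(built$model$xyz[-tm, 3] > 0))
  # validation errors
  expect_error(trimer_spec(beads_per_subdomain = 9), ">= 10")
  expect_error(trimer_spec(aspect = 1.5), ">= 2")
})

test_that("make_target_conformation: identity, global rotation, planted rotation", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 1))
  model <- built$model; part <- built$partition
  # zero motion: target equals start
  m0 <- planted_motion(seed = 1)
  expect_identical(make_target_conformation(model, part, m0)$xyz, model$xyz)
  # pure 120-degree whole-trimer rotation permutes the monomers
  mg <- planted_motion(global_rot_z = 120, seed = 1)
  tgt <- make_target_conformation(model, part, mg)
  iA <- which(model$monomer == "A"); iB <- which(model$monomer == "B")
  expect_lt(sqrt(mean(rowSums((tgt$xyz[iA, ] - model$xyz[iB, ])^2))), 1e-6)
  # planted 20-degree rotation: RMSD(start, target) equals the direct norm
  mr <- planted_motion(rotations = data.frame(monomer = "B", group = "PC2",
                                              dphi = 20, dtheta = 0), seed = 1)
  tgt <- make_target_conformation(model, part, mr)
  i <- partition_atoms(part, model, "PC2", "B")
  direct <- sqrt(mean(rowSums((tgt$xyz - model$xyz)^2)))
  expect_gt(direct, 0)
  expect_equal(rmsd_raw(tgt$xyz, model$xyz), direct, tolerance = 1e-12)
  expect_true(all(tgt$xyz[-i, ] == model$xyz[-i, ]))
})

test_that("rigid-body trajectories preserve internal distances and endpoints", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 1))
  motion <- planted_motion(
    rotations = data.frame(monomer = "A", group = "PN1", dphi = 20, dtheta = 10),
    translations = data.frame(monomer = "A", group = "DN",
                              dx = 1, dy = 0, dz = 0),
    n_frames = 6, noise = 0.05, seed = 9)
  traj <- generate_rigid_body_trajectory(built$model, built$partition, motion)
  expect_identical(n_frames(traj), 6L)
  # zero planted motion: every frame equals frame 1 up to the noise scale
  m0 <- planted_motion(n_frames = 4, noise = 0.05, seed = 2)
  t0 <- generate_rigid_body_trajectory(built$model, built$partition, m0)
  dev <- max(abs(t0$coords[, , 4] - t0$coords[, , 1]))
  expect_lt(dev, 6 * 0.05 * 2)
  # intra-subdomain pairwise distances preserved within the noise
  i <- partition_atoms(built$partition, built$model, "PN1", "A")
  d1 <- dist(traj$coords[i, , 1])
  d6 <- dist(traj$coords[i, , 6])
  expect_lt(max(abs(d1 - d6)), 10 * 0.05)  # each distance moves ~ noise * sqrt(2)
  # determinism
  traj2 <- generate_rigid_body_trajectory(built$model, built$partition, motion)
  expect_identical(traj$coords, traj2$coords)
})

test_that("fluctuation generator: null, planted block and phase-coupled pairs", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 1))
  model <- built$model; part <- built$partition
  # r = 0 everywhere: sample Pearson between any planted pair within +-0.08
  m0 <- planted_motion(sigma = 1.5, n_frames = 2000, seed = 21)
  t0 <- generate_fluctuation_trajectory(model, part, m0)
  i <- partition_atoms(part, model, "DN", "B")[1]
  j <- partition_atoms(part, model, "PC2", "B")[1]
  di <- t(t0$coords[i, , ]) - matrix(colMeans(t(t0$coords[i, , ])), 2000, 3, byrow = TRUE)
  dj <- t(t0$coords[j, , ]) - matrix(colMeans(t(t0$coords[j, , ])), 2000, 3, byrow = TRUE)
  r0 <- sum(di * dj) / sqrt(sum(di^2) * sum(dj^2))
  expect_lt(abs(r0), 0.08)
  # planted r = 0.9 block: sample Pearson within 0.9 +- 0.05 (brute force)
  mb <- planted_motion(blocks = list(list(a = "B.DN", b = "B.PC2", r = 0.9)),
                       sigma = 1.5, n_frames = 2000, seed = 22)
  tb <- generate_fluctuation_trajectory(model, part, mb)
  sel <- c(partition_atoms(part, model, "DN", "B")[1:3],
           partition_atoms(part, model, "PC2", "B")[1:3])
  P <- oracle_pearson(tb$coords[sel, , , drop = FALSE])
  offdiag <- P[upper.tri(P)]
  expect_true(all(abs(offdiag - 0.9) < 0.05))
  # phase-coupled pair: |Pearson| < 0.2 by construction
  i1 <- partition_atoms(part, model, "PN1", "B")[1]
  j1 <- partition_atoms(part, model, "PC1", "B")[1]
  mn <- planted_motion(nonlinear = data.frame(i = i1, j = j1),
                       sigma = 1.5, n_frames = 2000, seed = 23)
  tn <- generate_fluctuation_trajectory(model, part, mn)
  P2 <- oracle_pearson(tn$coords[c(i1, j1), , , drop = FALSE])
  expect_lt(abs(P2[1, 2]), 0.2)
  # validation: overlapping blocks and |r| > 1 are rejected
  expect_error(planted_motion(blocks = list(list(a = "B.DN", b = "B.PC2", r = 1.2))),
               "positive semi-definite")
  bad <- planted_motion(blocks = list(list(a = "B.DN", b = "B.PC2", r = 0.5),
                                      list(a = "B.DN", b = "B.PN2", r = 0.5)))
  expect_error(generate_fluctuation_trajectory(model, part, bad), "block 2")
})

test_that("sample correlation error shrinks roughly as n^(-1/2)", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 1))
  model <- built$model; part <- built$partition
  errs <- vapply(c(200, 2000, 20000), function(nf) {
    m <- planted_motion(blocks = list(list(a = "B.DN", b = "B.PC2", r = 0.6)),
                        sigma = 1, n_frames = nf, seed = 31)
    tr <- generate_fluctuation_trajectory(model, part, m)
    i <- partition_atoms(part, model, "DN", "B")[1:3]
    j <- partition_atoms(part, model, "PC2", "B")[1:3]
    P <- oracle_pearson(tr$coords[c(i, j), , , drop = FALSE])
    mean(abs(P[1:3, 4:6] - 0.6))   # mean error over 9 planted pairs
  }, 0)
  # each 10x increase in n should shrink the error substantially
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("ring twist plants recoverable Phi angles", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 1))
  motion <- planted_motion(
    ring_twist = data.frame(group = c("PN1", "PC2"), psi = c(15, 15)),
    n_frames = 3, noise = 0, seed = 1)
  traj <- generate_rigid_body_trajectory(built$model, built$partition, motion)
  ang <- orientation_angles(traj, built$partition, built$model, align = FALSE)
  fin <- ang[ang$frame == 3, ]
  expect_equal(fin$phi[fin$group %in% c("PN1", "PC2")], rep(15, 6),
               tolerance = 0.5)
  expect_lt(max(abs(fin$phi[!fin$group %in% c("PN1", "PC2")])), 0.5)
})
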