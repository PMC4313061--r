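# Superposition, principal axes, orientation angles, running averages,
# porcupine vectors.

test_that("kabsch_superpose recovers exact rigid motions and matches Horn", {
  set.seed(10)
  x <- matrix(rnorm(15, sd = 4), 5, 3)
  # identity
  id <- kabsch_superpose(x, x)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$R, diag(3), tolerance = 1e-8)
  # exact rigid motion: 90 degrees about z plus translation
  y <- x %*% t(rot_z(90)) + matrix(c(3, -2, 7), 5, 3, byrow = TRUE)
  fit <- kabsch_superpose(y, x)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$R, t(rot_z(90)), tolerance = 1e-8)
  # random noisy pairs match the independent Horn quaternion oracle
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(rnorm(15, sd = 3), 5, 3)
    b <- matrix(rnorm(15, sd = 3), 5, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, oracle_rmsd_horn(a, b),
                 tolerance = 1e-6)
  }
})

test_that("kabsch_superpose rejects degenerate selections", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear|degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 beads")
})

test_that("principal_axis matches a closed-form 3x3 eigensolver", {
  set.seed(11)
  for (rep in 1:5) {
    cloud <- cbind(rnorm(40, sd = 6), rnorm(40, sd = 2), rnorm(40, sd = 0.8))
    R <- rot_axis(rnorm(3), runif(1, 0, 180))
    cloud <- cloud %*% t(R)
    a <- principal_axis(cloud)
    I3 <- inertia_tensor(cloud)
    ev <- oracle_eigen3_values(I3)
    # axis satisfies I a = lambda_min a with the oracle's smallest eigenvalue
    expect_equal(as.numeric(I3 %*% a), ev[3] * a, tolerance = 1e-6)
  }
})

test_that("principal_axis conventions: rods, rotations, degeneracy", {
  rod <- cbind(seq(-5, 5, length.out = 20), rnorm(20, sd = 0.3),
               rnorm(20, sd = 0.15))
  a <- principal_axis(rod)
  expect_gt(abs(a[1]), 0.99)            # long axis ~ x
  # rigid 30-degree in-plane rotation rotates the axis by 30 degrees
  a2 <- principal_axis(rod %*% t(rot_z(30)))
  ang <- acos(min(1, abs(sum(a * a2))))
  expect_equal(ang * 180 / pi, 30, tolerance = 0.5)
  # exactly symmetric cloud (cube corners) is rejected as degenerate
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_error(principal_axis(cube), "degenerate")
})

test_that("orientation_angles recovers planted in-plane and tilt rotations", {
  rod <- cbind(seq(-6, 6, length.out = 25), rnorm(25, sd = 0.4),
               rnorm(25, sd = 0.2))
  part <- subdomain_partition(data.frame(group = "R", monomer = "A",
                                         start = 1, end = 25))
  model <- structure_model(rod)
  mk <- function(Rm) trajectory(list(rod, rod %*% t(Rm)))
  # 20 degrees about z: Phi = 20, Theta ~ 0
  ang <- orientation_angles(mk(rot_z(20)), part, model, align = FALSE)
  expect_equal(ang$phi[2], 20, tolerance = 0.5)
  expect_equal(ang$theta[2], 0, tolerance = 0.5)
  # 10-degree tilt toward +z: Theta = +10, Phi ~ 0
  a0 <- principal_axis(rod)
  w <- c(-a0[2], a0[1], 0); w <- w / sqrt(sum(w^2))
  ang <- orientation_angles(mk(rot_axis(w, -10)), part, model, align = FALSE)
  expect_equal(ang$theta[2], 10, tolerance = 0.5)
  expect_equal(ang$phi[2], 0, tolerance = 0.5)
  # no rotation: both zero
  ang <- orientation_angles(mk(diag(3)), part, model)
  expect_true(all(abs(ang$phi) < 1e-6 & abs(ang$theta) < 1e-6))
})

test_that("geometric series are invariant under global rigid motion", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 2))
  motion <- planted_motion(
    rotations = data.frame(monomer = "B", group = "PC2", dphi = 15, dtheta = 5),
    n_frames = 4, noise = 0, seed = 3)
  traj <- generate_rigid_body_trajectory(built$model, built$partition, motion,
                                         n_frames = 4)
  # membrane-preserving global rigid motion (rotation about the membrane
  # normal + translation); Phi/Theta are defined against the z axis, so this
  # is the class of motions they are exactly invariant under
  R <- rot_z(35)
  coords2 <- traj$coords
  for (f in 1:4) coords2[, , f] <- traj$coords[, , f] %*% t(R) +
      matrix(c(5, -8, 11), dim(coords2)[1], 3, byrow = TRUE)
  traj2 <- trajectory(coords2)
  a1 <- orientation_angles(traj, built$partition, built$model)
  a2 <- orientation_angles(traj2, built$partition, built$model)
  expect_equal(a2$phi, a1$phi, tolerance = 1e-5)
  expect_equal(a2$theta, a1$theta, tolerance = 1e-5)
  c1 <- com_displacement_series(traj, built$partition, built$model)
  c2 <- com_displacement_series(traj2, built$partition, built$model)
  expect_equal(c2$mag, c1$mag, tolerance = 1e-6)
})

test_that("com_displacement_series recovers a planted translation", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 2))
  motion <- planted_motion(
    translations = data.frame(monomer = "A", group = "PN2",
                              dx = 1, dy = 0, dz = 0),
    n_frames = 2, noise = 0, seed = 1)
  traj <- generate_rigid_body_trajectory(built$model, built$partition, motion,
                                         n_frames = 2)
  ser <- com_displacement_series(traj, built$partition, built$model)
  fin <- ser[ser$frame == 2, ]
  moved <- fin$mag[fin$monomer == "A" & fin$group == "PN2"]
  expect_equal(moved, 1, tolerance = 0.1)
  expect_lt(max(fin$mag[!(fin$monomer == "A" & fin$group == "PN2")]), 0.25)
  # static trajectory: all zero
  tstat <- trajectory(list(built$model$xyz, built$model$xyz))
  ser0 <- com_displacement_series(tstat, built$partition, built$model)
  expect_true(all(ser0$mag < 1e-10))
})

test_that("subdomain_rmsd_series: zeros on target, matches direct computation", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 2))
  tgt <- built$model
  traj <- trajectory(list(tgt$xyz, tgt$xyz, tgt$xyz))
  ser <- subdomain_rmsd_series(traj, built$partition, built$model, tgt)
  expect_true(all(ser$rmsd < 1e-10))
})

test_that("running_average is a trailing mean with prefix shrinkage", {
  expect_equal(running_average(1:10, 3)[5], mean(3:5))      # hand computation
  expect_equal(running_average(rep(7, 20), 20), rep(7, 20)) # constant
  expect_identical(running_average(c(4, 2, 9), 1), c(4, 2, 9)) # window 1
  expect_equal(running_average(1:4, 4), c(1, 1.5, 2, 2.5))  # prefix shrinkage
  expect_error(running_average(1:3, 4), "exceeds")
  # matches a literal loop implementation
  set.seed(5)
  x <- rnorm(30)
  ref <- vapply(seq_along(x), function(t) mean(x[max(1, t - 19):t]), 0)
  expect_equal(running_average(x, 20), ref, tolerance = 1e-12)
})

test_that("porcupine_vectors report displacements and axis motion", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 2))
  model <- built$model
  # identical structures: all zero
  pv0 <- porcupine_vectors(model, model, built$partition)
  expect_true(all(abs(c(pv0$vectors$dx, pv0$vectors$dy, pv0$vectors$dz)) < 1e-10))
  expect_true(all(pv0$axes$angle_deg < 1e-5))
  # planted subdomain rotation: the axis rod pair encloses the planted angle
  motion <- planted_motion(
    rotations = data.frame(monomer = "B", group = "PC2", dphi = 20, dtheta = 0),
    noise = 0, seed = 1)
  tgt <- make_target_conformation(model, built$partition, motion)
  pv <- porcupine_vectors(model, tgt, built$partition)
  got <- pv$axes$angle_deg[pv$axes$monomer == "B" & pv$axes$group == "PC2"]
  expect_equal(got, 20, tolerance = 1)
  # export writes a TSV and a two-model PDB
  tsv <- tempfile(fileext = ".tsv"); pdb <- tempfile(fileext = ".pdb")
  write_porcupine(pv, model, tsv, pdb)
  expect_identical(nrow(utils::read.table(tsv, header = TRUE, sep = "\t")),
                   n_atoms(model))
  expect_identical(n_frames(read_trajectory(pdb, "pdb")), 2L)
})

test_that("RMSD triangle inequality holds on superposed structures", {
  set.seed(77)
  A <- matrix(rnorm(30, sd = 3), 10, 3)
  B <- A + matrix(rnorm(30, sd = 1), 10, 3)
  C <- A + matrix(rnorm(30, sd = 2), 10, 3)
  ab <- kabsch_superpose(B, A)$rmsd
  bc <- kabsch_superpose(C, B)$rmsd
  ac <- kabsch_superpose(C, A)$rmsd
  expect_lte(ac, ab + bc + 1e-10)
})
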