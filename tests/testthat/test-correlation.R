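# RMSF, Pearson and generalized correlation, filters, block summaries,
# structure mapping.

test_that("compute_rmsf: zeros, closed form, brute-force agreement", {
  # static trajectory
  m <- tiny_model(n = 5)
  expect_true(all(compute_rmsf(trajectory(list(m$xyz, m$xyz))) < 1e-12))
  # isotropic Gaussian displacements, sigma = 1 per axis: RMSF = sqrt(3)
  set.seed(40)
  disp <- lapply(seq_len(5000), function(f) matrix(rnorm(15), 5, 3))
  traj <- displacement_trajectory(disp, base = m$xyz)
  rmsf <- compute_rmsf(traj, align = FALSE)
  expect_true(all(abs(rmsf - sqrt(3)) < 0.05))
  # arbitrary trajectory matches the two-pass brute force
  tr <- random_trajectory(n_atoms = 10, n_frames = 40, seed = 41)
  got <- compute_rmsf(tr, align = FALSE)
  ref <- vapply(1:10, function(i) {
    d <- t(tr$coords[i, , ])
    mu <- colMeans(d)
    sqrt(mean(rowSums(sweep(d, 2, mu)^2)))
  }, 0)
  expect_equal(got, ref, tolerance = 1e-10)
  expect_error(compute_rmsf(trajectory(list(m$xyz))), "2 frames")
})

test_that("pearson_matrix: exact cases and brute-force equality", {
  # bead j moves identically to bead i -> rho = 1; mirrored -> rho = -1
  set.seed(42)
  d <- matrix(rnorm(3 * 200), 200, 3)
  coords <- array(0, c(3, 3, 200))
  for (f in 1:200) {
    coords[1, , f] <- d[f, ]
    coords[2, , f] <- c(15, 0, 0) + d[f, ]
    coords[3, , f] <- c(0, 15, 0) - d[f, ]
  }
  res <- pearson_matrix(trajectory(coords), align = FALSE)
  expect_equal(res$matrix[1, 2], 1, tolerance = 1e-12)
  expect_equal(res$matrix[1, 3], -1, tolerance = 1e-12)
  expect_true(all(diag(res$matrix) == 1))
  # random 20-bead, 500-frame trajectory equals the double loop to 1e-10
  tr <- random_trajectory(n_atoms = 20, n_frames = 500, seed = 43)
  got <- pearson_matrix(tr, align = FALSE)
  ref <- oracle_pearson(tr$coords)
  expect_lt(max(abs(got$matrix - ref)), 1e-10)
  # zero-variance bead gets NA row/column with a warning
  coords2 <- tr$coords
  coords2[5, , ] <- coords2[5, , 1]
  expect_warning(res2 <- pearson_matrix(trajectory(coords2), align = FALSE),
                 "zero-variance")
  expect_true(all(is.na(res2$matrix[5, -5])))
})

test_that("generalized_matrix: saturation, independence, Gaussian recovery", {
  # identical beads saturate the transform
  set.seed(44)
  d <- matrix(rnorm(3 * 4000), 4000, 3)
  coords <- array(0, c(2, 3, 4000))
  for (f in 1:4000) {
    coords[1, , f] <- d[f, ]
    coords[2, , f] <- c(15, 0, 0) + d[f, ]
  }
  res <- generalized_matrix(trajectory(coords), align = FALSE, seed = 1)
  expect_gte(res$matrix[1, 2], 0.99)
  # independent beads: mean rho_gen below 0.1 over seeds
  vals <- vapply(1:6, function(s) {
    tr <- gauss_pair_traj(800, r = 0, seed = 100 + s)
    generalized_matrix(tr, align = FALSE, seed = s)$matrix[1, 2]
  }, 0)
  expect_lt(mean(vals), 0.1)
  # jointly Gaussian pair with r = 0.8 recovers rho_gen ~ 0.8
  tr <- gauss_pair_traj(2000, r = 0.8, seed = 50)
  g <- generalized_matrix(tr, align = FALSE, seed = 2)
  expect_equal(g$matrix[1, 2], 0.8, tolerance = 0.05)
  # deterministic given seed
  g2 <- generalized_matrix(tr, align = FALSE, seed = 2)
  expect_identical(g$matrix, g2$matrix)
  expect_error(generalized_matrix(random_trajectory(n_frames = 5), knn_k = 6),
               "knn_k")
})

test_that("C++ KSG estimator agrees with the pure-R reference", {
  set.seed(45)
  n <- 150
  a <- matrix(rnorm(3 * n), n, 3)
  b <- 0.7 * a + sqrt(1 - 0.49) * matrix(rnorm(3 * n), n, 3)
  got <- domainflux:::ksg_mi_pairs_cpp(cbind(a, b), matrix(c(1L, 2L), 1), 6L)
  ref <- oracle_ksg_mi(a, b, k = 6)
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("apply_filters semantics and monotonicity", {
  # synthetic correlation result
  set.seed(46)
  n <- 8
  M <- matrix(runif(n * n, -1, 1), n, n)
  M <- (M + t(M)) / 2; diag(M) <- 1
  rmsf <- c(2, 2, 1.4, 2, 0.5, 2, 2, 2)
  res <- structure(list(matrix = M, method = "pearson", rmsf = rmsf,
                        selection = 1:n, keys = as.character(1:n),
                        rmsf_threshold = 1.5, corr_threshold = 0.5,
                        knn_k = NA_integer_),
                   class = "correlation_result")
  pairs <- apply_filters(res)
  # both-members rule: any pair touching residues 3 (1.4 A) or 5 is excluded
  expect_false(any(pairs$i %in% c(3, 5) | pairs$j %in% c(3, 5)))
  expect_true(all(abs(pairs$value) >= 0.5))
  # either-member rule readmits pairs with one mobile residue
  pairs_e <- apply_filters(res, rmsf_rule = "either")
  expect_gte(nrow(pairs_e), nrow(pairs))
  # raising a threshold never adds pairs
  stricter <- apply_filters(res, corr_threshold = 0.7)
  expect_true(all(paste(stricter$i, stricter$j) %in% paste(pairs$i, pairs$j)))
  # all below threshold -> empty
  resl <- res; resl$matrix[upper.tri(M)] <- 0.2
  resl$matrix[lower.tri(M)] <- t(resl$matrix)[lower.tri(M)]
  expect_identical(nrow(apply_filters(resl)), 0L)
})

test_that("block_summary recovers planted blocks and nulls", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 1))
  model <- built$model; part <- built$partition
  motion <- planted_motion(blocks = list(list(a = "B.DN", b = "B.PC2", r = 0.9)),
                           sigma = 2, n_frames = 2000, seed = 60)
  traj <- generate_fluctuation_trajectory(model, part, motion)
  res <- pearson_matrix(traj, align = FALSE, model = model)
  bs <- block_summary(res, part, model)
  blk <- bs[bs$group_a == "B.DN" & bs$group_b == "B.PC2", ]
  expect_gte(blk$mean, 0.8)
  null_blk <- bs[bs$group_a == "A.PN1" & bs$group_b == "C.PC1", ]
  expect_identical(null_blk$n_above, 0L)
  # identity-correlated duplicate group: mean = max = 1
  dup <- bs[bs$group_a == "B.DN" & bs$group_b == "B.DN", ]
  expect_lt(abs(dup$mean - 0.9), 0.05)
  expect_identical(nrow(bs), 576L)   # all unit and monomer blocks
})

test_that("map_to_structure counts partners and recovers planted membership", {
  built <- build_trimer(trimer_spec(beads_per_subdomain = 12, seed = 1))
  model <- built$model; part <- built$partition
  motion <- planted_motion(blocks = list(list(a = "B.DN", b = "B.PC2", r = 0.9)),
                           sigma = 2, n_frames = 2000, seed = 61)
  traj <- generate_fluctuation_trajectory(model, part, motion)
  res <- pearson_matrix(traj, align = FALSE, model = model)
  pairs <- apply_filters(res)
  path <- tempfile(fileext = ".pdb")
  vals <- map_to_structure(pairs, res, model, mode = "count", path = path)
  annotated <- which(vals > 0)
  planted <- sort(c(partition_atoms(part, model, "DN", "B"),
                    partition_atoms(part, model, "PC2", "B")))
  jaccard <- length(intersect(annotated, planted)) /
    length(union(annotated, planted))
  expect_gte(jaccard, 0.9)
  # annotation written to the B-factor column
  m2 <- read_structure(path)
  expect_equal(m2$bfactor, round(vals, 2), tolerance = 0.01)
  # single pair -> residues i and j carry 1
  one <- pairs[1, , drop = FALSE]
  v1 <- map_to_structure(one, res, model, mode = "count")
  expect_identical(sum(v1), 2)
  # empty list -> all zero
  v0 <- map_to_structure(pairs[0, , drop = FALSE], res, model)
  expect_true(all(v0 == 0))
})
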