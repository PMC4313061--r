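# Fixtures built in code; the default study is expensive and shared between
# the pipeline and acceptance tests, so it is cached per session.

tiny_model <- function(n = 6, seed = 42, spread = 5) {
  set.seed(seed)
  structure_model(matrix(rnorm(3 * n, sd = spread), n, 3))
}

# small three-chain model: 3 monomers x nres beads on separated blobs
three_chain_model <- function(nres = 10, seed = 7) {
  set.seed(seed)
  xyz <- do.call(rbind, lapply(0:2, function(k)
    matrix(rnorm(3 * nres, sd = 2), nres, 3) +
      matrix(c(20 * k, 0, 0), nres, 3, byrow = TRUE)))
  structure_model(xyz,
                  residue_index = rep(seq_len(nres), 3),
                  monomer = rep(c("A", "B", "C"), each = nres))
}

random_trajectory <- function(n_atoms = 10, n_frames = 50, seed = 1, sd = 1) {
  set.seed(seed)
  base <- matrix(rnorm(3 * n_atoms, sd = 8), n_atoms, 3)
  coords <- array(0, c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- base + matrix(rnorm(3 * n_atoms, sd = sd), n_atoms, 3)
  }
  trajectory(coords, dt = 1)
}

# trajectory with prescribed per-frame displacements about a base structure
displacement_trajectory <- function(disp_list, base = NULL) {
  n <- nrow(disp_list[[1L]])
  base <- base %||% matrix(seq_len(3 * n), n, 3)
  trajectory(lapply(disp_list, function(d) base + d), dt = 1)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

.cache <- new.env(parent = emptyenv())

# The default five-protocol study (the stated toy world), run once per test
# session; used by the pipeline tests and acceptance criteria 6 and 9.
default_study <- function() {
  if (!is.null(.cache$study)) return(.cache$study)
  dir <- file.path(tempdir(), "domainflux-default-study")
  cfg <- run_config(seed = 1, out_dir = dir)
  run_study(cfg)
  .cache$study <- list(dir = dir, config = cfg)
  .cache$study
}

# A cheap two-protocol study for structural/determinism tests.
tiny_study <- function(seed = 1, out_dir = tempfile("study")) {
  cfg <- run_config(seed = seed, out_dir = out_dir,
                    protocols = c("freeDyn", "fullTMD"),
                    n_steps = 1500, n_steps_free = 3000,
                    beads_per_subdomain = 12,
                    gen_max_frames = 40, gen_bead_stride = 12)
  run_study(cfg)
  cfg
}

gauss_pair_traj <- function(n, r, seed, sd = 1) {
  # two beads whose 3-D displacements are jointly Gaussian with per-axis
  # correlation r
  set.seed(seed)
  a <- matrix(rnorm(3 * n, sd = sd), n, 3)
  b <- r * a + sqrt(1 - r^2) * matrix(rnorm(3 * n, sd = sd), n, 3)
  base1 <- c(0, 0, 0); base2 <- c(20, 0, 0)
  coords <- array(0, c(2, 3, n))
  for (f in seq_len(n)) {
    coords[1, , f] <- base1 + a[f, ]
    coords[2, , f] <- base2 + b[f, ]
  }
  trajectory(coords)
}

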