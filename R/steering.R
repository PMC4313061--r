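# Toy dynamics: elastic network model (ENM) + targeted-MD (TMD) biasing
# potential, integrated with overdamped (Brownian) Langevin dynamics.
#
# The TMD bias is the standard harmonic penalty on the best-fit RMSD between
# the current structure and a target over a steering selection, with a
# target-RMSD schedule decreasing over the run. A "per-atom" force constant
# k (kcal/(mol A^2), default 3) gives the total potential
#     U = (k * N_sel / 2) * (RMSD(t) - RMSD*(t))^2
# so the per-bead force  -k (RMSD - RMSD*) (x_i - y_i) / RMSD  is independent
# of the selection size (the steering tool convention the analysis emulates).
# The gradient is exact with the superposition held at its optimum (envelope
# theorem) when the fit selection equals the steered selection.

#' Elastic-network / dynamics parameters
#'
#' Units: kcal/mol, Angstrom, ps. Overdamped integration requires
#' `spring * timestep / friction < 0.1` (enforced); the thermal step noise is
#' sqrt(2 kB T dt / friction) per coordinate.
#'
#' @param cutoff ENM contact cutoff in Angstrom (> 0, default 10).
#' @param spring ENM bond spring constant, kcal/(mol A^2) (>= 0, default 1).
#' @param temperature Kelvin (> 0, default 310).
#' @param friction ps^-1 (default 0.25; low friction keeps the slow
#'   subdomain modes' relaxation time well inside a run so unbiased series
#'   are stationary).
#' @param timestep ps (default 0.0025).
#' @param n_steps number of integration steps (default 24000).
#' @param stride frames are recorded every `stride` steps (default 20).
#' @param seed integer RNG seed.
#' @return object of class `enm_parameters`.
#' @export
enm_parameters <- function(cutoff = 10, spring = 1, temperature = 310,
                           friction = 0.25, timestep = 0.0025, n_steps = 24000,
                           stride = 20, seed = 1) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  if (spring < 0) stopf("spring must be >= 0")
  if (temperature <= 0) stopf("temperature must be > 0")
  if (friction <= 0 || timestep <= 0) stopf("friction and timestep must be > 0")
  if (spring * timestep / friction >= 0.1)
    stopf("unstable integrator: spring * timestep / friction = %.3g >= 0.1",
          spring * timestep / friction)
  structure(list(cutoff = cutoff, spring = spring, temperature = temperature,
                 friction = friction, timestep = timestep,
                 n_steps = as.integer(n_steps), stride = as.integer(stride),
                 seed = as.integer(seed)),
            class = "enm_parameters")
}

#' Build the elastic network
#'
#' Beads (i, j) are bonded iff their reference distance is at most the
#' cutoff; the rest length is the reference distance. An isolated bead
#' triggers a warning (it would diffuse freely).
#'
#' @param model a [structure_model].
#' @param params an [enm_parameters].
#' @return object of class `enm_network`: data.frame (i, j, r0) plus the
#'   sparse incidence matrix used for force accumulation.
#' @export
build_enm <- function(model, params) {
  x <- model$xyz
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  hit <- which(upper.tri(d) & d <= params$cutoff, arr.ind = TRUE)
  bonds <- data.frame(i = hit[, 1L], j = hit[, 2L],
                      r0 = d[hit])
  isolated <- setdiff(seq_len(n), unique(c(bonds$i, bonds$j)))
  if (length(isolated) > 0L)
    warnf("%d isolated bead(s) without any ENM bond (first: bead %d)",
          length(isolated), isolated[1L])
  nb <- nrow(bonds)
  inc <- Matrix::sparseMatrix(i = c(bonds$i, bonds$j),
                              j = rep(seq_len(nb), 2L),
                              x = rep(c(1, -1), each = nb),
                              dims = c(n, nb))
  structure(list(bonds = bonds, incidence = inc, n = n), class = "enm_network")
}

# Harmonic bond forces, n x 3.
enm_forces <- function(x, net, spring) {
  b <- net$bonds
  D <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
  len <- sqrt(rowSums(D^2))
  coef <- -spring * (len - b$r0) / pmax(len, 1e-12)
  as.matrix(net$incidence %*% (D * coef))
}

#' Steering protocol
#'
#' @param target target [structure_model].
#' @param selection integer vector of steered bead indices (empty = no
#'   steering, the unbiased protocol).
#' @param k_tmd per-atom TMD force constant, kcal/(mol A^2) (default 3).
#' @param fit superposition convention for the TMD RMSD: fit on the steered
#'   selection only (default, the steering-tool convention) or on all beads.
#' @param schedule optional function(step, n_steps, rmsd0) returning the
#'   target RMSD* at a step; default: linear from the initial RMSD to 0.
#'   Must be monotonically non-increasing.
#' @param name optional protocol label.
#' @return object of class `steering_protocol`.
#' @export
steering_protocol <- function(target, selection, k_tmd = 3,
                              fit = c("selection", "all"), schedule = NULL,
                              name = NULL) {
  fit <- match.arg(fit)
  if (k_tmd < 0) stopf("k_tmd must be >= 0")
  selection <- sort(unique(as.integer(selection)))
  if (length(selection) > 0L && length(selection) < 3L)
    stopf("a non-empty steering selection needs >= 3 beads (superposition)")
  if (length(selection) > 0L && selection[1L] < 1L)
    stopf("selection indices must be >= 1")
  structure(list(target = target, selection = selection, k_tmd = k_tmd,
                 fit = fit, schedule = schedule, name = name),
            class = "steering_protocol")
}

#' TMD RMSD between current coordinates and the target
#'
#' Best-fit (rotation + translation) superposition of the target onto the
#' current frame over the fit selection, then RMSD over the steered
#' selection.
#'
#' @param x current n x 3 coordinates.
#' @param target target coordinates (n x 3) or a [structure_model].
#' @param selection steered bead indices (>= 3).
#' @param fit `"selection"` or `"all"`.
#' @return scalar RMSD in Angstrom.
#' @export
tmd_rmsd <- function(x, target, selection, fit = c("selection", "all")) {
  fit <- match.arg(fit)
  y <- if (inherits(target, "structure_model")) target$xyz else target
  if (length(selection) < 3L) stopf("selection needs >= 3 beads")
  fit_sel <- if (fit == "selection") selection else seq_len(nrow(x))
  al <- kabsch_superpose(y, x, sel = fit_sel)$aligned
  rmsd_raw(x, al, sel = selection)
}

#' TMD biasing forces
#'
#' Analytic gradient of U = (k N_sel / 2)(RMSD - RMSD*)^2 with the
#' superposition held at its optimum. Beads outside the steered selection
#' receive exactly zero force.
#'
#' @param x current n x 3 coordinates.
#' @param protocol a [steering_protocol].
#' @param rmsd_star current target RMSD (Angstrom).
#' @return list: `forces` (n x 3, kcal/(mol A)), `rmsd`, `energy`.
#' @export
tmd_force <- function(x, protocol, rmsd_star) {
  n <- nrow(x)
  forces <- matrix(0, n, 3L)
  sel <- protocol$selection
  if (length(sel) == 0L || protocol$k_tmd == 0) {
    return(list(forces = forces, rmsd = NA_real_, energy = 0))
  }
  y <- if (inherits(protocol$target, "structure_model")) protocol$target$xyz
       else protocol$target
  fit_sel <- if (protocol$fit == "selection") sel else seq_len(n)
  al <- kabsch_superpose(y, x, sel = fit_sel)$aligned
  dev <- x[sel, , drop = FALSE] - al[sel, , drop = FALSE]
  s <- sqrt(mean(rowSums(dev^2)))
  k <- protocol$k_tmd
  if (s > 1e-10) {
    forces[sel, ] <- -k * (s - rmsd_star) / s * dev
  }
  list(forces = forces,
       rmsd = s,
       energy = 0.5 * k * length(sel) * (s - rmsd_star)^2)
}

#' Run overdamped Langevin dynamics on the ENM, optionally steered
#'
#' First-order Euler-Maruyama integration of the ENM plus TMD forces:
#' dx = F dt / friction + sqrt(2 kB T dt / friction) * N(0,1). Deterministic
#' for a fixed seed; frames recorded every `params$stride` steps (frame 1 is
#' the initial structure). Aborts with the step number if any coordinate
#' exceeds 1e6 Angstrom or turns non-finite.
#'
#' @param model a [structure_model] (the starting conformation; also the ENM
#'   reference).
#' @param params an [enm_parameters].
#' @param protocol a [steering_protocol], or NULL for unbiased dynamics.
#' @return object of class `dynamics_result`: list with `trajectory`, `log`
#'   (data.frame step, rmsd, rmsd_star, bias_energy; NULL when unbiased),
#'   `model`, `params`, `protocol`.
#' @export
run_dynamics <- function(model, params, protocol = NULL) {
  net <- build_enm(model, params)
  x <- model$xyz
  n <- nrow(x)
  biased <- !is.null(protocol) && length(protocol$selection) > 0L &&
    protocol$k_tmd > 0
  rmsd0 <- if (biased) tmd_rmsd(x, protocol$target, protocol$selection,
                                protocol$fit) else NA_real_
  schedule <- if (biased) {
    protocol$schedule %||% function(step, n_steps, r0) r0 * (1 - step / n_steps)
  } else NULL
  if (biased) {
    sched_vals <- vapply(seq_len(params$n_steps), schedule, 0,
                         n_steps = params$n_steps, r0 = rmsd0)
    if (any(diff(sched_vals) > 1e-9))
      stopf("RMSD* schedule must be monotonically non-increasing")
  }
  dt <- params$timestep
  gam <- params$friction
  tgt <- if (biased) {
    if (inherits(protocol$target, "structure_model")) protocol$target$xyz
    else protocol$target
  } else matrix(0, 1L, 3L)
  out <- with_seed(params$seed,
    run_dynamics_cpp(x, net$bonds$i, net$bonds$j, net$bonds$r0,
                     params$spring, dt, gam,
                     .kB * params$temperature, params$n_steps, params$stride,
                     if (biased) protocol$k_tmd else 0,
                     if (biased) protocol$selection else integer(0),
                     tgt,
                     if (biased) sched_vals else numeric(0),
                     biased && protocol$fit == "all"))
  coords <- out$coords
  log <- if (biased) data.frame(step = seq_len(params$n_steps),
                                rmsd = out$log[, 1L],
                                rmsd_star = out$log[, 2L],
                                bias_energy = out$log[, 3L]) else NULL
  structure(list(trajectory = trajectory(coords,
                                         dt = dt * params$stride,
                                         seed = params$seed),
                 log = log, model = model, params = params,
                 protocol = protocol),
            class = "dynamics_result")
}

#' @method print dynamics_result
#' @export
print.dynamics_result <- function(x, ...) {
  cat(sprintf("<dynamics_result> %s, %d frames recorded\n",
              if (is.null(x$log)) "unbiased" else
                sprintf("steered (%d beads, k = %g)",
                        length(x$protocol$selection), x$protocol$k_tmd),
              n_frames(x$trajectory)))
  invisible(x)
}

#' Named steering selections for the five study protocols
#'
#' Table-1 style selections on the toy trimer: `freeDyn` steers nothing;
#' `tmDom` the transmembrane domain of all monomers; `freeMon` everything
#' except the free (analysis) monomer; `freePP` the union of `tmDom` and
#' `freeMon` (leaving only the free monomer's porter and docking domains
#' unbiased); `fullTMD` the entire protein. All selections refer to the
#' C-alpha beads.
#'
#' @param name one of freeDyn, tmDom, freeMon, freePP, fullTMD.
#' @param model a [structure_model].
#' @param partition the [subdomain_partition].
#' @param free_monomer label of the unsteered monomer (default "B", the
#'   T-state analogue).
#' @return integer vector of steered bead indices.
#' @export
protocol_selection <- function(name, model, partition, free_monomer = "B") {
  name <- match.arg(name, c("freeDyn", "tmDom", "freeMon", "freePP", "fullTMD"))
  switch(name,
         freeDyn = integer(0),
         tmDom = partition_atoms(partition, model, group = "TM"),
         freeMon = which(model$monomer != free_monomer),
         freePP = sort(union(partition_atoms(partition, model, group = "TM"),
                             which(model$monomer != free_monomer))),
         fullTMD = seq_len(n_atoms(model)))
}
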