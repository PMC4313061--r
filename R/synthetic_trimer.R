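# Synthetic trimer builder and trajectory generators with planted, exactly
# known motion parameters.
#
# The toy geometry is a stylized three-fold symmetric RND-transporter
# analogue: three monomers (A, B, C), each with a transmembrane rod (TM,
# below z = 0), a porter ring of four subdomains (PN1, PN2, PC1, PC2) and a
# docking pair (DN, DC) on top. Monomer k is monomer A rotated by 120k
# degrees about z (the membrane normal). Subdomains are elongated
# anisotropic bead rods so every principal axis is identifiable, and the
# layout places inter-monomer contacts at the docking ring and between
# neighbouring porter subdomains (as in the tightly interlocked trimer the
# model emulates), so an elastic network built on it couples the monomers.

.TRIMER_GROUPS <- c("TM", "PN1", "PN2", "PC1", "PC2", "DN", "DC")

# Layout of monomer A (monomers B and C are exact 120/240-degree copies).
# Subdomain rods point radially outward from the trimer (z) axis, their
# inner tips sitting on three staggered rings: the lower porter ring
# (PN2/PC1), the upper porter ring (PN1/PC2) and the docking ring (DN/DC);
# the tilted TM rod hangs below the membrane plane (z = 0). Each rod carries
# a protruding "linker" bead toward the axis (a loop-residue analogue that
# makes the inter-ring contacts) and, except for TM, a short tangential
# 3-bead "arm" curving clockwise toward the neighbouring rod of the same
# ring -- the arms interlock the rings with alternating own-monomer /
# neighbour-monomer contacts, the porter interdigitation the model emulates.
# Numbers were calibrated so every interface is a localized patch of
# elastic-network bonds: dense enough that the unbiased trimer is stationary
# on the run timescale, sparse enough that a 3 kcal/(mol A^2) per-atom
# steering spring can drive the torsional-wave target against the network.
trimer_layout <- function() {
  ring_radius <- 11.5
  z_lower <- 5
  z_upper <- z_lower + 9.8
  z_dock <- z_upper + 10.0
  radial <- function(az_deg, z, tilt = 0, linker = 3.0, linker_dz = 0,
                     arm = TRUE) {
    az <- deg2rad(az_deg)
    a <- c(cos(az), sin(az), 0)
    if (tilt != 0) a <- c(a[1:2] * sqrt(1 - tilt^2), -tilt)
    tip <- c(ring_radius * cos(az), ring_radius * sin(az), z)
    list(center = tip, axis = a, az = az_deg, z = z,
         linker = linker, linker_dz = linker_dz, arm = arm)
  }
  list(
    TM  = radial(30.9, -4.05, tilt = 0.36, linker = 3.0, linker_dz = 2.49,
                 arm = FALSE),
    PN1 = radial(30, z_upper, linker = 3.0, linker_dz = -2.49),
    PN2 = radial(60, z_lower, linker = 3.0),
    PC1 = radial(0, z_lower, linker = 3.0),
    PC2 = radial(-30, z_upper, linker = 3.0, linker_dz = -2.49),
    DN  = radial(60, z_dock, linker = 3.5, linker_dz = -2.88),
    DC  = radial(0, z_dock, linker = 3.5, linker_dz = -2.88)
  )
}

#' Specification of a synthetic trimer
#'
#' @param beads_per_subdomain beads per subdomain (>= 10, default 56; the
#'   default is deliberately generous because the bead density sets the
#'   internal stiffness of each subdomain under the elastic network, hence
#'   the thermal RMSD floor of steered runs). Includes the linker bead and,
#'   where present, the 3 arm beads.
#' @param aspect elongation factor of each rod (>= 2 for principal-axis
#'   identifiability): rod half-length = 2.5 * aspect Angstrom against a
#'   transverse helix radius of about 2.5 Angstrom.
#' @param seed integer seed for the (deterministic) bead jitter.
#' @param monomers three monomer labels.
#' @return object of class `trimer_spec`.
#' @export
trimer_spec <- function(beads_per_subdomain = 56, aspect = 2.24, seed = 1,
                        monomers = c("A", "B", "C")) {
  if (beads_per_subdomain < 10)
    stopf("beads_per_subdomain must be >= 10 (inertia tensor ill-conditioned)")
  if (aspect < 2) stopf("aspect must be >= 2 for principal-axis identifiability")
  if (length(monomers) != 3L || anyDuplicated(monomers) > 0L)
    stopf("exactly three distinct monomer labels required")
  structure(list(beads_per_subdomain = as.integer(beads_per_subdomain),
                 aspect = aspect, seed = as.integer(seed),
                 monomers = as.character(monomers)),
            class = "trimer_spec")
}

#' Build the synthetic trimer
#'
#' Deterministic for a given seed. Monomer k equals monomer A rotated by
#' 120k degrees about z; TM beads lie below z = 0, porter and docking beads
#' above. Residues are numbered 1..7n per monomer, one subdomain per
#' contiguous block of n = `beads_per_subdomain`.
#'
#' @param spec a [trimer_spec].
#' @return list with `model` ([structure_model]) and `partition`
#'   ([subdomain_partition]).
#' @export
build_trimer <- function(spec) {
  if (!inherits(spec, "trimer_spec")) stopf("spec must be a trimer_spec")
  n <- spec$beads_per_subdomain
  h <- 2.5 * spec$aspect                      # rod half-length, Angstrom
  layout <- trimer_layout()
  rx <- 2.5; ry <- 1.8                        # transverse helix radii
  local <- with_seed(spec$seed, {
    lapply(layout, function(g) {
      u <- g$axis / sqrt(sum(g$axis^2))
      Fm <- complete_frame(u)                 # columns u, v, w
      n_arm <- if (g$arm) 3L else 0L
      nb <- n - n_arm - 1L                    # spindle body beads
      # spindle on an elliptical helix: dense enough to be internally stiff
      # under the ENM (a straight chain has no transverse bond stiffness),
      # tapered so interfaces stay tip-localized, anisotropic so all three
      # principal moments are distinct
      q <- seq(-1, 1, length.out = nb)
      taper <- sqrt(pmax(1 - 0.85 * q^2, 0))
      psi <- 2 * pi * (seq_len(nb) - 1) * 137.5 / 360
      a <- rx * taper * cos(psi) + stats::rnorm(nb, 0, 0.2)
      b <- ry * taper * sin(psi) + stats::rnorm(nb, 0, 0.2)
      body <- cbind(h * q, a, b) %*% t(Fm)
      # protruding linker bead toward the trimer axis (+ vertical tilt)
      linker <- c(-(h + g$linker), stats::rnorm(2, 0, 0.1)) %*% t(Fm)
      linker[3] <- linker[3] + g$linker_dz
      pts <- rbind(linker, body)
      pts <- sweep_rows(pts, -(g$center + h * (g$axis / sqrt(sum(g$axis^2)))))
      if (n_arm > 0L) {
        # tangential arm curving clockwise toward the ring neighbour
        arm <- t(vapply(seq_len(n_arm), function(k) {
          azk <- deg2rad(g$az - 15 * k)
          rk <- 11.5 + 3.2
          c(rk * cos(azk), rk * sin(azk),
            g$z + 0.3 * k + stats::rnorm(1, 0, 0.2))
        }, numeric(3)))
        pts <- rbind(pts, arm)
      }
      pts
    })
  })
  xyz <- matrix(0, 21L * n, 3L)
  monomer <- character(21L * n)
  resid <- integer(21L * n)
  part_rows <- list()
  row <- 0L
  for (k in 0:2) {
    Rk <- rot_z(120 * k)
    res0 <- 0L
    for (g in .TRIMER_GROUPS) {
      pts <- local[[g]] %*% t(Rk)
      idx <- row + seq_len(n)
      xyz[idx, ] <- pts
      monomer[idx] <- spec$monomers[k + 1L]
      resid[idx] <- res0 + seq_len(n)
      part_rows[[length(part_rows) + 1L]] <- data.frame(
        group = g, monomer = spec$monomers[k + 1L],
        start = res0 + 1L, end = res0 + n, stringsAsFactors = FALSE)
      row <- row + n
      res0 <- res0 + n
    }
  }
  model <- structure_model(xyz, residue_index = resid, monomer = monomer)
  partition <- subdomain_partition(do.call(rbind, part_rows))
  validate_partition(partition, model)
  # every subdomain must have a well-separated long axis
  for (u in seq_len(nrow(partition))) {
    i <- partition_atoms(partition, model, partition$group[u],
                         partition$monomer[u])
    principal_axis(model$xyz[i, , drop = FALSE], gap_tol = 1e-3)
  }
  list(model = model, partition = partition)
}

#' Planted motion parameters for synthetic trajectories
#'
#' Describes exactly known motion to plant: per-subdomain rigid-body
#' rotations (Phi*, Theta*, degrees) and monomer-local-frame CoM
#' translations; block-structured linear correlations (every pair across and
#' within the two named groups gets Pearson correlation r via a shared
#' latent factor); and nonlinear phase-coupled bead pairs whose xy
#' displacements move on a common circle with a 90-degree phase offset
#' (coordinate dot-product correlation exactly zero, mutual information
#' high).
#'
#' @param rotations data.frame (monomer, group, dphi, dtheta) in degrees.
#'   Positive dphi rotates the subdomain counter-clockwise about z (through
#'   its own CoM); positive dtheta tilts its long axis toward +z.
#' @param translations data.frame (monomer, group, dx, dy, dz) in the
#'   monomer-local frame (rotated by the monomer's 120k placement).
#' @param ring_twist data.frame (group, psi) in degrees: rigid rotation of
#'   the named subdomain about the trimer (z) axis, applied identically in
#'   every monomer BEFORE the per-subdomain rotations/translations. A
#'   z-graded twist profile is the torsional-wave (functional-rotation
#'   analogue) motion of the default study.
#' @param blocks list of `list(a = "B.DN", b = "B.PC2", r = 0.8)` entries
#'   ("monomer.group" labels); block memberships must be disjoint so the
#'   planted covariance is positive semi-definite by construction.
#' @param nonlinear data.frame (i, j) of bead indices for phase-coupled
#'   pairs; beads must not belong to any correlation block.
#' @param sigma isotropic per-bead displacement s.d. in Angstrom (> 0).
#' @param n_frames number of frames to generate.
#' @param noise rigid-body trajectory noise s.d. in Angstrom (<= 0.1).
#' @param global_rot_z whole-trimer rotation about the z axis (degrees),
#'   applied about the origin.
#' @param seed integer RNG seed.
#' @return object of class `planted_motion`.
#' @export
planted_motion <- function(rotations = NULL, translations = NULL,
                           ring_twist = NULL, blocks = NULL, nonlinear = NULL,
                           sigma = 1, n_frames = 1000, noise = 0.05,
                           global_rot_z = 0, seed = 1) {
  if (sigma <= 0) stopf("sigma must be > 0")
  if (noise < 0 || noise > 0.1) stopf("rigid-body noise must be in [0, 0.1] Angstrom")
  if (!is.null(blocks)) {
    for (b in seq_along(blocks)) {
      bl <- blocks[[b]]
      if (!all(c("a", "b", "r") %in% names(bl)))
        stopf("block %d needs fields a, b, r", b)
      if (abs(bl$r) > 1)
        stopf("planted covariance not positive semi-definite: block %d has |r| = %g > 1",
              b, abs(bl$r))
    }
  }
  structure(list(rotations = rotations, translations = translations,
                 ring_twist = ring_twist,
                 blocks = blocks, nonlinear = nonlinear, sigma = sigma,
                 n_frames = as.integer(n_frames), noise = noise,
                 global_rot_z = global_rot_z, seed = as.integer(seed)),
            class = "planted_motion")
}

# Resolve "M.G" labels to bead indices.
label_atoms <- function(label, partition, model) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) {
    partition_atoms(partition, model, monomer = parts[1L])
  } else {
    partition_atoms(partition, model, group = parts[2L], monomer = parts[1L])
  }
}

# Rigid transform of one subdomain for interpolation fraction s in [0, 1].
# Exact-angle construction: rotate about z by s*dphi through the subdomain
# CoM, then tilt by s*dtheta about the in-plane axis perpendicular to the
# (already phi-rotated) long axis; positive dtheta moves the axis toward +z.
group_transform <- function(coords, a0, dphi, dtheta, trans, s) {
  com <- colMeans(coords)
  X <- sweep_rows(coords, com)
  R1 <- rot_z(s * dphi)
  X <- X %*% t(R1)
  if (abs(dtheta) > 0) {
    a1 <- as.numeric(R1 %*% a0)
    w <- crossprod_3(c(0, 0, 1), a1)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-10) stopf("cannot tilt a subdomain whose axis is parallel to z")
    # rotation about w by -beta moves the axis toward +z (theta decreases)
    X <- X %*% t(rot_axis(w / wn, -s * dtheta))
  }
  sweep_rows(X, -(com + s * trans))
}

# Table of per-unit transforms resolved against a model/partition.
resolve_motion_units <- function(motion, partition, model) {
  units <- partition_units(partition)
  units$dphi <- units$dtheta <- 0
  units$dx <- units$dy <- units$dz <- 0
  pick <- function(df, u, col) {
    if (is.null(df)) return(0)
    hit <- df$monomer == units$monomer[u] & df$group == units$group[u]
    if (any(hit)) df[[col]][which(hit)[1L]] else 0
  }
  for (u in seq_len(nrow(units))) {
    units$dphi[u] <- pick(motion$rotations, u, "dphi")
    units$dtheta[u] <- pick(motion$rotations, u, "dtheta")
    units$dx[u] <- pick(motion$translations, u, "dx")
    units$dy[u] <- pick(motion$translations, u, "dy")
    units$dz[u] <- pick(motion$translations, u, "dz")
  }
  units
}

# Monomer placement rotation (monomer label -> rot_z(120k)).
monomer_rotation <- function(model, mono) {
  k <- match(mono, unique(model$monomer)) - 1L
  rot_z(120 * k)
}

apply_motion <- function(model, partition, motion, s = 1) {
  xyz <- model$xyz
  if (abs(motion$global_rot_z) > 0) {
    xyz <- xyz %*% t(rot_z(s * motion$global_rot_z))
  }
  if (!is.null(motion$ring_twist)) {
    for (r in seq_len(nrow(motion$ring_twist))) {
      psi <- motion$ring_twist$psi[r]
      if (psi == 0) next
      i <- partition_atoms(partition, model, motion$ring_twist$group[r])
      xyz[i, ] <- xyz[i, ] %*% t(rot_z(s * psi))
    }
  }
  units <- resolve_motion_units(motion, partition, model)
  for (u in seq_len(nrow(units))) {
    if (units$dphi[u] == 0 && units$dtheta[u] == 0 &&
        units$dx[u] == 0 && units$dy[u] == 0 && units$dz[u] == 0) next
    i <- partition_atoms(partition, model, units$group[u], units$monomer[u])
    a0 <- principal_axis(xyz[i, , drop = FALSE])
    tr <- as.numeric(monomer_rotation(model, units$monomer[u]) %*%
                       c(units$dx[u], units$dy[u], units$dz[u]))
    xyz[i, ] <- group_transform(xyz[i, , drop = FALSE], a0,
                                units$dphi[u], units$dtheta[u], tr, s)
  }
  xyz
}

#' Target conformation from planted motion
#'
#' Deterministic endpoint structure: the model with every planted
#' rotation/translation fully applied (the steering target).
#'
#' @param model a [structure_model].
#' @param partition the [subdomain_partition].
#' @param motion a [planted_motion].
#' @return a [structure_model].
#' @export
make_target_conformation <- function(model, partition, motion) {
  out <- model
  out$xyz <- apply_motion(model, partition, motion, s = 1)
  out
}

#' Rigid-body interpolation trajectory
#'
#' Each planted subdomain rigidly interpolates from identity to its planted
#' rotation/translation across frames, with small iid Gaussian noise
#' superimposed. Frame 1 is the start structure (plus noise), the final
#' frame the full planted motion.
#'
#' @inheritParams make_target_conformation
#' @param n_frames number of frames (default from `motion`).
#' @param dt frame interval in ps.
#' @return a [trajectory].
#' @export
generate_rigid_body_trajectory <- function(model, partition, motion,
                                           n_frames = NULL, dt = 1) {
  nf <- n_frames %||% motion$n_frames
  if (nf < 2L) stopf("need at least 2 frames")
  n <- n_atoms(model)
  with_seed(motion$seed, {
    coords <- array(0, c(n, 3L, nf))
    for (f in seq_len(nf)) {
      s <- (f - 1) / (nf - 1)
      x <- apply_motion(model, partition, motion, s = s)
      if (motion$noise > 0)
        x <- x + matrix(stats::rnorm(3L * n, 0, motion$noise), n, 3L)
      coords[, , f] <- x
    }
    trajectory(coords, dt = dt, seed = motion$seed)
  })
}

#' Correlated Gaussian fluctuation trajectory
#'
#' Frames are the reference coordinates plus a zero-mean displacement
#' process: iid isotropic Gaussian displacements of s.d. `sigma` per axis
#' for every bead, except that (a) beads belonging to a planted correlation
#' block share a per-axis latent factor giving every within/cross-block pair
#' Pearson correlation r, and (b) nonlinear pairs move on a common circle in
#' the xy plane with a shared uniform random phase per frame, a 90-degree
#' offset between the two beads and independent radius jitter, so their
#' displacement-vector Pearson correlation is ~0 while mutual information is
#' high.
#'
#' @inheritParams make_target_conformation
#' @param n_frames number of frames (default from `motion`).
#' @param dt frame interval in ps.
#' @return a [trajectory].
#' @export
generate_fluctuation_trajectory <- function(model, partition, motion,
                                            n_frames = NULL, dt = 1) {
  nf <- n_frames %||% motion$n_frames
  n <- n_atoms(model)
  sigma <- motion$sigma
  blocks <- motion$blocks
  # resolve block membership, enforce disjointness (PSD by construction)
  members <- lapply(seq_along(blocks %||% list()), function(b) {
    bl <- blocks[[b]]
    sort(unique(c(label_atoms(bl$a, partition, model),
                  label_atoms(bl$b, partition, model))))
  })
  taken <- integer(0)
  for (b in seq_along(members)) {
    clash <- intersect(members[[b]], taken)
    if (length(clash) > 0L)
      stopf("planted covariance invalid: block %d overlaps another block (bead %d)",
            b, clash[1L])
    taken <- c(taken, members[[b]])
  }
  nl <- motion$nonlinear
  if (!is.null(nl)) {
    nli <- unique(c(nl$i, nl$j))
    clash <- intersect(nli, taken)
    if (length(clash) > 0L)
      stopf("nonlinear bead %d also belongs to a correlation block", clash[1L])
    if (anyDuplicated(c(nl$i, nl$j)) > 0L)
      stopf("a bead may appear in at most one nonlinear pair")
  }
  with_seed(motion$seed, {
    coords <- array(0, c(n, 3L, nf))
    base <- matrix(model$xyz, n, 3L)
    for (f in seq_len(nf)) {
      disp <- matrix(stats::rnorm(3L * n, 0, sigma), n, 3L)
      for (b in seq_along(members)) {
        r <- blocks[[b]]$r
        idx <- members[[b]]
        fac <- stats::rnorm(3L, 0, sigma)      # shared latent factor per axis
        sgn <- sign(r); if (sgn == 0) sgn <- 1
        disp[idx, ] <- sqrt(abs(r)) * matrix(fac, length(idx), 3L, byrow = TRUE) +
          sqrt(1 - abs(r)) * disp[idx, ]
        if (sgn < 0) {
          # anti-correlated across the block pair: flip the factor sign on b
          bi <- label_atoms(blocks[[b]]$b, partition, model)
          keep <- idx %in% bi
          disp[idx[keep], ] <- disp[idx[keep], ] -
            2 * sqrt(abs(r)) * matrix(fac, sum(keep), 3L, byrow = TRUE)
        }
      }
      if (!is.null(nl)) {
        for (p in seq_len(nrow(nl))) {
          phi <- stats::runif(1, 0, 2 * pi)
          R0 <- sigma * sqrt(2)
          ri <- R0 * (1 + 0.25 * stats::rnorm(1))
          rj <- R0 * (1 + 0.25 * stats::rnorm(1))
          disp[nl$i[p], 1:2] <- ri * c(cos(phi), sin(phi))
          disp[nl$j[p], 1:2] <- rj * c(-sin(phi), cos(phi))
          disp[nl$i[p], 3] <- stats::rnorm(1, 0, 0.3 * sigma)
          disp[nl$j[p], 3] <- stats::rnorm(1, 0, 0.3 * sigma)
        }
      }
      coords[, , f] <- base + disp
    }
    trajectory(coords, dt = dt, seed = motion$seed)
  })
}

#' Default planted study motion
#'
#' The stated toy world for the five-protocol steering study: a three-fold
#' symmetric torsional wave (the functional-rotation analogue) that twists
#' each ring of subdomains rigidly about the trimer axis -- TM 0, lower
#' porter ring (PN2, PC1) 13, upper porter ring (PN1, PC2) 28 and docking
#' ring (DN, DC) 43 degrees -- plus small per-subdomain extras that give the
#' orientation analyses distinguishable signals: an 8-degree in-plane
#' rotation of PN1 and 8/5-degree tilts of PN2/PC2 toward the membrane
#' normal. The twist is nearly stress-free in the elastic network (rings
#' rotate rigidly, only inter-ring shear costs energy), which is what makes
#' partial steering able to propagate it.
#'
#' @param seed RNG seed.
#' @param n_frames frames for generator-based trajectories.
#' @return a [planted_motion].
#' @export
default_study_motion <- function(seed = 1, n_frames = 200) {
  twist <- data.frame(
    group = c("TM", "PN2", "PC1", "PN1", "PC2", "DN", "DC"),
    psi = c(0, 13, 13, 28, 28, 43, 43),
    stringsAsFactors = FALSE)
  rot <- data.frame(
    monomer = rep(c("A", "B", "C"), each = 3L),
    group = rep(c("PN1", "PN2", "PC2"), 3L),
    dphi = rep(c(8, 0, 0), 3L),
    dtheta = rep(c(0, 8, 5), 3L),
    stringsAsFactors = FALSE)
  planted_motion(ring_twist = twist, rotations = rot, seed = seed,
                 n_frames = n_frames)
}

#' Default planted fluctuation motion
#'
#' The stated toy world for the correlation analyses: displacement s.d. 2
#' Angstrom, three disjoint correlation blocks echoing the couplings the
#' analysis is meant to resolve (DN-PC2 r = 0.8 and DC-PN2 r = 0.7 within
#' monomer B; an inter-monomer DN-DN block at r = 0.6 between monomers A and
#' C), and three phase-coupled nonlinear pairs between PN1 and PC1 beads of
#' monomer B.
#'
#' @param model,partition a built trimer (used to resolve nonlinear bead
#'   indices).
#' @param seed RNG seed.
#' @param n_frames number of frames (default 2000).
#' @return a [planted_motion].
#' @export
default_fluctuation_motion <- function(model, partition, seed = 1,
                                       n_frames = 2000) {
  pn1 <- partition_atoms(partition, model, "PN1", "B")
  pc1 <- partition_atoms(partition, model, "PC1", "B")
  planted_motion(
    blocks = list(list(a = "B.DN", b = "B.PC2", r = 0.8),
                  list(a = "B.DC", b = "B.PN2", r = 0.7),
                  list(a = "A.DN", b = "C.DN", r = 0.6)),
    nonlinear = data.frame(i = pn1[1:3], j = pc1[1:3]),
    sigma = 2, n_frames = n_frames, seed = seed)
}
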