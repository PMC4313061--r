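# Subdomain geometry: optimal superposition, RMSD-to-target series,
# centre-of-mass displacement, principal-axis orientation angles (Phi/Theta),
# running averages and porcupine vectors.
#
# Conventions: the membrane normal is +z (guaranteed by the synthetic
# builder); beads have uniform mass; Phi is the signed angle between the
# membrane-plane projections of the long axis at frame t and frame 0
# (positive = counter-clockwise seen from +z); Theta is the signed change in
# tilt relative to the membrane normal, positive when the axis moves TOWARD
# +z. Both are defined with respect to the initial conformation.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `ref` over a selection, returning a
#' proper rotation (determinant +1).
#'
#' @param mobile,ref n x 3 coordinate matrices (Angstrom).
#' @param sel bead indices used for the fit (default: all). At least 3
#'   non-collinear beads are required.
#' @return list with `R` (3x3 rotation), `t` (translation), `rmsd` (over the
#'   fit selection) and `aligned` (all of `mobile` transformed:
#'   `mobile %*% t(R) + t`).
#' @export
kabsch_superpose <- function(mobile, ref, sel = NULL) {
  sel <- sel %||% seq_len(nrow(mobile))
  if (length(sel) < 3L)
    stopf("superposition needs at least 3 beads (got %d)", length(sel))
  M <- mobile[sel, , drop = FALSE]
  P <- ref[sel, , drop = FALSE]
  cm <- colMeans(M); cp <- colMeans(P)
  Mc <- sweep_rows(M, cm); Pc <- sweep_rows(P, cp)
  # collinearity check on both point sets
  for (X in list(Mc, Pc)) {
    s <- svd(X, nu = 0, nv = 0)$d
    if (s[2L] < 1e-8 * max(s[1L], 1e-12))
      stopf("degenerate (collinear) selection: superposition underdetermined")
  }
  H <- crossprod(Mc, Pc)                       # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps mobile frame -> ref frame
  tvec <- cp - as.numeric(R %*% cm)
  aligned <- mobile %*% t(R) + matrix(tvec, nrow(mobile), 3, byrow = TRUE)
  dev <- aligned[sel, , drop = FALSE] - ref[sel, , drop = FALSE]
  list(R = R, t = tvec, rmsd = sqrt(mean(rowSums(dev^2))), aligned = aligned)
}

#' Plain (unfitted) RMSD between two coordinate sets
#' @param a,b n x 3 matrices.
#' @param sel optional bead indices.
#' @export
rmsd_raw <- function(a, b, sel = NULL) {
  sel <- sel %||% seq_len(nrow(a))
  sqrt(mean(rowSums((a[sel, , drop = FALSE] - b[sel, , drop = FALSE])^2)))
}

#' Per-subdomain RMSD to a target state along a trajectory
#'
#' Each frame is superposed onto the target over `fit_sel` (a global fit,
#' e.g. one monomer as in a per-monomer analysis), then per-subdomain RMSD is
#' measured without refitting. With `per_group_fit = TRUE` each subdomain is
#' instead fitted onto its own target coordinates before measuring.
#'
#' @param traj a [trajectory].
#' @param partition a [subdomain_partition].
#' @param model the congruent [structure_model].
#' @param target target [structure_model] (congruent with `model`).
#' @param fit_sel bead indices for the global fit (default: all beads).
#' @param per_group_fit logical; fit each subdomain independently.
#' @return data.frame (frame, monomer, group, rmsd).
#' @export
subdomain_rmsd_series <- function(traj, partition, model, target,
                                  fit_sel = NULL, per_group_fit = FALSE) {
  check_congruent(traj, model)
  if (n_atoms(target) != n_atoms(model))
    stopf("target not congruent with model")
  units <- partition_units(partition)
  idx <- lapply(seq_len(nrow(units)), function(u)
    partition_atoms(partition, model, units$group[u], units$monomer[u]))
  nf <- n_frames(traj)
  out <- vector("list", nf)
  tref <- target$xyz
  for (f in seq_len(nf)) {
    x <- traj$coords[, , f]
    if (!per_group_fit) {
      al <- kabsch_superpose(x, tref, sel = fit_sel)$aligned
      r <- vapply(idx, function(i) rmsd_raw(al, tref, i), 0)
    } else {
      r <- vapply(idx, function(i) kabsch_superpose(x, tref, sel = i)$rmsd, 0)
    }
    out[[f]] <- data.frame(frame = f, monomer = units$monomer,
                           group = units$group, rmsd = r,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-subdomain centre-of-mass displacement series
#'
#' Each frame is globally superposed onto frame 1 over all beads (removing
#' rigid-body drift of the whole model), then the uniform-mass CoM of each
#' subdomain is compared with its frame-1 position.
#'
#' @inheritParams subdomain_rmsd_series
#' @param align superpose frames globally onto frame 1 first (default TRUE).
#' @return data.frame (frame, monomer, group, dx, dy, dz, mag).
#' @export
com_displacement_series <- function(traj, partition, model, align = TRUE) {
  check_congruent(traj, model)
  units <- partition_units(partition)
  idx <- lapply(seq_len(nrow(units)), function(u)
    partition_atoms(partition, model, units$group[u], units$monomer[u]))
  nf <- n_frames(traj)
  ref <- traj$coords[, , 1L]
  com0 <- lapply(idx, function(i) colMeans(ref[i, , drop = FALSE]))
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    x <- traj$coords[, , f]
    if (align && f > 1L) x <- kabsch_superpose(x, ref)$aligned
    d <- t(vapply(seq_along(idx), function(u)
      colMeans(x[idx[[u]], , drop = FALSE]) - com0[[u]], numeric(3)))
    out[[f]] <- data.frame(frame = f, monomer = units$monomer,
                           group = units$group,
                           dx = d[, 1], dy = d[, 2], dz = d[, 3],
                           mag = sqrt(rowSums(d^2)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Principal axis of a bead cloud
#'
#' Eigenvector of the uniform-mass moment-of-inertia tensor about the
#' centroid. For an elongated body the long geometric axis is the axis of
#' the SMALLEST principal moment; visualization tools' "major principal
#' axis" follows that convention and it is the default here. `which =
#' "largest_moment"` returns the eigenvector of the largest moment instead.
#'
#' Sign convention (frame-0 rule): positive z component; if |z| ~ 0,
#' positive x; then positive y. Frame-to-frame sign continuity is handled by
#' [orientation_angles].
#'
#' @param coords n x 3 matrix (n >= 3, non-collinear not required for the
#'   long axis but the relevant principal moment must be non-degenerate).
#' @param which `"long"` (smallest moment, default) or `"largest_moment"`.
#' @param gap_tol relative eigenvalue gap below which the axis is declared
#'   degenerate (error).
#' @return unit 3-vector.
#' @export
principal_axis <- function(coords, which = c("long", "largest_moment"),
                           gap_tol = 1e-6) {
  which <- match.arg(which)
  if (nrow(coords) < 3L) stopf("principal axis needs >= 3 beads")
  X <- sweep_rows(coords, colMeans(coords))
  r2 <- rowSums(X^2)
  Iten <- diag(3) * sum(r2) - crossprod(X)     # uniform masses
  e <- eigen(Iten, symmetric = TRUE)           # values decreasing
  vals <- e$values
  k <- if (which == "long") 3L else 1L
  gaps <- abs(vals[k] - vals[-k]) / max(abs(vals[1L]), 1e-12)
  if (min(gaps) < gap_tol)
    stopf("degenerate principal moments (relative gap %.2e)", min(gaps))
  axis_sign_canonical(e$vectors[, k])
}

axis_sign_canonical <- function(a, tol = 1e-8) {
  if (abs(a[3L]) > tol) {
    if (a[3L] < 0) a <- -a
  } else if (abs(a[1L]) > tol) {
    if (a[1L] < 0) a <- -a
  } else if (a[2L] < 0) a <- -a
  a
}

signed_phi <- function(a0, at, tol = 1e-8) {
  p0 <- a0[1:2]; pt <- at[1:2]
  if (sqrt(sum(pt^2)) < tol || sqrt(sum(p0^2)) < tol) return(NA_real_)
  rad2deg(atan2(p0[1L] * pt[2L] - p0[2L] * pt[1L], sum(p0 * pt)))
}

#' Principal-axis orientation angles along a trajectory
#'
#' For every subdomain and frame, the long principal axis is computed (after
#' optional global superposition of the frame onto frame 1), its sign fixed
#' by continuity with the previous frame (frame 1: positive-z rule), and two
#' angles relative to frame 1 are reported: Phi, the signed angle between
#' the xy-plane (membrane-plane) projections of axis(t) and axis(1); and
#' Theta, the signed tilt change relative to the membrane normal (+z),
#' positive when the axis tilts toward +z. Frames whose axis is parallel to
#' z (projection below `tol`) get Phi = NA (logged as a warning).
#'
#' @inheritParams subdomain_rmsd_series
#' @param align superpose frames globally onto frame 1 over all beads.
#' @param which axis convention, see [principal_axis].
#' @param tol minimum xy-projection norm for Phi.
#' @return data.frame (frame, monomer, group, phi, theta) in degrees.
#' @export
orientation_angles <- function(traj, partition, model, align = TRUE,
                               which = "long", tol = 1e-8) {
  check_congruent(traj, model)
  units <- partition_units(partition)
  idx <- lapply(seq_len(nrow(units)), function(u)
    partition_atoms(partition, model, units$group[u], units$monomer[u]))
  nf <- n_frames(traj)
  ref <- traj$coords[, , 1L]
  nu <- nrow(units)
  a0 <- vector("list", nu)
  prev <- vector("list", nu)
  out <- vector("list", nf)
  n_undef <- 0L
  for (f in seq_len(nf)) {
    x <- traj$coords[, , f]
    if (align && f > 1L) x <- kabsch_superpose(x, ref)$aligned
    phi <- theta <- numeric(nu)
    for (u in seq_len(nu)) {
      a <- principal_axis(x[idx[[u]], , drop = FALSE], which = which)
      if (f == 1L) {
        a0[[u]] <- a
      } else if (sum(a * prev[[u]]) < 0) {
        a <- -a                                 # continuity: no 180-deg flips
      }
      prev[[u]] <- a
      phi[u] <- signed_phi(a0[[u]], a, tol = tol)
      if (is.na(phi[u])) n_undef <- n_undef + 1L
      theta[u] <- rad2deg(acos(max(-1, min(1, a0[[u]][3L]))) -
                            acos(max(-1, min(1, a[3L]))))
    }
    out[[f]] <- data.frame(frame = f, monomer = units$monomer,
                           group = units$group, phi = phi, theta = theta,
                           stringsAsFactors = FALSE)
  }
  if (n_undef > 0L)
    warnf("Phi undefined for %d frame/subdomain combinations (axis parallel to z)",
          n_undef)
  do.call(rbind, out)
}

#' Trailing running average
#'
#' Causal window mean: entry t averages the last `window` entries; the first
#' `window - 1` entries average over the available prefix.
#'
#' @param x numeric series.
#' @param window width in frames (default 20, >= 1).
#' @return numeric series of the same length.
#' @export
running_average <- function(x, window = 20) {
  window <- as.integer(window)
  if (window < 1L) stopf("window must be >= 1")
  n <- length(x)
  if (window > n) stopf("window (%d) exceeds series length (%d)", window, n)
  cs <- cumsum(c(0, x))
  t <- seq_len(n)
  lo <- pmax(0L, t - window)
  (cs[t + 1L] - cs[lo + 1L]) / (t - lo)
}

#' Combined per-subdomain orientation series
#'
#' Convenience wrapper joining CoM displacement, Phi/Theta angles, and
#' (optionally) RMSD-to-target into one table, with trailing running
#' averages of the scalar columns appended as `*_smooth`.
#'
#' @inheritParams subdomain_rmsd_series
#' @param target optional target [structure_model] for `rmsd`.
#' @param window running-average width in frames (default 20).
#' @param fit_sel global fit selection for the RMSD series.
#' @return data.frame, one row per frame x subdomain.
#' @export
orientation_series <- function(traj, partition, model, target = NULL,
                               window = 20, fit_sel = NULL) {
  com <- com_displacement_series(traj, partition, model)
  ang <- orientation_angles(traj, partition, model)
  out <- merge(com, ang, by = c("frame", "monomer", "group"), sort = FALSE)
  if (!is.null(target)) {
    rms <- subdomain_rmsd_series(traj, partition, model, target,
                                 fit_sel = fit_sel)
    out <- merge(out, rms, by = c("frame", "monomer", "group"), sort = FALSE)
  }
  out <- out[order(out$monomer, out$group, out$frame), ]
  smooth_cols <- intersect(c("mag", "phi", "theta", "rmsd"), names(out))
  for (cc in smooth_cols) {
    out[[paste0(cc, "_smooth")]] <- stats::ave(
      out[[cc]], paste(out$monomer, out$group),
      FUN = function(v) running_average(v, min(window, length(v))))
  }
  rownames(out) <- NULL
  out
}

#' Porcupine displacement vectors between two conformations
#'
#' Per-bead displacement (final - initial) after globally superposing the
#' final structure onto the initial one, plus the initial and final long
#' principal axes of each subdomain and the angle the axis pair encloses.
#'
#' @param initial,final congruent [structure_model]s.
#' @param partition optional [subdomain_partition] for the axis rods.
#' @return list with `vectors` (data.frame atom, monomer, residue, dx, dy,
#'   dz) and `axes` (data.frame monomer, group, axis-0/axis-1 components,
#'   angle_deg), plus `aligned_final` coordinates.
#' @export
porcupine_vectors <- function(initial, final, partition = NULL) {
  if (n_atoms(initial) != n_atoms(final))
    stopf("initial and final structures are not congruent")
  al <- kabsch_superpose(final$xyz, initial$xyz)$aligned
  d <- al - initial$xyz
  vectors <- data.frame(atom = initial$atom_index, monomer = initial$monomer,
                        residue = initial$residue_index,
                        dx = d[, 1], dy = d[, 2], dz = d[, 3],
                        stringsAsFactors = FALSE)
  axes <- NULL
  if (!is.null(partition)) {
    units <- partition_units(partition)
    rows <- lapply(seq_len(nrow(units)), function(u) {
      i <- partition_atoms(partition, initial, units$group[u], units$monomer[u])
      a0 <- principal_axis(initial$xyz[i, , drop = FALSE])
      a1 <- principal_axis(al[i, , drop = FALSE])
      if (sum(a0 * a1) < 0) a1 <- -a1
      data.frame(monomer = units$monomer[u], group = units$group[u],
                 x0 = a0[1], y0 = a0[2], z0 = a0[3],
                 x1 = a1[1], y1 = a1[2], z1 = a1[3],
                 angle_deg = rad2deg(acos(max(-1, min(1, sum(a0 * a1))))),
                 stringsAsFactors = FALSE)
    })
    axes <- do.call(rbind, rows)
  }
  list(vectors = vectors, axes = axes, aligned_final = al)
}

#' Export porcupine vectors
#'
#' Writes the per-bead displacement table as TSV and, optionally, a
#' two-model PDB (initial conformation + aligned final conformation).
#'
#' @param pv result of [porcupine_vectors].
#' @param initial the initial [structure_model].
#' @param path_tsv output TSV path.
#' @param path_pdb optional two-model PDB path.
#' @export
write_porcupine <- function(pv, initial, path_tsv, path_pdb = NULL) {
  utils::write.table(pv$vectors, path_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(path_pdb)) {
    traj <- trajectory(list(initial$xyz, pv$aligned_final), dt = 1)
    write_trajectory(traj, initial, path_pdb, format = "pdb")
  }
  invisible(path_tsv)
}
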