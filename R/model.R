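# Core containers: bead structure models, subdomain partitions, trajectories.

#' Create a bead structure model
#'
#' A structure model is one bead per residue (a C-alpha representation):
#' coordinates in Angstrom plus residue and monomer labels. Residue indices
#' are 1-based and must be unique within a monomer; atom indices are strictly
#' increasing.
#'
#' @param xyz numeric n x 3 matrix of coordinates (Angstrom).
#' @param residue_index integer vector, 1-based residue number per bead.
#' @param monomer character vector of monomer (chain) labels per bead.
#' @param atom_index integer vector of atom serial numbers.
#' @param bfactor optional numeric per-bead scalar (temperature factor).
#' @param box optional 3-vector of box lengths (Angstrom); unused by the
#'   analyses (toy systems are non-periodic) but carried through I/O.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(xyz,
                            residue_index = seq_len(nrow(xyz)),
                            monomer = rep("A", nrow(xyz)),
                            atom_index = seq_len(nrow(xyz)),
                            bfactor = NULL,
                            box = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stopf("coordinates must be an n x 3 matrix")
  storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  if (!all(is.finite(xyz))) stopf("non-finite coordinate in structure model")
  atom_index <- as.integer(atom_index)
  residue_index <- as.integer(residue_index)
  monomer <- as.character(monomer)
  if (length(atom_index) != n || length(residue_index) != n ||
      length(monomer) != n) {
    stopf("atom_index, residue_index and monomer must each have one entry per bead")
  }
  if (anyDuplicated(atom_index) > 0L)
    stopf("duplicate atom index %d", atom_index[anyDuplicated(atom_index)])
  if (any(diff(atom_index) <= 0L))
    stopf("atom_index must be strictly increasing")
  key <- paste(monomer, residue_index, sep = ":")
  if (anyDuplicated(key) > 0L)
    stopf("residue_index must be unique within a monomer (duplicate %s)",
          key[anyDuplicated(key)])
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
      stopf("box must be a positive 3-vector")
  }
  structure(list(xyz = xyz, atom_index = atom_index,
                 residue_index = residue_index, monomer = monomer,
                 bfactor = bfactor, box = box),
            class = "structure_model")
}

#' @method print structure_model
#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d beads, monomers: %s\n",
              nrow(x$xyz), paste(unique(x$monomer), collapse = ", ")))
  invisible(x)
}

#' Number of beads in a model
#' @param model a `structure_model`.
#' @export
n_atoms <- function(model) nrow(model$xyz)

# "A:12" keys identifying residues across monomers.
residue_keys <- function(model) paste(model$monomer, model$residue_index, sep = ":")

#' Create a trajectory
#'
#' @param coords either an n_atoms x 3 x n_frames array or a list of n x 3
#'   coordinate matrices (Angstrom).
#' @param dt frame time interval in ps (> 0).
#' @param seed optional integer recording the RNG seed that produced the
#'   trajectory.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, dt = 1, seed = NULL) {
  if (is.list(coords)) {
    n <- nrow(coords[[1L]])
    if (any(vapply(coords, nrow, 0L) != n))
      stopf("all frames must have the same atom count")
    arr <- array(0, c(n, 3L, length(coords)))
    for (f in seq_along(coords)) arr[, , f] <- coords[[f]]
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stopf("coords must be an n_atoms x 3 x n_frames array")
  if (!all(is.finite(coords))) stopf("non-finite coordinate in trajectory")
  dt <- as.numeric(dt)
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0) stopf("dt must be > 0")
  structure(list(coords = coords, dt = dt, seed = seed), class = "trajectory")
}

#' @method print trajectory
#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d frames x %d beads, dt = %g ps\n", d[3], d[1], x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Extract one frame as an n x 3 matrix
#' @param traj a `trajectory`.
#' @param i frame number (1-based).
#' @export
frame_coords <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 1L || i > nf) stopf("frame %d out of range (1..%d)", i, nf)
  traj$coords[, , i]
}

check_congruent <- function(traj, model) {
  if (dim(traj$coords)[1L] != n_atoms(model))
    stopf("trajectory has %d beads but model has %d",
          dim(traj$coords)[1L], n_atoms(model))
  invisible(TRUE)
}

#' Define a subdomain partition
#'
#' Named groups of residue ranges per monomer, e.g. the porter subdomains
#' PN1/PN2/PC1/PC2, the transmembrane domain TM, and the docking subdomains
#' DN/DC. Ranges are inclusive on both ends. Groups within one monomer must
#' be pairwise disjoint.
#'
#' @param df data.frame with columns `group`, `monomer`, `start`, `end`
#'   (1-based residue indices, inclusive).
#' @return object of class `subdomain_partition`.
#' @export
subdomain_partition <- function(df) {
  need <- c("group", "monomer", "start", "end")
  if (!all(need %in% names(df))) stopf("partition needs columns %s",
                                       paste(need, collapse = ", "))
  df$group <- as.character(df$group)
  df$monomer <- as.character(df$monomer)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end < df$start)) stopf("range end before start in partition")
  # disjointness within each monomer
  for (m in unique(df$monomer)) {
    sub <- df[df$monomer == m, , drop = FALSE]
    res <- unlist(Map(seq.int, sub$start, sub$end))
    if (anyDuplicated(res) > 0L) {
      stopf("overlapping groups in monomer %s (residue %d claimed twice)",
            m, res[anyDuplicated(res)])
    }
  }
  structure(df[order(df$monomer, df$start), , drop = FALSE],
            class = c("subdomain_partition", "data.frame"))
}

#' Validate a partition against a model
#'
#' Every referenced residue must exist in the model.
#' @param partition a `subdomain_partition`.
#' @param model a `structure_model`.
#' @export
validate_partition <- function(partition, model) {
  keys <- residue_keys(model)
  for (r in seq_len(nrow(partition))) {
    want <- paste(partition$monomer[r], partition$start[r]:partition$end[r],
                  sep = ":")
    missing <- setdiff(want, keys)
    if (length(missing) > 0L)
      stopf("partition group %s references residue %s absent from the model",
            partition$group[r], missing[1L])
  }
  invisible(TRUE)
}

#' Bead indices of a partition group
#'
#' @param partition a `subdomain_partition`.
#' @param model a `structure_model`.
#' @param group group name (e.g. "PC2"); NULL selects all groups.
#' @param monomer monomer label(s); NULL selects all monomers.
#' @return integer vector of bead (row) indices into the model.
#' @export
partition_atoms <- function(partition, model, group = NULL, monomer = NULL) {
  sel <- rep(TRUE, nrow(partition))
  if (!is.null(group)) sel <- sel & partition$group %in% group
  if (!is.null(monomer)) sel <- sel & partition$monomer %in% monomer
  sub <- partition[sel, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("no partition rows match group=%s monomer=%s",
                             paste(group, collapse = "/") %||% "*",
                             paste(monomer, collapse = "/") %||% "*")
  idx <- integer(0)
  for (r in seq_len(nrow(sub))) {
    hit <- which(model$monomer == sub$monomer[r] &
                   model$residue_index >= sub$start[r] &
                   model$residue_index <= sub$end[r])
    idx <- c(idx, hit)
  }
  sort(unique(idx))
}

# All (monomer, group) units of a partition as a data.frame.
partition_units <- function(partition) {
  unique(data.frame(monomer = partition$monomer, group = partition$group,
                    stringsAsFactors = FALSE))
}
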