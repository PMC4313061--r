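# Correlation analysis of C-alpha motions: per-residue RMSF, Pearson and
# generalized (mutual-information based) correlation matrices, RMSF and
# correlation-magnitude filters, block summaries over a subdomain partition,
# and mapping of surviving correlations back onto the structure.
#
# Pearson here is the displacement-vector correlation
#   rho_P(i,j) = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>),
# which only detects collinear correlation. The generalized coefficient
#   rho_gen(i,j) = sqrt(1 - exp(-2 I(r_i; r_j) / 3))
# (d = 3 dimensional displacement variables) uses a Kraskov k-nearest-
# neighbour estimate of the mutual information I and also detects
# non-collinear coupling; for jointly Gaussian displacements with per-axis
# correlation r it equals |r|.

# Aligned displacement matrices: returns list(X = n_frames x (3 n_sel)
# centered coordinate matrix grouped per bead, mean = per-bead mean coords).
displacement_matrix <- function(traj, selection = NULL, align = TRUE) {
  nf <- n_frames(traj)
  if (nf < 2L) stopf("need at least 2 frames")
  selection <- selection %||% seq_len(dim(traj$coords)[1L])
  ns <- length(selection)
  X <- matrix(0, nf, 3L * ns)
  for (f in seq_len(nf)) {
    X[f, ] <- as.numeric(t(traj$coords[selection, , f]))
  }
  if (align) {
    # two-pass: align to frame 1, then to the running mean
    ref <- matrix(X[1L, ], ns, 3L, byrow = TRUE)
    for (pass in 1:2) {
      for (f in seq_len(nf)) {
        cur <- matrix(X[f, ], ns, 3L, byrow = TRUE)
        X[f, ] <- as.numeric(t(kabsch_superpose(cur, ref)$aligned))
      }
      m <- colMeans(X)
      ref <- matrix(m, ns, 3L, byrow = TRUE)
    }
  }
  mu <- colMeans(X)
  list(X = sweep(X, 2L, mu), selection = selection)
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each bead about its trajectory mean, after optional per-frame
#' superposition of the selection onto the mean structure.
#'
#' @param traj a [trajectory] (>= 2 frames).
#' @param selection bead indices (default: all).
#' @param align superpose frames first (default TRUE).
#' @return numeric vector of RMSF values (Angstrom), one per selected bead.
#' @export
compute_rmsf <- function(traj, selection = NULL, align = TRUE) {
  dm <- displacement_matrix(traj, selection, align)
  ns <- ncol(dm$X) / 3L
  msf <- colMeans(dm$X^2)
  sqrt(msf[3 * seq_len(ns) - 2] + msf[3 * seq_len(ns) - 1] +
         msf[3 * seq_len(ns)])
}

new_correlation_result <- function(matrix, method, rmsf, selection, keys,
                                   rmsf_threshold = 1.5, corr_threshold = 0.5,
                                   knn_k = NA_integer_) {
  dimnames(matrix) <- list(keys, keys)
  structure(list(matrix = matrix, method = method, rmsf = rmsf,
                 selection = selection, keys = keys,
                 rmsf_threshold = rmsf_threshold,
                 corr_threshold = corr_threshold, knn_k = knn_k),
            class = "correlation_result")
}

#' @method print correlation_result
#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s, %d residues (rmsf > %g A, |corr| >= %g)\n",
              x$method, nrow(x$matrix), x$rmsf_threshold, x$corr_threshold))
  invisible(x)
}

#' Pearson (displacement-vector) correlation matrix
#'
#' @inheritParams compute_rmsf
#' @param model optional [structure_model] supplying residue keys for the
#'   matrix dimnames.
#' @param rmsf_threshold,corr_threshold filter metadata stored on the result
#'   (defaults 1.5 Angstrom and 0.5); applied later by [apply_filters].
#' @return a `correlation_result` with a symmetric matrix in [-1, 1],
#'   diagonal 1. A zero-variance bead gets an NA row/column (warning).
#' @export
pearson_matrix <- function(traj, selection = NULL, align = TRUE, model = NULL,
                           rmsf_threshold = 1.5, corr_threshold = 0.5) {
  dm <- displacement_matrix(traj, selection, align)
  ns <- ncol(dm$X) / 3L
  nf <- nrow(dm$X)
  # sum of the per-axis cross-covariances = <dr_i . dr_j>
  C <- matrix(0, ns, ns)
  for (d in 1:3) {
    Xd <- dm$X[, 3 * seq_len(ns) - 3 + d, drop = FALSE]
    C <- C + crossprod(Xd) / nf
  }
  v <- diag(C)
  bad <- which(v < 1e-12)
  denom <- sqrt(pmax(v, 1e-300))
  M <- C / outer(denom, denom)
  M[M > 1] <- 1; M[M < -1] <- -1
  diag(M) <- 1
  if (length(bad) > 0L) {
    M[bad, ] <- NA_real_
    M[, bad] <- NA_real_
    warnf("%d zero-variance bead(s); their correlations are undefined (NA)",
          length(bad))
  }
  rmsf <- sqrt(pmax(v, 0))  # per-bead msf = sum of the 3 axis variances
  keys <- if (!is.null(model)) residue_keys(model)[dm$selection]
          else as.character(dm$selection)
  new_correlation_result(M, "pearson", rmsf, dm$selection, keys,
                         rmsf_threshold, corr_threshold)
}

# rho_gen transform for d = 3 variables; negative MI estimates clamp to 0.
mi_to_rhogen <- function(mi) sqrt(1 - exp(-2 * pmax(mi, 0) / 3))

#' Generalized correlation matrix (Kraskov kNN mutual information)
#'
#' KSG (variant 1) k-nearest-neighbour mutual information between every pair
#' of 3-D bead displacement variables, Chebyshev metric, transformed to
#' rho_gen = sqrt(1 - exp(-2 I / 3)). A tiny seeded uniform jitter (1e-10
#' Angstrom scale) breaks distance ties, making the estimate deterministic
#' for a given seed.
#'
#' @inheritParams pearson_matrix
#' @param knn_k number of nearest neighbours (default 6; must satisfy
#'   `n_frames >= knn_k + 2`).
#' @param seed jitter seed (default 1).
#' @param pairs optional 2-column matrix of selection-relative bead index
#'   pairs; when given, only those entries (and their transposes) are
#'   computed and all other off-diagonal entries are NA. Saves time when
#'   only specific pairs matter.
#' @return a `correlation_result` with a symmetric matrix in [0, 1],
#'   diagonal 1 by convention.
#' @export
generalized_matrix <- function(traj, selection = NULL, knn_k = 6, seed = 1,
                               align = TRUE, model = NULL,
                               rmsf_threshold = 1.5, corr_threshold = 0.5,
                               pairs = NULL) {
  nf <- n_frames(traj)
  if (nf < knn_k + 2L) stopf("need at least knn_k + 2 = %d frames (got %d)",
                             knn_k + 2L, nf)
  dm <- displacement_matrix(traj, selection, align)
  ns <- ncol(dm$X) / 3L
  X <- dm$X + with_seed(seed, matrix(stats::runif(length(dm$X), -1e-10, 1e-10),
                                     nrow(dm$X), ncol(dm$X)))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ns, 2L))
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    if (any(pairs < 1L | pairs > ns)) stopf("pair index out of range")
  }
  mi <- ksg_mi_pairs_cpp(X, pairs, as.integer(knn_k))
  M <- matrix(NA_real_, ns, ns)
  M[pairs] <- mi_to_rhogen(mi)
  M[pairs[, 2:1, drop = FALSE]] <- M[pairs]
  diag(M) <- 1
  msf <- colMeans(dm$X^2)
  rmsf <- sqrt(msf[3 * seq_len(ns) - 2] + msf[3 * seq_len(ns) - 1] +
                 msf[3 * seq_len(ns)])
  keys <- if (!is.null(model)) residue_keys(model)[dm$selection]
          else as.character(dm$selection)
  new_correlation_result(M, "generalized", rmsf, dm$selection, keys,
                         rmsf_threshold, corr_threshold, as.integer(knn_k))
}

#' Filter a correlation matrix to significant, mobile pairs
#'
#' Keeps pairs (i, j), i < j, with |value| >= `corr_threshold` whose
#' residues' RMSF exceeds `rmsf_threshold` — by default BOTH residues must
#' exceed it ("related residues"); `rmsf_rule = "either"` relaxes that to at
#' least one.
#'
#' @param result a `correlation_result`.
#' @param rmsf_threshold Angstrom (default: from the result, 1.5).
#' @param corr_threshold correlation magnitude (default: from the result, 0.5).
#' @param rmsf_rule `"both"` (default) or `"either"`.
#' @return data.frame (i, j, key_i, key_j, value, rmsf_i, rmsf_j); i/j are
#'   selection-relative indices.
#' @export
apply_filters <- function(result, rmsf_threshold = NULL, corr_threshold = NULL,
                          rmsf_rule = c("both", "either")) {
  rmsf_rule <- match.arg(rmsf_rule)
  rt <- rmsf_threshold %||% result$rmsf_threshold
  ct <- corr_threshold %||% result$corr_threshold
  M <- result$matrix
  n <- nrow(M)
  ut <- which(upper.tri(M) & !is.na(M) & abs(M) >= ct, arr.ind = TRUE)
  if (nrow(ut) > 0L) {
    ri <- result$rmsf[ut[, 1L]]
    rj <- result$rmsf[ut[, 2L]]
    keep <- if (rmsf_rule == "both") ri > rt & rj > rt else ri > rt | rj > rt
    ut <- ut[keep, , drop = FALSE]
  }
  data.frame(i = ut[, 1L], j = ut[, 2L],
             key_i = result$keys[ut[, 1L]], key_j = result$keys[ut[, 2L]],
             value = M[ut],
             rmsf_i = result$rmsf[ut[, 1L]], rmsf_j = result$rmsf[ut[, 2L]],
             stringsAsFactors = FALSE)
}

#' Block summary of a correlation matrix over a partition
#'
#' For every ordered pair of groups — all (monomer, subdomain) units plus
#' whole-monomer groups — the mean, max and count of |values| at or above
#' the correlation threshold over the corresponding matrix block (diagonal
#' entries excluded).
#'
#' @param result a `correlation_result` computed over beads of `model`.
#' @param partition a [subdomain_partition].
#' @param model the [structure_model] the selection refers to.
#' @param corr_threshold threshold for the count column (default: from the
#'   result).
#' @return data.frame (group_a, group_b, n_pairs, mean, max, n_above).
#' @export
block_summary <- function(result, partition, model, corr_threshold = NULL) {
  ct <- corr_threshold %||% result$corr_threshold
  units <- partition_units(partition)
  labels <- c(paste(units$monomer, units$group, sep = "."),
              unique(units$monomer))
  sel_pos <- match(result$selection, seq_len(n_atoms(model)))
  groups <- lapply(labels, function(lb) {
    idx <- label_atoms(lb, partition, model)
    pos <- match(idx, result$selection)
    pos <- pos[!is.na(pos)]
    if (length(pos) == 0L) stopf("group %s is empty within the analysed selection", lb)
    pos
  })
  names(groups) <- labels
  rows <- list()
  M <- result$matrix
  for (a in labels) {
    for (b in labels) {
      blk <- M[groups[[a]], groups[[b]], drop = FALSE]
      if (a == b) {
        keep <- upper.tri(blk)
        vals <- blk[keep]
      } else {
        vals <- as.numeric(blk)
      }
      vals <- vals[!is.na(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = a, group_b = b, n_pairs = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        max = if (length(vals)) max(vals) else NA_real_,
        n_above = sum(abs(vals) >= ct),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Map surviving correlations back onto the structure
#'
#' Per-residue scalar from a filtered pair list — the number of surviving
#' correlation partners (`mode = "count"`) or the maximum surviving
#' |correlation| (`mode = "max"`) — written to the B-factor column of a PDB
#' file via [write_bfactor_annotation].
#'
#' @param pairs a filtered pair data.frame from [apply_filters].
#' @param result the `correlation_result` the pairs came from.
#' @param model the [structure_model].
#' @param mode `"count"` or `"max"`.
#' @param path optional output PDB path.
#' @return (invisibly) the per-residue annotation vector over all model
#'   beads.
#' @export
map_to_structure <- function(pairs, result, model, mode = c("count", "max"),
                             path = NULL) {
  mode <- match.arg(mode)
  values <- numeric(n_atoms(model))
  if (nrow(pairs) > 0L) {
    ai <- result$selection[pairs$i]
    aj <- result$selection[pairs$j]
    for (p in seq_len(nrow(pairs))) {
      if (mode == "count") {
        values[ai[p]] <- values[ai[p]] + 1
        values[aj[p]] <- values[aj[p]] + 1
      } else {
        values[ai[p]] <- max(values[ai[p]], abs(pairs$value[p]))
        values[aj[p]] <- max(values[aj[p]], abs(pairs$value[p]))
      }
    }
  }
  if (!is.null(path)) write_bfactor_annotation(model, values, path)
  invisible(values)
}

#' Write a correlation matrix as long-format TSV
#'
#' @param result a `correlation_result`.
#' @param path output path.
#' @param keep_na include NA (uncomputed) entries.
#' @export
write_correlation_tsv <- function(result, path, keep_na = FALSE) {
  M <- result$matrix
  ut <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(key_i = result$keys[ut[, 1L]],
                   key_j = result$keys[ut[, 2L]],
                   value = M[ut], stringsAsFactors = FALSE)
  if (!keep_na) df <- df[!is.na(df$value), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
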