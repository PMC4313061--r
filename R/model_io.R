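# Text-format I/O: single- and multi-model PDB, XYZ trajectory blocks,
# B-factor annotation, and the plain-text partition config.
#
# Only the C-alpha bead dialect is supported: ATOM/HETATM records with one
# bead per residue, chain id = monomer label. Coordinates are Angstrom,
# written at the PDB's native 1e-3 precision.

parse_pdb_atom <- function(line, lineno) {
  num <- function(from, to, what) {
    s <- trimws(substr(line, from, to))
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stopf("parse error at line %d: bad %s field '%s'",
                        lineno, what, s)
    v
  }
  list(serial = as.integer(num(7, 11, "atom serial")),
       chain = {
         ch <- substr(line, 22, 22)
         if (ch == " ") "A" else ch
       },
       resseq = as.integer(num(23, 26, "residue number")),
       x = num(31, 38, "x coordinate"),
       y = num(39, 46, "y coordinate"),
       z = num(47, 54, "z coordinate"),
       b = if (nchar(line) >= 66 &&
               nzchar(trimws(substr(line, 61, 66)))) num(61, 66, "B factor") else 0)
}

pdb_atoms_to_model <- function(atoms, box = NULL) {
  serial <- vapply(atoms, `[[`, 0L, "serial")
  ord <- order(serial)
  atoms <- atoms[ord]
  structure_model(
    xyz = do.call(rbind, lapply(atoms, function(a) c(a$x, a$y, a$z))),
    residue_index = vapply(atoms, `[[`, 0L, "resseq"),
    monomer = vapply(atoms, `[[`, "", "chain"),
    atom_index = serial[ord],
    bfactor = vapply(atoms, `[[`, 0, "b"),
    box = box)
}

#' Read a bead structure from file
#'
#' @param path file path.
#' @param format `"pdb"` (ATOM/HETATM records, monomer = chain id) or
#'   `"xyz"` (plain XYZ block; monomer/residue labels come from the sidecar
#'   arguments since XYZ carries no metadata).
#' @param monomer,residue_index sidecar labels for `format = "xyz"`;
#'   defaults: all beads in monomer "A", residues 1..n.
#' @return a [structure_model].
#' @export
read_structure <- function(path, format = c("pdb", "xyz"),
                           monomer = NULL, residue_index = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    atoms <- list()
    box <- NULL
    for (i in seq_along(lines)) {
      rec <- substr(lines[i], 1, 6)
      if (rec %in% c("ATOM  ", "HETATM")) {
        atoms[[length(atoms) + 1L]] <- parse_pdb_atom(lines[i], i)
      } else if (rec == "CRYST1") {
        box <- suppressWarnings(as.numeric(c(substr(lines[i], 7, 15),
                                             substr(lines[i], 16, 24),
                                             substr(lines[i], 25, 33))))
        if (any(is.na(box))) stopf("parse error at line %d: bad CRYST1 record", i)
      } else if (rec %in% c("ENDMDL", "MODEL ")) {
        # single-structure reader stops at the first model boundary after atoms
        if (rec == "ENDMDL" && length(atoms) > 0L) break
      }
    }
    if (length(atoms) == 0L) stopf("no ATOM records in %s", path)
    pdb_atoms_to_model(atoms, box = box)
  } else {
    blk <- parse_xyz_block(lines, 1L, frame = 1L)
    n <- nrow(blk$xyz)
    structure_model(blk$xyz,
                    residue_index = residue_index %||% seq_len(n),
                    monomer = monomer %||% rep("A", n))
  }
}

format_pdb_atom <- function(serial, chain, resseq, xyz, b = 0) {
  if (abs(b) > 999.99) stopf("value %g not representable in the B-factor column", b)
  sprintf("ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, chain, resseq, xyz[1], xyz[2], xyz[3], 1, b)
}

model_pdb_lines <- function(model, bfactor = NULL) {
  b <- bfactor %||% model$bfactor %||% rep(0, n_atoms(model))
  vapply(seq_len(n_atoms(model)), function(i) {
    format_pdb_atom(model$atom_index[i], model$monomer[i],
                    model$residue_index[i], model$xyz[i, ], b[i])
  }, "")
}

#' Write a bead structure to a PDB file
#'
#' @param model a [structure_model].
#' @param path output path.
#' @param bfactor optional per-bead scalars for the temperature-factor
#'   column (2 decimals).
#' @export
write_structure <- function(model, path, bfactor = NULL) {
  lines <- character(0)
  if (!is.null(model$box)) {
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     model$box[1], model$box[2], model$box[3])
  }
  lines <- c(lines, model_pdb_lines(model, bfactor), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Annotate a structure with per-residue scalars in the B-factor column
#'
#' Used to map analysis results (e.g. counts of surviving correlation
#' partners) back onto the structure. Values are recoverable to 2 decimals
#' on re-reading.
#'
#' @param model a [structure_model].
#' @param values numeric vector, one value per residue (bead).
#' @param path output PDB path.
#' @export
write_bfactor_annotation <- function(model, values, path) {
  if (length(values) != n_atoms(model))
    stopf("got %d values for %d residues", length(values), n_atoms(model))
  if (!all(is.finite(values))) stopf("non-finite annotation value")
  write_structure(model, path, bfactor = values)
}

parse_xyz_block <- function(lines, at, frame) {
  if (at > length(lines) || !nzchar(trimws(lines[at]))) return(NULL)
  n <- suppressWarnings(as.integer(trimws(lines[at])))
  if (is.na(n) || n <= 0L)
    stopf("parse error at line %d: bad XYZ atom count '%s'", at, lines[at])
  if (at + 1L + n > length(lines))
    stopf("truncated XYZ frame %d (expected %d atoms)", frame, n)
  xyz <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    ln <- at + 1L + k
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L)
      stopf("parse error at line %d: expected 'name x y z'", ln)
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v)))
      stopf("parse error at line %d: non-numeric coordinate", ln)
    xyz[k, ] <- v
  }
  list(xyz = xyz, next_at = at + 2L + n)
}

#' Read a trajectory from file
#'
#' @param path file path.
#' @param format `"pdb"` (multi-model: MODEL/ENDMDL blocks) or `"xyz"`
#'   (concatenated XYZ blocks).
#' @param dt frame interval in ps (not stored in either format).
#' @return a [trajectory].
#' @export
read_trajectory <- function(path, format = c("pdb", "xyz"), dt = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  if (format == "pdb") {
    cur <- list()
    in_model <- FALSE
    flush <- function() {
      if (length(cur) > 0L) frames[[length(frames) + 1L]] <<-
          do.call(rbind, lapply(cur, function(a) c(a$x, a$y, a$z)))
      cur <<- list()
    }
    for (i in seq_along(lines)) {
      rec <- substr(lines[i], 1, 6)
      if (rec %in% c("ATOM  ", "HETATM")) {
        cur[[length(cur) + 1L]] <- parse_pdb_atom(lines[i], i)
      } else if (rec == "ENDMDL") {
        flush(); in_model <- FALSE
      } else if (rec == "MODEL ") {
        if (in_model) stopf("parse error at line %d: nested MODEL record", i)
        in_model <- TRUE
      }
    }
    flush()
  } else {
    at <- 1L
    repeat {
      # skip blank separator lines
      while (at <= length(lines) && !nzchar(trimws(lines[at]))) at <- at + 1L
      if (at > length(lines)) break
      blk <- parse_xyz_block(lines, at, frame = length(frames) + 1L)
      frames[[length(frames) + 1L]] <- blk$xyz
      at <- blk$next_at
    }
  }
  if (length(frames) == 0L) stopf("no frames found in %s", path)
  counts <- vapply(frames, nrow, 0L)
  if (any(counts != counts[1L]))
    stopf("frame %d has %d atoms but frame 1 has %d",
          which(counts != counts[1L])[1L], counts[counts != counts[1L]][1L],
          counts[1L])
  trajectory(frames, dt = dt)
}

#' Write a trajectory to file
#'
#' @param traj a [trajectory].
#' @param model the congruent [structure_model] providing labels.
#' @param path output path.
#' @param format `"pdb"` (multi-model) or `"xyz"`.
#' @export
write_trajectory <- function(traj, model, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  check_congruent(traj, model)
  nf <- n_frames(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    m <- model
    m$xyz <- traj$coords[, , f]
    if (format == "pdb") {
      writeLines(sprintf("MODEL %8d", f), con)
      writeLines(model_pdb_lines(m), con)
      writeLines("ENDMDL", con)
    } else {
      writeLines(as.character(n_atoms(model)), con)
      writeLines(sprintf("frame %d dt %g", f, traj$dt), con)
      writeLines(sprintf("CA %12.6f %12.6f %12.6f",
                         m$xyz[, 1], m$xyz[, 2], m$xyz[, 3]), con)
    }
  }
  if (format == "pdb") writeLines("END", con)
  invisible(path)
}

#' Read a subdomain partition from a plain-text config
#'
#' One group per line: `name: monomer start-end[, monomer start-end ...]`,
#' e.g. `PN1: A 11-20, B 11-20, C 11-20`. `#` starts a comment.
#'
#' @param path file path.
#' @return a [subdomain_partition].
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^([^:]+):(.+)$", ln))[[1L]]
    if (length(m) != 3L) stopf("parse error at line %d: expected 'name: ranges'", i)
    grp <- trimws(m[2L])
    for (part in strsplit(m[3L], ",")[[1L]]) {
      pm <- regmatches(part,
                       regexec("^\\s*(\\S+)\\s+(\\d+)\\s*-\\s*(\\d+)\\s*$", part))[[1L]]
      if (length(pm) != 4L)
        stopf("parse error at line %d: bad range '%s'", i, trimws(part))
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, monomer = pm[2L],
        start = as.integer(pm[3L]), end = as.integer(pm[4L]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stopf("no partition entries in %s", path)
  subdomain_partition(do.call(rbind, rows))
}

#' Write a subdomain partition config
#'
#' @param partition a [subdomain_partition].
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  out <- character(0)
  for (g in unique(partition$group)) {
    sub <- partition[partition$group == g, , drop = FALSE]
    out <- c(out, sprintf("%s: %s", g,
                          paste(sprintf("%s %d-%d", sub$monomer, sub$start,
                                        sub$end), collapse = ", ")))
  }
  writeLines(out, path)
  invisible(path)
}
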