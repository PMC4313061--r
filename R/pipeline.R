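# Study orchestration: build the toy trimer, run the five steering
# protocols, run all analyses, and emit a comparison report as TSV/PDB files
# in an output directory.

.PROTOCOLS <- c("freeDyn", "tmDom", "freeMon", "freePP", "fullTMD")

#' Default study configuration
#'
#' One configuration object drives the whole study; no hidden defaults
#' outside it. Per-protocol dynamics seeds are derived as `seed + protocol
#' index` so runs are independent but the report is bit-reproducible.
#'
#' @param seed master seed.
#' @param out_dir report directory.
#' @param protocols subset of freeDyn, tmDom, freeMon, freePP, fullTMD.
#' @param n_steps integration steps per steered protocol run.
#' @param n_steps_free integration steps for the unbiased (freeDyn) run;
#'   default 5x the steered duration, mirroring the study design of a long
#'   equilibrium reference versus shorter steered runs (and giving the
#'   stationarity statistics enough independent samples).
#' @param beads_per_subdomain trimer size knob.
#' @param k_tmd per-atom TMD force constant (kcal/(mol A^2)).
#' @param free_monomer unsteered monomer label (T-state analogue).
#' @param rmsf_threshold,corr_threshold,knn_k analysis thresholds.
#' @param window running-average width (frames) for the summary.
#' @param gen_max_frames frame cap for the generalized matrix (subsampling
#'   keeps the kNN estimate inside the runtime budget).
#' @param gen_bead_stride bead subsampling stride for the generalized matrix
#'   (every `gen_bead_stride`-th bead; 1 = all beads). A pure runtime knob:
#'   the kNN mutual-information estimate is O(pairs x frames^2).
#' @return object of class `run_config` (a list).
#' @export
run_config <- function(seed = 1, out_dir = file.path(tempdir(), "domainflux"),
                       protocols = .PROTOCOLS, n_steps = 24000,
                       n_steps_free = 5 * n_steps,
                       beads_per_subdomain = 56, k_tmd = 3,
                       free_monomer = "B", rmsf_threshold = 1.5,
                       corr_threshold = 0.5, knn_k = 6, window = 20,
                       gen_max_frames = 200, gen_bead_stride = 2) {
  protocols <- match.arg(protocols, .PROTOCOLS, several.ok = TRUE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 protocols = protocols,
                 spec = trimer_spec(beads_per_subdomain = beads_per_subdomain,
                                    seed = seed),
                 motion = default_study_motion(seed = seed),
                 enm = enm_parameters(n_steps = n_steps, seed = seed),
                 n_steps_free = as.integer(n_steps_free),
                 k_tmd = k_tmd, free_monomer = free_monomer,
                 rmsf_threshold = rmsf_threshold,
                 corr_threshold = corr_threshold, knn_k = knn_k,
                 window = as.integer(window),
                 gen_max_frames = as.integer(gen_max_frames),
                 gen_bead_stride = as.integer(gen_bead_stride)),
            class = "run_config")
}

#' Read a study configuration from a plain-text file
#'
#' Flat `key = value` lines (comments with `#`); recognised keys are the
#' arguments of [run_config] (`protocols` as a comma-separated list).
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", ln))[[1L]]
    if (length(m) != 3L) stopf("parse error at line %d: expected 'key = value'", i)
    kv[[m[2L]]] <- trimws(m[3L])
  }
  args <- list()
  num_keys <- c("seed", "n_steps", "n_steps_free", "beads_per_subdomain", "k_tmd",
                "rmsf_threshold", "corr_threshold", "knn_k", "window",
                "gen_max_frames", "gen_bead_stride")
  for (k in names(kv)) {
    args[[k]] <- if (k %in% num_keys) as.numeric(kv[[k]])
    else if (k == "protocols") trimws(strsplit(kv[[k]], ",")[[1L]])
    else kv[[k]]
  }
  do.call(run_config, args)
}

validate_protocol_sets <- function(model, partition, free_monomer) {
  sel <- lapply(.PROTOCOLS, protocol_selection, model = model,
                partition = partition, free_monomer = free_monomer)
  names(sel) <- .PROTOCOLS
  if (!setequal(sel$freePP, union(sel$tmDom, sel$freeMon)))
    stopf("protocol invariant violated: freePP != tmDom + freeMon")
  for (p in setdiff(.PROTOCOLS, "fullTMD")) {
    if (length(setdiff(sel[[p]], sel$fullTMD)) > 0L)
      stopf("protocol invariant violated: fullTMD does not contain %s", p)
  }
  sel
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("study stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full toy study
#'
#' Builds the trimer, validates the protocol set algebra, runs every
#' requested steering protocol, and writes per-protocol trajectories,
#' steering logs, per-subdomain RMSD-to-target series, CoM displacement
#' series and Phi/Theta orientation series, plus — for the unbiased run —
#' Pearson and generalized correlation matrices, filtered pairs, block
#' summaries and the structure annotation. Finishes with a cross-protocol
#' summary TSV. Deterministic for fixed seeds; a stage failure aborts with
#' the stage name (partial outputs are retained).
#'
#' @param config a [run_config].
#' @return the report directory path (invisibly).
#' @export
run_study <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  built <- run_stage("build_trimer", build_trimer(config$spec))
  model <- built$model; partition <- built$partition
  target <- run_stage("make_target",
                      make_target_conformation(model, partition, config$motion))
  sels <- run_stage("protocol_validation",
                    validate_protocol_sets(model, partition, config$free_monomer))
  write_structure(model, file.path(config$out_dir, "structure.pdb"))
  write_structure(target, file.path(config$out_dir, "target.pdb"))
  write_partition(partition, file.path(config$out_dir, "partition.cfg"))
  # RMSD-to-target is measured in the free monomer's porter frame (the
  # per-monomer analysis convention)
  fit_sel <- partition_atoms(partition, model,
                             group = c("PN1", "PN2", "PC1", "PC2"),
                             monomer = config$free_monomer)

  for (pi in seq_along(config$protocols)) {
    pname <- config$protocols[pi]
    pdir <- file.path(config$out_dir, pname)
    dir.create(pdir, showWarnings = FALSE)
    params <- config$enm
    params$seed <- config$seed + match(pname, .PROTOCOLS)
    if (pname == "freeDyn") params$n_steps <- config$n_steps_free
    prot <- steering_protocol(target, sels[[pname]], k_tmd = config$k_tmd,
                              name = pname)
    res <- run_stage(paste0("dynamics/", pname),
                     run_dynamics(model, params, prot))
    write_trajectory(res$trajectory, model, file.path(pdir, "traj.xyz"),
                     format = "xyz")
    if (!is.null(res$log)) write_tsv(res$log, file.path(pdir, "steering_log.tsv"))
    run_stage(paste0("geometry/", pname), {
      ser <- orientation_series(res$trajectory, partition, model,
                                target = target, window = config$window,
                                fit_sel = fit_sel)
      write_tsv(ser, file.path(pdir, "orientation_series.tsv"))
    })
    if (pname == "freeDyn") {
      run_stage("correlation/freeDyn", {
        traj <- res$trajectory
        nf <- n_frames(traj)
        pear <- pearson_matrix(traj, model = model,
                               rmsf_threshold = config$rmsf_threshold,
                               corr_threshold = config$corr_threshold)
        write_correlation_tsv(pear, file.path(pdir, "pearson.tsv"))
        sub <- traj
        if (nf > config$gen_max_frames) {
          keep <- round(seq(1, nf, length.out = config$gen_max_frames))
          sub <- trajectory(traj$coords[, , keep, drop = FALSE],
                            dt = traj$dt, seed = traj$seed)
        }
        gsel <- seq(1L, n_atoms(model), by = config$gen_bead_stride)
        gen <- generalized_matrix(sub, selection = gsel,
                                  knn_k = config$knn_k,
                                  seed = config$seed, model = model,
                                  rmsf_threshold = config$rmsf_threshold,
                                  corr_threshold = config$corr_threshold)
        write_correlation_tsv(gen, file.path(pdir, "generalized.tsv"))
        pairs <- apply_filters(gen)
        write_tsv(pairs, file.path(pdir, "filtered_pairs.tsv"))
        write_tsv(block_summary(gen, partition, model),
                  file.path(pdir, "block_summary.tsv"))
        map_to_structure(pairs, gen, model, mode = "count",
                         path = file.path(pdir, "correlation_map.pdb"))
      })
    }
  }
  summary <- run_stage("compare_protocols",
                       compare_protocols(config$out_dir,
                                         window = config$window))
  write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
  invisible(config$out_dir)
}

#' Cross-protocol comparison table
#'
#' One row per protocol x subdomain: the final running-average-smoothed
#' RMSD-to-target, the final smoothed Phi and Theta changes, and the final
#' smoothed CoM displacement magnitude, read from the per-protocol stage
#' outputs of [run_study].
#'
#' @param report_dir a [run_study] output directory.
#' @param window running-average width in frames (default 20).
#' @return data.frame (protocol, monomer, group, rmsd_final, dphi, dtheta,
#'   com_mag).
#' @export
compare_protocols <- function(report_dir, window = 20) {
  rows <- list()
  for (pname in .PROTOCOLS) {
    f <- file.path(report_dir, pname, "orientation_series.tsv")
    if (!dir.exists(file.path(report_dir, pname))) next
    if (!file.exists(f))
      stopf("missing stage output for protocol %s: %s", pname, f)
    ser <- read_tsv(f)
    ser <- ser[order(ser$monomer, ser$group, ser$frame), ]
    agg <- do.call(rbind, lapply(split(ser, paste(ser$monomer, ser$group)),
                                 function(s) {
      w <- min(window, nrow(s))
      data.frame(protocol = pname, monomer = s$monomer[1L],
                 group = s$group[1L],
                 rmsd_final = running_average(s$rmsd, w)[nrow(s)],
                 dphi = running_average(s$phi, w)[nrow(s)],
                 dtheta = running_average(s$theta, w)[nrow(s)],
                 com_mag = running_average(s$mag, w)[nrow(s)],
                 stringsAsFactors = FALSE)
    }))
    rows[[length(rows) + 1L]] <- agg
  }
  if (length(rows) == 0L) stopf("no protocol outputs found under %s", report_dir)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Command-line entry point
#'
#' `domainflux study --config cfg [--out dir] [--seed S]` runs the full
#' study; `domainflux run --protocol P [--config cfg] [--seed S] --out
#' traj.pdb` runs a single protocol and writes the trajectory (plus a
#' steering log TSV next to it); `domainflux analyze --traj t.pdb
#' --partition p.cfg [--method pearson|generalized] --out out.tsv` analyses
#' an existing trajectory. Invoked by the `inst/cli/domainflux` script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: domainflux study   --config cfg.txt [--out dir] [--seed S]",
    "       domainflux run     --protocol NAME [--config cfg.txt] [--seed S] --out traj.pdb",
    "       domainflux analyze --traj traj.pdb --partition part.cfg",
    "                          [--method pearson|generalized] --out out.tsv",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- list()
  i <- 2L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--") || i == length(args))
      stopf("bad argument '%s'\n%s", args[i], usage)
    opt[[substring(args[i], 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  if (cmd == "study") {
    cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    if (!is.null(opt$out)) cfg$out_dir <- opt$out
    run_study(cfg)
    message("report written to ", cfg$out_dir)
  } else if (cmd == "run") {
    if (is.null(opt$protocol) || is.null(opt$out)) stopf("run needs --protocol and --out\n%s", usage)
    cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    built <- build_trimer(cfg$spec)
    target <- make_target_conformation(built$model, built$partition, cfg$motion)
    sel <- protocol_selection(opt$protocol, built$model, built$partition,
                              cfg$free_monomer)
    params <- cfg$enm; params$seed <- cfg$seed
    res <- run_dynamics(built$model, params,
                        steering_protocol(target, sel, k_tmd = cfg$k_tmd))
    fmt <- if (grepl("\\.xyz$", opt$out)) "xyz" else "pdb"
    write_trajectory(res$trajectory, built$model, opt$out, format = fmt)
    if (!is.null(res$log))
      write_tsv(res$log, paste0(sub("\\.(pdb|xyz)$", "", opt$out),
                                "_steering_log.tsv"))
    message("trajectory written to ", opt$out)
  } else if (cmd == "analyze") {
    if (is.null(opt$traj) || is.null(opt$partition) || is.null(opt$out))
      stopf("analyze needs --traj, --partition and --out\n%s", usage)
    fmt <- if (grepl("\\.xyz$", opt$traj)) "xyz" else "pdb"
    traj <- read_trajectory(opt$traj, format = fmt)
    method <- opt$method %||% "pearson"
    res <- if (method == "generalized")
      generalized_matrix(traj, seed = as.integer(opt$seed %||% "1"))
    else pearson_matrix(traj)
    write_correlation_tsv(res, opt$out)
    message("correlation matrix written to ", opt$out)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
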