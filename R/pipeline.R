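#' Read a pipeline run configuration
#'
#' The configuration is YAML with the schema documented in
#' \code{\link{run_pipeline}}. Paths are interpreted relative to the config
#' file's directory.
#'
#' @param path YAML file.
#' @return a named list of class \code{eef_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  cfg$topology_pdb <- rel(cfg$topology_pdb)
  cfg$topology_tsv <- rel(cfg$topology_tsv)
  for (i in seq_along(cfg$conditions)) {
    cfg$conditions[[i]]$trajectory <- rel(cfg$conditions[[i]]$trajectory)
  }
  class(cfg) <- c("eef_config", class(cfg))
  cfg
}

## Canonical md5 hash of the semantically meaningful config fields.
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  cfg$verbose <- NULL
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x) %||% seq_along(x))]
      lapply(x, canon)
    } else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(canon(unclass(cfg)), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

build_selection <- function(x, name) {
  do.call(selection_spec, c(list(name = name), x))
}

#' Run every analysis stage over a condition matrix
#'
#' One configuration drives all stages for all conditions (ambient plus
#' field runs) and all condition pairs, writing per-condition CSVs, pair
#' CSVs and a JSON manifest with summary statistics and a config hash.
#' Reruns with the same config produce byte-identical CSVs.
#'
#' Config fields: \code{topology_pdb}, \code{topology_tsv}; a
#' \code{conditions} list of \code{{name, trajectory}} (multi-model PDB
#' paths); optional \code{pairs} list of \code{{eef, ambient}} condition
#' names for delta-RMSF and endpoint displacement; optional
#' \code{distance_probes} list of \code{{name, probe, target}} where probe/
#' target are selection filter sets; \code{distribution_window} (ps pair;
#' default: the last half of each trajectory); and scalar options
#' \code{salt_bridge_cutoff} (3.2), \code{displacement_threshold} (2),
#' \code{bend_mode} ("beta_only"), \code{probe_mode} ("residue_com"),
#' \code{dipole_reference} ("com"), \code{frame_interval} (25).
#' Selections referenced anywhere are resolved against the topology before
#' any stage runs; a failure aborts before any output is written.
#'
#' @param config an \code{eef_config} (or equivalent list).
#' @param out_dir output directory (default \code{config$out_dir}).
#' @param verbose print one line per stage (default FALSE).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir, verbose = isTRUE(config$verbose)) {
  if (is.null(out_dir)) stop("no output directory configured")
  cutoff <- config$salt_bridge_cutoff %||% 3.2
  dthr <- config$displacement_threshold %||% 2
  bend_mode <- config$bend_mode %||% "beta_only"
  probe_mode <- config$probe_mode %||% "residue_com"
  dref <- config$dipole_reference %||% "com"
  dt <- config$frame_interval %||% 25

  topo <- read_structure(config$topology_pdb, config$topology_tsv)

  ## fail-fast: resolve every referenced selection before any stage runs
  probes <- lapply(config$distance_probes %||% list(), function(p) {
    list(name = p$name,
         probe = build_selection(p$probe, paste0(p$name, ":probe")),
         target = build_selection(p$target, paste0(p$name, ":target")))
  })
  resolve_selection(ca_selection(), topo)
  for (p in probes) {
    resolve_selection(p$probe, topo)
    resolve_selection(p$target, topo)
  }
  for (sel in list(selection_spec("alpha H7", monomer = "alpha", region = "H7"),
                   selection_spec("beta H7", monomer = "beta", region = "H7"))) {
    resolve_selection(sel, topo)
  }
  cond_names <- vapply(config$conditions, `[[`, "", "name")
  for (pr in config$pairs %||% list()) {
    for (nm in c(pr$eef, pr$ambient)) {
      if (!nm %in% cond_names) stopf("pair references unknown condition '%s'", nm)
    }
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "eeftraj",
                   version = as.character(utils::packageVersion("eeftraj")),
                   config_hash = config_hash(config),
                   complete = FALSE, conditions = list(), pairs = list())
  wcsv <- function(df, ...) utils::write.csv(df, file.path(out_dir, ...), row.names = FALSE)
  log_line <- function(...) if (verbose) message(sprintf(...))

  stage <- function(cond, what, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed for condition '%s': %s", what, cond, conditionMessage(e))
    })
    log_line("[%s] %s: %.2fs", cond, what, proc.time()[3] - t0)
    out
  }

  results <- list()
  for (cond in config$conditions) {
    nm <- cond$name
    cdir <- file.path(out_dir, nm)
    dir.create(cdir, showWarnings = FALSE)
    traj <- stage(nm, "read_trajectory",
                  read_trajectory(cond$trajectory, topo, frame_interval = dt))
    tmax <- traj$times[n_frames(traj)] + dt
    dwin <- as.numeric(config$distribution_window %||% c(tmax / 2, tmax))

    srs <- stage(nm, "rmsd_series_by_ss", rmsd_series_by_ss(traj, topo))
    wcsv(srs, nm, "rmsd.csv")
    rf <- stage(nm, "rmsf", rmsf(traj, topo, window = dwin))
    wcsv(rf, nm, "rmsf.csv")
    dip <- stage(nm, "dipole_series", dipole_series(traj, topo, reference_point = dref))
    wcsv(dip, nm, "dipole.csv")
    bend <- stage(nm, "bend_angle_series",
                  bend_angle_series(traj, topo, reference = topo, mode = bend_mode, window = dwin))
    wcsv(attr(bend, "series"), nm, "bend.csv")
    ## the alternate bend reading is always reported alongside
    alt_mode <- if (bend_mode == "beta_only") "combined" else "beta_only"
    bend_alt <- stage(nm, paste0("bend_angle_series:", alt_mode),
                      bend_angle_series(traj, topo, reference = topo, mode = alt_mode, window = dwin))
    wcsv(attr(bend_alt, "series"), nm, paste0("bend_", alt_mode, ".csv"))
    elo <- stage(nm, "elongation_series", elongation_series(traj, topo, window = dwin))
    wcsv(attr(elo, "series"), nm, "elongation.csv")
    dists <- list()
    for (p in probes) {
      ds <- stage(nm, paste0("distance:", p$name),
                  distance_series(traj, topo, p$probe, p$target,
                                  probe_mode = probe_mode, window = dwin))
      wcsv(attr(ds, "series"), nm, paste0("distance_", p$name, ".csv"))
      dists[[p$name]] <- ds
    }
    ms <- stage(nm, "msd", msd(traj, topo))
    wcsv(ms, nm, "msd.csv")
    sb <- stage(nm, "salt_bridges",
                salt_bridges(topo, xyz = frame_coords(traj, 1), cutoff = cutoff))
    wcsv(sb, nm, "salt_bridges.csv")
    cnt <- stage(nm, "ss_counts", ss_counts(traj, topo, classifier = "labels"))
    wcsv(cnt, nm, "ss_counts.csv")

    results[[nm]] <- list(traj = traj, rmsf = rf, window = dwin)
    manifest$conditions[[nm]] <- list(
      n_frames = n_frames(traj),
      distribution_window_ps = dwin,
      rmsd_all_mean = mean(srs$rmsd_all),
      rmsd_helix_sheet_mean = mean(srs$rmsd_helix_sheet),
      rmsd_other_mean = mean(srs$rmsd_other),
      dipole_mean_debye = mean(dip$magnitude_debye),
      bend = list(mode = bend_mode, mean = bend$mean, quartiles = as.list(bend$quartiles)),
      bend_alt = list(mode = alt_mode, mean = bend_alt$mean),
      elongation = list(mean = elo$mean, quartiles = as.list(elo$quartiles)),
      distances = lapply(dists, function(d) list(mean = d$mean, quartiles = as.list(d$quartiles))),
      n_salt_bridges = nrow(sb))
  }

  for (pr in config$pairs %||% list()) {
    pname <- paste0(pr$eef, "_vs_", pr$ambient)
    te <- results[[pr$eef]]$traj; ta <- results[[pr$ambient]]$traj
    drf <- stage(pname, "delta_rmsf", delta_rmsf(results[[pr$eef]]$rmsf, results[[pr$ambient]]$rmsf))
    wcsv(drf, paste0("delta_rmsf_", pname, ".csv"))
    xa <- frame_coords(ta, n_frames(ta)); xb <- frame_coords(te, n_frames(te))
    fd <- stage(pname, "final_displacement", final_displacement(xa, xb, topo))
    wcsv(fd, paste0("final_displacement_", pname, ".csv"))
    dv <- stage(pname, "displacement_vectors",
                displacement_vectors(xa, xb, topo, threshold = dthr))
    wcsv(dv, paste0("displacement_vectors_", pname, ".csv"))
    manifest$pairs[[pname]] <- list(
      max_displacement_A = max(fd$displacement_A, na.rm = TRUE),
      n_vectors_over_threshold = nrow(dv),
      delta_rmsf_max = max(drf$delta_rmsf_A))
  }

  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write the canonical synthetic fixture set
#'
#' Ambient plus the four field directions at each of {50, 100, 200, 750}
#' kV/cm -- 17 conditions. Each condition directory gets the dimer PDB +
#' annotation TSV, a multi-model PDB trajectory and a ground-truth JSON.
#' \code{tiny} = 50 frames per condition, \code{standard} = 2000. Seeds are
#' derived deterministically from \code{seed} per condition, so the same
#' seed rewrites identical files.
#'
#' @param out_dir output directory.
#' @param scale \code{"tiny"} (default) or \code{"standard"}.
#' @param seed base seed (default 1).
#' @param conditions optional subset of condition names to write.
#' @return invisibly, a data.frame describing the written conditions.
#' @export
make_fixtures <- function(out_dir, scale = c("tiny", "standard"), seed = 1,
                          conditions = NULL) {
  scale <- match.arg(scale)
  nf <- if (scale == "tiny") 50 else 2000
  grid <- fixture_grid()
  if (!is.null(conditions)) {
    bad <- setdiff(conditions, grid$name)
    if (length(bad)) stopf("unknown condition(s): %s", paste(bad, collapse = ", "))
    grid <- grid[grid$name %in% conditions, , drop = FALSE]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(grid))) {
    nm <- grid$name[i]
    cdir <- file.path(out_dir, nm)
    dir.create(cdir, showWarnings = FALSE)
    params <- eef_preset(grid$preset[i], grid$strength[i], n_frames = nf,
                         seed = seed + grid$offset[i])
    st <- build_synthetic_dimer(params)
    gen <- generate_trajectory(st, params)
    write_structure(st, file.path(cdir, "structure.pdb"), file.path(cdir, "annotations.tsv"))
    write_trajectory(gen$trajectory, st, file.path(cdir, "trajectory.pdb"))
    jsonlite::write_json(gen$ground_truth, file.path(cdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(grid)
}

fixture_grid <- function() {
  dirs <- c("pos_transverse", "neg_transverse", "pos_longitudinal", "neg_longitudinal")
  strengths <- c(50, 100, 200, 750)
  g <- expand.grid(preset = dirs, strength = strengths, stringsAsFactors = FALSE)
  g <- g[order(g$preset, g$strength), ]
  out <- rbind(data.frame(preset = "ambient", strength = 0, stringsAsFactors = FALSE), g)
  out$name <- ifelse(out$preset == "ambient", "ambient",
                     paste0(out$preset, "_", out$strength))
  out$offset <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}
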