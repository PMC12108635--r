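# End-to-end pipeline: alignment -> trajectory statistics -> representative
# frame -> start-vs-representative geometry, interactions and binding-site
# conservation -> optional assay fits; tidy CSV/JSON outputs plus a run log.

#' Pipeline configuration
#'
#' @param trajectory path to a multi-model PDB trajectory, or a `Trajectory`.
#' @param domain_map path to a domain-map YAML, or a `DomainMap`.
#' @param reference optional start `Structure` (or PDB path); defaults to
#'   frame 1 of the trajectory.
#' @param melt_csv,binding_csv optional assay-table paths.
#' @param out_dir output directory (created if needed).
#' @param conservation_threshold binding-site conservation threshold
#'   (Angstrom, default 2).
#' @param superposition_cutoff closest-frame quality cutoff (Angstrom,
#'   default 10).
#' @param stages character vector of stages to run, from
#'   `c("geometry", "interactions", "cdr", "assays")`.
#' @param seed seed recorded in the log (analyses are deterministic).
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(trajectory, domain_map, reference = NULL,
                            melt_csv = NULL, binding_csv = NULL,
                            out_dir = "pipeline_out",
                            conservation_threshold = 2,
                            superposition_cutoff = 10,
                            stages = c("geometry", "interactions", "cdr",
                                       "assays"),
                            seed = 1) {
  if (conservation_threshold <= 0 || superposition_cutoff <= 0)
    stop("thresholds must be positive")
  for (p in c(if (is.character(trajectory)) trajectory,
              if (is.character(domain_map)) domain_map,
              if (is.character(reference)) reference, melt_csv, binding_csv))
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  structure(list(trajectory = trajectory, domain_map = domain_map,
                 reference = reference, melt_csv = melt_csv,
                 binding_csv = binding_csv, out_dir = out_dir,
                 conservation_threshold = conservation_threshold,
                 superposition_cutoff = superposition_cutoff,
                 stages = stages, seed = seed),
            class = "PipelineConfig")
}

.summary_as_list <- function(g) {
  list(pivot = as.numeric(g$pivot),
       centers = apply(g$centers, 2, as.numeric, simplify = FALSE),
       xy_angles_deg = as.list(g$xy_angles),
       pivot_distances_A = as.list(g$pivot_distances),
       z_offsets_A = as.list(g$z_offsets),
       conformation = g$label)
}

#' Run the full analysis pipeline
#'
#' Stages: align frames to the reference on alpha-carbons; trajectory
#' statistics (RMSD, per-domain RMSD, RMSF, Rg, centroid frame, closest
#' frame to the final frame); geometry summaries of the start and
#' representative (centroid) conformations with the start-vs-representative
#' comparison; interaction report; binding-site conservation report; assay
#' fits when tables are configured.  Writes tidy CSV series, a JSON report
#' and a plain-text run log into `out_dir`.  A stage failure aborts with
#' the stage name.
#'
#' @param config a [pipeline_config()].
#' @return the report bundle, invisibly (also written to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("scfvfcdyn %s | seed %d",
                         as.character(utils::packageVersion("scfvfcdyn")),
                         config$seed))
  log <- function(...) log_lines <<- c(log_lines, sprintf(...))

  traj <- stage("load", {
    if (inherits(config$trajectory, "Trajectory")) config$trajectory
    else read_trajectory(config$trajectory)
  })
  map <- stage("load", {
    if (inherits(config$domain_map, "DomainMap")) config$domain_map
    else parse_domain_map(config$domain_map)
  })
  reference <- stage("load", {
    if (is.null(config$reference)) frame_structure(traj, 1)
    else if (inherits(config$reference, "Structure")) config$reference
    else read_structure(config$reference)
  })
  stage("validate", validate_domain_map(map, reference))
  log("loaded trajectory: %d frames x %d atoms", n_frames(traj),
      nrow(traj$topology$atoms))

  report <- list()
  traj <- stage("align", align_frames(traj, reference))
  stats_ <- stage("trajectory-stats", {
    ts <- trajectory_stats(traj, reference, map)
    ts$closest_frame <- closest_frame(traj, map = map,
                                      quality_cutoff = config$superposition_cutoff)
    ts
  })
  rep_idx <- stats_$centroid_index
  rep_struct <- frame_structure(traj, rep_idx)
  start_struct <- frame_structure(traj, 1)
  log("representative (centroid) frame: %d", rep_idx)
  log("closest frame to final: %d (RMSD %.2f A, within %.0f A cutoff: %s)",
      stats_$closest_frame$index, stats_$closest_frame$rmsd,
      config$superposition_cutoff, stats_$closest_frame$within_cutoff)

  series <- data.frame(
    frame = seq_len(n_frames(traj)),
    metric = "rmsd", subunit = "all", value = stats_$rmsd_series,
    units = "A", stringsAsFactors = FALSE)
  for (s in names(stats_$domain_rmsd))
    series <- rbind(series, data.frame(frame = seq_len(n_frames(traj)),
                                       metric = "domain_rmsd", subunit = s,
                                       value = stats_$domain_rmsd[[s]],
                                       units = "A"))
  series <- rbind(series, data.frame(frame = seq_len(n_frames(traj)),
                                     metric = "rg", subunit = "all",
                                     value = stats_$rg_series, units = "A"))
  utils::write.csv(series, file.path(config$out_dir, "trajectory_series.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_$rmsf, file.path(config$out_dir, "rmsf.csv"),
                   row.names = FALSE)
  report$trajectory_stats <- list(
    n_frames = n_frames(traj),
    centroid_frame = rep_idx,
    closest_frame = stats_$closest_frame,
    rmsd_final_A = stats_$rmsd_series[n_frames(traj)])

  if ("geometry" %in% config$stages) {
    geo <- stage("geometry", {
      g0 <- geometry_summary(start_struct, map)
      g1 <- geometry_summary(rep_struct, map)
      list(start = g0, representative = g1,
           comparison = comparison_summary(g0, g1))
    })
    report$geometry <- list(
      start = .summary_as_list(geo$start),
      representative = .summary_as_list(geo$representative),
      comparison = list(
        contraction_percent = as.list(geo$comparison$contraction_percent),
        z_displacement_A = as.list(geo$comparison$z_displacement),
        angle_change_deg = as.list(geo$comparison$angle_change),
        start = "frame 1", representative = sprintf("frame %d", rep_idx)))
    log("geometry: contraction scFv1 %.2f %%, scFv2 %.2f %%",
        geo$comparison$contraction_percent["scFv1"],
        geo$comparison$contraction_percent["scFv2"])
  }

  if ("interactions" %in% config$stages) {
    ir <- stage("interactions",
                interaction_summary(start_struct, rep_struct, map))
    report$interactions <- list(
      energy_model = ir$energy_model,
      pairs = lapply(ir$pairs, function(p)
        list(e_start_kcal_mol = p$e_start, e_end_kcal_mol = p$e_end,
             percent_change = p$percent_change,
             n_hbonds_start = nrow(p$hbonds_start),
             n_hbonds_end = nrow(p$hbonds_end),
             n_salt_bridges_end = nrow(p$salt_end))),
      interchain = ir$interchain,
      linker_hbond_count = ir$linker_hbond_count)
  }

  if ("cdr" %in% config$stages) {
    cr <- stage("cdr", cdr_report(rep_struct, map,
                                  reference_structure = reference,
                                  threshold = config$conservation_threshold))
    report$cdr <- lapply(unclass(cr), function(r)
      list(overall_rmsd_A = r$overall_rmsd,
           per_cdr_rmsd_A = as.list(r$per_cdr_rmsd),
           conserved = r$conserved, threshold_A = r$threshold))
    log("binding-site conservation: scFv1 %.2f A, scFv2 %.2f A (threshold %.1f A)",
        cr$scFv1$overall_rmsd, cr$scFv2$overall_rmsd,
        config$conservation_threshold)
  }

  if ("assays" %in% config$stages) {
    if (!is.null(config$melt_csv)) {
      tm <- stage("assays", tm_from_melt(read_melt_curve(config$melt_csv)))
      report$dsf <- list(tm_mean_C = tm$tm_mean, tm_sd_C = tm$tm_sd,
                         tm_per_replicate_C = tm$tm_per_replicate)
      log("DSF: Tm %.2f degC", tm$tm_mean)
    }
    if (!is.null(config$binding_csv)) {
      bc <- stage("assays", read_binding_curve(config$binding_csv))
      sat <- stage("assays", fit_saturation_binding(bc))
      lg <- stage("assays", fit_ec50(bc))
      report$binding <- list(kd_nM = sat$kd, bmax = sat$bmax,
                             kd_se = sat$kd_se, bmax_se = sat$bmax_se,
                             ec50_nM = lg$ec50, hill = lg$hill)
      log("binding: KD %.3g nM, Bmax %.4g, EC50 %.3g nM",
          sat$kd, sat$bmax, lg$ec50)
    }
  }

  report$config <- list(
    stages = config$stages, seed = config$seed,
    conservation_threshold_A = config$conservation_threshold,
    superposition_cutoff_A = config$superposition_cutoff)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(report)
}
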