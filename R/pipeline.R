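# End-to-end comparative analysis of two systems (e.g. apo vs complex).
# Stages are independent: a failing stage is recorded in the report and
# the remaining stages still run.

pipeline_defaults <- function() {
  list(contact_cutoff = 4.5, neighbor_exclusion = 2L,
       cluster_threshold_coarse = 2.4, cluster_threshold_fine = 1.5,
       hbond_distance = 3.5, hbond_angle = 135,
       temperature = 300, fel_bins = 50L, basin_depth_cut = 3,
       selection = "calpha", discard_frac = 0.1, cluster_stride = 1L,
       max_cluster_frames = 400L, seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Fills documented defaults (4.5 A contact cutoff, 2.4/1.5 A cluster
#' thresholds, 3.5 A / 135 deg hydrogen-bond criterion, 300 K, 50x50 FEL
#' bins), rejects unknown keys, and range-checks every threshold. Applied
#' defaults are reported in the `applied_defaults` attribute.
#'
#' @param config named list of overrides (may be empty).
#' @return validated config list.
#' @export
validate_config <- function(config = list()) {
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  applied <- setdiff(names(defs), names(config))
  out <- utils::modifyList(defs, config)
  chk <- function(cond, field, bounds)
    if (!cond) stop(sprintf("validation error: %s out of range (%s)",
                            field, bounds))
  chk(out$contact_cutoff > 0, "contact_cutoff", "> 0")
  chk(out$neighbor_exclusion >= 0, "neighbor_exclusion", ">= 0")
  chk(out$cluster_threshold_coarse > 0, "cluster_threshold_coarse", "> 0")
  chk(out$cluster_threshold_fine > 0, "cluster_threshold_fine", "> 0")
  chk(out$hbond_distance > 0, "hbond_distance", "> 0")
  chk(out$hbond_angle >= 0 && out$hbond_angle <= 180, "hbond_angle",
      "[0, 180]")
  chk(out$temperature > 0, "temperature", "> 0")
  chk(out$fel_bins >= 2, "fel_bins", ">= 2")
  chk(out$discard_frac >= 0 && out$discard_frac < 1, "discard_frac",
      "[0, 1)")
  attr(out, "applied_defaults") <- applied
  out
}

run_stage <- function(report, name, fun) {
  res <- tryCatch(list(status = "ok", result = fun()),
                  error = function(e) list(status = "failed",
                                           error = conditionMessage(e)))
  report[[name]] <- res
  report
}

analyse_system <- function(traj, config) {
  sel <- select_atoms(traj, config$selection)
  if (!length(sel)) sel <- seq_len(n_atoms(traj))
  rep <- list()
  rep <- run_stage(rep, "rmsd", function() {
    r <- rmsd_series(traj, sel = sel, discard_frac = config$discard_frac)
    list(mean = r$mean, sd = r$sd, n = length(r$rmsd))
  })
  rep <- run_stage(rep, "rmsf", function() {
    r <- rmsf(traj, sel)
    b <- bfactor_from_rmsf(r)
    list(rmsf = unname(r), bfactor = unname(b))
  })
  rep <- run_stage(rep, "rgyr", function()
    list(first = radius_of_gyration(frame_coords(traj, 1L), sel),
         last = radius_of_gyration(frame_coords(traj, n_frames(traj)), sel)))
  rep <- run_stage(rep, "cluster", function() {
    idx <- if (n_frames(traj) > config$max_cluster_frames)
      round(seq(1, n_frames(traj), length.out = config$max_cluster_frames))
    else seq_len(n_frames(traj))
    sub <- trajectory(traj$topology,
                      traj$coords[, , idx, drop = FALSE])
    m <- pairwise_rmsd_matrix(sub, sel)
    coarse <- threshold_cluster(m, config$cluster_threshold_coarse)
    fine <- threshold_cluster(m, config$cluster_threshold_fine)
    growth <- cluster_growth(m, threshold = config$cluster_threshold_fine,
                             stride = config$cluster_stride)
    list(coarse_n = coarse$n_clusters, coarse_occupancy = coarse$occupancy,
         fine_n = fine$n_clusters,
         growth = growth$n_clusters[length(growth$n_clusters)])
  })
  rep <- run_stage(rep, "contacts", function() {
    first <- contact_map(traj, cutoff = config$contact_cutoff,
                         neighbor_exclusion = config$neighbor_exclusion,
                         frame_index = 1L)
    last <- contact_map(traj, cutoff = config$contact_cutoff,
                        neighbor_exclusion = config$neighbor_exclusion,
                        frame_index = n_frames(traj))
    cmp <- compare_maps(first, last)
    list(common = cmp$common, specific_first = cmp$specific_first,
         specific_last = cmp$specific_last,
         total_first = cmp$total_first, total_last = cmp$total_last,
         similarity = cmp$similarity, reduction_rate = cmp$reduction_rate)
  })
  rep <- run_stage(rep, "fel", function() {
    mod <- pca_traj(traj, sel)
    grid <- fel_grid(mod, T = config$temperature, bins = config$fel_bins)
    basins <- find_basins(grid, depth_cut = config$basin_depth_cut)
    list(n_basins = length(basins),
         basin_occupancy = vapply(basins, `[[`, numeric(1), "occupancy"),
         basin_floor = vapply(basins, `[[`, numeric(1), "floor_dg"),
         pc1_var_frac = mod$eigenvalues[1] / sum(mod$eigenvalues),
         pc1_gaussianity = pc_gaussianity(mod$projections[, 1]))
  })
  rep <- run_stage(rep, "hbonds", function() {
    if (!any(traj$topology$element == "H"))
      return(list(n_candidates = 0L, occupancy = numeric(0),
                  note = "no explicit hydrogens in topology"))
    cand <- find_hbond_candidates(traj)
    stats <- lapply(seq_len(nrow(cand)), function(i)
      hbond_occupancy(traj, cand[i, ], d_max = config$hbond_distance,
                      angle_min = config$hbond_angle))
    list(n_candidates = nrow(cand),
         occupancy = setNames(vapply(stats, `[[`, numeric(1), "frequency"),
                              cand$label))
  })
  rep
}

#' Run the full comparative analysis of two systems
#'
#' Executes RMSD/RMSF/Rg, clustering with growth, first-vs-last contact
#' comparison, PCA + free-energy landscape + basins, and a hydrogen-bond
#' scan for each system. Each stage's outcome is recorded with
#' `status: ok` or `status: failed` plus the error; a failure does not
#' stop the other stages. Identical inputs and config give an identical
#' report.
#'
#' @param traj_a,traj_b the two `trajectory` objects (e.g. apo, complex),
#'   or paths to multi-model PDB files.
#' @param config list of overrides accepted by [validate_config()].
#' @param output optional path to write the report as JSON.
#' @return nested report list (`systems$a`, `systems$b`, `config`).
#' @export
run_compare <- function(traj_a, traj_b, config = list(), output = NULL) {
  config <- validate_config(config)
  if (is.character(traj_a)) traj_a <- read_pdb(traj_a)
  if (is.character(traj_b)) traj_b <- read_pdb(traj_b)
  report <- list(config = config[order(names(config))],
                 systems = list(a = analyse_system(traj_a, config),
                                b = analyse_system(traj_b, config)))
  if (!is.null(output))
    jsonlite::write_json(report, output, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  report
}
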