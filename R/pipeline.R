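# Orchestration: run the full condition-vs-control comparison and emit
# the table/heatmap/landscape data bundles, plus crystal-structure
# distance checks.

#' Run the full ensemble comparison analysis
#'
#' For every condition: end-to-end distance, radius of gyration, total
#' SASA with and without phosphosites (summary-table rows), secondary-
#' structure composition, Ramachandran region populations, salt-bridge
#' and hydrogen-bond occupancy maps, and (optionally) the tICA landscape
#' with cluster selection.  Every non-control condition additionally gets
#' its difference products against the control.
#'
#' @param conditions Named list; each element a list with `topology`
#'   (a `reg_topology`) and `trajectory` (a `reg_traj` or path to a
#'   multi-model PDB).
#' @param control Name of the control condition (default the first).
#' @param landscape Fit the tICA landscape per condition (default FALSE;
#'   it is the expensive stage).
#' @param tica_lag,cluster_ks Landscape parameters (see [fit_tica()],
#'   [cluster_scan()]).
#' @param sasa_n_points Shrake-Rupley test points per atom.
#' @param saltbridge_cutoff,hbond_cutoff Contact cutoffs, nm.
#' @return A `reg_report`: per-condition results under `$conditions`,
#'   differences under `$differences`, the summary table under
#'   `$summary_table`, and the run configuration under `$config`.
#' @export
run_analysis <- function(conditions, control = names(conditions)[1L],
                         landscape = FALSE, tica_lag = 100L,
                         cluster_ks = 2:10, sasa_n_points = 240L,
                         saltbridge_cutoff = 0.35, hbond_cutoff = 0.30) {
  stopifnot(length(conditions) >= 1L, !is.null(names(conditions)),
            control %in% names(conditions))
  res <- list()
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    top <- cond$topology
    traj <- cond$trajectory
    if (is.character(traj)) traj <- read_ensemble(traj, top)
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop("stage '", what, "' failed for condition '", nm, "': ",
             conditionMessage(e), call. = FALSE))
    }
    ee <- stage("end_to_end", end_to_end(traj))
    rg <- stage("radius_of_gyration", radius_of_gyration(traj))
    smat <- stage("sasa", residue_sasa_series(traj,
                                             n_points = sasa_n_points))
    phos <- top$author_number[top$is_phosphorylated]
    sasa_all <- total_sasa(smat)
    sasa_np <- total_sasa(smat, exclude_sites = phos)
    ss <- stage("secstruct", assign_secstruct(traj, top))
    rama <- stage("ramachandran", region_populations(traj))
    sb <- stage("contacts",
                saltbridge_occupancy(traj, top,
                                     cutoff = saltbridge_cutoff))
    hb <- stage("contacts", {
      g <- charged_groups(top)
      hbond_occupancy(traj, g, g, cutoff = hbond_cutoff)
    })
    ls <- NULL
    if (landscape) ls <- stage("landscape", {
      tica <- fit_tica(featurize_dihedrals(traj), lag = tica_lag)
      list(tica = tica,
           surface = free_energy_surface(tica$projection),
           clusters = cluster_scan(tica$projection, ks = cluster_ks))
    })
    res[[nm]] <- list(
      label = nm, topology = top, n_frames = n_frames(traj),
      ee = ee, rg = rg, sasa_matrix = smat,
      sasa_total = sasa_all, sasa_total_excl_phos = sasa_np,
      ss = ss, ss_composition = ss_composition(ss),
      rama_populations = rama,
      saltbridge = sb, hbond = hb, landscape = ls)
  }
  diffs <- list()
  for (nm in setdiff(names(conditions), control)) {
    diffs[[nm]] <- list(
      vs = control,
      sasa = sasa_difference(res[[nm]]$sasa_matrix,
                             res[[control]]$sasa_matrix),
      ss = res[[nm]]$ss_composition - res[[control]]$ss_composition,
      rama = population_difference(res[[nm]]$rama_populations,
                                   res[[control]]$rama_populations),
      saltbridge = occupancy_difference(res[[nm]]$saltbridge,
                                        res[[control]]$saltbridge),
      hbond = occupancy_difference(res[[nm]]$hbond,
                                   res[[control]]$hbond))
  }
  stab <- summary_table(c(
    stats::setNames(lapply(res, `[[`, "ee"),
                    paste0(names(res), ".EE_dist")),
    stats::setNames(lapply(res, `[[`, "rg"),
                    paste0(names(res), ".Rg")),
    stats::setNames(lapply(res, `[[`, "sasa_total_excl_phos"),
                    paste0(names(res), ".SASA_excl_phos"))))
  structure(list(conditions = res, differences = diffs,
                 summary_table = stab,
                 config = list(control = control, landscape = landscape,
                               tica_lag = tica_lag,
                               sasa_n_points = sasa_n_points,
                               saltbridge_cutoff = saltbridge_cutoff,
                               hbond_cutoff = hbond_cutoff)),
            class = "reg_report")
}

#' @export
print.reg_report <- function(x, ...) {
  cat("reg_report:", length(x$conditions), "condition(s), control =",
      x$config$control, "\n")
  print(x$summary_table)
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' CSV tables (summary, composition, Ramachandran populations, contact
#' matrices, differences) plus a JSON manifest of the configuration.
#'
#' @param report A `reg_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary_table,
                   file.path(dir, "summary_table.csv"), row.names = FALSE)
  comp <- do.call(rbind, lapply(report$conditions, `[[`,
                                "ss_composition"))
  utils::write.csv(data.frame(condition = rownames(comp), comp,
                              check.names = FALSE),
                   file.path(dir, "ss_composition.csv"),
                   row.names = FALSE)
  rama <- do.call(rbind, lapply(report$conditions, `[[`,
                                "rama_populations"))
  utils::write.csv(data.frame(condition = rownames(rama), rama,
                              check.names = FALSE),
                   file.path(dir, "ramachandran_populations.csv"),
                   row.names = FALSE)
  for (nm in names(report$conditions)) {
    utils::write.csv(unclass(report$conditions[[nm]]$saltbridge),
                     file.path(dir, paste0("saltbridge_", nm, ".csv")))
  }
  for (nm in names(report$differences)) {
    utils::write.csv(report$differences[[nm]]$saltbridge,
                     file.path(dir, paste0("saltbridge_diff_", nm, ".csv")))
  }
  jsonlite::write_json(report$config,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Crystal-structure distance checks
#'
#' End-to-end CA distance of the construct span and the CA distance of a
#' named residue pair, measured on a supplied structure (e.g. a
#' crystallographic or cryo-EM model read with [read_ensemble()]).
#'
#' @param structure A `reg_traj` (single- or multi-model) or PDB path.
#' @param first,last Author numbers of the construct span (default
#'   351-393).
#' @param pair Residue pair for the second distance (default
#'   `c(351, 386)`, the lysine pair used as a span reference).
#' @return Data frame with one row per model: `ee_dist` and `pair_dist`
#'   in nm.
#' @export
crystal_checks <- function(structure, first = 351L, last = 393L,
                           pair = c(351L, 386L)) {
  traj <- if (is.character(structure)) read_ensemble(structure) else
    structure
  sub <- select_atoms(traj, resno = first:last)
  data.frame(
    model = seq_len(n_frames(sub)),
    ee_dist = as.numeric(end_to_end(sub)),
    pair_dist = as.numeric(pair_distance(sub, pair[1L], pair[2L])))
}
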