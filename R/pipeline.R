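#' Pipeline configuration
#'
#' Loads (YAML or JSON) or builds the configuration driving
#' [run_experiment()]. All randomness flows from the single \code{seed} via
#' named substreams, so stages are independently re-runnable.
#'
#' @param config Path to a YAML/JSON file, or a named list overriding the
#'   defaults below.
#' @return An object of class \code{pipeline_config}: \code{seed},
#'   \code{out_dir}, \code{generator} (arguments for [generator_params()]),
#'   \code{n_subjects}, \code{n_scans}, \code{modes}, \code{stoppages},
#'   \code{diameter}, \code{stride}, \code{window}, \code{n_bins},
#'   \code{n_null}, \code{n_tracts}, \code{compensation}.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, out_dir = tempfile("spectralconn_run_"),
                   generator = list(), n_subjects = 6L, n_scans = 2L,
                   modes = 2:4, stoppages = c(0.25, 0.5, 0.75, 1),
                   diameter = 12, stride = 2L, window = 2L,
                   n_bins = 100L, n_null = 6L, n_tracts = 8L,
                   compensation = 0.25)
  cfg <- utils::modifyList(defaults, config)
  cfg$generator <- do.call(generator_params, as.list(cfg$generator))
  structure(cfg, class = "pipeline_config")
}

#' Run a named end-to-end experiment
#'
#' Orchestrates the analysis stages into five reproducible experiments and
#' writes their tables (TSV/JSON) plus a run log under
#' \code{config$out_dir}:
#' \describe{
#'   \item{eigenmodes}{Synthetic connectome; Laplacian eigensystem export
#'     and hemisphere separation of the second eigenmode.}
#'   \item{importance}{Lesion importance maps for the configured modes and
#'     stoppage values, with the pairwise stoppage-robustness correlations.}
#'   \item{reliability}{Test-retest cohort; per-scan importance maps
#'     aggregated to a toy tract atlas; per-tract ICC table.}
#'   \item{richclub}{Rich-club edge classification, RC/FC/LC edge-density
#'     maps, and their correlations with eigenmode importance maps.}
#'   \item{callosotomy}{Control, virtual-callosotomy and synthetic
#'     callosal-agenesis cohorts; normalized second-eigenvalue group
#'     comparison and eigenmode-splitting report.}
#' }
#'
#' @param name One of \code{"eigenmodes"}, \code{"importance"},
#'   \code{"reliability"}, \code{"richclub"}, \code{"callosotomy"}.
#' @param config A [pipeline_config()] (or list / file path coerced by it).
#' @return The report list of the experiment, invisibly; file paths in
#'   \code{$files}.
#' @export
run_experiment <- function(name, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  name <- match.arg(name, c("eigenmodes", "importance", "reliability",
                            "richclub", "callosotomy"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed,  5L)
  names(seeds) <- c("eigenmodes", "importance", "reliability", "richclub",
                    "callosotomy")
  report <- switch(name,
    eigenmodes = experiment_eigenmodes(config, seeds[["eigenmodes"]]),
    importance = experiment_importance(config, seeds[["importance"]]),
    reliability = experiment_reliability(config, seeds[["reliability"]]),
    richclub = experiment_richclub(config, seeds[["richclub"]]),
    callosotomy = experiment_callosotomy(config, seeds[["callosotomy"]]))
  log_path <- file.path(config$out_dir, paste0(name, "_run.json"))
  jsonlite::write_json(
    list(experiment = name, seed = config$seed,
         package_version = as.character(utils::packageVersion("spectralconn")),
         r_version = R.version.string,
         parameters = config[setdiff(names(config), c("generator", "out_dir"))],
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    log_path, auto_unbox = TRUE, digits = NA, force = TRUE)
  report$files <- c(report$files, run_log = log_path)
  invisible(report)
}

out_path <- function(config, ...) file.path(config$out_dir, paste0(...))

experiment_eigenmodes <- function(config, seed) {
  gen <- generate_connectome(config$generator, seed = seed)
  es <- eigendecompose(build_laplacian(gen$connectome))
  files <- write_eigensystem(es, out_path(config, "eigenmodes"),
                             node_ids = gen$connectome$node_ids)
  cpaths <- write_connectome(gen$connectome, out_path(config, "connectome"))
  v2 <- es$vectors[, 2L]
  sep <- hemisphere_separation(v2, gen$connectome$hemisphere)
  list(eigensystem = es, connectome = gen$connectome,
       hemisphere_separation_v2 = sep,
       files = c(files, cpaths))
}

experiment_importance <- function(config, seed) {
  gen <- generate_connectome(config$generator, seed = seed)
  sweep <- stoppage_sweep(gen$connectome, gen$trajectories,
                          modes = config$modes, stoppages = config$stoppages,
                          diameter = config$diameter, stride = config$stride,
                          window = config$window)
  cor_path <- out_path(config, "stoppage_correlations.tsv")
  utils::write.table(sweep$correlations, cor_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  map_paths <- character()
  for (nm in names(sweep$maps))
    map_paths[nm] <- write_map(sweep$maps[[nm]],
                               out_path(config, "importance_", nm))[["tsv"]]
  list(correlations = sweep$correlations, maps = sweep$maps,
       files = c(correlations = cor_path, map_paths))
}

experiment_reliability <- function(config, seed) {
  cohort <- generate_cohort(config$generator, n_subjects = config$n_subjects,
                            n_scans = config$n_scans, seed = seed)
  atlas <- generate_tract_atlas(cohort$trajectories, config$n_tracts)
  mode <- config$modes[1L]
  n_sub <- length(cohort$subjects)
  n_scan <- length(cohort$subjects[[1L]]$scans)
  tract_ids <- sort(unique(atlas$labels))
  vals <- array(NA_real_,
                dim = c(n_sub, n_scan, length(tract_ids)),
                dimnames = list(NULL, NULL, atlas$tract_names[tract_ids]))
  for (s in seq_len(n_sub)) {
    for (k in seq_len(n_scan)) {
      m <- importance_map(cohort$subjects[[s]]$scans[[k]],
                          cohort$trajectories, mode = mode,
                          stoppage = 1, diameter = config$diameter,
                          stride = config$stride, window = config$window)
      vals[s, k, ] <- suppressWarnings(
        aggregate_importance_by_tract(m, atlas))
    }
  }
  tab <- reliability_table(vals)
  path <- out_path(config, "reliability_mode", mode, ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(table = tab, atlas = atlas, mode = mode, files = c(reliability = path))
}

experiment_richclub <- function(config, seed) {
  gen <- generate_connectome(config$generator, seed = seed)
  rich <- rich_club_nodes(gen$connectome, nodes = gen$hubs)
  classes <- classify_edges(gen$connectome, rich)
  class_path <- out_path(config, "edge_classes.tsv")
  utils::write.table(classes, class_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  density <- lapply(stats::setNames(levels(classes$category),
                                    levels(classes$category)),
                    function(cat) edge_density_map(
                      gen$trajectories, classes[classes$category == cat, ]))
  imaps <- lapply(stats::setNames(config$modes,
                                  paste0("mode", config$modes)),
                  function(m) importance_map(
                    gen$connectome, gen$trajectories, mode = m, stoppage = 1,
                    diameter = config$diameter, stride = config$stride,
                    window = config$window))
  wm <- white_matter_voxels(gen$trajectories)
  rows <- list()
  for (mn in names(imaps)) for (cn in names(density)) {
    cc <- correlate_maps(imaps[[mn]], density[[cn]], mask = wm)
    rows[[length(rows) + 1L]] <- data.frame(
      mode = mn, category = cn, r = cc$r, lower = cc$lower, upper = cc$upper,
      n_voxels = cc$n)
  }
  cors <- do.call(rbind, rows)
  cor_path <- out_path(config, "importance_density_correlations.tsv")
  utils::write.table(cors, cor_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cross <- map_correlation_matrix(imaps, mask = wm)
  list(rich_nodes = rich, classes = classes, density = density,
       importance = imaps, correlations = cors,
       importance_cross_correlation = cross,
       files = c(classes = class_path, correlations = cor_path))
}

experiment_callosotomy <- function(config, seed) {
  cohort <- generate_cohort(config$generator, n_subjects = config$n_subjects,
                            n_scans = 1L, seed = seed)
  controls <- lapply(cohort$subjects, function(s) s$scans[[1L]])
  cuts <- lapply(controls, virtual_callosotomy, traj = cohort$trajectories)
  agcc <- lapply(seq_along(controls), function(s)
    generate_agcc_variant(controls[[s]], cohort$trajectories,
                          compensation = config$compensation,
                          seed = seed + s)$connectome)
  comp <- compare_groups(list(control = controls, agcc = agcc,
                              callosotomy = cuts))
  es_con <- eigendecompose(build_laplacian(average_connectomes(controls)))
  es_cut <- eigendecompose(build_laplacian(average_connectomes(cuts)))
  split <- detect_mode_splitting(es_con, es_cut,
                                 cohort$template$hemisphere,
                                 top_k = max(config$modes))
  subj_path <- out_path(config, "group_lambda2.tsv")
  utils::write.table(comp$subjects, subj_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  split_path <- out_path(config, "mode_splitting.tsv")
  utils::write.table(as.data.frame(split), split_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  json_path <- out_path(config, "group_summary.json")
  jsonlite::write_json(list(summary = comp$summary, tests = comp$tests),
                       json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  list(comparison = comp, splitting = split,
       files = c(subjects = subj_path, splitting = split_path,
                 summary = json_path))
}

#' Hemispheric separation of an eigenmode
#'
#' Fraction of nodes on which the sign of the eigenvector agrees with a
#' hemisphere labeling (maximized over the two sign conventions); 1 means
#' the mode's sign pattern separates the hemispheres exactly, as expected
#' for the interhemispheric second eigenmode of a two-hemisphere network
#' with weak callosal coupling.
#'
#' @param v Eigenvector.
#' @param hemisphere Per-node labels ("left"/"right").
#' @return Agreement fraction in [0.5, 1].
#' @export
hemisphere_separation <- function(v, hemisphere) {
  stopifnot(length(v) == length(hemisphere))
  right <- hemisphere == "right"
  agree <- mean((v > 0) == right)
  max(agree, 1 - agree)
}
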