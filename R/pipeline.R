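# pipeline orchestration: config, staged execution, manifest, YAML I/O

#' Construct a pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"cell_table"`
#'   (read an existing CSV cell table).
#' @param input Path to the input cell table (non-simulate modes).
#' @param stages Named logical list toggling `phenotype`, `abundance`,
#'   `spatial`, `morphometry`, `enrichment`.
#' @param groups,cases_per_group,rois_per_case,n_cells Simulation design
#'   (see [simulate_cohort()]).
#' @param d_min,d_max,n_perm Spatial stage parameters.
#' @param floor_fraction,floor_count Detection floors.
#' @param threshold_method `"gmm2"` or `"quantile"`.
#' @param seed Global seed; all stage randomness derives from it.
#' @param outdir Output directory (created if needed).
#' @return A `run_config`.
#' @export
run_config <- function(mode = c("simulate", "cell_table"),
                       input = NULL,
                       stages = list(),
                       groups = c("group1", "group2", "group3", "thrlbcl"),
                       cases_per_group = 2L, rois_per_case = 2L, n_cells = 600L,
                       d_min = 3, d_max = 30, n_perm = 200L,
                       floor_fraction = 0.001, floor_count = 20L,
                       threshold_method = "gmm2",
                       seed = 1L, outdir = tempfile("spatlymph_run_")) {
  mode <- match.arg(mode)
  st <- list(phenotype = TRUE, abundance = TRUE, spatial = TRUE,
             morphometry = TRUE, enrichment = FALSE)
  for (nm in names(stages)) {
    if (!nm %in% names(st)) spl_config_error("unknown stage toggle '%s'", nm)
    st[[nm]] <- isTRUE(stages[[nm]])
  }
  if (mode == "cell_table") {
    if (is.null(input)) spl_config_error("mode 'cell_table' requires an input path")
    if (!file.exists(input)) spl_config_error("input file does not exist: %s", input)
  }
  cfg <- structure(list(
    mode = mode, input = input, stages = st, groups = groups,
    cases_per_group = cases_per_group, rois_per_case = rois_per_case,
    n_cells = n_cells, d_min = d_min, d_max = d_max, n_perm = n_perm,
    floor_fraction = floor_fraction, floor_count = floor_count,
    threshold_method = threshold_method, seed = as.integer(seed),
    outdir = outdir), class = "run_config")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  st <- cfg$stages
  deps <- list(abundance = "phenotype", spatial = "phenotype",
               morphometry = "phenotype", enrichment = "spatial")
  for (nm in names(deps)) {
    if (isTRUE(st[[nm]]) && !isTRUE(st[[deps[[nm]]]]))
      spl_config_error("stage dependency unmet: '%s' requires stage '%s'",
                       nm, deps[[nm]])
  }
  if (!(cfg$d_min >= 0 && cfg$d_min < cfg$d_max))
    spl_config_error("need 0 <= d_min < d_max")
  cfg
}

#' Read / write a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path YAML path.
#' @return Reading returns a validated `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) spl_config_error("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order -- simulate (or read a
#' cell table), phenotype, abundance, spatial, morphometry -- writing all
#' products as CSV plus a JSON run manifest with parameters, seed, package
#' version, per-stage row counts and output checksums. Deterministic for a
#' fixed seed (identical manifests across reruns).
#'
#' @param config A [run_config()] or a path to a YAML config.
#' @return A `pipeline_result` list with in-memory stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(cfg$outdir, f)
  res <- list(config = cfg)
  counts <- list()

  if (cfg$mode == "simulate") {
    sim <- simulate_cohort(groups = cfg$groups,
                           cases_per_group = cfg$cases_per_group,
                           rois_per_case = cfg$rois_per_case,
                           n_cells = cfg$n_cells,
                           seed = derive_seed(cfg$seed, "simulate"),
                           polygons = isTRUE(cfg$stages$morphometry))
    cells <- sim$cells
    res$truths <- sim$truths
  } else {
    cells <- read_cell_table(cfg$input)
  }
  write_cell_table(cells, outfile("cells.csv"))
  counts$cells <- nrow(cells)
  res$cells <- cells

  if (isTRUE(cfg$stages$phenotype)) {
    thr <- fit_marker_thresholds(cells, method = cfg$threshold_method)
    pheno <- assign_phenotypes(cells, default_schema(), thr)
    write_cell_table(pheno, outfile("cells_phenotyped.csv"))
    write_schema_yaml(thr, outfile("thresholds.yaml"))
    counts$phenotyped <- nrow(pheno)
    res$thresholds <- thr
    res$phenotyped <- pheno
  }

  if (isTRUE(cfg$stages$abundance)) {
    comp <- roi_composition(res$phenotyped)
    zm <- withCallingHandlers(zscore_matrix(comp),
                              warning = function(w) invokeRestart("muffleWarning"))
    gsum <- group_summary(zm, comp)
    utils::write.csv(comp, outfile("composition.csv"), row.names = FALSE)
    utils::write.csv(data.frame(population = rownames(zm$z), zm$z,
                                check.names = FALSE),
                     outfile("zscores_roi.csv"), row.names = FALSE)
    utils::write.csv(data.frame(population = rownames(zm$group_z), zm$group_z,
                                check.names = FALSE),
                     outfile("zscores_group.csv"), row.names = FALSE)
    utils::write.csv(gsum, outfile("group_summary.csv"), row.names = FALSE)
    counts$composition_rois <- nrow(comp)
    res$composition <- comp
    res$zscores <- zm
  }

  if (isTRUE(cfg$stages$spatial)) {
    res$interactions <- list()
    for (g in unique(res$phenotyped$group)) {
      sub <- as_cell_table(as.data.table(res$phenotyped)[group == g],
                           markers = cell_markers(res$phenotyped))
      setattr(sub, "populations", attr(res$phenotyped, "populations"))
      graph <- build_neighbor_graph(sub, cfg$d_min, cfg$d_max)
      im <- interaction_scores(graph, setNames(sub$phenotype, sub$cell_id),
                               populations = c(attr(res$phenotyped, "populations"),
                                               "other"))
      utils::write.csv(im$S, outfile(sprintf("interactions_%s.csv", g)))
      res$interactions[[g]] <- im
      if (isTRUE(cfg$stages$enrichment)) {
        enr <- permutation_enrichment(sub, n_perm = cfg$n_perm,
                                      seed = derive_seed(cfg$seed, "enrich", g),
                                      graph = graph)
        utils::write.csv(enr$pairs, outfile(sprintf("enrichment_%s.csv", g)),
                         row.names = FALSE)
        res$enrichment[[g]] <- enr
      }
    }
    counts$interaction_matrices <- length(res$interactions)
  }

  if (isTRUE(cfg$stages$morphometry)) {
    if (cfg$mode == "simulate") {
      polys <- rbindlist(lapply(res$truths, function(t) t$polygons))
      morph <- tumor_nuclear_morphometry(res$phenotyped, polys)
      utils::write.csv(morph$per_nucleus, outfile("tumor_morphometry.csv"),
                       row.names = FALSE)
      utils::write.csv(morph$group_summary, outfile("tumor_morphometry_groups.csv"),
                       row.names = FALSE)
      res$morphometry <- morph
      counts$tumor_nuclei <- nrow(morph$per_nucleus)
    }
    pf <- rbindlist(lapply(c("PU1", "CD163", "CD14"), function(m)
      positive_fraction(res$phenotyped %||% cells, m)))
    utils::write.csv(pf, outfile("positive_fractions.csv"), row.names = FALSE)
    res$positive_fractions <- pf
    counts$positive_fraction_rows <- nrow(pf)
  }

  outputs <- sort(list.files(cfg$outdir, full.names = FALSE))
  checks <- tools::md5sum(file.path(cfg$outdir, outputs))
  names(checks) <- outputs
  manifest <- list(
    package = "spatlymph",
    version = as.character(utils::packageVersion("spatlymph")),
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(unclass(cfg)), "outdir")],
    row_counts = counts,
    outputs = as.list(checks))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  res
}
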