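#' Marker panel modeled by the synthetic tissue generator
#'
#' The phenotype-defining subset of a CODEX/PhenoCycler lymphoma panel:
#' B-cell markers (CD20, BCL6, IGD), T-cell markers (CD3, CD4, CD8, PD1,
#' LAG3, CD69, FOXP3) and macrophage/monocyte markers (CD68, MPO, CD14,
#' PU1, CD163). PU1/CD163/CD14 double as the immunohistochemistry
#' surrogates used for positive-cell-fraction quantification.
#'
#' @return Character vector of marker (column) names.
#' @export
codex_markers <- function() {
  c("CD20", "BCL6", "IGD", "CD3", "CD4", "CD8", "PD1", "LAG3", "CD69",
    "FOXP3", "CD68", "MPO", "CD14", "PU1", "CD163")
}

#' Canonical population names
#'
#' Machine names for the twelve gated populations, in gating-table order.
#' @return Character vector of length 12.
#' @export
population_names <- function() {
  c("tumor_b", "tme_b", "helper_t", "act_helper_t", "tfh", "atfh",
    "cytotoxic_t", "act_cytotoxic_t", "treg", "dpt", "macrophage", "monocyte")
}

# which markers each generated population expresses (superset of the gating
# requirements; macrophage lineage additionally expresses the IHC surrogates)
default_positive_sets <- function() {
  list(
    tumor_b         = c("CD20", "BCL6"),
    tme_b           = c("CD20", "IGD"),
    helper_t        = c("CD3", "CD4"),
    act_helper_t    = c("CD3", "CD4", "LAG3", "CD69"),
    tfh             = c("CD3", "CD4", "PD1", "BCL6"),
    atfh            = c("CD3", "CD4", "PD1", "BCL6", "LAG3", "CD69"),
    cytotoxic_t     = c("CD3", "CD8"),
    act_cytotoxic_t = c("CD3", "CD8", "LAG3", "CD69"),
    treg            = c("CD3", "CD4", "FOXP3"),
    dpt             = c("CD3", "CD4", "CD8"),
    macrophage      = c("CD68", "PU1", "CD163", "CD14"),
    monocyte        = c("CD68", "MPO", "CD14", "PU1"),
    other           = character(0)
  )
}

#' Default marker intensity model
#'
#' Two log-normal components per marker: a dim "negative" background
#' component and a bright "positive" component, the usual skewed shape of
#' immunofluorescence intensities. Which component a cell draws from is
#' decided by its population's positive-marker set.
#'
#' @param pos,neg Named numeric vectors `c(meanlog=, sdlog=)`.
#' @return List with elements `pos`, `neg`, `positive_sets`.
#' @export
default_intensity_model <- function(pos = c(meanlog = log(400), sdlog = 0.35),
                                    neg = c(meanlog = log(12), sdlog = 0.45)) {
  list(pos = pos, neg = neg, positive_sets = default_positive_sets())
}

# per-population nuclear area model (mean, sd in square microns); tumor_b is
# overridden per preset to encode the nuclear-size gradient
default_nuclear_size_model <- function(tumor_mean = 35, tumor_sd = 6) {
  base <- list(
    tumor_b    = c(mean = tumor_mean, sd = tumor_sd),
    macrophage = c(mean = 35, sd = 6),
    monocyte   = c(mean = 25, sd = 4)
  )
  pops <- c(population_names(), "other")
  out <- lapply(pops, function(p) base[[p]] %||% c(mean = 18, sd = 3))
  names(out) <- pops
  out
}

#' Construct a synthetic-tissue configuration
#'
#' A `tissue_config` fully specifies one simulated region of interest (ROI):
#' architecture (nodular vs diffuse point pattern), target cell count,
#' expected population composition, optional TFH-rosette construction,
#' marker intensity model, nuclear size model, and the seed.
#'
#' @param architecture `"nodular"` or `"diffuse"`.
#' @param roi_size Width and height of the ROI in microns, length-2 numeric.
#' @param n_cells Target number of cells.
#' @param nodule_count,nodule_radius Nodule layout (nodular architecture only);
#'   radius in microns.
#' @param composition Named numeric vector of expected population fractions
#'   (over [population_names()] plus `"other"`); must sum to 1.
#' @param rosette_spec `NULL`, or `list(tfh_per_lp =, rosette_annulus = c(r_lo, r_hi))`
#'   (microns): every tumor-B (LP) cell gets `tfh_per_lp` TFH cells placed
#'   uniformly in the annulus around it.
#' @param intensity_model See [default_intensity_model()].
#' @param nuclear_size_model Per-population `c(mean=, sd=)` nuclear areas (um^2).
#' @param min_spacing Minimum center-to-center distance in microns enforced by
#'   dart-throwing rejection (default 4, about one lymphocyte radius).
#' @param background_frac Fraction of cells placed outside nodules when
#'   `architecture == "nodular"`.
#' @param polygons Generate per-cell nucleus polygons (default `TRUE`; turn
#'   off for large abundance-only simulations).
#' @param group Group label stamped on generated cells.
#' @param seed Integer seed; simulation is deterministic given `(seed, roi index)`.
#' @return An object of class `tissue_config`.
#' @seealso [make_group_presets()], [simulate_tissue()]
#' @export
tissue_config <- function(architecture = c("diffuse", "nodular"),
                          roi_size = c(600, 600),
                          n_cells = 2000,
                          nodule_count = 4,
                          nodule_radius = 110,
                          composition,
                          rosette_spec = NULL,
                          intensity_model = default_intensity_model(),
                          nuclear_size_model = default_nuclear_size_model(),
                          min_spacing = 4,
                          background_frac = 0.1,
                          polygons = TRUE,
                          group = NA_character_,
                          seed = 1L) {
  architecture <- match.arg(architecture)
  cfg <- structure(list(
    architecture = architecture, roi_size = as.numeric(roi_size),
    n_cells = as.integer(n_cells), nodule_count = as.integer(nodule_count),
    nodule_radius = as.numeric(nodule_radius), composition = composition,
    rosette_spec = rosette_spec, intensity_model = intensity_model,
    nuclear_size_model = nuclear_size_model, min_spacing = as.numeric(min_spacing),
    background_frac = as.numeric(background_frac), polygons = isTRUE(polygons),
    group = group, seed = as.integer(seed)
  ), class = "tissue_config")
  validate_tissue_config(cfg)
}

validate_tissue_config <- function(cfg) {
  comp <- cfg$composition
  if (is.null(names(comp)) || any(!nzchar(names(comp))))
    spl_config_error("composition must be a named vector of population fractions")
  if (any(comp < 0))
    spl_config_error("composition fractions must be nonnegative")
  if (abs(sum(comp) - 1) > 1e-9)
    spl_config_error("composition must sum to 1 (got %.12f)", sum(comp))
  if (length(cfg$roi_size) != 2L || any(!is.finite(cfg$roi_size)) || any(cfg$roi_size <= 0))
    spl_config_error("roi_size must be two positive dimensions in microns")
  if (!is_count(cfg$n_cells) || cfg$n_cells < 1)
    spl_config_error("n_cells must be a positive integer")
  if (!is.null(cfg$rosette_spec)) {
    ann <- cfg$rosette_spec$rosette_annulus
    if (length(ann) != 2L || ann[1] < 0 || ann[1] >= ann[2])
      spl_config_error("rosette_annulus must satisfy 0 <= r_lo < r_hi")
    if (!is_count(cfg$rosette_spec$tfh_per_lp) || cfg$rosette_spec$tfh_per_lp < 1)
      spl_config_error("tfh_per_lp must be a positive integer")
  }
  if (cfg$min_spacing < 0) spl_config_error("min_spacing must be nonnegative")
  cfg
}

# preset composition table; columns are the four analysis groups.  Values are
# implementation choices constrained only by the published qualitative
# orderings (tumor-B ascending group1 -> THRLBCL, TME-B descending,
# macrophage/monocyte maximal in THRLBCL, etc.); the published Z-scores are
# data-dependent outputs, never generative parameters.
preset_composition <- function() {
  m <- rbind(
    tumor_b         = c(0.010, 0.030, 0.080, 0.150),
    tme_b           = c(0.300, 0.180, 0.080, 0.020),
    helper_t        = c(0.200, 0.170, 0.100, 0.130),
    act_helper_t    = c(0.020, 0.025, 0.050, 0.015),
    tfh             = c(0.100, 0.110, 0.095, 0.070),
    atfh            = c(0.010, 0.020, 0.040, 0.050),
    cytotoxic_t     = c(0.080, 0.080, 0.075, 0.120),
    act_cytotoxic_t = c(0.010, 0.020, 0.015, 0.030),
    treg            = c(0.020, 0.030, 0.035, 0.050),
    dpt             = c(0.020, 0.025, 0.015, 0.002),
    macrophage      = c(0.050, 0.045, 0.060, 0.150),
    monocyte        = c(0.020, 0.025, 0.030, 0.060)
  )
  colnames(m) <- c("group1", "group2", "group3", "thrlbcl")
  m <- rbind(m, other = 1 - colSums(m))
  m
}

#' Group presets for the four analysis groups
#'
#' Returns a ready-to-simulate [tissue_config()] for one of the four analysis
#' groups of the NLPHL/THRLBCL spectrum: `group1` (typical nodular patterns
#' A/B, TFH rosettes planted around LP cells), `group2` (variant nodular
#' patterns C/D), `group3` (variant diffuse pattern E) and `thrlbcl`.
#' Compositions encode the qualitative gradients of the disease spectrum:
#' tumor-B fraction increases group1 < group2 < group3 < thrlbcl, TME-B
#' decreases in the same order, and macrophage/monocyte content is maximal in
#' THRLBCL. Tumor nuclear areas are ordered group1 < group2 < thrlbcl < group3.
#'
#' @param group One of `"group1"`, `"group2"`, `"group3"`, `"thrlbcl"`.
#' @param n_cells,seed,polygons Passed through to [tissue_config()].
#' @return A `tissue_config`.
#' @export
make_group_presets <- function(group, n_cells = 2000, seed = 1L, polygons = TRUE) {
  groups <- c("group1", "group2", "group3", "thrlbcl")
  if (length(group) != 1L || !group %in% groups)
    spl_config_error("unknown group '%s'; expected one of %s",
                     paste(group, collapse = ","), paste(groups, collapse = ", "))
  comp <- preset_composition()[, group]
  nodular <- group %in% c("group1", "group2")
  tumor_area <- c(group1 = 30, group2 = 40, group3 = 60, thrlbcl = 50)[[group]]
  tissue_config(
    architecture = if (nodular) "nodular" else "diffuse",
    composition = comp,
    rosette_spec = if (group == "group1")
      list(tfh_per_lp = 4L, rosette_annulus = c(5, 12)) else NULL,
    nuclear_size_model = default_nuclear_size_model(tumor_mean = tumor_area),
    n_cells = n_cells, polygons = polygons, group = group, seed = seed
  )
}
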