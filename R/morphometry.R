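# nuclear morphometry and positive-cell-fraction quantification

# orientation of the triple (p, q, r); 0 = collinear
orient <- function(px, py, qx, qy, rx, ry) {
  v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
  ifelse(abs(v) < 1e-12, 0, sign(v))
}

segments_cross <- function(p1, p2, p3, p4) {
  o1 <- orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  o2 <- orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  o3 <- orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  o4 <- orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c)
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  (o1 == 0 && on_seg(p1, p2, p3)) || (o2 == 0 && on_seg(p1, p2, p4)) ||
    (o3 == 0 && on_seg(p3, p4, p1)) || (o4 == 0 && on_seg(p3, p4, p2))
}

is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    for (j in seq_len(n)) {
      if (j <= i) next
      j2 <- if (j == n) 1L else j + 1L
      # skip edges sharing a vertex
      if (i2 == j || j2 == i || (i == 1L && j == n)) next
      if (segments_cross(poly[i, ], poly[i2, ], poly[j, ], poly[j2, ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Polygon area and perimeter
#'
#' Area by the shoelace formula (absolute value), perimeter as the sum of
#' consecutive vertex distances including the closing edge. A duplicated
#' closing vertex is tolerated; self-intersecting polygons are rejected.
#'
#' @param polygon Two-column numeric matrix (or data.frame) of ordered
#'   vertices in microns.
#' @param check_simple Verify non-self-intersection (O(V^2); default `TRUE`).
#' @return Named numeric vector `c(area =, perimeter =)`.
#' @export
polygon_area_perimeter <- function(polygon, check_simple = TRUE) {
  poly <- as.matrix(polygon)[, 1:2, drop = FALSE]
  if (nrow(poly) >= 2L && all(abs(poly[1, ] - poly[nrow(poly), ]) < 1e-12))
    poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 3L) spl_data_error("polygon needs at least 3 distinct vertices")
  if (check_simple && !is_simple_polygon(poly))
    spl_data_error("polygon is self-intersecting")
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  perimeter <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  c(area = area, perimeter = perimeter)
}

# grouped shoelace over a cell_id/x_um/y_um vertex table (no simplicity check;
# generated nuclei are star-shaped by construction)
polygon_metrics_table <- function(polygons) {
  dt <- as.data.table(polygons)
  dt[, {
    xn <- c(x_um[-1], x_um[1]); yn <- c(y_um[-1], y_um[1])
    .(area_um2 = abs(sum(x_um * yn - xn * y_um)) / 2,
      perimeter_um = sum(sqrt((xn - x_um)^2 + (yn - y_um)^2)))
  }, by = cell_id]
}

#' Tumor nuclear morphometry
#'
#' Per-nucleus area and perimeter for tumor-marker-positive cells only
#' (tumor-B phenotype label as the MEF2B-IHC surrogate), per-group medians,
#' and pairwise Mann-Whitney (rank-sum) tests.
#'
#' @param cells A `phenotyped_cell_table` with a `group` column.
#' @param polygons Nucleus polygon table (`cell_id`, `x_um`, `y_um`), e.g.
#'   `truth$polygons` from [simulate_tissue()].
#' @param tumor_label Phenotype treated as tumor positive (default
#'   `"tumor_b"`).
#' @return List with `per_nucleus` (cell_id, group, area_um2, perimeter_um),
#'   `group_summary` (medians and n; groups without tumor nuclei are `NA`),
#'   and `tests` (pairwise p-values per metric).
#' @export
tumor_nuclear_morphometry <- function(cells, polygons, tumor_label = "tumor_b") {
  dt <- as.data.table(cells)
  if (!"phenotype" %in% names(dt))
    spl_data_error("cells are not phenotyped")
  tum <- dt[phenotype == tumor_label, .(cell_id, group)]
  met <- polygon_metrics_table(polygons)
  per <- met[tum, on = "cell_id", nomatch = 0L]
  groups <- unique(as.character(dt$group))
  gs <- rbindlist(lapply(groups, function(g) {
    sub <- per[group == g]
    data.table(group = g, n = nrow(sub),
               median_area_um2 = if (nrow(sub)) median(sub$area_um2) else NA_real_,
               median_perimeter_um = if (nrow(sub)) median(sub$perimeter_um) else NA_real_)
  }))
  tests <- list()
  if (length(groups) >= 2L) {
    cmb <- combn(groups, 2)
    for (k in seq_len(ncol(cmb))) {
      ga <- cmb[1, k]; gb <- cmb[2, k]
      for (metric in c("area_um2", "perimeter_um")) {
        xa <- per[group == ga][[metric]]; xb <- per[group == gb][[metric]]
        p <- if (length(xa) && length(xb))
          rank_sum_test(xa, xb)$p_two_sided else NA_real_
        tests[[length(tests) + 1L]] <- data.table(
          groupA = ga, groupB = gb, metric = metric, p_two_sided = p)
      }
    }
  }
  list(per_nucleus = per, group_summary = gs,
       tests = if (length(tests)) rbindlist(tests) else NULL)
}

#' Positive-cell fractions per core with per-case medians
#'
#' The image-analysis-style quantification for single markers (e.g. PU.1,
#' CD163, CD14): fraction of cells above the positivity threshold per core,
#' consolidated to a per-case median percentage.
#'
#' @param cells A `cell_table` with `case_id` and a core identifier column.
#' @param marker Marker column name.
#' @param threshold A [threshold_set()] or a single transformed-scale cutoff;
#'   fitted by `gmm2` on these cells when `NULL`.
#' @param cofactor arcsinh cofactor when fitting/applying a bare threshold.
#' @param core_col Column naming the core (defaults to `roi_id`).
#' @return data.table with one row per core: `case_id`, `core_id`, `group`
#'   (when present), `marker`, `n_cells`, `fraction`, `case_median`,
#'   `case_median_pct`.
#' @export
positive_fraction <- function(cells, marker, threshold = NULL, cofactor = 150,
                              core_col = "roi_id") {
  dt <- as.data.table(cells)
  if (!marker %in% names(dt)) spl_data_error("marker '%s' not present", marker)
  if (!core_col %in% names(dt)) spl_data_error("core column '%s' not present", core_col)
  if (is.factor(dt[[core_col]])) {
    empty <- setdiff(levels(dt[[core_col]]), unique(as.character(dt[[core_col]])))
    if (length(empty)) spl_data_error("core '%s' is empty", empty[1])
  }
  ts <- if (is.null(threshold)) {
    fit_marker_thresholds(as_cell_table(dt, markers = marker), method = "gmm2",
                          markers = marker, cofactor = cofactor)
  } else if (inherits(threshold, "threshold_set")) threshold else
    threshold_set(setNames(threshold, marker), cofactor)
  posv <- transform_intensity(dt[[marker]], ts) > ts$thresholds[[marker]]
  dt[, .pos_tmp := posv]
  has_group <- "group" %in% names(dt)
  rec <- dt[, {
    out <- list(case_id = as.character(case_id[1]),
                n_cells = .N, fraction = mean(.pos_tmp))
    if (has_group) out$group <- as.character(group[1])
    out
  }, by = c(core_col)]
  setnames(rec, core_col, "core_id")
  rec[, marker := marker]
  rec[, case_median := median(fraction), by = case_id]
  rec[, case_median_pct := 100 * case_median]
  setcolorder(rec, c("case_id", "core_id"))
  rec[]
}

#' Compare per-case median positive fractions between two groups
#'
#' @param records Output of [positive_fraction()] (with a `group` column).
#' @param groupA,groupB Group labels.
#' @param alternative Passed to [rank_sum_test()].
#' @return A `rank_sum_test` on the unique per-case medians.
#' @export
compare_case_medians <- function(records, groupA, groupB,
                                 alternative = "two.sided") {
  dt <- as.data.table(records)
  if (!"group" %in% names(dt)) spl_data_error("records carry no group column")
  med <- unique(dt[, .(case_id, group, case_median)])
  for (g in c(groupA, groupB))
    if (!g %in% med$group) spl_config_error("unknown group '%s'", g)
  rank_sum_test(med[group == groupA, case_median],
                med[group == groupB, case_median],
                alternative = alternative)
}
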