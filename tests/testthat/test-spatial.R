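# neighbor graph, interaction scores, permutation null, Voronoi

random_roi <- function(n, seed, roi = "r1", side = 300) {
  set.seed(seed)
  dt <- data.table::data.table(
    cell_id = sprintf("%s_c%04d", roi, seq_len(n)), roi_id = roi,
    case_id = "c1", group = "g1",
    x_um = runif(n, 0, side), y_um = runif(n, 0, side))
  as_cell_table(dt, markers = character(0), bbox = c(0, side, 0, side))
}

edge_keys <- function(graph, cells) {
  idx <- setNames(seq_len(nrow(cells)), cells$cell_id)
  i <- pmin(idx[graph$edges$a], idx[graph$edges$b])
  j <- pmax(idx[graph$edges$a], idx[graph$edges$b])
  sort(paste(i, j, sep = "|"))
}

test_that("annulus bounds are inclusive and exclude sub-d_min pairs", {
  two <- function(d) {
    dt <- data.table::data.table(cell_id = c("a", "b"), roi_id = "r",
                                 case_id = "c", group = "g",
                                 x_um = c(0, d), y_um = 0)
    build_neighbor_graph(as_cell_table(dt, markers = character(0)))
  }
  expect_identical(nrow(two(10)$edges), 1L)   # inside [3, 30]
  expect_identical(nrow(two(2)$edges), 0L)    # below d_min
  expect_identical(nrow(two(3)$edges), 1L)    # boundary inclusive
  expect_identical(nrow(two(30)$edges), 1L)
  expect_identical(nrow(two(31)$edges), 0L)
})

test_that("graph equals the brute-force all-pairs oracle", {
  for (seed in c(2, 4)) {
    cells <- random_roi(200, seed)
    g <- build_neighbor_graph(cells, 3, 30)
    expect_identical(edge_keys(g, cells),
                     brute_force_edges(cells$x_um, cells$y_um, 3, 30))
  }
})

test_that("no cross-ROI edges; duplicates rejected; scale consistency", {
  a <- random_roi(80, 1, roi = "rA")
  b <- random_roi(80, 2, roi = "rB")
  both <- as_cell_table(rbind(a, b), markers = character(0))
  g <- build_neighbor_graph(both)
  rois_a <- both$roi_id[match(g$edges$a, both$cell_id)]
  rois_b <- both$roi_id[match(g$edges$b, both$cell_id)]
  expect_true(all(rois_a == rois_b))

  dup <- rbind(a, a)
  expect_error(build_neighbor_graph(as_cell_table(dup, markers = character(0))),
               "duplicate cell id")

  # doubling coordinates with doubled bounds leaves the edge set unchanged
  a2 <- data.table::copy(a)[, `:=`(x_um = x_um * 2, y_um = y_um * 2)]
  g1 <- build_neighbor_graph(a, 3, 30)
  g2 <- build_neighbor_graph(as_cell_table(a2, markers = character(0)), 6, 60)
  expect_identical(edge_keys(g1, a), edge_keys(g2, a2))
})

test_that("interaction scores implement the size correction exactly", {
  # deterministic layout: 3 'A' cells in a 10-um chain, 2 'B' nearby, 1 'C' far
  dt <- data.table::data.table(
    cell_id = sprintf("c%d", 1:6), roi_id = "r", case_id = "c", group = "g",
    x_um = c(0, 10, 20, 5, 15, 200), y_um = c(0, 0, 0, 8, 8, 200))
  cells <- as_cell_table(dt, markers = character(0))
  labels <- setNames(c("A", "A", "A", "B", "B", "C"), dt$cell_id)
  g <- build_neighbor_graph(cells, 3, 30)
  im <- interaction_scores(g, labels)

  # hand-count with the brute-force distances
  d <- as.matrix(dist(cbind(dt$x_um, dt$y_um)))
  qual <- d >= 3 & d <= 30
  lab <- unname(labels)
  E_ab <- sum(qual[lab == "A", lab == "B"])
  E_aa <- sum(qual[lab == "A", lab == "A"]) / 2
  expect_equal(im$E["A", "B"], E_ab)
  expect_equal(im$S["A", "B"], E_ab / (3 + 2))
  expect_equal(im$S["A", "A"], E_aa / (2 * 3))
  expect_equal(im$S["C", "C"], 0)        # isolated cell, no self pairs

  # absent population yields the NA sentinel
  im2 <- interaction_scores(g, labels, populations = c("A", "B", "C", "D"))
  expect_true(all(is.na(im2$S["D", ])))
  expect_identical(unname(im2$n["D"]), 0)

  # symmetry
  expect_equal(im$S, t(im$S))
  expect_equal(im$E, t(im$E))

  # missing label rejected
  expect_error(interaction_scores(g, labels[-1]), "label missing")
})

test_that("permutation enrichment is deterministic and well-formed", {
  cells <- random_roi(150, 8)
  set.seed(99)
  labels <- setNames(sample(c("A", "B"), 150, replace = TRUE), cells$cell_id)
  e1 <- permutation_enrichment(cells, labels, n_perm = 99, seed = 42)
  e2 <- permutation_enrichment(cells, labels, n_perm = 99, seed = 42)
  expect_identical(e1$pairs, e2$pairs)
  expect_true(all(e1$pairs$p_enrich > 0 & e1$pairs$p_enrich <= 1))
  expect_true(all(e1$pairs$p_deplete > 0 & e1$pairs$p_deplete <= 1))
  expect_true(all(e1$pairs$ratio >= 0, na.rm = TRUE))
  # symmetric storage: (A,B) appears once with i <= j ordering
  expect_identical(nrow(e1$pairs), 3L)

  # single-population ROI: only the self pair is assessable
  solo <- setNames(rep("A", 150), cells$cell_id)
  es <- permutation_enrichment(cells, solo, n_perm = 19, seed = 1)
  expect_identical(nrow(es$pairs), 1L)
  expect_equal(es$pairs$ratio, 1)        # null equals observed exactly
})

test_that("label shuffling is stratified within ROI", {
  a <- random_roi(60, 11, roi = "rA")
  b <- random_roi(60, 12, roi = "rB")
  both <- as_cell_table(rbind(a, b), markers = character(0))
  # population X exists only in rA; shuffling must keep it there, so the
  # X-X score is identical across permutations and the ratio is exactly 1
  labels <- setNames(c(rep("X", 60), rep("Y", 60)), both$cell_id)
  e <- permutation_enrichment(both, labels, n_perm = 49, seed = 2)
  xx <- e$pairs[e$pairs$pop_i == "X" & e$pairs$pop_j == "X", ]
  expect_equal(xx$null_sd, 0)
  expect_equal(xx$ratio, 1)
})

test_that("Voronoi tessellation tiles the rectangle and respects geometry", {
  # four cells at square corners: congruent quadrant polygons
  dt <- data.table::data.table(
    cell_id = paste0("c", 1:4), roi_id = "r", case_id = "c", group = "g",
    x_um = c(25, 75, 25, 75), y_um = c(25, 25, 75, 75))
  cells <- as_cell_table(dt, markers = character(0), bbox = c(0, 100, 0, 100))
  v <- voronoi_export(cells)
  areas <- vapply(v$polygons, function(p) polygon_area_perimeter(p)[["area"]],
                  numeric(1))
  expect_equal(unname(areas), rep(2500, 4))
  expect_equal(sum(areas), 100 * 100, tolerance = 1e-6)

  # random layout: tiling and point-in-own-polygon
  cells2 <- random_roi(40, 3, side = 200)
  v2 <- voronoi_export(cells2)
  areas2 <- vapply(v2$polygons, function(p) polygon_area_perimeter(p)[["area"]],
                   numeric(1))
  expect_equal(sum(areas2), 200 * 200, tolerance = 200 * 200 * 1e-6)
  for (k in seq_len(nrow(cells2))) {
    poly <- v2$polygons[[cells2$cell_id[k]]]
    ctr <- colMeans(poly)
    # convexity: cell centroid inside its polygon (all cross products one sign)
    pt <- c(cells2$x_um[k], cells2$y_um[k])
    n <- nrow(poly)
    sgn <- vapply(seq_len(n), function(i) {
      j <- if (i == n) 1L else i + 1L
      (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) -
        (poly[j, 2] - poly[i, 2]) * (pt[1] - poly[i, 1])
    }, numeric(1))
    expect_true(all(sgn >= -1e-9) || all(sgn <= 1e-9))
  }

  # collinear degenerate input is rejected
  col <- data.table::data.table(
    cell_id = paste0("c", 1:4), roi_id = "r", case_id = "c", group = "g",
    x_um = c(10, 20, 30, 40), y_um = c(10, 20, 30, 40))
  expect_error(voronoi_export(as_cell_table(col, markers = character(0))),
               "collinear")
})

test_that("Voronoi areas agree with the deldir oracle", {
  skip_if_not_installed("deldir")
  cells <- random_roi(30, 17, side = 120)
  v <- voronoi_export(cells)
  mine <- sort(vapply(v$polygons, function(p) polygon_area_perimeter(p)[["area"]],
                      numeric(1)))
  dd <- deldir::deldir(cells$x_um, cells$y_um, rw = c(0, 120, 0, 120))
  ref <- sort(vapply(deldir::tile.list(dd), function(t)
    polygon_area_perimeter(cbind(t$x, t$y))[["area"]], numeric(1)))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("GeoJSON polygon round trip preserves coordinates and labels", {
  cells <- random_roi(10, 21, side = 80)
  ph <- data.table::copy(cells)[, phenotype := rep(c("A", "B"), 5)]
  ph <- as_cell_table(ph, markers = character(0), bbox = c(0, 80, 0, 80))
  data.table::setattr(ph, "class", unique(c("phenotyped_cell_table", class(ph))))
  v <- voronoi_export(ph)
  f <- tempfile(fileext = ".geojson")
  write_geojson_polygons(v, f)
  back <- read_geojson_polygons(f)
  expect_setequal(unique(back$cell_id), cells$cell_id)
  id1 <- cells$cell_id[1]
  expect_equal(as.matrix(back[back$cell_id == id1, c("x_um", "y_um")]),
               v$polygons[[id1]], ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(unique(back$label[back$cell_id == id1]), "A")
})
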