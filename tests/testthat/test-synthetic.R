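# synthetic tissue generator

test_that("group presets encode the qualitative composition gradients", {
  presets <- lapply(c("group1", "group2", "group3", "thrlbcl"), make_group_presets)
  names(presets) <- c("group1", "group2", "group3", "thrlbcl")
  comp <- sapply(presets, function(p) p$composition)

  # tumor-B ascending, TME-B descending across the spectrum
  expect_true(all(diff(comp["tumor_b", ]) > 0))
  expect_true(all(diff(comp["tme_b", ]) < 0))
  # macrophage+monocyte maximal in THRLBCL; macrophage strictly greater there
  macmono <- comp["macrophage", ] + comp["monocyte", ]
  expect_equal(names(which.max(macmono)), "thrlbcl")
  expect_true(all(comp["macrophage", "thrlbcl"] > comp["macrophage", 1:3]))
  # architectures and rosettes
  expect_identical(presets$group1$architecture, "nodular")
  expect_identical(presets$group2$architecture, "nodular")
  expect_identical(presets$group3$architecture, "diffuse")
  expect_identical(presets$thrlbcl$architecture, "diffuse")
  expect_false(is.null(presets$group1$rosette_spec))
  expect_true(all(vapply(presets[2:4], function(p) is.null(p$rosette_spec), logical(1))))
  # TME-B maximal in group1 across presets
  expect_equal(names(which.max(comp["tme_b", ])), "group1")
  # compositions sum to 1
  expect_true(all(abs(colSums(comp) - 1) < 1e-9))
  # tumor nuclear size ordering group1 < group2 < thrlbcl < group3
  tum <- vapply(presets, function(p) p$nuclear_size_model$tumor_b[["mean"]], numeric(1))
  expect_true(tum[["group1"]] < tum[["group2"]] &&
                tum[["group2"]] < tum[["thrlbcl"]] &&
                tum[["thrlbcl"]] < tum[["group3"]])
})

test_that("unknown group and invalid configs are rejected", {
  expect_error(make_group_presets("group9"), "unknown group")
  expect_error(tissue_config(composition = c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(tissue_config(composition = c(a = -0.1, b = 1.1)), "nonnegative")
  expect_error(tissue_config(composition = c(a = 1), roi_size = c(-5, 10)), "positive")
  expect_error(
    tissue_config(composition = c(tumor_b = 0.5, tfh = 0.5),
                  rosette_spec = list(tfh_per_lp = 2, rosette_annulus = c(9, 6))),
    "r_lo < r_hi")
})

test_that("simulation is deterministic given (config, seed) and roi_index varies", {
  cfg <- tiny_config(seed = 7)
  a <- simulate_tissue(cfg)
  b <- simulate_tissue(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$truth$polygons, b$truth$polygons)
  c2 <- simulate_tissue(cfg, roi_index = 2)
  expect_false(identical(a$cells$x_um, c2$cells$x_um))
})

test_that("minimum spacing is enforced and infeasible packing is rejected", {
  sim <- simulate_tissue(tiny_config(n_cells = 400, seed = 3))
  d <- as.matrix(dist(cbind(sim$cells$x_um, sim$cells$y_um)))
  diag(d) <- Inf
  expect_gte(min(d), 4)
  cramped <- tissue_config(roi_size = c(30, 30), n_cells = 500,
                           composition = c(other = 1))
  expect_error(simulate_tissue(cramped), "infeasible packing")
})

test_that("rosette construction: planted TFH ring every LP cell", {
  cfg <- make_group_presets("group1", n_cells = 1200, seed = 5)
  sim <- simulate_tissue(cfg)
  truth <- sim$truth
  cells <- sim$cells
  xy <- cbind(cells$x_um, cells$y_um)
  rownames(xy) <- cells$cell_id
  ann <- cfg$rosette_spec$rosette_annulus

  # every planted member lies in the annulus of its anchor (exact property)
  ros <- truth$rosettes
  expect_gt(nrow(ros), 0)
  dd <- sqrt(rowSums((xy[ros$lp, , drop = FALSE] - xy[ros$tfh, , drop = FALSE])^2))
  expect_true(all(dd >= ann[1] - 1e-9 & dd <= ann[2] + 1e-9))

  # brute-force scan: >= tfh_per_lp TFH within r_hi of every LP cell
  lp_ids <- names(truth$labels)[truth$labels == "tumor_b"]
  tfh_ids <- names(truth$labels)[truth$labels == "tfh"]
  for (lp in lp_ids) {
    d <- sqrt(colSums((t(xy[tfh_ids, , drop = FALSE]) - xy[lp, ])^2))
    expect_gte(sum(d <= ann[2] + 1e-9), cfg$rosette_spec$tfh_per_lp)
  }
})

test_that("generated label frequencies converge to the configured composition", {
  cfg <- tissue_config(architecture = "diffuse", roi_size = c(1300, 1300),
                       n_cells = 10000, composition = tiny_composition(),
                       polygons = FALSE, seed = 21)
  sim <- simulate_tissue(cfg)
  emp <- table(factor(sim$truth$labels, levels = names(cfg$composition))) / 10000
  se <- sqrt(cfg$composition * (1 - cfg$composition) / 10000)
  expect_true(all(abs(as.numeric(emp) - cfg$composition) < 3 * se + 1e-12))
})

test_that("ground-truth labels and polygons satisfy their invariants", {
  sim <- simulate_tissue(tiny_config(n_cells = 150, seed = 9))
  expect_true(all(sim$truth$labels %in% c(population_names(), "other")))
  polys <- sim$truth$polygons
  expect_setequal(unique(polys$cell_id), sim$cells$cell_id)
  for (id in sample(unique(polys$cell_id), 25)) {
    m <- as.matrix(polys[polys$cell_id == id, c("x_um", "y_um")])
    expect_silent(polygon_area_perimeter(m))   # rejects self-intersection
  }
})

test_that("rendered images reflect the planted nuclei", {
  # one cell at ROI center: nuclear argmax inside its polygon
  cfg <- tissue_config(roi_size = c(40, 40), n_cells = 1,
                       composition = c(helper_t = 1), seed = 2)
  sim <- simulate_tissue(cfg)
  img <- render_image(sim$cells, sim$truth, pixel_size = 1, noise_sd = 0)
  nuc <- img$channels$nuclear
  k <- which.max(nuc)
  px <- ((k - 1) %/% nrow(nuc)) + 1 - 0.5
  py <- ((k - 1) %% nrow(nuc)) + 1 - 0.5
  poly <- as.matrix(sim$truth$polygons[, c("x_um", "y_um")])
  # argmax within the nucleus bounding box (blob mode at the centroid)
  expect_true(px >= min(poly[, 1]) - 1 && px <= max(poly[, 1]) + 1)
  expect_true(py >= min(poly[, 2]) - 1 && py <= max(poly[, 2]) + 1)

  # five disjoint nuclei, zero noise: exactly 5 components above half max
  cfg5 <- tissue_config(roi_size = c(200, 200), n_cells = 5,
                        composition = c(helper_t = 1), min_spacing = 40, seed = 4)
  sim5 <- simulate_tissue(cfg5)
  img5 <- render_image(sim5$cells, sim5$truth, pixel_size = 1, noise_sd = 0)
  expect_identical(count_components(img5$channels$nuclear,
                                    max(img5$channels$nuclear) / 2), 5L)

  # doubling pixel_size halves raster dimensions
  img2 <- render_image(sim5$cells, sim5$truth, pixel_size = 2, noise_sd = 0)
  expect_equal(dim(img2$channels$nuclear), dim(img5$channels$nuclear) / 2)

  expect_error(render_image(sim5$cells[0, ], sim5$truth), "empty")
})
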