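# marker gating

test_that("default schema matches the published population definitions", {
  sch <- default_schema()
  expect_length(sch$rules, 12)
  expect_setequal(schema_populations(sch), population_names())
  rules <- setNames(sch$rules, vapply(sch$rules, `[[`, character(1), "name"))
  # activated TFH strictly extends TFH
  expect_true(all(rules$tfh$required %in% rules$atfh$required))
  expect_gt(length(rules$atfh$required), length(rules$tfh$required))
  expect_setequal(rules$monocyte$required, c("CD68", "MPO", "CD14"))
  expect_setequal(rules$dpt$required, c("CD3", "CD4", "CD8"))
  expect_setequal(rules$tumor_b$required, c("CD20", "BCL6"))
})

test_that("schema invariants are enforced", {
  r <- function(...) list(...)
  expect_error(phenotype_schema(list(
    r(name = "a", required = "CD3", forbidden = character(0), priority = 1),
    r(name = "a", required = "CD4", forbidden = character(0), priority = 2))),
    "unique")
  expect_error(phenotype_schema(list(
    r(name = "a", required = character(0), forbidden = character(0), priority = 1))),
    "non-empty")
  expect_error(phenotype_schema(list(
    r(name = "a", required = "CD3", forbidden = character(0), priority = 1),
    r(name = "b", required = "CD4", forbidden = character(0), priority = 1))),
    "priorities")
})

test_that("assignment follows most-specific-rule precedence", {
  mk <- codex_markers()
  st <- matrix(FALSE, 5, length(mk), dimnames = list(NULL, mk))
  st[1, c("CD3", "CD4", "PD1", "BCL6", "LAG3", "CD69")] <- TRUE  # aTFH
  st[2, "CD68"] <- TRUE                                          # macrophage
  # row 3 all negative -> other
  st[4, c("CD3", "CD4", "CD8")] <- TRUE                          # DPT
  st[5, c("CD20", "BCL6", "IGD")] <- TRUE                        # tumor/TME tie
  ph <- assign_phenotypes(state_cells(st), default_schema(), fixed_thresholds())
  expect_identical(ph$phenotype,
                   c("atfh", "macrophage", "other", "dpt", "tumor_b"))
  expect_true(all(ph$CD3_pos == st[, "CD3"]))
})

test_that("every cell gets exactly one label and counts add up", {
  st <- random_states(400, seed = 31)
  ph <- assign_phenotypes(state_cells(st), default_schema(), fixed_thresholds())
  expect_identical(nrow(ph), 400L)
  expect_false(anyNA(ph$phenotype))
  expect_identical(sum(table(ph$phenotype)), 400L)
})

test_that("assignment equals the literal rule-scan oracle on random states", {
  sch <- default_schema()
  for (seed in c(101, 202)) {
    st <- random_states(300, seed = seed)
    ph <- assign_phenotypes(state_cells(st), sch, fixed_thresholds())
    expect_identical(ph$phenotype, unname(oracle_assign(st, sch)))
  }
})

test_that("rule order permutation (priorities fixed) does not change assignments", {
  sch <- default_schema()
  st <- random_states(300, seed = 77)
  base <- assign_phenotypes(state_cells(st), sch, fixed_thresholds())$phenotype
  set.seed(1)
  for (k in 1:3) {
    shuf <- phenotype_schema(sample(sch$rules))
    got <- assign_phenotypes(state_cells(st), shuf, fixed_thresholds())$phenotype
    expect_identical(got, base)
  }
})

test_that("gmm2 thresholds recover the generating components", {
  sim <- simulate_tissue(tiny_config(n_cells = 1500, seed = 12, polygons = FALSE))
  cells <- sim$cells
  thr <- fit_marker_thresholds(cells, method = "gmm2")
  im <- default_intensity_model()
  for (m in c("CD3", "CD20", "CD4")) {
    truth_pos <- vapply(im$positive_sets[sim$truth$labels],
                        function(s) m %in% s, logical(1))
    called <- asinh(cells[[m]] / 150) > thr$thresholds[[m]]
    expect_gte(mean(called == truth_pos), 0.99)
  }
})

test_that("degenerate and quantile threshold paths behave as specified", {
  dt <- data.table::data.table(
    cell_id = sprintf("c%d", 1:10), roi_id = "r", case_id = "c", group = "g",
    x_um = 1:10, y_um = 1:10, M1 = 0, M2 = as.numeric(1:10))
  cells <- as_cell_table(dt, markers = c("M1", "M2"))
  expect_warning(thr <- fit_marker_thresholds(cells, markers = "M1"), "degenerate")
  expect_identical(sum(asinh(cells$M1 / 150) > thr$thresholds[["M1"]]), 0L)

  thrq <- fit_marker_thresholds(cells, method = "quantile", markers = "M2", q = 0.9)
  expect_identical(sum(asinh(cells$M2 / 150) > thrq$thresholds[["M2"]]), 1L)
})

test_that("missing marker columns are rejected by name", {
  dt <- data.table::data.table(cell_id = "c1", roi_id = "r", case_id = "c",
                               group = "g", x_um = 1, y_um = 1, CD3 = 5)
  expect_error(assign_phenotypes(as_cell_table(dt, markers = "CD3")), "CD20")
})

test_that("gating recovers simulated populations with precision/recall >= 0.95", {
  sims <- lapply(c("group1", "group2", "group3", "thrlbcl"), function(g)
    simulate_tissue(make_group_presets(g, n_cells = 2500, seed = 11,
                                       polygons = FALSE), roi_id = g))
  cells <- data.table::rbindlist(lapply(sims, `[[`, "cells"))
  cells <- as_cell_table(cells, markers = codex_markers())
  truth <- unlist(lapply(sims, function(s) s$truth$labels))
  ph <- assign_phenotypes(cells, default_schema(),
                          fit_marker_thresholds(cells))
  tv <- truth[ph$cell_id]
  for (p in population_names()) {
    tp <- sum(tv == p & ph$phenotype == p)
    expect_gte(tp / sum(ph$phenotype == p), 0.95)
    expect_gte(tp / sum(tv == p), 0.95)
  }
})

test_that("detect_population applies both detection floors to pooled cells", {
  mk_case <- function(n_total, n_dpt) {
    lab <- c(rep("dpt", n_dpt), rep("helper_t", n_total - n_dpt))
    dt <- data.table::data.table(
      cell_id = sprintf("c%05d", seq_len(n_total)),
      roi_id = rep(c("r1", "r2"), length.out = n_total),
      case_id = "case", group = "g", x_um = 0, y_um = 0, phenotype = lab)
    x <- as_cell_table(dt, markers = character(0))
    data.table::setattr(x, "populations", population_names())
    x
  }
  expect_true(detect_population(mk_case(20000, 25), "dpt"))    # 0.00125, 25
  expect_false(detect_population(mk_case(20000, 0), "dpt"))    # zero cells
  expect_false(detect_population(mk_case(1900, 19), "dpt"))    # count floor
  expect_error(detect_population(mk_case(100, 5), "nk_cell"), "unknown population")
})

test_that("schema and threshold YAML round-trips are lossless", {
  sch <- default_schema()
  f1 <- tempfile(fileext = ".yaml")
  write_schema_yaml(sch, f1)
  back <- read_schema_yaml(f1)
  expect_equal(back$rules, sch$rules)

  ts <- fixed_thresholds()
  f2 <- tempfile(fileext = ".yaml")
  write_schema_yaml(ts, f2)
  ts2 <- read_schema_yaml(f2)
  expect_equal(ts2$thresholds, ts$thresholds)
  expect_equal(ts2$transform$cofactor, 150)
})
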