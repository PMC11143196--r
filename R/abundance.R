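# composition, Z-score abundance profiling, rank-sum testing, detection rates

#' Per-ROI population composition
#'
#' Fractions of each schema population (plus `"other"`) per ROI; each row
#' sums to 1.
#'
#' @param cells A `phenotyped_cell_table` with `roi_id` (and ideally
#'   `case_id`, `group`) columns.
#' @return A `composition_table`: data.frame with columns `roi_id`,
#'   `case_id`, `group` and one fraction column per population; the
#'   population names are carried in the `"populations"` attribute.
#' @export
roi_composition <- function(cells) {
  if (!"phenotype" %in% names(cells))
    spl_data_error("cells are not phenotyped; run assign_phenotypes() first")
  pops <- c(attr(cells, "populations") %||% schema_populations(default_schema()),
            "other")
  if (is.factor(cells$roi_id)) {
    empty <- setdiff(levels(cells$roi_id), unique(as.character(cells$roi_id)))
    if (length(empty))
      spl_data_error("ROI '%s' contains no cells", empty[1])
  }
  dt <- as.data.table(cells)
  if (!"case_id" %in% names(dt)) dt[, case_id := NA_character_]
  if (!"group" %in% names(dt)) dt[, group := NA_character_]
  tab <- dt[, {
    f <- as.numeric(table(factor(phenotype, levels = pops))) / .N
    c(list(case_id = as.character(case_id[1]), group = as.character(group[1])),
      setNames(as.list(f), pops))
  }, by = roi_id]
  out <- as.data.frame(tab)
  attr(out, "populations") <- pops
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Cross-ROI Z-score matrix
#'
#' Standardizes each population's per-ROI fraction across all ROIs pooled
#' (mean 0, SD 1; SD with denominator n). Values for a case are the mean of
#' its member-ROI Z-scores, and group values are the mean of member-case
#' values (case-first consolidation). A zero-variance population row comes
#' back all zero with a warning.
#'
#' @param comp A [roi_composition()] result with at least 2 ROIs.
#' @return A `zscore_matrix`: list with `z` (population x ROI), `case_z`,
#'   `group_z`, and `populations`.
#' @export
zscore_matrix <- function(comp) {
  pops <- attr(comp, "populations")
  if (nrow(comp) < 2L) spl_data_error("need >= 2 ROIs to standardize")
  X <- t(as.matrix(comp[, pops, drop = FALSE]))
  colnames(X) <- comp$roi_id
  mu <- rowMeans(X)
  sdv <- apply(X, 1L, pop_sd)
  z <- (X - mu) / ifelse(sdv > 0, sdv, 1)
  if (any(sdv == 0)) {
    warning(sprintf("zero-variance population row(s) emitted as all-zero: %s",
                    paste(pops[sdv == 0], collapse = ", ")))
    z[sdv == 0, ] <- 0
  }
  case_of <- setNames(as.character(comp$case_id), comp$roi_id)
  group_of_case <- tapply(as.character(comp$group), as.character(comp$case_id),
                          function(g) g[1])
  cases <- unique(unname(case_of))
  case_z <- vapply(cases, function(cs)
    rowMeans(z[, comp$roi_id[case_of[comp$roi_id] == cs], drop = FALSE]),
    numeric(nrow(z)))
  case_z <- matrix(case_z, nrow = nrow(z),
                   dimnames = list(rownames(z), cases))
  groups <- as.character(unique(unname(group_of_case)))
  group_z <- vapply(groups, function(g)
    rowMeans(case_z[, cases[group_of_case[cases] == g], drop = FALSE]),
    numeric(nrow(z)))
  group_z <- matrix(group_z, nrow = nrow(z),
                    dimnames = list(rownames(z), groups))
  structure(list(z = z, case_z = case_z, group_z = group_z, populations = pops),
            class = "zscore_matrix")
}

# midranks of a vector (standard rank-sum convention for ties)
midranks <- function(v) rank(v, ties.method = "average")

#' Rank-sum (Wilcoxon / Mann-Whitney) test
#'
#' Exact p-values by enumeration of all `choose(n1+n2, n1)` group labelings
#' of the pooled mid-ranks whenever `min(n1, n2) <= 10` (and the enumeration
#' fits in memory); otherwise the normal approximation with tie correction
#' and continuity correction. Two-sided by default. When every pooled value
#' is identical the p-value is 1.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or `"less"`.
#' @param exact_max_min Largest `min(n1, n2)` for which enumeration is used.
#' @return A `rank_sum_test` list: `statistic` (rank sum W of `x`), `u`
#'   (Mann-Whitney U), `p_value`, `p_two_sided`, `n1`, `n2`, `method`
#'   (`"exact"` or `"normal_tie_corrected"`), `alternative`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                          exact_max_min = 10L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) spl_data_error("both samples must be non-empty")
  n <- n1 + n2
  r <- midranks(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  eps <- 1e-9

  use_exact <- min(n1, n2) <= exact_max_min && choose(n, n1) <= 5e5
  if (use_exact) {
    cmb <- combn(n, n1)
    rs <- colSums(matrix(r[cmb], nrow = n1))
    p_two <- mean(abs(rs - mu) >= abs(W - mu) - eps)
    p_gt <- mean(rs >= W - eps)
    p_lt <- mean(rs <= W + eps)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_corr))
    if (sigma == 0) {
      p_two <- p_gt <- p_lt <- 1
    } else {
      z_two <- (abs(W - mu) - 0.5) / sigma
      p_two <- min(1, 2 * pnorm(-max(z_two, 0)))
      p_gt <- pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
      p_lt <- pnorm((W - mu + 0.5) / sigma)
    }
    method <- "normal_tie_corrected"
  }
  p <- switch(alternative, two.sided = p_two, greater = p_gt, less = p_lt)
  structure(list(statistic = W, u = W - n1 * (n1 + 1) / 2,
                 p_value = p, p_two_sided = p_two,
                 n1 = n1, n2 = n2, method = method, alternative = alternative),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("rank-sum test (%s): W = %.2f, n = (%d, %d), p[%s] = %.4g\n",
              x$method, x$statistic, x$n1, x$n2, x$alternative, x$p_value))
  invisible(x)
}

#' Per-group population detection rate
#'
#' Splits the cells by case, applies [detect_population()] to each case
#' (pooled across its ROIs), and reports the detected proportion as a
#' percentage rounded to one decimal.
#'
#' @param cases A `phenotyped_cell_table` covering one or more cases, or a
#'   list of per-case tables.
#' @param population Population name.
#' @param floor_fraction,floor_count Passed to [detect_population()].
#' @return List with `percent`, `detected`, `n_cases`, and the per-case
#'   logical vector `per_case`.
#' @export
detection_rate <- function(cases, population, floor_fraction = 0.001,
                           floor_count = 20L) {
  if (!is.list(cases) || is.data.frame(cases)) {
    cases <- split(as.data.table(cases), by = "case_id", sorted = TRUE)
    cases <- lapply(cases, function(x) {
      setattr(x, "class", unique(c("phenotyped_cell_table", "cell_table", class(x)))); x
    })
  }
  if (!length(cases)) spl_data_error("need at least one case")
  det <- vapply(cases, detect_population, logical(1),
                name = population, floor_fraction = floor_fraction,
                floor_count = floor_count)
  list(percent = round(100 * mean(det), 1), detected = sum(det),
       n_cases = length(det), per_case = det)
}

#' Compare a population's abundance between two groups
#'
#' Rank-sum test on the per-ROI fractions of the two groups.
#'
#' @param comp A [roi_composition()] result.
#' @param population Population (column) name.
#' @param groupA,groupB Group labels present in `comp$group`.
#' @param alternative Passed to [rank_sum_test()].
#' @return A `rank_sum_test`.
#' @export
group_compare <- function(comp, population, groupA, groupB,
                          alternative = "two.sided") {
  if (!population %in% names(comp))
    spl_config_error("unknown population '%s'", population)
  for (g in c(groupA, groupB))
    if (!g %in% comp$group) spl_config_error("unknown group '%s'", g)
  rank_sum_test(comp[comp$group == groupA, population],
                comp[comp$group == groupB, population],
                alternative = alternative)
}

#' Tidy group-level abundance summary
#'
#' One row per (population, group): mean Z-score and the number of member
#' ROIs, the export shape used by the pipeline report.
#'
#' @param zm A [zscore_matrix()] result.
#' @param comp The matching [roi_composition()] result.
#' @return data.frame with columns `population`, `group`, `mean_z`, `n_rois`.
#' @export
group_summary <- function(zm, comp) {
  groups <- colnames(zm$group_z)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(population = rownames(zm$group_z), group = g,
               mean_z = zm$group_z[, g],
               n_rois = sum(comp$group == g), row.names = NULL)
  }))
  out
}
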