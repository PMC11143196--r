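# marker co-expression gating: schema, thresholds, assignment, detectability

#' Build a phenotype gating schema
#'
#' @param rules List of rules; each rule is a list with `name`, `required`
#'   (character, non-empty), `forbidden` (character, possibly empty) and
#'   integer `priority` (lower wins ties among rules with equally many
#'   required markers).
#' @return A `phenotype_schema`.
#' @export
phenotype_schema <- function(rules) {
  nms <- vapply(rules, `[[`, character(1), "name")
  if (anyDuplicated(nms)) spl_config_error("schema rule names must be unique")
  if (any(vapply(rules, function(r) length(r$required) == 0L, logical(1))))
    spl_config_error("every rule needs a non-empty required marker set")
  pr <- vapply(rules, `[[`, numeric(1), "priority")
  if (anyDuplicated(pr)) spl_config_error("rule priorities must be strictly ordered")
  structure(list(rules = rules), class = "phenotype_schema")
}

#' Schema population names
#' @param schema A `phenotype_schema`.
#' @return Character vector of rule names, in priority order.
#' @export
schema_populations <- function(schema) {
  nms <- vapply(schema$rules, `[[`, character(1), "name")
  pr <- vapply(schema$rules, `[[`, numeric(1), "priority")
  nms[order(pr)]
}

#' The default 12-population gating schema
#'
#' Encodes the co-expression definitions used across the NLPHL/THRLBCL
#' spectrum: tumor B (CD20/BCL6), TME B (CD20/IgD), helper T (CD3/CD4),
#' activated helper T (CD3/CD4/LAG3/CD69), TFH (CD3/CD4/PD1/BCL6), activated
#' TFH (CD3/CD4/PD1/BCL6/LAG3/CD69), cytotoxic T (CD3/CD8), activated
#' cytotoxic T (CD3/CD8/LAG3/CD69), T-reg (CD3/CD4/FOXP3), CD4/CD8
#' double-positive T (CD3/CD4/CD8), macrophage (CD68) and monocyte
#' (CD68/MPO/CD14). Forbidden sets implement confirmation-by-absence: B rules
#' exclude CD3; T rules exclude CD20 and CD68; plain helper T additionally
#' excludes the activation/subset markers (CD8, FOXP3, PD1, LAG3, CD69);
#' cytotoxic rules exclude CD4 (the double-positive rule requires both);
#' macrophage/monocyte exclude CD3 and CD20. When a cell satisfies several
#' rules the rule with the most required markers wins, with the tie between
#' tumor B and TME B (CD20+/BCL6+/IgD+) resolved to tumor B by priority.
#'
#' @return A `phenotype_schema` with 12 rules.
#' @export
default_schema <- function() {
  r <- function(name, required, forbidden, priority)
    list(name = name, required = required, forbidden = forbidden, priority = priority)
  phenotype_schema(list(
    r("tumor_b",         c("CD20", "BCL6"),                              c("CD3"),                                        1L),
    r("tme_b",           c("CD20", "IGD"),                               c("CD3"),                                        2L),
    r("helper_t",        c("CD3", "CD4"),                                c("CD8", "FOXP3", "PD1", "LAG3", "CD69", "CD20", "CD68"), 3L),
    r("act_helper_t",    c("CD3", "CD4", "LAG3", "CD69"),                c("CD8", "FOXP3", "CD20", "CD68"),               4L),
    r("tfh",             c("CD3", "CD4", "PD1", "BCL6"),                 c("CD8", "CD20", "CD68"),                        5L),
    r("atfh",            c("CD3", "CD4", "PD1", "BCL6", "LAG3", "CD69"), c("CD8", "CD20", "CD68"),                        6L),
    r("cytotoxic_t",     c("CD3", "CD8"),                                c("CD4", "CD20", "CD68"),                        7L),
    r("act_cytotoxic_t", c("CD3", "CD8", "LAG3", "CD69"),                c("CD4", "CD20", "CD68"),                        8L),
    r("treg",            c("CD3", "CD4", "FOXP3"),                       c("CD8", "CD20", "CD68"),                        9L),
    r("dpt",             c("CD3", "CD4", "CD8"),                         c("CD20", "CD68"),                               10L),
    r("macrophage",      c("CD68"),                                      c("CD3", "CD20"),                                11L),
    r("monocyte",        c("CD68", "MPO", "CD14"),                       c("CD3", "CD20"),                                12L)
  ))
}

#' Construct a threshold set
#'
#' @param thresholds Named numeric vector of per-marker positivity thresholds
#'   on the arcsinh-transformed scale.
#' @param cofactor arcsinh cofactor of the transform `asinh(x / cofactor)`.
#' @return A `threshold_set`.
#' @export
threshold_set <- function(thresholds, cofactor = 150) {
  if (any(!is.finite(thresholds)))
    spl_config_error("thresholds must be finite")
  structure(list(thresholds = thresholds,
                 transform = list(type = "arcsinh", cofactor = cofactor)),
            class = "threshold_set")
}

transform_intensity <- function(x, ts) asinh(x / ts$transform$cofactor)

# deterministic 1-D two-component Gaussian mixture: 2-means (min/max init)
# followed by EM; returns component means (sorted)
gmm2_means <- function(y, n_iter = 200L, tol = 1e-8) {
  c1 <- min(y); c2 <- max(y)
  for (k in seq_len(50L)) {
    z <- abs(y - c1) <= abs(y - c2)
    if (!any(z) || all(z)) break
    n1 <- mean(y[z]); n2 <- mean(y[!z])
    if (abs(n1 - c1) + abs(n2 - c2) < tol) { c1 <- n1; c2 <- n2; break }
    c1 <- n1; c2 <- n2
  }
  z <- abs(y - c1) <= abs(y - c2)
  mu <- c(c1, c2)
  s <- pmax(c(if (any(z)) sd(y[z]) else 0, if (any(!z)) sd(y[!z]) else 0),
            1e-3, na.rm = TRUE)
  s[is.na(s)] <- 1e-3
  pi1 <- mean(z)
  for (it in seq_len(n_iter)) {
    d1 <- pi1 * dnorm(y, mu[1], s[1])
    d2 <- (1 - pi1) * dnorm(y, mu[2], s[2])
    g <- d1 / pmax(d1 + d2, 1e-300)
    pi1_new <- mean(g)
    mu_new <- c(sum(g * y) / max(sum(g), 1e-12),
                sum((1 - g) * y) / max(sum(1 - g), 1e-12))
    s_new <- pmax(c(sqrt(sum(g * (y - mu_new[1])^2) / max(sum(g), 1e-12)),
                    sqrt(sum((1 - g) * (y - mu_new[2])^2) / max(sum(1 - g), 1e-12))),
                  1e-3)
    delta <- sum(abs(mu_new - mu)) + sum(abs(s_new - s)) + abs(pi1_new - pi1)
    mu <- mu_new; s <- s_new; pi1 <- pi1_new
    if (delta < tol) break
  }
  sort(mu)
}

#' Fit per-marker positivity thresholds
#'
#' Intensities are arcsinh-transformed (`asinh(x / cofactor)`) and a
#' threshold is placed per marker: for `method = "gmm2"` at the midpoint of
#' the two component means of a two-component Gaussian mixture
#' (deterministically initialized, so no RNG is consumed); for
#' `method = "quantile"` at the configured upper quantile. A degenerate
#' (constant) marker gets a threshold above its maximum, so no cell is
#' positive, with a warning.
#'
#' @param cells A `cell_table`.
#' @param method `"gmm2"` or `"quantile"`.
#' @param markers Markers to fit (default: all marker columns).
#' @param cofactor arcsinh cofactor (default 150, a conventional
#'   fluorescence-scale compression; not data-derived).
#' @param q Upper quantile for `method = "quantile"`.
#' @param seed Accepted for interface stability; the fit is deterministic.
#' @return A [threshold_set()].
#' @export
fit_marker_thresholds <- function(cells, method = c("gmm2", "quantile"),
                                  markers = NULL, cofactor = 150, q = 0.9,
                                  seed = NULL) {
  method <- match.arg(method)
  markers <- markers %||% cell_markers(cells)
  ts <- threshold_set(setNames(rep(0, length(markers)), markers), cofactor)
  for (m in markers) {
    y <- transform_intensity(cells[[m]], ts)
    if (diff(range(y)) < 1e-10) {
      warning(sprintf("marker %s is degenerate (constant); no cell called positive", m))
      ts$thresholds[[m]] <- max(y) + 1
    } else if (method == "gmm2") {
      mu <- gmm2_means(y)
      ts$thresholds[[m]] <- mean(mu)
    } else {
      ts$thresholds[[m]] <- as.numeric(quantile(y, q, type = 7))
    }
  }
  ts
}

#' Assign phenotypes by thresholded marker co-expression
#'
#' A cell matches a rule iff all its required markers are positive and all
#' its forbidden markers are negative (positive means transformed intensity
#' strictly above the marker threshold). Among matching rules the one with
#' the most required markers wins; ties break by schema priority; cells with
#' no match get `"other"`.
#'
#' @param cells A `cell_table`.
#' @param schema A `phenotype_schema` (default [default_schema()]).
#' @param thresholds A [threshold_set()]; fitted with defaults when `NULL`.
#' @return A `phenotyped_cell_table`: the input plus a `phenotype` column and
#'   one `<marker>_pos` logical column per thresholded marker.
#' @export
assign_phenotypes <- function(cells, schema = default_schema(), thresholds = NULL) {
  need <- unique(unlist(lapply(schema$rules, function(r) c(r$required, r$forbidden))))
  miss <- setdiff(need, names(cells))
  if (length(miss))
    spl_data_error("missing marker column(s): %s", paste(miss, collapse = ", "))
  thresholds <- thresholds %||% fit_marker_thresholds(cells, markers = need)
  tm <- intersect(names(thresholds$thresholds), names(cells))
  pos <- vapply(tm, function(m)
    transform_intensity(cells[[m]], thresholds) > thresholds$thresholds[[m]],
    logical(nrow(cells)))
  if (nrow(cells) == 1L) pos <- matrix(pos, nrow = 1L, dimnames = list(NULL, tm))

  n <- nrow(cells)
  best_score <- rep(-Inf, n)
  assigned <- rep("other", n)
  for (r in schema$rules) {
    ok <- rep(TRUE, n)
    for (m in r$required) ok <- ok & pos[, m]
    for (m in r$forbidden) ok <- ok & !pos[, m]
    score <- 1000 * length(r$required) - r$priority
    upd <- ok & score > best_score
    assigned[upd] <- r$name
    best_score[upd] <- score
  }
  out <- copy(as.data.table(cells))
  out[, phenotype := assigned]
  for (m in tm) out[, (paste0(m, "_pos")) := pos[, m]]
  out <- as_cell_table(out, markers = cell_markers(cells), bbox = attr(cells, "bbox"))
  setattr(out, "populations", schema_populations(schema))
  setattr(out, "class", unique(c("phenotyped_cell_table", class(out))))
  out
}

#' Decide whether a population is detectable in a case
#'
#' Pools the case's cells across ROIs; the population counts as detected iff
#' its pooled fraction is at least `floor_fraction` and its pooled count is
#' at least `floor_count`.
#'
#' @param case_cells A `phenotyped_cell_table` for one case.
#' @param name Population name (must be a schema population or `"other"`).
#' @param floor_fraction,floor_count Detection floors (defaults 0.001 and 20).
#' @return `TRUE` or `FALSE`.
#' @export
detect_population <- function(case_cells, name, floor_fraction = 0.001,
                              floor_count = 20L) {
  if (nrow(case_cells) == 0L) spl_data_error("case has no cells")
  known <- c(attr(case_cells, "populations") %||% schema_populations(default_schema()),
             "other")
  if (!name %in% known)
    spl_config_error("unknown population name '%s'", name)
  cnt <- sum(case_cells$phenotype == name)
  cnt / nrow(case_cells) >= floor_fraction && cnt >= floor_count
}

#' Read / write a phenotype schema or threshold set as YAML
#' @param x A `phenotype_schema` or `threshold_set`.
#' @param path YAML file path.
#' @return Reading returns the reconstructed object.
#' @export
write_schema_yaml <- function(x, path) {
  if (inherits(x, "phenotype_schema")) {
    yaml::write_yaml(list(kind = "phenotype_schema", rules = x$rules), path, precision = 15)
  } else if (inherits(x, "threshold_set")) {
    yaml::write_yaml(list(kind = "threshold_set",
                          thresholds = as.list(x$thresholds),
                          transform = x$transform), path, precision = 15)
  } else spl_config_error("cannot serialize object of class %s", class(x)[1])
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (identical(y$kind, "phenotype_schema")) {
    rules <- lapply(y$rules, function(r) {
      r$required <- as.character(unlist(r$required))
      r$forbidden <- as.character(unlist(r$forbidden))
      r$priority <- as.integer(r$priority)
      r
    })
    phenotype_schema(rules)
  } else if (identical(y$kind, "threshold_set")) {
    threshold_set(unlist(y$thresholds), cofactor = y$transform$cofactor)
  } else spl_config_error("unrecognized YAML schema file: %s", path)
}
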