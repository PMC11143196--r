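# annulus neighbor graph, size-corrected interaction scores, permutation
# null calibration, Voronoi tessellation export

#' Build the annulus-range neighbor graph
#'
#' Two cells of the same ROI are neighbors iff their centroid Euclidean
#' distance lies in `[d_min, d_max]` (both ends inclusive); no cross-ROI
#' edges. Implemented with grid binning at `d_max`, equivalent to the
#' brute-force all-pairs computation.
#'
#' @param cells A `cell_table` with unique `cell_id` per ROI.
#' @param d_min,d_max Annulus bounds in microns (defaults 3 and 30).
#' @return A `neighbor_graph`: list with the `edges` table (`roi_id`, `a`,
#'   `b` cell ids with `a < b`, `ai`/`bi` row indices, `dist_um`), the cell
#'   index (`cell_ids`, `roi`), and `d_min`/`d_max`.
#' @export
build_neighbor_graph <- function(cells, d_min = 3, d_max = 30) {
  if (!(d_min >= 0 && d_min < d_max))
    spl_config_error("need 0 <= d_min < d_max (got %.3f, %.3f)", d_min, d_max)
  dt <- as.data.table(cells)
  dup <- dt[, .N, by = .(roi_id, cell_id)][N > 1L]
  if (nrow(dup))
    spl_data_error("duplicate cell id '%s' within ROI '%s'",
                   dup$cell_id[1], dup$roi_id[1])
  edges <- list()
  for (roi in unique(dt$roi_id)) {
    ridx <- which(dt$roi_id == roi)
    xs <- dt$x_um[ridx]; ys <- dt$y_um[ridx]
    nb <- data.table(i = seq_along(ridx), x = xs, y = ys,
                     bx = floor(xs / d_max), by = floor(ys / d_max))
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
    nb9 <- rbindlist(lapply(seq_len(nrow(off)), function(k)
      data.table(j = nb$i, x2 = nb$x, y2 = nb$y,
                 bx = nb$bx + off[k, 1], by = nb$by + off[k, 2])))
    setkey(nb9, bx, by)
    p <- nb9[nb, on = c("bx", "by"), nomatch = 0L, allow.cartesian = TRUE]
    p <- p[i < j]
    p[, d := sqrt((x - x2)^2 + (y - y2)^2)]
    p <- p[d >= d_min & d <= d_max]
    if (nrow(p))
      edges[[length(edges) + 1L]] <- data.table(
        roi_id = roi, ai = ridx[p$i], bi = ridx[p$j],
        a = dt$cell_id[ridx[p$i]], b = dt$cell_id[ridx[p$j]], dist_um = p$d)
  }
  edges <- if (length(edges)) rbindlist(edges) else
    data.table(roi_id = character(0), ai = integer(0), bi = integer(0),
               a = character(0), b = character(0), dist_um = numeric(0))
  structure(list(edges = edges, cell_ids = dt$cell_id, roi = dt$roi_id,
                 d_min = d_min, d_max = d_max),
            class = "neighbor_graph")
}

# resolve a labels argument (phenotyped table, named vector, or plain vector
# aligned with graph$cell_ids) to a character vector per graph cell
resolve_labels <- function(graph, labels) {
  if (inherits(labels, "phenotyped_cell_table") ||
      (is.data.frame(labels) && "phenotype" %in% names(labels)))
    labels <- setNames(labels$phenotype, labels$cell_id)
  if (!is.null(names(labels))) {
    out <- unname(labels[graph$cell_ids])
    if (anyNA(out))
      spl_data_error("label missing for cell '%s'",
                     graph$cell_ids[which(is.na(out))[1]])
    return(as.character(out))
  }
  if (length(labels) != length(graph$cell_ids))
    spl_data_error("labels must cover every graph node (%d != %d)",
                   length(labels), length(graph$cell_ids))
  as.character(labels)
}

# raw pair-count matrix E over a set of edges: E[i,j] = number of edges with
# endpoint labels {i, j} (each edge counted once)
edge_pair_counts <- function(la, lb, K) {
  k1 <- pmin(la, lb); k2 <- pmax(la, lb)
  cnt <- tabulate((k1 - 1L) * K + k2, nbins = K * K)
  M <- matrix(cnt, K, K, byrow = TRUE)   # M[k1, k2], k1 <= k2
  M + t(M) - diag(diag(M), K)
}

#' Size-corrected pairwise interaction scores
#'
#' `S[i,j] = E[i,j] / (n_i + n_j)` for distinct populations and
#' `S[i,i] = E[i,i] / (2 n_i)`, where `E[i,j]` is the number of qualifying
#' neighbor pairs and `n_i` the population size over the graph's cells --
#' the correction of each interaction for the total number of cells involved
#' in it. Populations absent from the data get `NA` ("not assessable") rows
#' and columns. A per-cell variant (`partner_counts[i,j]` = number of cells
#' of population i with at least one j neighbor) is exported alongside.
#'
#' @param graph A [build_neighbor_graph()] result.
#' @param labels Phenotyped cell table, named label vector, or vector aligned
#'   with the graph's cells.
#' @param populations Population universe (default: schema populations plus
#'   `"other"` when labels come from a phenotyped table, otherwise the
#'   observed labels).
#' @return An `interaction_matrix`: list with `S`, `E`, `n`,
#'   `partner_counts`, `populations`.
#' @export
interaction_scores <- function(graph, labels, populations = NULL) {
  if (is.null(populations)) {
    populations <- if (!is.null(attr(labels, "populations")))
      c(attr(labels, "populations"), "other") else NULL
  }
  lv <- resolve_labels(graph, labels)
  populations <- populations %||% sort(unique(lv))
  f <- factor(lv, levels = populations)
  if (anyNA(f))
    spl_data_error("labels contain populations outside the stated universe: %s",
                   paste(setdiff(unique(lv), populations), collapse = ", "))
  K <- length(populations)
  n <- as.numeric(table(f))
  ia <- as.integer(f)[graph$edges$ai]
  ib <- as.integer(f)[graph$edges$bi]
  E <- if (length(ia)) edge_pair_counts(ia, ib, K) else matrix(0, K, K)
  denom <- outer(n, n, `+`)
  diag(denom) <- 2 * n
  S <- ifelse(denom > 0, E / denom, NA_real_)
  absent <- n == 0
  S[absent, ] <- NA_real_; S[, absent] <- NA_real_
  dimnames(S) <- dimnames(E) <- list(populations, populations)
  names(n) <- populations

  pc <- matrix(0, K, K, dimnames = list(populations, populations))
  if (length(ia)) {
    dd <- unique(rbind(data.table(cell = graph$edges$ai, pop = ia, nbr = ib),
                       data.table(cell = graph$edges$bi, pop = ib, nbr = ia)))
    cnt <- dd[, .N, by = .(pop, nbr)]
    pc[cbind(cnt$pop, cnt$nbr)] <- cnt$N
  }
  structure(list(S = S, E = E, n = n, partner_counts = pc,
                 populations = populations),
            class = "interaction_matrix")
}

#' Permutation-null enrichment of interaction scores
#'
#' Holds cell positions (and hence the neighbor graph) fixed and shuffles
#' phenotype labels uniformly within each ROI, recomputing the corrected
#' interaction score for every population pair. The observed score is
#' compared to the permutation null: `ratio = observed / null mean`, with
#' one-sided enrichment and depletion p-values using the add-one rule
#' `p = (1 + #{S_perm >= S_obs}) / (n_perm + 1)`.
#'
#' @param cells A `cell_table` (or phenotyped table supplying labels).
#' @param labels Labels (defaults to `cells$phenotype`).
#' @param d_min,d_max Annulus bounds in microns.
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param graph Optional pre-built [build_neighbor_graph()] result.
#' @param populations Optional population universe.
#' @return An `enrichment_result`: list with the per-pair table `pairs`
#'   (`pop_i`, `pop_j`, `S_obs`, `null_mean`, `null_sd`, `ratio`,
#'   `p_enrich`, `p_deplete`), the observed `interaction_matrix` as
#'   `observed`, `n_perm`, and `seed`.
#' @export
permutation_enrichment <- function(cells, labels = NULL, d_min = 3, d_max = 30,
                                   n_perm = 1000L, seed = 1L, graph = NULL,
                                   populations = NULL) {
  labels <- labels %||% cells
  graph <- graph %||% build_neighbor_graph(cells, d_min, d_max)
  if (nrow(graph$edges) == 0L) spl_data_error("neighbor graph has no edges")
  obs <- interaction_scores(graph, labels, populations)
  populations <- obs$populations
  K <- length(populations)
  f <- as.integer(factor(resolve_labels(graph, labels), levels = populations))
  n <- obs$n
  denom <- outer(n, n, `+`); diag(denom) <- 2 * n
  ea <- graph$edges$ai; eb <- graph$edges$bi
  roi_split <- split(seq_along(graph$cell_ids), graph$roi)

  S_obs <- obs$S
  sum_S <- matrix(0, K, K); sum_S2 <- matrix(0, K, K)
  ge <- matrix(0, K, K); le <- matrix(0, K, K)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      lp <- f
      for (idx in roi_split) lp[idx] <- f[idx][sample.int(length(idx))]
      Ep <- edge_pair_counts(lp[ea], lp[eb], K)
      Sp <- ifelse(denom > 0, Ep / denom, NA_real_)
      sum_S <- sum_S + Sp
      sum_S2 <- sum_S2 + Sp^2
      ge <- ge + (Sp >= S_obs - 1e-12)
      le <- le + (Sp <= S_obs + 1e-12)
    }
  })
  null_mean <- sum_S / n_perm
  null_sd <- sqrt(pmax(sum_S2 / n_perm - null_mean^2, 0))
  ratio <- ifelse(null_mean > 0, S_obs / null_mean, NA_real_)
  p_enrich <- (1 + ge) / (n_perm + 1)
  p_deplete <- (1 + le) / (n_perm + 1)

  ut <- which(upper.tri(S_obs, diag = TRUE) & !is.na(S_obs), arr.ind = TRUE)
  pairs <- data.table(
    pop_i = populations[ut[, 1]], pop_j = populations[ut[, 2]],
    S_obs = S_obs[ut], null_mean = null_mean[ut], null_sd = null_sd[ut],
    ratio = ratio[ut], p_enrich = p_enrich[ut], p_deplete = p_deplete[ut])
  structure(list(pairs = pairs, observed = obs, null_mean = null_mean,
                 null_sd = null_sd, ratio = ratio, p_enrich = p_enrich,
                 p_deplete = p_deplete, n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

# ---- Voronoi tessellation ------------------------------------------------

# clip a convex polygon to the half-plane a*x + b*y <= c (Sutherland-Hodgman)
clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  v <- a * poly[, 1] + b * poly[, 2] - cc
  if (all(v <= 1e-12)) return(poly)
  if (all(v >= -1e-12)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- v[i] <= 0; pj_in <- v[j] <= 0
    if (pi_in) out <- rbind(out, poly[i, ])
    if (pi_in != pj_in) {
      t <- v[i] / (v[i] - v[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Voronoi tessellation of cell centroids, clipped to the ROI rectangle
#'
#' Exact construction by half-plane clipping: each cell's polygon is the ROI
#' rectangle clipped by the perpendicular bisector against every other cell
#' of the ROI. Polygons tile the rectangle and each carries its cell's
#' phenotype label (when available).
#'
#' @param cells A `cell_table` (single ROI) with at least 3 non-collinear
#'   cells.
#' @param roi_bounds `c(xmin, xmax, ymin, ymax)`; default [cell_bbox()].
#' @return A `voronoi_set`: list with `polygons` (named list of vertex
#'   matrices in microns), `labels`, `cell_ids`, `bounds`.
#' @export
voronoi_export <- function(cells, roi_bounds = NULL) {
  if (nrow(cells) < 3L) spl_data_error("need >= 3 cells for a tessellation")
  P <- cbind(cells$x_um, cells$y_um)
  ctr <- sweep(P, 2, colMeans(P))
  if (svd(ctr)$d[2] < 1e-9 * max(1, svd(ctr)$d[1]))
    spl_data_error("degenerate input: cell centroids are collinear")
  b <- roi_bounds %||% cell_bbox(cells)
  rect <- rbind(c(b[1], b[3]), c(b[2], b[3]), c(b[2], b[4]), c(b[1], b[4]))
  n <- nrow(P)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- rect
    pi_ <- P[i, ]
    ord <- order((P[, 1] - pi_[1])^2 + (P[, 2] - pi_[2])^2)
    for (j in ord) {
      if (j == i || nrow(poly) == 0L) next
      qj <- P[j, ]
      a <- 2 * (qj[1] - pi_[1]); bb <- 2 * (qj[2] - pi_[2])
      cc <- sum(qj^2) - sum(pi_^2)
      poly <- clip_halfplane(poly, a, bb, cc)
    }
    polys[[i]] <- poly
  }
  names(polys) <- cells$cell_id
  structure(list(polygons = polys,
                 labels = if ("phenotype" %in% names(cells))
                   setNames(cells$phenotype, cells$cell_id) else NULL,
                 cell_ids = cells$cell_id, bounds = b),
            class = "voronoi_set")
}

#' Write polygons as GeoJSON
#'
#' Serializes a [voronoi_export()] result or a nucleus polygon table
#' (`cell_id`/`x_um`/`y_um`) as a GeoJSON FeatureCollection with coordinates
#' in microns and the label (phenotype) as a feature property.
#'
#' @param x A `voronoi_set` or polygon data.table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(x, path) {
  if (inherits(x, "voronoi_set")) {
    ids <- x$cell_ids
    polys <- x$polygons
    labels <- x$labels %||% setNames(rep(NA_character_, length(ids)), ids)
  } else {
    dt <- as.data.table(x)
    ids <- unique(dt$cell_id)
    polys <- lapply(ids, function(id) as.matrix(dt[cell_id == id, .(x_um, y_um)]))
    names(polys) <- ids
    labels <- setNames(rep(NA_character_, length(ids)), ids)
  }
  feats <- lapply(ids, function(id) {
    ring <- polys[[id]]
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(cell_id = id, label = unname(labels[[id]])),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) as.numeric(ring[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON polygons back to a table
#' @param path GeoJSON path written by [write_geojson_polygons()].
#' @return data.table with columns `cell_id`, `vertex`, `x_um`, `y_um`, `label`.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path)
  rbindlist(lapply(g$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    ring <- ring[-length(ring)]
    data.table(cell_id = f$properties$cell_id,
               vertex = seq_along(ring),
               x_um = vapply(ring, function(p) as.numeric(p[[1]]), numeric(1)),
               y_um = vapply(ring, function(p) as.numeric(p[[2]]), numeric(1)),
               label = f$properties$label %||% NA_character_)
  }))
}
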