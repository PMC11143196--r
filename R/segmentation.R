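# nuclear segmentation: Gaussian smoothing, local-maxima seeds, radius-bounded
# region growth with a size cutoff, per-cell quantification, spillover
# compensation

#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian smoothing SD in pixels applied before seed
#'   detection and growth.
#' @param maxima_min_distance Minimum seed separation in pixels (a seed must be
#'   a strict maximum over the Euclidean disc of this radius).
#' @param maxima_min_intensity Seeds must exceed this fraction of the smoothed
#'   channel maximum.
#' @param growth_radius Region growth radius in pixels (default 5).
#' @param size_cutoff_factor Regions with area below this fraction of the
#'   median region area are discarded (default 0.1). Interpreted as a
#'   relative-area filter: the reference quantity for the cutoff is the median
#'   segmented area.
#' @param spillover_alpha Neighbor-subtraction weight in `[0, 1]` used by
#'   [compensate_spillover()].
#' @param seed_floor_frac Per-seed intensity floor as a fraction of the seed
#'   peak; pixels below it are not claimed by that seed (default 0.1).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(smoothing_sigma = 1.5,
                                maxima_min_distance = 3L,
                                maxima_min_intensity = 0.1,
                                growth_radius = 5L,
                                size_cutoff_factor = 0.1,
                                spillover_alpha = 0.25,
                                seed_floor_frac = 0.1) {
  if (growth_radius < 1) spl_config_error("growth_radius must be >= 1")
  if (size_cutoff_factor < 0 || size_cutoff_factor >= 1)
    spl_config_error("size_cutoff_factor must be in [0, 1)")
  if (spillover_alpha < 0 || spillover_alpha > 1)
    spl_config_error("spillover_alpha must be in [0, 1]")
  structure(list(smoothing_sigma = smoothing_sigma,
                 maxima_min_distance = as.integer(maxima_min_distance),
                 maxima_min_intensity = maxima_min_intensity,
                 growth_radius = as.integer(growth_radius),
                 size_cutoff_factor = size_cutoff_factor,
                 spillover_alpha = spillover_alpha,
                 seed_floor_frac = seed_floor_frac),
            class = "segmentation_params")
}

# separable Gaussian smoothing by shift-and-add with -replicate- edges
smooth_gaussian <- function(m, sigma) {
  if (is.null(sigma) || sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  w <- dnorm(-r:r, sd = sigma); w <- w / sum(w)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (k in -r:r) {
    idx <- pmin(pmax(seq_len(H) + k, 1L), H)
    out <- out + w[k + r + 1L] * m[idx, , drop = FALSE]
  }
  m2 <- out; out <- matrix(0, H, W)
  for (k in -r:r) {
    idx <- pmin(pmax(seq_len(W) + k, 1L), W)
    out <- out + w[k + r + 1L] * m2[, idx, drop = FALSE]
  }
  out
}

# matrix shifted by (dy, dx), vacated cells filled with `fill`
shift_matrix <- function(m, dy, dx, fill = -Inf) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1L, 1L + dy):min(H, H + dy)
  cs <- max(1L, 1L + dx):min(W, W + dx)
  out[rs, cs] <- m[rs - dy, cs - dx, drop = FALSE]
  out
}

# integer offsets inside a Euclidean disc of radius r (optionally w/o origin)
disc_offsets <- function(r, include_origin = FALSE) {
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
  if (!include_origin) g <- g[!(g$dx == 0 & g$dy == 0), , drop = FALSE]
  g
}

#' Detect nuclear seeds as smoothed local intensity maxima
#'
#' A seed is a pixel of the Gaussian-smoothed nuclear channel that is a
#' strict maximum over the Euclidean disc of radius `maxima_min_distance`
#' and exceeds `maxima_min_intensity` times the smoothed channel maximum.
#' Seeds come back sorted by descending intensity, ties broken row-major.
#'
#' @param nuclear Numeric matrix (nuclear channel).
#' @param params A [segmentation_params()].
#' @return data.frame with columns `row`, `col`, `value`; zero rows when the
#'   raster is flat or all-zero.
#' @export
detect_maxima <- function(nuclear, params = segmentation_params()) {
  if (!is.matrix(nuclear) || !length(nuclear))
    spl_data_error("nuclear channel must be a non-empty matrix")
  sm <- smooth_gaussian(nuclear, params$smoothing_sigma)
  mx <- max(sm)
  if (mx <= 0) return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  off <- disc_offsets(params$maxima_min_distance)
  neigh <- matrix(-Inf, nrow(sm), ncol(sm))
  for (k in seq_len(nrow(off)))
    neigh <- pmax(neigh, shift_matrix(sm, off$dy[k], off$dx[k]))
  keep <- which(sm > neigh & sm >= params$maxima_min_intensity * mx)
  if (!length(keep)) return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  rows <- ((keep - 1L) %% nrow(sm)) + 1L
  cols <- ((keep - 1L) %/% nrow(sm)) + 1L
  vals <- sm[keep]
  ord <- order(-vals, rows, cols)
  data.frame(row = rows[ord], col = cols[ord], value = vals[ord])
}

# keep only the 4-connected component of `pix` (n x 2, row/col) containing
# `seed_rc`; returns logical keep vector
connected_to_seed <- function(pix, seed_rc) {
  key <- pix[, 1] * 1e6 + pix[, 2]
  idx <- match(seed_rc[1] * 1e6 + seed_rc[2], key)
  keep <- rep(FALSE, nrow(pix))
  if (is.na(idx)) return(keep)
  queue <- idx; keep[idx] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- match((pix[cur, 1] + d[1]) * 1e6 + (pix[cur, 2] + d[2]), key)
      if (!is.na(nb) && !keep[nb]) { keep[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  keep
}

#' Grow labeled regions around seeds
#'
#' Each pixel within `growth_radius` (Euclidean, in pixels) of at least one
#' seed and above that seed's intensity floor (`seed_floor_frac` x seed peak
#' on the smoothed raster) is assigned to its nearest seed; distance ties go
#' to the higher-intensity seed, then the lower label. Regions are pruned to
#' the 4-connected component containing their seed, and regions with area
#' below `size_cutoff_factor` times the median region area are removed with
#' labels recompacted.
#'
#' @param nuclear Numeric matrix (nuclear channel).
#' @param seeds data.frame from [detect_maxima()] (columns `row`, `col`).
#' @param params A [segmentation_params()].
#' @return A `label_mask`: list with the integer `mask` matrix (0 =
#'   background) and the retained `seeds` data.frame.
#' @export
grow_regions <- function(nuclear, seeds, params = segmentation_params()) {
  H <- nrow(nuclear); W <- ncol(nuclear)
  mask <- matrix(0L, H, W)
  if (is.null(seeds) || nrow(seeds) == 0L)
    return(structure(list(mask = mask, seeds = seeds), class = "label_mask"))
  sm <- smooth_gaussian(nuclear, params$smoothing_sigma)
  off <- disc_offsets(params$growth_radius, include_origin = TRUE)
  ns <- nrow(seeds)
  seedval <- sm[cbind(seeds$row, seeds$col)]

  cand <- data.table(
    seed_id = rep(seq_len(ns), each = nrow(off)),
    row = rep(seeds$row, each = nrow(off)) + rep(off$dy, times = ns),
    col = rep(seeds$col, each = nrow(off)) + rep(off$dx, times = ns),
    d2 = rep(off$dx^2 + off$dy^2, times = ns)
  )
  cand <- cand[row >= 1L & row <= H & col >= 1L & col <= W]
  cand[, seedval := seedval[seed_id]]
  cand <- cand[sm[cbind(row, col)] >= params$seed_floor_frac * seedval]
  if (nrow(cand) == 0L)
    return(structure(list(mask = mask, seeds = seeds[0, ]), class = "label_mask"))
  setorder(cand, d2, -seedval, seed_id)
  cand <- cand[!duplicated(cand[, .(row, col)])]

  # prune to the 4-connected component containing each seed
  keep_rows <- logical(nrow(cand))
  cand_split <- split(seq_len(nrow(cand)), cand$seed_id)
  for (s in names(cand_split)) {
    idx <- cand_split[[s]]
    pix <- as.matrix(cand[idx, .(row, col)])
    sid <- as.integer(s)
    keep_rows[idx] <- connected_to_seed(pix, c(seeds$row[sid], seeds$col[sid]))
  }
  cand <- cand[keep_rows]

  areas <- table(factor(cand$seed_id, levels = seq_len(ns)))
  present <- as.integer(names(areas))[areas > 0]
  med <- median(as.numeric(areas[areas > 0]))
  keep_seeds <- present[as.numeric(areas[as.character(present)]) >=
                          params$size_cutoff_factor * med]
  cand <- cand[seed_id %in% keep_seeds]
  relabel <- integer(ns); relabel[sort(keep_seeds)] <- seq_along(keep_seeds)
  mask[as.matrix(cand[, .(row, col)])] <- relabel[cand$seed_id]
  kept <- seeds[sort(keep_seeds), , drop = FALSE]
  kept$label <- seq_len(nrow(kept))
  structure(list(mask = mask, seeds = kept), class = "label_mask")
}

#' Quantify per-cell marker intensities from a label mask
#'
#' One record per label: centroid (mean of member-pixel centers) converted to
#' microns, per-channel mean intensity over the region, and area in square
#' microns.
#'
#' @param mask A `label_mask` from [grow_regions()] (or a bare integer matrix).
#' @param image An [image_grid()] with the same raster shape.
#' @param roi_id,case_id,group Metadata stamped on the resulting rows.
#' @return A `cell_table` with an extra `label` column and `area_um2`.
#' @export
quantify_cells <- function(mask, image, roi_id = "roi1", case_id = "case1",
                           group = NA_character_) {
  m <- if (inherits(mask, "label_mask")) mask$mask else mask
  ps <- image$pixel_size
  ref <- image$channels[[1]]
  if (!all(dim(m) == dim(ref)))
    spl_data_error("mask (%dx%d) and image (%dx%d) shapes disagree",
                   nrow(m), ncol(m), nrow(ref), ncol(ref))
  idx <- which(m > 0L)
  if (!length(idx)) spl_data_error("label mask contains no regions")
  dt <- data.table(
    label = m[idx],
    row = ((idx - 1L) %% nrow(m)) + 1L,
    col = ((idx - 1L) %/% nrow(m)) + 1L
  )
  for (ch in names(image$channels))
    dt[, (ch) := image$channels[[ch]][cbind(row, col)]]
  agg <- dt[, c(list(x_um = mean((col - 0.5) * ps),
                     y_um = mean((row - 0.5) * ps),
                     area_um2 = .N * ps^2),
                lapply(.SD, mean)),
            by = label, .SDcols = names(image$channels)]
  setorder(agg, label)
  agg[, `:=`(cell_id = sprintf("%s_seg%04d", roi_id, label),
             roi_id = roi_id, case_id = case_id, group = group)]
  markers <- setdiff(names(image$channels), "nuclear")
  as_cell_table(agg, markers = markers,
                bbox = c(0, ncol(m) * ps, 0, nrow(m) * ps))
}

# unordered label adjacency under 1-pixel dilation (8-neighborhood contact)
mask_adjacency <- function(m) {
  pairs <- list()
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (d in offs) {
    sh <- shift_matrix(m, d[1], d[2], fill = 0L)
    sel <- m > 0L & sh > 0L & m != sh
    if (any(sel)) pairs[[length(pairs) + 1L]] <-
        data.table(a = pmin(m[sel], sh[sel]), b = pmax(m[sel], sh[sel]))
  }
  if (!length(pairs)) return(data.table(a = integer(0), b = integer(0)))
  unique(rbindlist(pairs))
}

#' Compensate marker spillover from mask-adjacent neighbor cells
#'
#' For every cell and marker, `corrected = max(0, raw - alpha * mean(raw of
#' mask-adjacent neighbors))`, all corrections computed from the uncorrected
#' values. Cells without adjacent neighbors are unchanged; `alpha = 0` is the
#' identity.
#'
#' @param cells A `cell_table` from [quantify_cells()] (must carry `label`).
#' @param mask The `label_mask` the cells were quantified from.
#' @param alpha Spillover weight in `[0, 1]`.
#' @return The corrected `cell_table`.
#' @export
compensate_spillover <- function(cells, mask, alpha = 0.25) {
  if (alpha < 0 || alpha > 1) spl_config_error("alpha must be in [0, 1]")
  m <- if (inherits(mask, "label_mask")) mask$mask else mask
  if (!"label" %in% names(cells))
    spl_data_error("cells must carry a 'label' column matching the mask")
  if (alpha == 0) return(cells)
  adj <- mask_adjacency(m)
  if (!nrow(adj)) return(cells)
  nb <- rbind(adj, adj[, .(a = b, b = a)])   # directed neighbor list
  out <- copy(as.data.table(cells))
  markers <- cell_markers(cells)
  lab_idx <- match(nb$b, out$label)
  for (mk in markers) {
    nb_mean <- tapply(out[[mk]][lab_idx], nb$a, mean)
    corr <- rep(0, nrow(out))
    hit <- match(out$label, as.integer(names(nb_mean)))
    corr[!is.na(hit)] <- nb_mean[hit[!is.na(hit)]]
    out[, (mk) := pmax(get(mk) - alpha * corr, 0)]
  }
  as_cell_table(out, markers = markers, bbox = attr(cells, "bbox"))
}

#' Read / write a label mask as plain-text CSV
#' @param mask A `label_mask` or integer matrix.
#' @param path File path.
#' @return `read_label_mask`: a `label_mask` (seed table absent).
#' @export
write_label_mask <- function(mask, path) {
  m <- if (inherits(mask, "label_mask")) mask$mask else mask
  write_raster_csv(m, path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- read_raster_csv(path)
  storage.mode(m) <- "integer"
  structure(list(mask = m, seeds = NULL), class = "label_mask")
}
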