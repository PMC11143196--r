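# synthetic tissue generator: point placement, labels, intensities, nuclei

# all pairs (i over `a`, j over `b`) closer than `s`, found by binning into an
# s-sized grid and joining 3x3 bin neighborhoods; avoids the O(n^2) scan
close_pairs <- function(a, b, s, self = FALSE) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.table(i = integer(0), j = integer(0)))
  da <- data.table(i = seq_len(nrow(a)), x = a[, 1], y = a[, 2])
  da[, `:=`(bx = floor(x / s), by = floor(y / s))]
  db <- data.table(j = seq_len(nrow(b)), x2 = b[, 1], y2 = b[, 2])
  db[, `:=`(bx0 = floor(x2 / s), by0 = floor(y2 / s))]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  db9 <- rbindlist(lapply(seq_len(nrow(off)), function(k) {
    data.table(j = db$j, x2 = db$x2, y2 = db$y2,
               bx = db$bx0 + off[k, 1], by = db$by0 + off[k, 2])
  }))
  setkey(db9, bx, by)
  p <- db9[da, on = c("bx", "by"), nomatch = 0L, allow.cartesian = TRUE]
  if (nrow(p) == 0L) return(data.table(i = integer(0), j = integer(0)))
  p <- p[(x - x2)^2 + (y - y2)^2 < s^2]
  if (self) p <- p[i != j]
  p[, .(i, j)]
}

# dart-throwing with batch rejection: propose points, drop those conflicting
# with already-accepted points or with an earlier point in the same batch
place_points <- function(n, propose, existing = NULL, min_spacing = 4,
                         max_rounds = 80L) {
  acc <- matrix(numeric(0), 0L, 2L)
  if (n == 0L) return(acc)
  for (round in seq_len(max_rounds)) {
    need <- n - nrow(acc)
    if (need <= 0L) break
    cand <- propose(max(2L * need, 32L))
    if (!is.matrix(cand) || nrow(cand) == 0L) next
    if (min_spacing > 0) {
      ref <- rbind(existing, acc)
      if (!is.null(ref) && nrow(ref) > 0L) {
        bad <- unique(close_pairs(cand, ref, min_spacing)$i)
        if (length(bad)) cand <- cand[-bad, , drop = FALSE]
      }
      if (nrow(cand) > 1L) {
        cp <- close_pairs(cand, cand, min_spacing, self = TRUE)
        drop <- unique(cp[j > i, j])  # keep the earlier proposal of each pair
        if (length(drop)) cand <- cand[-drop, , drop = FALSE]
      }
    }
    if (nrow(cand) > need) cand <- cand[seq_len(need), , drop = FALSE]
    acc <- rbind(acc, cand)
  }
  if (nrow(acc) < n)
    spl_config_error(paste0(
      "infeasible packing: placed %d of %d cells at min_spacing %.1f um; ",
      "reduce n_cells or enlarge the ROI"), nrow(acc), n, min_spacing)
  acc
}

# architecture-specific uniform proposers
make_proposer <- function(cfg, inset = 0) {
  W <- cfg$roi_size[1]; H <- cfg$roi_size[2]
  if (cfg$architecture == "diffuse") {
    function(m) cbind(runif(m, inset, W - inset), runif(m, inset, H - inset))
  } else {
    r <- min(cfg$nodule_radius, (min(W, H) - 2 * inset) / 2 - 1e-6)
    centers <- cbind(runif(cfg$nodule_count, r + inset, W - r - inset),
                     runif(cfg$nodule_count, r + inset, H - r - inset))
    function(m) {
      in_bg <- runif(m) < cfg$background_frac
      k <- sample.int(nrow(centers), m, replace = TRUE)
      rad <- r * sqrt(runif(m)); th <- runif(m, 0, 2 * pi)
      p <- cbind(centers[k, 1] + rad * cos(th), centers[k, 2] + rad * sin(th))
      nb <- sum(in_bg)
      if (nb) p[in_bg, ] <- cbind(runif(nb, inset, W - inset), runif(nb, inset, H - inset))
      p
    }
  }
}

# place rosette TFH cells: every LP anchor gets `per` cells uniformly in the
# [r_lo, r_hi] annulus, respecting the global spacing constraint
place_rosettes <- function(anchors, per, annulus, cfg, existing,
                           max_rounds = 200L) {
  W <- cfg$roi_size[1]; H <- cfg$roi_size[2]
  n_lp <- nrow(anchors)
  slots <- rep(seq_len(n_lp), each = per)
  placed <- matrix(NA_real_, length(slots), 2L)
  done <- rep(FALSE, length(slots))
  acc <- existing
  for (round in seq_len(max_rounds)) {
    todo <- which(!done)
    if (!length(todo)) break
    r <- sqrt(runif(length(todo), annulus[1]^2, annulus[2]^2))
    th <- runif(length(todo), 0, 2 * pi)
    cand <- cbind(anchors[slots[todo], 1] + r * cos(th),
                  anchors[slots[todo], 2] + r * sin(th))
    ok <- cand[, 1] >= 0 & cand[, 1] <= W & cand[, 2] >= 0 & cand[, 2] <= H
    if (cfg$min_spacing > 0 && any(ok)) {
      bad <- unique(close_pairs(cand, acc, cfg$min_spacing)$i)
      ok[bad] <- FALSE
      cp <- close_pairs(cand, cand, cfg$min_spacing, self = TRUE)
      if (nrow(cp)) ok[unique(cp[, pmax(i, j)])] <- FALSE
    }
    keep <- todo[ok]
    if (length(keep)) {
      placed[keep, ] <- cand[ok, , drop = FALSE]
      done[keep] <- TRUE
      acc <- rbind(acc, cand[ok, , drop = FALSE])
    }
  }
  if (any(!done))
    spl_config_error("could not place all rosette TFH cells (%d slots unfilled)",
                     sum(!done))
  list(points = placed, slot_anchor = slots)
}

# star-shaped noisy ellipse polygons, vectorized over cells; radii are scaled
# so the expected polygon area matches the drawn nuclear area
make_nucleus_polygons <- function(centers, areas, k = 14L) {
  n <- nrow(centers)
  th0 <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  r_base <- sqrt(2 * areas / (k * sin(2 * pi / k)))      # exact-area regular k-gon
  ecc <- runif(n, 0.75, 1)                                # axis ratio b/a
  phi <- runif(n, 0, pi)
  noise <- matrix(1 + runif(n * k, -0.12, 0.12), n, k)
  th <- matrix(th0, n, k, byrow = TRUE)
  ax <- (r_base / sqrt(ecc)) * cos(th) * noise
  ay <- (r_base * sqrt(ecc)) * sin(th) * noise
  xr <- ax * cos(phi) - ay * sin(phi) + centers[, 1]
  yr <- ax * sin(phi) + ay * cos(phi) + centers[, 2]
  data.table(
    cell_id = rep(seq_len(n), each = k),
    vertex = rep(seq_len(k), times = n),
    x_um = as.vector(t(xr)), y_um = as.vector(t(yr))
  )
}

#' Simulate one synthetic ROI with ground truth
#'
#' Draws population labels from the configured composition (exact multinomial
#' counts), places cells as a nodular or diffuse point pattern under a hard
#' minimum-spacing constraint, optionally plants TFH rosettes around every
#' tumor-B (LP) cell, draws marker intensities from the two-component
#' log-normal model, and generates nucleus polygons. Deterministic given
#' `(config$seed, roi_index)`.
#'
#' @param config A [tissue_config()].
#' @param roi_id,case_id Identifiers stamped on the cells.
#' @param roi_index Integer stream index so multiple ROIs from one config get
#'   independent, reproducible randomness.
#' @return `list(cells = <cell_table>, truth = <ground_truth>)`. The truth
#'   object carries per-cell `labels`, the nucleus `polygons`
#'   (cell_id/vertex/x_um/y_um table, or `NULL`), the realized `composition`,
#'   and `rosettes` (lp/tfh cell-id pairs).
#' @export
simulate_tissue <- function(config, roi_id = "roi1", case_id = "case1",
                            roi_index = 1L) {
  cfg <- validate_tissue_config(config)
  with_seed(derive_seed(cfg$seed, "tissue", roi_index), {
    pops <- names(cfg$composition)
    counts <- drop(rmultinom(1L, cfg$n_cells, cfg$composition))
    n <- sum(counts)

    rosettes_on <- !is.null(cfg$rosette_spec) && counts[["tumor_b"]] > 0L
    n_lp <- if ("tumor_b" %in% pops) counts[["tumor_b"]] else 0L
    per <- if (rosettes_on) cfg$rosette_spec$tfh_per_lp else 0L
    if (rosettes_on && counts[["tfh"]] < n_lp * per)
      spl_config_error(
        "rosette spec needs %d TFH cells but composition yields only %d",
        n_lp * per, counts[["tfh"]])

    labels <- character(n)
    coords <- matrix(NA_real_, n, 2L)
    idx_next <- 1L
    take <- function(k) {
      out <- seq.int(idx_next, length.out = k); idx_next <<- idx_next + k; out
    }

    rosette_dt <- data.table(lp = integer(0), tfh = integer(0))
    if (rosettes_on) {
      ann_hi <- cfg$rosette_spec$rosette_annulus[2]
      lp_prop <- make_proposer(cfg, inset = ann_hi + 0.5)
      lp_idx <- take(n_lp)
      coords[lp_idx, ] <- place_points(n_lp, lp_prop, min_spacing = cfg$min_spacing)
      labels[lp_idx] <- "tumor_b"
      ros <- place_rosettes(coords[lp_idx, , drop = FALSE], per,
                            cfg$rosette_spec$rosette_annulus, cfg,
                            existing = coords[lp_idx, , drop = FALSE])
      tfh_idx <- take(n_lp * per)
      coords[tfh_idx, ] <- ros$points
      labels[tfh_idx] <- "tfh"
      rosette_dt <- data.table(lp = lp_idx[ros$slot_anchor], tfh = tfh_idx)
      counts[["tumor_b"]] <- 0L
      counts[["tfh"]] <- counts[["tfh"]] - n_lp * per
    }

    n_rest <- n - idx_next + 1L
    if (n_rest > 0L) {
      rest_idx <- take(n_rest)
      prop <- make_proposer(cfg)
      coords[rest_idx, ] <- place_points(
        n_rest, prop, existing = coords[seq_len(rest_idx[1] - 1L), , drop = FALSE],
        min_spacing = cfg$min_spacing)
      labels[rest_idx] <- sample(rep(pops, counts))
    }

    # marker intensities: log-normal positive/negative components
    im <- cfg$intensity_model
    markers <- codex_markers()
    intens <- matrix(NA_real_, n, length(markers), dimnames = list(NULL, markers))
    pos_sets <- im$positive_sets
    for (m in markers) {
      pos <- vapply(pos_sets[labels], function(s) m %in% s, logical(1))
      intens[, m] <- rlnorm(n,
        meanlog = ifelse(pos, im$pos[["meanlog"]], im$neg[["meanlog"]]),
        sdlog = ifelse(pos, im$pos[["sdlog"]], im$neg[["sdlog"]]))
    }

    polygons <- NULL
    if (cfg$polygons) {
      nsm <- cfg$nuclear_size_model
      mu <- vapply(nsm[labels], `[[`, numeric(1), "mean")
      sg <- vapply(nsm[labels], `[[`, numeric(1), "sd")
      areas <- pmax(rnorm(n, mu, sg), 4)
      polygons <- make_nucleus_polygons(coords, areas)
    }

    ids <- sprintf("%s_c%05d", roi_id, seq_len(n))
    cells <- data.table(
      cell_id = ids, roi_id = roi_id, case_id = case_id,
      group = cfg$group, x_um = coords[, 1], y_um = coords[, 2])
    cells <- cbind(cells, as.data.table(intens))
    cells <- as_cell_table(cells, markers = markers,
                           bbox = c(0, cfg$roi_size[1], 0, cfg$roi_size[2]))

    if (!is.null(polygons)) polygons[, cell_id := ids[cell_id]]
    truth <- structure(list(
      labels = setNames(labels, ids),
      polygons = polygons,
      composition = table(factor(labels, levels = pops)) / n,
      rosettes = data.table(lp = ids[rosette_dt$lp], tfh = ids[rosette_dt$tfh])
    ), class = "ground_truth")

    list(cells = cells, truth = truth)
  })
}

#' Simulate a multi-case, multi-ROI cohort
#'
#' Convenience wrapper producing one combined cell table across groups, cases
#' and ROIs, with per-ROI ground truths. Matches the study design shape:
#' cases per group, several ROIs per case.
#'
#' @param groups Character vector of preset names (see [make_group_presets()]).
#' @param cases_per_group Named or unnamed integer vector, recycled to `groups`.
#' @param rois_per_case Number of ROIs per case.
#' @param n_cells Cells per ROI.
#' @param seed Global seed.
#' @param polygons Generate nucleus polygons.
#' @return `list(cells = <cell_table>, truths = <named list of ground_truth>)`.
#' @export
simulate_cohort <- function(groups = c("group1", "group2", "group3", "thrlbcl"),
                            cases_per_group = 2L, rois_per_case = 2L,
                            n_cells = 800L, seed = 1L, polygons = FALSE) {
  cases_per_group <- rep_len(cases_per_group, length(groups))
  all_cells <- list(); truths <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    for (ci in seq_len(cases_per_group[gi])) {
      case_id <- sprintf("%s_case%02d", g, ci)
      for (ri in seq_len(rois_per_case)) {
        roi_id <- sprintf("%s_roi%d", case_id, ri)
        cfg <- make_group_presets(g, n_cells = n_cells,
                                  seed = derive_seed(seed, g, ci), polygons = polygons)
        sim <- simulate_tissue(cfg, roi_id = roi_id, case_id = case_id, roi_index = ri)
        all_cells[[roi_id]] <- sim$cells
        truths[[roi_id]] <- sim$truth
      }
    }
  }
  cells <- rbindlist(all_cells)
  cells <- as_cell_table(cells, markers = codex_markers())
  list(cells = cells, truths = truths)
}
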