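# rendering synthetic cells into multichannel rasters

#' Construct an image grid
#'
#' A named list of equally-shaped nonnegative 2-D rasters plus the pixel
#' size. Convention: matrices are indexed `[row, col]` with the origin at the
#' top-left and y increasing downward; the pixel `(r, c)` center sits at
#' `((c - 0.5) * pixel_size, (r - 0.5) * pixel_size)` in microns.
#'
#' @param channels Named list of numeric matrices, all the same dimension.
#' @param pixel_size Microns per pixel, positive scalar.
#' @return An `image_grid`.
#' @export
image_grid <- function(channels, pixel_size) {
  if (!length(channels) || is.null(names(channels)))
    spl_data_error("channels must be a non-empty named list of matrices")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    spl_data_error("all channels must share the same dimensions")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    spl_data_error("pixel_size must be positive")
  structure(list(channels = channels, pixel_size = as.numeric(pixel_size),
                 channel_names = names(channels)),
            class = "image_grid")
}

# logical raster of pixels whose centers fall inside a polygon (even-odd rule)
rasterize_polygon <- function(poly, nrow, ncol, pixel_size) {
  xs <- poly[, 1]; ys <- poly[, 2]
  cmin <- max(1L, floor(min(xs) / pixel_size)); cmax <- min(ncol, ceiling(max(xs) / pixel_size))
  rmin <- max(1L, floor(min(ys) / pixel_size)); rmax <- min(nrow, ceiling(max(ys) / pixel_size))
  if (cmin > cmax || rmin > rmax) return(NULL)
  cols <- cmin:cmax; rows <- rmin:rmax
  px <- (rep(cols, each = length(rows)) - 0.5) * pixel_size
  py <- (rep(rows, times = length(cols)) - 0.5) * pixel_size
  inside <- rep(FALSE, length(px))
  k <- length(xs)
  jj <- k
  for (ii in seq_len(k)) {
    xi <- xs[ii]; yi <- ys[ii]; xj <- xs[jj]; yj <- ys[jj]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    jj <- ii
  }
  if (!any(inside)) return(NULL)
  cbind(row = rep(rows, times = length(cols))[inside],
        col = rep(cols, each = length(rows))[inside])
}

#' Render synthetic cells into a multichannel image
#'
#' Produces the raster surrogate of a processed multiplex acquisition: a
#' `nuclear` channel that is a sum of per-nucleus Gaussian blobs (each blob
#' integrates to its polygon area, so isolated nuclei share a common peak
#' height), plus one channel per marker in which each cell's intensity is
#' painted over its rasterized nucleus polygon, with optional additive
#' Gaussian noise.
#'
#' @param cells A `cell_table`.
#' @param truth The matching `ground_truth` (supplies nucleus polygons).
#' @param pixel_size Microns per pixel.
#' @param noise_sd Additive Gaussian noise SD on marker channels (and the
#'   nuclear channel), in intensity units.
#' @param markers Markers to render (default: all in `cells`).
#' @param seed Seed for the noise draw.
#' @return An [image_grid()] whose first channel is `"nuclear"`.
#' @export
render_image <- function(cells, truth, pixel_size = 1, noise_sd = 0.01,
                         markers = NULL, seed = 1L) {
  if (nrow(cells) == 0L) spl_data_error("cannot render an empty cell table")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    spl_config_error("pixel_size must be positive")
  if (is.null(truth$polygons))
    spl_data_error("ground truth carries no polygons; simulate with polygons = TRUE")
  markers <- markers %||% cell_markers(cells)
  bbox <- cell_bbox(cells)
  W <- bbox[2]; H <- bbox[4]
  ncol <- as.integer(round(W / pixel_size)); nrow <- as.integer(round(H / pixel_size))
  polys <- split(as.data.frame(truth$polygons[, .(x_um, y_um)]),
                 factor(truth$polygons$cell_id, levels = cells$cell_id))

  with_seed(seed, {
    nuclear <- matrix(0, nrow, ncol)
    masks <- vector("list", nrow(cells))
    for (k in seq_len(nrow(cells))) {
      poly <- as.matrix(polys[[cells$cell_id[k]]])
      a <- abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                     c(poly[-1, 1], poly[1, 1]) * poly[, 2])) / 2
      sig <- sqrt(a / (2 * pi))           # blob integrates to polygon area
      sig_px <- sig / pixel_size
      cx <- cells$x_um[k] / pixel_size; cy <- cells$y_um[k] / pixel_size
      rr <- max(2L, ceiling(4 * sig_px))
      cset <- max(1L, floor(cx - rr)):min(ncol, ceiling(cx + rr))
      rset <- max(1L, floor(cy - rr)):min(nrow, ceiling(cy + rr))
      if (length(cset) && length(rset)) {
        dx2 <- ((cset - 0.5) - cx)^2
        dy2 <- ((rset - 0.5) - cy)^2
        blob <- exp(-(outer(dy2, dx2, `+`)) / (2 * sig_px^2))
        nuclear[rset, cset] <- nuclear[rset, cset] + blob
      }
      masks[[k]] <- rasterize_polygon(poly, nrow, ncol, pixel_size)
    }
    channels <- list(nuclear = nuclear)
    for (m in markers) {
      ch <- matrix(0, nrow, ncol)
      for (k in seq_len(nrow(cells))) {
        if (!is.null(masks[[k]])) ch[masks[[k]]] <- cells[[m]][k]
      }
      if (noise_sd > 0) ch <- pmax(ch + matrix(rnorm(nrow * ncol, 0, noise_sd), nrow), 0)
      channels[[m]] <- ch
    }
    if (noise_sd > 0)
      channels$nuclear <- pmax(channels$nuclear +
                                 matrix(rnorm(nrow * ncol, 0, noise_sd), nrow), 0)
    image_grid(channels, pixel_size)
  })
}

#' Read / write a single raster channel as plain-text CSV
#'
#' Offline-friendly stand-in for TIFF export: one numeric matrix per file.
#' @param m Numeric matrix (for writing).
#' @param path File path.
#' @return `read_raster_csv`: a numeric matrix.
#' @export
write_raster_csv <- function(m, path) {
  fwrite(as.data.table(m), path, col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  as.matrix(fread(path, header = FALSE))
}
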