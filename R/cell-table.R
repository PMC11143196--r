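# the CellTable container: one row per cell, centroid in microns, one column
# per marker, plus roi/case/group identifiers

CELL_TABLE_REQUIRED <- c("cell_id", "roi_id", "case_id", "group", "x_um", "y_um")

#' Coerce a data frame to a cell table
#'
#' @param x A data.frame/data.table with the mandatory columns `cell_id`,
#'   `roi_id`, `case_id`, `group`, `x_um`, `y_um` and one numeric column per
#'   marker.
#' @param markers Character vector of marker column names; if `NULL`, every
#'   numeric column not in the mandatory set (and not a derived `*_pos` /
#'   `phenotype` / `label` / `area_um2` column) is taken as a marker.
#' @param bbox Optional ROI bounds `c(xmin, xmax, ymin, ymax)` in microns.
#' @return A `cell_table` (a data.table subclass carrying `markers` and
#'   `bbox` attributes).
#' @export
as_cell_table <- function(x, markers = NULL, bbox = NULL) {
  x <- as.data.table(x)
  miss <- setdiff(CELL_TABLE_REQUIRED, names(x))
  if (length(miss))
    spl_data_error("cell table is missing mandatory column(s): %s",
                   paste(miss, collapse = ", "))
  # an all-NA identifier column reads back from CSV as logical; keep it typed
  for (cc in c("cell_id", "roi_id", "case_id", "group")) {
    if (is.logical(x[[cc]]) && all(is.na(x[[cc]])))
      x[[cc]] <- NA_character_
  }
  for (cc in c("x_um", "y_um")) {
    v <- x[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      spl_data_error("non-numeric coordinate in column '%s' at row %d", cc,
                     if (is.na(bad)) 1L else bad)
    }
  }
  if (is.null(markers)) {
    skip <- c(CELL_TABLE_REQUIRED, "phenotype", "label", "area_um2", "core_id")
    cand <- setdiff(names(x), skip)
    cand <- cand[!grepl("_pos$", cand)]
    markers <- cand[vapply(x[, cand, with = FALSE], is.numeric, logical(1))]
  }
  setattr(x, "markers", markers)
  if (!is.null(bbox)) setattr(x, "bbox", as.numeric(bbox))
  setattr(x, "class", unique(c("cell_table", class(x))))
  x
}

#' Marker columns of a cell table
#' @param x A `cell_table`.
#' @return Character vector of marker names.
#' @export
cell_markers <- function(x) {
  attr(x, "markers") %||% intersect(codex_markers(), names(x))
}

#' ROI bounding box of a cell table
#'
#' The recorded bounds if present, otherwise the coordinate range.
#' @param x A `cell_table`.
#' @return `c(xmin, xmax, ymin, ymax)` in microns.
#' @export
cell_bbox <- function(x) {
  attr(x, "bbox") %||% c(min(x$x_um), max(x$x_um), min(x$y_um), max(x$y_um))
}

#' Read / write a cell table (CSV)
#'
#' CSV is the supported on-disk format; the documented schema is
#' `cell_id, roi_id, case_id, group, x_um, y_um, <marker>...`. Unknown extra
#' columns are preserved. Parquet is not supported in this build (no arrow
#' runtime available) and raises an informative error.
#'
#' @param path File path ending in `.csv` (or `.parquet`, rejected).
#' @return `read_cell_table`: a `cell_table`. `write_cell_table`: `path`,
#'   invisibly.
#' @export
read_cell_table <- function(path) {
  if (grepl("\\.parquet$", path, ignore.case = TRUE))
    spl_config_error("Parquet support requires the 'arrow' package, which is not available; use CSV")
  if (!file.exists(path)) spl_data_error("file not found: %s", path)
  as_cell_table(fread(path))
}

#' @rdname read_cell_table
#' @param cells A `cell_table`.
#' @export
write_cell_table <- function(cells, path) {
  if (grepl("\\.parquet$", path, ignore.case = TRUE))
    spl_config_error("Parquet support requires the 'arrow' package, which is not available; use CSV")
  fwrite(as.data.table(cells), path)
  invisible(path)
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d ROI(s), %d marker(s)\n",
              nrow(x), length(unique(x$roi_id)), length(cell_markers(x))))
  NextMethod()
}
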