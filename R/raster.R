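#' Classified land-cover raster
#'
#' The unit of change detection: a grid of integer class codes stamped with
#' an epoch (calendar year) and a per-cell area. Grids are ordinary R integer
#' matrices; `NA` cells (or the scheme's nodata code, which is converted to
#' `NA` on construction) are excluded from all downstream accounting.
#'
#' @param values integer matrix of class codes.
#' @param epoch calendar year of the classification.
#' @param cell_area_ha area of one pixel in hectares (> 0). The study's
#'   Landsat pixels are 30 m, i.e. 0.09 ha.
#' @param scheme a [class_scheme()].
#' @return an object of class `lc_raster`.
#' @examples
#' m <- matrix(c(1L, 1L, 1L, 3L), 2, 2)
#' r <- lc_raster(m, epoch = 2000, cell_area_ha = 1, scheme = default_scheme())
#' forest_area(r)
#' @export
lc_raster <- function(values, epoch, cell_area_ha = 0.09,
                      scheme = default_scheme()) {
  if (!is.matrix(values)) stopf("values must be a matrix of class codes")
  storage.mode(values) <- "integer"
  if (!is.na(scheme$nodata_code)) {
    values[values == scheme$nodata_code] <- NA_integer_
  }
  bad <- setdiff(unique(values[!is.na(values)]), scheme$codes)
  if (length(bad) > 0) {
    stopf("raster contains codes outside the scheme: %s",
          paste(bad, collapse = ", "))
  }
  if (!is.numeric(cell_area_ha) || length(cell_area_ha) != 1 || cell_area_ha <= 0) {
    stopf("cell_area_ha must be a single positive number")
  }
  structure(
    list(values = values, epoch = as.numeric(epoch),
         cell_area_ha = as.numeric(cell_area_ha), scheme = scheme),
    class = "lc_raster"
  )
}

#' @export
print.lc_raster <- function(x, ...) {
  cat(sprintf("Land-cover raster %dx%d, epoch %s, cell %.4g ha\n",
              nrow(x$values), ncol(x$values), format(x$epoch), x$cell_area_ha))
  tab <- class_areas(x)
  for (i in seq_along(tab)) {
    if (tab[i] > 0) cat(sprintf("  %-18s %10.2f ha\n", names(tab)[i], tab[i]))
  }
  invisible(x)
}

#' Class areas of a raster
#'
#' @param r an [lc_raster()].
#' @return named numeric vector of area (ha) per scheme class, zero for
#'   classes absent from the grid; nodata cells contribute nothing.
#' @export
class_areas <- function(r) {
  counts <- tabulate(match(r$values, r$scheme$codes), nbins = length(r$scheme$codes))
  stats::setNames(counts * r$cell_area_ha, r$scheme$labels)
}

#' @describeIn class_areas forest area (ha) of a raster.
#' @export
forest_area <- function(r) {
  unname(class_areas(r)[r$scheme$forest_label])
}

#' Read and write text-grid rasters
#'
#' Rasters are exchanged as whitespace-delimited integer grids alongside a
#' JSON sidecar (same path with extension `.json`) holding the epoch, cell
#' area, nodata code, and scheme. This keeps classified maps diffable and
#' free of geospatial binary formats; grids must already be co-registered.
#'
#' @param r an [lc_raster()] (for writing).
#' @param path grid file path; the sidecar is `<path>.json`.
#' @return `read_lc_raster()` returns an [lc_raster()];
#'   `write_lc_raster()` returns `path` invisibly.
#' @export
write_lc_raster <- function(r, path) {
  vals <- r$values
  nodata <- if (is.na(r$scheme$nodata_code)) -9999L else r$scheme$nodata_code
  vals[is.na(vals)] <- nodata
  lines <- apply(vals, 1L, paste, collapse = " ")
  writeLines(lines, path)
  sidecar <- list(
    epoch = r$epoch,
    cell_area_ha = r$cell_area_ha,
    nodata = nodata,
    scheme = list(labels = r$scheme$labels, codes = r$scheme$codes,
                  forest_label = r$scheme$forest_label)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lc_raster
#' @export
read_lc_raster <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stopf("missing sidecar %s", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(vals) <- NULL
  storage.mode(vals) <- "integer"
  vals[vals == meta$nodata] <- NA_integer_
  scheme <- class_scheme(meta$scheme$labels, meta$scheme$codes,
                         forest_label = meta$scheme$forest_label)
  lc_raster(vals, epoch = meta$epoch, cell_area_ha = meta$cell_area_ha,
            scheme = scheme)
}
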