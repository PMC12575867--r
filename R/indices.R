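#' Multi-band reflectance stack
#'
#' Per-pixel surface reflectance for the five bands used by the spectral
#' indices. Reflectances are nominally in [0, 1]; values outside that range
#' are accepted with a warning because sensor scaling conventions vary.
#' Cells that are `NA` in any supplied band are treated as nodata.
#'
#' @param bands named list of numeric matrices; recognised names are
#'   `Blue`, `Green`, `Red`, `NIR`, `SWIR`. All matrices must share a shape.
#'   Only the bands an index needs have to be present.
#' @param epoch calendar year label.
#' @return an object of class `spectral_stack`.
#' @export
spectral_stack <- function(bands, epoch = NA_real_) {
  known <- c("Blue", "Green", "Red", "NIR", "SWIR")
  if (is.null(names(bands)) || !all(names(bands) %in% known)) {
    stopf("bands must be a named list drawn from: %s", paste(known, collapse = ", "))
  }
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1) stopf("all band grids must share the same shape")
  if (any(vapply(bands, function(b) any(b < 0 | b > 1, na.rm = TRUE), logical(1)))) {
    warning("reflectances outside [0, 1] detected; indices computed anyway",
            call. = FALSE)
  }
  structure(list(bands = bands, epoch = as.numeric(epoch)),
            class = "spectral_stack")
}

#' Index formula coefficients
#'
#' Coefficients of the enhanced vegetation index: gain `G`, atmospheric
#' resistance coefficients `C1` and `C2`, and soil adjustment `L`. Defaults
#' are the values in common use (G = 2.5, C1 = 6, C2 = 7.5, L = 1).
#'
#' @param G gain factor.
#' @param C1,C2 atmospheric resistance coefficients.
#' @param L soil adjustment factor.
#' @return a list of class `index_params`.
#' @export
index_params <- function(G = 2.5, C1 = 6, C2 = 7.5, L = 1) {
  structure(list(G = G, C1 = C1, C2 = C2, L = L), class = "index_params")
}

#' Compute a spectral index from a reflectance stack
#'
#' The four indices supported:
#' \describe{
#'   \item{NDBI}{(SWIR - NIR) / (SWIR + NIR), built-up surfaces}
#'   \item{NDVI}{(NIR - Red) / (NIR + Red), green vegetation}
#'   \item{NDWI}{(Green - NIR) / (Green + NIR), open water}
#'   \item{EVI}{G (NIR - Red) / (NIR + C1 Red - C2 Blue + L)}
#' }
#' Normalized-difference outputs lie in [-1, 1] wherever both bands are
#' non-negative and not both zero. Pixels whose denominator is zero (within
#' 1e-12) become `NA` rather than infinities, and nodata in any required
#' band propagates to the output.
#'
#' @param stack a [spectral_stack()].
#' @param which one of `"NDBI"`, `"NDVI"`, `"NDWI"`, `"EVI"`.
#' @param params an [index_params()]; only EVI uses it.
#' @return a numeric matrix the shape of the input bands.
#' @examples
#' s <- spectral_stack(list(NIR = matrix(0.5), Red = matrix(0.1)))
#' compute_index(s, "NDVI")  # 0.666...
#' @export
compute_index <- function(stack, which = c("NDVI", "NDBI", "NDWI", "EVI"),
                          params = index_params()) {
  which <- match.arg(which)
  needed <- switch(which,
    NDBI = c("SWIR", "NIR"),
    NDVI = c("NIR", "Red"),
    NDWI = c("Green", "NIR"),
    EVI  = c("NIR", "Red", "Blue")
  )
  missing_bands <- setdiff(needed, names(stack$bands))
  if (length(missing_bands) > 0) {
    stopf("%s requires band(s) not in the stack: %s", which,
          paste(missing_bands, collapse = ", "))
  }
  b <- stack$bands
  out <- switch(which,
    NDBI = normalized_difference(b$SWIR, b$NIR),
    NDVI = normalized_difference(b$NIR, b$Red),
    NDWI = normalized_difference(b$Green, b$NIR),
    EVI = {
      denom <- b$NIR + params$C1 * b$Red - params$C2 * b$Blue + params$L
      denom[abs(denom) < 1e-12] <- NA_real_
      params$G * (b$NIR - b$Red) / denom
    }
  )
  if (all(is.na(out))) warning("index grid is entirely nodata", call. = FALSE)
  out
}

normalized_difference <- function(a, b) {
  denom <- a + b
  denom[abs(denom) < 1e-12] <- NA_real_
  (a - b) / denom
}

#' Write an index grid as whitespace-delimited text
#'
#' @param grid numeric matrix as returned by [compute_index()].
#' @param path output file; `NA` cells are written as `NA`.
#' @return `path`, invisibly.
#' @export
write_index_grid <- function(grid, path) {
  utils::write.table(format(grid, trim = TRUE, digits = 10), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
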