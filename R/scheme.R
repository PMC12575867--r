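#' Land-cover classification scheme
#'
#' A scheme binds integer class codes to land-cover labels and records which
#' class is forest and which code (if any) marks nodata. All rasters in a
#' change analysis must share one scheme so that transition matrices and
#' change maps are comparable.
#'
#' @param labels character vector of class labels, one per class.
#' @param codes integer codes, same length as `labels`, all distinct.
#' @param forest_label label of the forest class; must appear in `labels`.
#' @param nodata_code integer code reserved for missing pixels, or `NA` to
#'   use `NA` cells directly.
#' @return an object of class `class_scheme`.
#' @examples
#' sch <- default_scheme()
#' sch$labels
#' @export
class_scheme <- function(labels, codes = seq_along(labels),
                         forest_label = "forest", nodata_code = NA_integer_) {
  labels <- as.character(labels)
  codes <- as.integer(codes)
  if (length(labels) < 2L) stopf("a scheme needs at least 2 classes")
  if (length(labels) != length(codes)) stopf("labels and codes differ in length")
  if (anyDuplicated(codes)) stopf("class codes must be unique")
  if (anyDuplicated(labels)) stopf("class labels must be unique")
  if (!forest_label %in% labels) stopf("forest class '%s' not in scheme", forest_label)
  if (!is.na(nodata_code) && nodata_code %in% codes) {
    stopf("nodata code %d collides with a class code", nodata_code)
  }
  structure(
    list(labels = labels, codes = codes, forest_label = forest_label,
         nodata_code = as.integer(nodata_code)),
    class = "class_scheme"
  )
}

#' @describeIn class_scheme the seven-class scheme used throughout the
#'   package: forest, shrubland, cropland, built-up, wetland, waterbody,
#'   sparse vegetation, coded 1..7.
#' @export
default_scheme <- function() {
  class_scheme(
    labels = c("forest", "shrubland", "cropland", "built-up",
               "wetland", "waterbody", "sparse vegetation"),
    codes = 1:7,
    forest_label = "forest"
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("Land-cover scheme (", length(x$labels), " classes)\n", sep = "")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %d = %s%s\n", x$codes[i], x$labels[i],
                if (x$labels[i] == x$forest_label) "  [forest]" else ""))
  }
  if (!is.na(x$nodata_code)) cat("  nodata =", x$nodata_code, "\n")
  invisible(x)
}

forest_code <- function(scheme) {
  scheme$codes[match(scheme$forest_label, scheme$labels)]
}

scheme_identical <- function(a, b) {
  identical(a$labels, b$labels) && identical(a$codes, b$codes) &&
    identical(a$forest_label, b$forest_label)
}
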