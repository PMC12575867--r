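#' Thresholds for trend and convergence classification
#'
#' Bundles the decision thresholds used by [classify_direction()] and
#' [classify_convergence()]: a satellite trajectory is "stable" when the
#' absolute net change over the analysis window is below
#' `stable_max_net_change_pct` percent of the window-start area and the
#' linear trend is non-significant (p >= `stable_min_trend_p`); agreement of
#' `full_convergence_min` or more of survey responses with the satellite
#' direction gives full convergence (or dissonance when that share points
#' the opposite way), and shares between `partial_min` and
#' `full_convergence_min` give partial convergence. Threshold comparisons
#' are inclusive (>=).
#'
#' @param stable_max_net_change_pct percent net change below which a patch
#'   can be called stable (default 2).
#' @param stable_min_trend_p significance level at or above which the trend
#'   is treated as flat (default 0.10).
#' @param full_convergence_min minimum response share for full convergence
#'   or dissonance (default 0.65).
#' @param partial_min lower bound of the partial-convergence band
#'   (default 0.35).
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(stable_max_net_change_pct = 2.0,
                             stable_min_trend_p = 0.10,
                             full_convergence_min = 0.65,
                             partial_min = 0.35) {
  if (stable_max_net_change_pct <= 0) stopf("stable_max_net_change_pct must be > 0")
  if (!(partial_min > 0 && partial_min < full_convergence_min &&
        full_convergence_min < 1)) {
    stopf("need 0 < partial_min < full_convergence_min < 1")
  }
  structure(list(stable_max_net_change_pct = stable_max_net_change_pct,
                 stable_min_trend_p = stable_min_trend_p,
                 full_convergence_min = full_convergence_min,
                 partial_min = partial_min),
            class = "threshold_config")
}

#' Cross-tabulate land-cover transitions between two epochs
#'
#' Post-classification change detection: intersects two co-registered
#' classified maps pixel by pixel and tabulates the area moving between
#' every pair of classes. Pixels that are nodata in either epoch are
#' excluded from the matrix entirely, so row sums equal the epoch-from class
#' areas over the jointly valid mask and the grand total equals the valid
#' overlap area.
#'
#' @param map_a,map_b [lc_raster()]s sharing shape, scheme and cell area,
#'   with `map_a$epoch < map_b$epoch`.
#' @return an object of class `transition_matrix` with fields `flows`
#'   (K x K area matrix, ha, rows = from-class), `epoch_from`, `epoch_to`,
#'   `scheme`.
#' @examples
#' sch <- default_scheme()
#' a <- lc_raster(matrix(c(1L, 1L, 1L, 3L), 2), 2000, 1, sch)
#' b <- lc_raster(matrix(c(1L, 1L, 3L, 3L), 2), 2005, 1, sch)
#' crosstab_transitions(a, b)$flows[1:3, 1:3]
#' @export
crosstab_transitions <- function(map_a, map_b) {
  check_map_pair(map_a, map_b)
  valid <- !is.na(map_a$values) & !is.na(map_b$values)
  if (!any(valid)) stopf("no jointly valid pixels between the two epochs")
  labs <- map_a$scheme$labels
  fa <- factor(map_a$values[valid], levels = map_a$scheme$codes, labels = labs)
  fb <- factor(map_b$values[valid], levels = map_a$scheme$codes, labels = labs)
  flows <- unclass(table(fa, fb)) * map_a$cell_area_ha
  dimnames(flows) <- list(labs, labs)
  structure(list(flows = flows, epoch_from = map_a$epoch,
                 epoch_to = map_b$epoch, scheme = map_a$scheme),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Land-cover transitions %s -> %s (ha)\n",
              format(x$epoch_from), format(x$epoch_to)))
  keep <- rowSums(x$flows) > 0 | colSums(x$flows) > 0
  print(round(x$flows[keep, keep, drop = FALSE], 2))
  invisible(x)
}

check_map_pair <- function(map_a, map_b) {
  if (!identical(dim(map_a$values), dim(map_b$values))) {
    stopf("maps differ in shape: %dx%d vs %dx%d",
          nrow(map_a$values), ncol(map_a$values),
          nrow(map_b$values), ncol(map_b$values))
  }
  if (!scheme_identical(map_a$scheme, map_b$scheme)) stopf("maps use different schemes")
  if (map_a$cell_area_ha != map_b$cell_area_ha) stopf("maps differ in cell area")
  if (!(map_a$epoch < map_b$epoch)) stopf("map_a must precede map_b in time")
  invisible(TRUE)
}

#' Forest change map between two epochs
#'
#' Collapses the pixel-level transitions into the four forest-change
#' categories: net deforestation (forest to non-forest), net regrowth
#' (non-forest to forest), stable forest, and stable non-forest. Pixels
#' nodata in either epoch are `NA`.
#'
#' @inheritParams crosstab_transitions
#' @return an object of class `change_map`: integer matrix `values` coded
#'   1..4 with a `categories` label vector, plus the epochs and cell area.
#' @export
change_map <- function(map_a, map_b) {
  check_map_pair(map_a, map_b)
  fc <- forest_code(map_a$scheme)
  a_forest <- map_a$values == fc
  b_forest <- map_b$values == fc
  out <- matrix(NA_integer_, nrow(map_a$values), ncol(map_a$values))
  out[a_forest & !b_forest] <- 1L
  out[!a_forest & b_forest] <- 2L
  out[a_forest & b_forest] <- 3L
  out[!a_forest & !b_forest] <- 4L
  structure(list(values = out,
                 categories = c("net deforestation", "net regrowth",
                                "stable forest", "stable non-forest"),
                 epoch_from = map_a$epoch, epoch_to = map_b$epoch,
                 cell_area_ha = map_a$cell_area_ha),
            class = "change_map")
}

#' Areas of the four change categories
#'
#' @param cm a [change_map()].
#' @return named numeric vector of areas (ha).
#' @export
change_areas <- function(cm) {
  counts <- tabulate(cm$values, nbins = 4L)
  stats::setNames(counts * cm$cell_area_ha, cm$categories)
}

#' Forest-area trajectory of a patch
#'
#' Builds a patch's forest-area series either from classified rasters (area
#' = forest-pixel count x cell area) or directly from a table of areas, and
#' normalizes it to the baseline epoch (set to 100). This normalized
#' trajectory, in percent of baseline extent, is what trends are fitted to.
#'
#' @param maps list of [lc_raster()]s (any order; sorted by epoch).
#' @param patch_id patch label.
#' @param baseline_epoch epoch whose area anchors the 100% line; defaults to
#'   the earliest epoch.
#' @return an object of class `patch_series`: data frame with columns
#'   `epoch`, `forest_area_ha`, `normalized_pct`, plus attributes
#'   `patch_id` and `baseline_epoch`.
#' @export
forest_area_series <- function(maps, patch_id = "patch", baseline_epoch = NULL) {
  if (length(maps) < 2) stopf("need at least 2 epochs")
  epochs <- vapply(maps, function(m) m$epoch, numeric(1))
  areas <- vapply(maps, forest_area, numeric(1))
  o <- order(epochs)
  patch_series(patch_id, epochs[o], areas[o], baseline_epoch)
}

#' @describeIn forest_area_series build a series directly from epochs and
#'   areas (e.g. read from a CSV of `patch_id, year, forest_area_ha`).
#' @param epochs numeric years.
#' @param areas_ha forest areas (ha), same length.
#' @export
patch_series <- function(patch_id, epochs, areas_ha, baseline_epoch = NULL) {
  if (length(epochs) != length(areas_ha)) stopf("epochs and areas differ in length")
  if (any(areas_ha < 0)) stopf("areas must be non-negative")
  if (anyDuplicated(epochs)) stopf("duplicate epochs in series")
  o <- order(epochs)
  epochs <- epochs[o]; areas_ha <- areas_ha[o]
  if (is.null(baseline_epoch)) baseline_epoch <- epochs[1]
  if (!baseline_epoch %in% epochs) stopf("baseline epoch %s not in series", baseline_epoch)
  base <- areas_ha[match(baseline_epoch, epochs)]
  if (base <= 0) stopf("baseline forest area is zero; cannot normalize")
  df <- data.frame(epoch = epochs, forest_area_ha = areas_ha,
                   normalized_pct = 100 * areas_ha / base)
  structure(df, class = c("patch_series", "data.frame"),
            patch_id = patch_id, baseline_epoch = baseline_epoch)
}

#' Signed net change as percent of the starting area
#'
#' Positive values are losses, negative values gains, following the
#' reporting convention of land-change tables.
#'
#' @param area_start,area_end areas (ha); `area_start` must be positive.
#' @return `100 * (area_start - area_end) / area_start`, full precision.
#' @seealso [reported_net_change()] for the printed-precision convention.
#' @examples
#' net_change_percent(619, 505)   # 18.416..., printed as 18.4
#' @export
net_change_percent <- function(area_start, area_end) {
  if (any(area_start <= 0)) stopf("area_start must be positive")
  100 * (area_start - area_end) / area_start
}

#' @describeIn net_change_percent rounds half away from zero to one decimal
#'   place, or two when the magnitude is below 0.1 (so a 0.0856% loss prints
#'   as 0.09, not 0.1 or 0).
#' @export
reported_net_change <- function(area_start, area_end) {
  v <- net_change_percent(area_start, area_end)
  ifelse(abs(v) < 0.1, round_half_up(v, 2), round_half_up(v, 1))
}

#' Fit a linear trend to a normalized forest-area series
#'
#' Ordinary least squares of the normalized trajectory (percent of baseline)
#' on calendar year, restricted to an analysis window. The slope is in
#' percent of baseline per year. The two-sided slope p-value comes from the
#' t distribution with n - 2 degrees of freedom; with exactly two epochs the
#' p-value is undefined and flagged (`p_undefined = TRUE`), and the slope
#' passes exactly through both points.
#'
#' @param series a [patch_series()].
#' @param window length-2 numeric `(start_year, end_year)` or `NULL` for the
#'   full series.
#' @param use_normalized fit the normalized series (default) or absolute
#'   areas.
#' @return an object of class `trend_result`: `slope`, `intercept`,
#'   `p_value`, `p_undefined`, `net_change_pct` (over the window endpoints
#'   present in the series), `n`, `window`, `patch_id`, and `direction`
#'   (`NA` until [classify_direction()] fills it).
#' @export
fit_trend <- function(series, window = NULL, use_normalized = TRUE) {
  df <- as.data.frame(series)
  if (!is.null(window)) {
    df <- df[df$epoch >= window[1] & df$epoch <= window[2], , drop = FALSE]
  } else {
    window <- range(df$epoch)
  }
  if (nrow(df) < 2) stopf("fewer than 2 epochs in the analysis window")
  y <- if (use_normalized) df$normalized_pct else df$forest_area_ha
  fit <- stats::lm(y ~ epoch, data = df)
  co <- stats::coef(fit)
  n <- nrow(df)
  p_undefined <- n == 2
  if (p_undefined) {
    p <- NA_real_
  } else {
    rss <- sum(stats::residuals(fit)^2)
    if (rss < 1e-16) {
      # numerically perfect fit: slope either exactly flat or unambiguous
      p <- if (abs(co[["epoch"]]) < 1e-12) NA_real_ else 0
      p_undefined <- is.na(p)
    } else {
      p <- summary(fit)$coefficients["epoch", "Pr(>|t|)"]
    }
  }
  net <- net_change_percent(df$forest_area_ha[1], df$forest_area_ha[nrow(df)])
  structure(list(patch_id = attr(series, "patch_id"),
                 slope = unname(co[["epoch"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 p_value = unname(p), p_undefined = p_undefined,
                 net_change_pct = net, n = n,
                 window = c(df$epoch[1], df$epoch[nrow(df)]),
                 direction = NA_character_),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Trend %s [%s-%s]: slope %+.3f %%/yr, p %s, net change %+.2f%%%s\n",
              x$patch_id, format(x$window[1]), format(x$window[2]), x$slope,
              if (x$p_undefined) "undefined" else sprintf("%.4f", x$p_value),
              x$net_change_pct,
              if (is.na(x$direction)) "" else paste0(" -> ", x$direction)))
  invisible(x)
}

#' Classify the satellite direction of change for a patch
#'
#' Applies the stability rule: a patch is *stable* when the absolute net
#' change over the window is below the threshold (default 2% of the
#' window-start area) and the linear trend is non-significant (p >= 0.10) or
#' undefined (only two epochs, where the rule degrades to the net-change
#' condition alone). Otherwise the patch is *decline* when the net change is
#' a loss and *increase* when it is a gain; an exactly zero net change with
#' a significant trend is resolved by the slope sign.
#'
#' @inheritParams fit_trend
#' @param thresholds a [threshold_config()].
#' @return a `trend_result` with `direction` filled in.
#' @export
classify_direction <- function(series, window = NULL,
                               thresholds = threshold_config(),
                               use_normalized = TRUE) {
  tr <- fit_trend(series, window, use_normalized)
  flat <- tr$p_undefined || tr$p_value >= thresholds$stable_min_trend_p
  tr$direction <- if (abs(tr$net_change_pct) < thresholds$stable_max_net_change_pct && flat) {
    "stable"
  } else if (tr$net_change_pct > 0) {
    "decline"
  } else if (tr$net_change_pct < 0) {
    "increase"
  } else {
    if (tr$slope < 0) "decline" else "increase"
  }
  tr
}

#' Export transition matrices as a long table
#'
#' @param tm a [transition_matrix()] (or use [sankey_flows()] for several).
#' @param keep_zero keep zero-area flows?
#' @return data frame `epoch_from, epoch_to, class_from, class_to, area_ha`.
#' @export
transitions_long <- function(tm, keep_zero = FALSE) {
  labs <- tm$scheme$labels
  df <- expand.grid(class_from = labs, class_to = labs,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$area_ha <- as.vector(tm$flows)
  df <- cbind(epoch_from = tm$epoch_from, epoch_to = tm$epoch_to, df)
  if (!keep_zero) df <- df[df$area_ha > 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}
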