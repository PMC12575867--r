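#' Published summaries of the nine West African study patches
#'
#' Per-patch figures as published for nine forest patches in Togo, Benin,
#' Nigeria and Cameroon: forest area at the 2010 and 2022 epochs (ha), the
#' 2000-baseline endpoint areas where published (Ewe-Adakplame and
#' Hlanzoun), respondent counts, and the percentage of respondents
#' reporting a decrease or an increase in forest cover over the five- and
#' ten-year recall periods. Percentages not published for a patch are `NA`;
#' only the dominant directional shares were reported, so the remaining
#' response mass is unobserved.
#'
#' @return data frame, one row per patch.
#' @export
study_patch_summaries <- function() {
  path <- system.file("extdata", "patch_summaries.csv",
                      package = "forestconverge", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Response summaries for the study patches from published percentages
#'
#' Expands the published directional percentages into full four-category
#' response distributions: published shares are taken as-is and the
#' unpublished remainder is split evenly across the remaining categories.
#' This synthetic fill is neutral for convergence classification, which
#' depends only on whether the dominant published shares cross the
#' thresholds.
#'
#' @param recall_period `"10y"` (default) or `"5y"`.
#' @return named list of [response_summary()] objects, one per patch.
#' @export
study_response_summaries <- function(recall_period = c("10y", "5y")) {
  recall_period <- match.arg(recall_period)
  tab <- study_patch_summaries()
  dec_col <- paste0("pct_decreased_", recall_period)
  inc_col <- paste0("pct_increased_", recall_period)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    known <- c(Decreased = tab[[dec_col]][i] / 100,
               Increased = tab[[inc_col]][i] / 100,
               `No change` = NA_real_, `Don't know` = NA_real_)
    miss <- is.na(known)
    known[miss] <- (1 - sum(known[!miss])) / sum(miss)
    out[[tab$patch_id[i]]] <- response_summary(
      tab$patch_id[i], recall_period, n = tab$n_respondents[i],
      proportions = known)
  }
  out
}

#' Classify convergence for the nine study patches
#'
#' Runs the full decision chain on the published figures: a two-epoch
#' forest-area series per patch over the analysis window (where the trend
#' p-value is undefined and the stability rule degrades to the net-change
#' condition alone), the satellite direction from [classify_direction()],
#' and the convergence category from [classify_convergence()] against the
#' published response shares.
#'
#' @param recall_period `"10y"` (default) or `"5y"`.
#' @param thresholds a [threshold_config()].
#' @return data frame with one row per patch: `patch_id`, `country`,
#'   `net_change_pct` (full precision), `reported_net_change`
#'   (printed-precision convention), `rs_direction`, `lk_consensus`,
#'   `matching_proportion`, `category`, `mixed`.
#' @examples
#' classify_study_patches()[, c("patch_id", "rs_direction", "category")]
#' @export
classify_study_patches <- function(recall_period = "10y",
                                   thresholds = threshold_config()) {
  tab <- study_patch_summaries()
  lks <- study_response_summaries(recall_period)
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    pid <- tab$patch_id[i]
    series <- patch_series(pid, c(2010, 2022),
                           c(tab$area_2010_ha[i], tab$area_2022_ha[i]))
    trend <- classify_direction(series, window = c(2010, 2022),
                                thresholds = thresholds)
    asm <- classify_convergence(trend, lks[[pid]], thresholds)
    rows[[pid]] <- data.frame(
      patch_id = pid, country = tab$country[i],
      net_change_pct = trend$net_change_pct,
      reported_net_change = reported_net_change(tab$area_2010_ha[i],
                                                tab$area_2022_ha[i]),
      rs_direction = trend$direction,
      lk_consensus = asm$lk_consensus_direction,
      matching_proportion = asm$matching_proportion,
      category = asm$category, mixed = asm$mixed_flag,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
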