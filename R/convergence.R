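#' Classify agreement between satellite and local-knowledge evidence
#'
#' The convergence-matrix decision rule for one forest patch. Let `m` be
#' the share of survey responses matching the satellite direction (decline
#' matches "Decreased", increase matches "Increased", stable matches
#' "No change"; "Don't know" never counts toward any direction) and let `o`
#' be the largest share among the non-matching directional categories. The
#' decision, with inclusive thresholds, in order of precedence:
#'
#' 1. `m >= full_convergence_min` -> **full convergence**;
#' 2. else `o >= full_convergence_min` -> **dissonance** (a qualified
#'    majority contradicts the satellite signal);
#' 3. else -> **partial convergence** (weak or mixed consensus).
#'
#' `mixed_flag` marks patches where no single directional category reaches
#' `full_convergence_min` — sites without one dominant narrative.
#'
#' @param rs a `trend_result` with `direction` set
#'   (from [classify_direction()]).
#' @param lk a [response_summary()] for the same patch.
#' @param thresholds a [threshold_config()].
#' @return an object of class `convergence_assessment` with fields
#'   `patch_id`, `rs_direction`, `lk_consensus_direction`,
#'   `lk_consensus_proportion`, `matching_proportion`,
#'   `opposing_proportion`, `category`, `mixed_flag`, `recall_period`,
#'   `window`, `thresholds`.
#' @examples
#' sm <- response_summary("p", "10y", 100,
#'   c(Decreased = 0.93, Increased = 0.03, `No change` = 0.02,
#'     `Don't know` = 0.02))
#' tr <- classify_direction(patch_series("p", c(2010, 2022), c(619, 505)))
#' classify_convergence(tr, sm)$category
#' @export
classify_convergence <- function(rs, lk, thresholds = threshold_config()) {
  if (is.na(rs$direction)) stopf("satellite direction missing; run classify_direction()")
  if (!identical(rs$patch_id, lk$patch_id)) {
    stopf("satellite result is for '%s' but survey summary for '%s'",
          rs$patch_id, lk$patch_id)
  }
  match_cat <- c(decline = "Decreased", increase = "Increased",
                 stable = "No change")[[rs$direction]]
  directional <- lk$proportions[c("Decreased", "Increased", "No change")]
  m <- unname(directional[[match_cat]])
  o <- max(directional[setdiff(names(directional), match_cat)])
  category <- if (m >= thresholds$full_convergence_min) {
    "full_convergence"
  } else if (o >= thresholds$full_convergence_min) {
    "dissonance"
  } else {
    "partial_convergence"
  }
  mixed <- max(directional) < thresholds$full_convergence_min
  structure(list(patch_id = rs$patch_id, rs_direction = rs$direction,
                 lk_consensus_direction = lk$consensus_direction,
                 lk_consensus_proportion = lk$consensus_proportion,
                 matching_proportion = m, opposing_proportion = unname(o),
                 category = category, mixed_flag = mixed,
                 recall_period = lk$recall_period,
                 window = rs$window, thresholds = thresholds),
            class = "convergence_assessment")
}

#' @export
print.convergence_assessment <- function(x, ...) {
  cat(sprintf("%s: satellite %s vs local %s (%.0f%% matching) -> %s%s\n",
              x$patch_id, x$rs_direction, x$lk_consensus_direction,
              100 * x$matching_proportion, x$category,
              if (x$mixed_flag) " *mixed responses*" else ""))
  invisible(x)
}

#' Flatten transition matrices into Sankey flow records
#'
#' @param matrices list of [crosstab_transitions()] results sharing one
#'   scheme.
#' @return data frame `period, class_from, class_to, area_ha`, zero flows
#'   omitted, ordered by period then area descending — the machine-readable
#'   form of a Sankey diagram of land-cover transitions.
#' @export
sankey_flows <- function(matrices) {
  if (length(matrices) == 0) {
    return(data.frame(period = character(0), class_from = character(0),
                      class_to = character(0), area_ha = numeric(0)))
  }
  sch <- matrices[[1]]$scheme
  for (tm in matrices) {
    if (!scheme_identical(tm$scheme, sch)) stopf("matrices use different schemes")
  }
  recs <- lapply(matrices, function(tm) {
    df <- transitions_long(tm)
    data.frame(period = sprintf("%s-%s", format(tm$epoch_from),
                                format(tm$epoch_to)),
               class_from = df$class_from, class_to = df$class_to,
               area_ha = df$area_ha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$period, -out$area_ha, out$class_from, out$class_to), ]
  rownames(out) <- NULL
  out
}

#' Run the full evidence-integration pipeline
#'
#' For every configured patch: read (or accept in-memory) the classified
#' rasters or an area series, build the normalized forest trajectory,
#' classify the satellite direction over the analysis window, summarize the
#' survey responses for the chosen recall period, and classify convergence.
#' Writes per-patch JSON assessments, long-format transition CSVs, Sankey
#' flow records, an optional accuracy report when reference samples are
#' supplied, a consolidated convergence CSV, and a run log with the seed,
#' package version, and thresholds. A failure in one patch is logged and
#' the remaining patches proceed. Outputs contain no timestamps, so a rerun
#' with identical inputs is byte-identical.
#'
#' @param config either a path to a JSON config file or a list with
#'   elements: `patches` — list of per-patch lists each holding `patch_id`
#'   and one of `raster_dir` (directory of `raster_<year>.txt` grids),
#'   `raster_paths`, or `series` (data frame / CSV path with columns
#'   `epoch`, `forest_area_ha`), plus optional `survey_csv` or `survey`
#'   (data frame) and optional `reference_csv` (columns `mapped_class`,
#'   `reference_class`); optional `window` (default `c(2010, 2022)`),
#'   `recall_period` (default `"10y"`), `thresholds` (list of
#'   [threshold_config()] fields), `seed`.
#' @param out_dir directory for outputs (created if needed).
#' @return invisibly, a list with `assessments` (per patch), `summary`
#'   (consolidated data frame), and `errors` (named character vector of
#'   per-patch failures, empty when all succeed).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  window <- as.numeric(config$window %||% c(2010, 2022))
  recall <- config$recall_period %||% "10y"
  thr <- do.call(threshold_config, as.list(config$thresholds %||% list()))
  seed <- as.integer(config$seed %||% 1L)

  assessments <- list()
  errors <- character(0)
  summary_rows <- list()
  for (pc in config$patches %||% list()) {
    pid <- pc$patch_id
    res <- tryCatch({
      run_one_patch(pc, window, recall, thr, seed, out_dir)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors[pid] <- res
    } else {
      assessments[[pid]] <- res$assessment
      summary_rows[[pid]] <- res$summary_row
    }
  }
  summary <- if (length(summary_rows) > 0) {
    do.call(rbind, summary_rows)
  } else {
    data.frame(patch_id = character(0), rs_direction = character(0),
               net_change_pct = numeric(0), lk_consensus = character(0),
               matching_proportion = numeric(0), category = character(0),
               mixed = logical(0))
  }
  rownames(summary) <- NULL
  utils::write.csv(summary, file.path(out_dir, "convergence_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, package_version = as.character(utils::packageVersion("forestconverge")),
         window = window, recall_period = recall, thresholds = unclass(thr),
         n_patches = length(config$patches %||% list()),
         failed_patches = as.list(errors)),
    file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(assessments = assessments, summary = summary, errors = errors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_one_patch <- function(pc, window, recall, thr, seed, out_dir) {
  pid <- pc$patch_id
  if (is.null(pid)) stopf("patch entry without patch_id")
  rasters <- NULL
  if (!is.null(pc$raster_dir)) {
    grids <- sort(list.files(pc$raster_dir, pattern = "^raster_\\d+\\.txt$",
                             full.names = TRUE))
    rasters <- lapply(grids, read_lc_raster)
  } else if (!is.null(pc$raster_paths)) {
    rasters <- lapply(unlist(pc$raster_paths), read_lc_raster)
  }
  if (!is.null(rasters) && length(rasters) > 0) {
    rasters <- rasters[order(vapply(rasters, function(r) r$epoch, numeric(1)))]
    series <- forest_area_series(rasters, patch_id = pid)
    tms <- lapply(seq_len(length(rasters) - 1), function(i) {
      crosstab_transitions(rasters[[i]], rasters[[i + 1]])
    })
    trans <- do.call(rbind, lapply(tms, transitions_long))
    utils::write.csv(trans, file.path(out_dir, sprintf("transitions_%s.csv", pid)),
                     row.names = FALSE)
    utils::write.csv(sankey_flows(tms),
                     file.path(out_dir, sprintf("sankey_%s.csv", pid)),
                     row.names = FALSE)
  } else if (!is.null(pc$series)) {
    s <- pc$series
    if (is.character(s)) s <- utils::read.csv(s, stringsAsFactors = FALSE)
    series <- patch_series(pid, s$epoch, s$forest_area_ha)
  } else {
    stopf("patch '%s' has neither rasters nor a series", pid)
  }

  trend <- classify_direction(series, window = window, thresholds = thr)

  survey <- pc$survey
  if (!is.null(pc$survey_csv)) {
    survey <- utils::read.csv(pc$survey_csv, stringsAsFactors = FALSE)
  }
  assessment <- NULL
  if (!is.null(survey)) {
    lk <- summarize_responses(survey, pid, recall)
    assessment <- classify_convergence(trend, lk, thr)
    jsonlite::write_json(
      list(patch_id = pid, rs_direction = assessment$rs_direction,
           slope_pct_per_yr = trend$slope,
           trend_p_value = if (trend$p_undefined) NA else trend$p_value,
           net_change_pct = trend$net_change_pct,
           lk_consensus_direction = assessment$lk_consensus_direction,
           lk_consensus_proportion = assessment$lk_consensus_proportion,
           matching_proportion = assessment$matching_proportion,
           category = assessment$category, mixed_flag = assessment$mixed_flag,
           recall_period = recall, window = window),
      file.path(out_dir, sprintf("assessment_%s.json", pid)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }

  if (!is.null(pc$reference_csv)) {
    refs <- utils::read.csv(pc$reference_csv, stringsAsFactors = FALSE)
    cm <- confusion_from_refs(refs$mapped_class, refs$reference_class)
    write_accuracy_report(accuracy_metrics(cm),
                          path_json = file.path(out_dir, sprintf("accuracy_%s.json", pid)))
  }

  summary_row <- data.frame(
    patch_id = pid, rs_direction = trend$direction,
    net_change_pct = trend$net_change_pct,
    lk_consensus = if (is.null(assessment)) NA_character_ else assessment$lk_consensus_direction,
    matching_proportion = if (is.null(assessment)) NA_real_ else assessment$matching_proportion,
    category = if (is.null(assessment)) NA_character_ else assessment$category,
    mixed = if (is.null(assessment)) NA else assessment$mixed_flag,
    stringsAsFactors = FALSE)
  list(assessment = assessment, summary_row = summary_row)
}
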