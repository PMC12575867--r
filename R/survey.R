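#' Summarize perceived-change responses for one patch
#'
#' Aggregates a survey table to per-patch response proportions over the
#' four canonical categories, keeping "Don't know" in the denominator (the
#' directional shares reported by field studies do not sum to 100 across the
#' named categories, which implies an inclusive denominator). The consensus
#' direction is the modal category among the three directional ones,
#' mapped Decreased -> decline, Increased -> increase, No change -> stable;
#' ties give consensus "none".
#'
#' @param table survey data frame, one row per respondent, with columns
#'   `patch_id` and `perceived_change_<period>`.
#' @param patch_id patch to aggregate.
#' @param recall_period `"10y"` or `"5y"`.
#' @return an object of class `response_summary` (see [response_summary()]).
#' @export
summarize_responses <- function(table, patch_id, recall_period = c("10y", "5y")) {
  recall_period <- match.arg(recall_period)
  col <- paste0("perceived_change_", recall_period)
  if (!col %in% names(table)) stopf("column %s missing from survey table", col)
  rows <- table[table$patch_id == patch_id, , drop = FALSE]
  if (nrow(rows) == 0) stopf("no respondents for patch '%s'", patch_id)
  cats <- response_categories()
  resp <- rows[[col]]
  bad <- setdiff(unique(resp), cats)
  if (length(bad) > 0) {
    stopf("unknown response categories: %s", paste(bad, collapse = ", "))
  }
  counts <- table(factor(resp, levels = cats))
  response_summary(patch_id, recall_period, n = nrow(rows),
                   proportions = as.numeric(counts) / nrow(rows))
}

#' Construct a response summary from known proportions
#'
#' Used both by [summarize_responses()] and to enter published per-patch
#' response percentages directly.
#'
#' @param patch_id patch label.
#' @param recall_period `"10y"` or `"5y"`.
#' @param n number of respondents behind the proportions.
#' @param proportions numeric length-4 vector over
#'   `Decreased, Increased, No change, Don't know` (in that order, or named);
#'   must sum to 1 within 1e-9.
#' @return an object of class `response_summary` with fields `patch_id`,
#'   `recall_period`, `n`, `proportions` (named), `consensus_direction`
#'   (`decline`, `increase`, `stable` or `none`), `consensus_proportion`.
#' @export
response_summary <- function(patch_id, recall_period, n, proportions) {
  cats <- response_categories()
  if (!is.null(names(proportions))) {
    if (!setequal(names(proportions), cats)) {
      stopf("proportions must be named over: %s", paste(cats, collapse = ", "))
    }
    proportions <- proportions[cats]
  } else {
    if (length(proportions) != 4) stopf("proportions must have length 4")
    names(proportions) <- cats
  }
  if (any(proportions < 0) || !sums_to_one(proportions)) {
    stopf("proportions must be non-negative and sum to 1")
  }
  directional <- proportions[c("Decreased", "Increased", "No change")]
  top <- max(directional)
  modal <- names(directional)[directional == top]
  consensus <- if (length(modal) > 1 || top == 0) {
    "none"
  } else {
    c(Decreased = "decline", Increased = "increase",
      `No change` = "stable")[[modal]]
  }
  structure(list(patch_id = patch_id, recall_period = recall_period,
                 n = as.integer(n), proportions = proportions,
                 consensus_direction = consensus,
                 consensus_proportion = if (consensus == "none") NA_real_ else unname(top)),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("Responses %s (%s recall, n=%d): ", x$patch_id,
              x$recall_period, x$n))
  cat(paste(sprintf("%s %.0f%%", names(x$proportions), 100 * x$proportions),
            collapse = ", "), "\n")
  cat(sprintf("  consensus: %s (%.0f%%)\n", x$consensus_direction,
              100 * ifelse(is.na(x$consensus_proportion), 0,
                           x$consensus_proportion)))
  invisible(x)
}

#' Summarize cited drivers of forest change for one patch
#'
#' Each respondent may cite any number of drivers; a respondent citing k
#' drivers contributes to k percentages, all with the patch respondent
#' count as denominator.
#'
#' @param table survey data frame with a `drivers_<period>` column of
#'   semicolon-joined driver labels.
#' @param patch_id patch to aggregate.
#' @param recall_period `"10y"` or `"5y"`.
#' @param valence_map optional named character vector mapping driver label
#'   to `"positive"`, `"neutral"` or `"negative"`; enables per-valence
#'   totals.
#' @return an object of class `driver_summary`: data frame `drivers` with
#'   columns `driver`, `n_citing`, `pct` (and `valence` when mapped), plus
#'   `valence_totals` when mapped.
#' @export
summarize_drivers <- function(table, patch_id, recall_period = c("10y", "5y"),
                              valence_map = NULL) {
  recall_period <- match.arg(recall_period)
  col <- paste0("drivers_", recall_period)
  if (!col %in% names(table)) stopf("column %s missing from survey table", col)
  rows <- table[table$patch_id == patch_id, , drop = FALSE]
  if (nrow(rows) == 0) stopf("no respondents for patch '%s'", patch_id)
  cited <- strsplit(ifelse(is.na(rows[[col]]), "", rows[[col]]), ";", fixed = TRUE)
  all_drivers <- unlist(cited)
  all_drivers <- all_drivers[nzchar(all_drivers)]
  if (length(all_drivers) == 0) {
    drivers <- data.frame(driver = character(0), n_citing = integer(0),
                          pct = numeric(0), stringsAsFactors = FALSE)
  } else {
    tab <- sort(table(all_drivers), decreasing = TRUE)
    drivers <- data.frame(driver = names(tab), n_citing = as.integer(tab),
                          pct = 100 * as.integer(tab) / nrow(rows),
                          stringsAsFactors = FALSE)
  }
  valence_totals <- NULL
  if (!is.null(valence_map)) {
    bad <- setdiff(drivers$driver, names(valence_map))
    if (length(bad) > 0) {
      stopf("drivers without a valence: %s", paste(bad, collapse = ", "))
    }
    if (!all(valence_map %in% c("positive", "neutral", "negative"))) {
      stopf("valence must be positive, neutral or negative")
    }
    drivers$valence <- unname(valence_map[drivers$driver])
    valence_totals <- vapply(c("positive", "neutral", "negative"), function(v) {
      sum(drivers$n_citing[drivers$valence == v])
    }, numeric(1))
  }
  structure(list(patch_id = patch_id, recall_period = recall_period,
                 n = nrow(rows), drivers = drivers,
                 valence_totals = valence_totals),
            class = "driver_summary")
}

#' Test association between a demographic factor and perceived change
#'
#' Dispatches between the two tests commonly used for categorical survey
#' data: Fisher's exact test when the factor has at most `level_cap`
#' observed levels, and the Kruskal-Wallis H test otherwise, with responses
#' rank-coded on the ordinal scale Decreased < No change < Increased and
#' "Don't know" excluded from the ranks. For Fisher on tables larger than
#' 2 x 2 an exact p is attempted first and a seeded Monte-Carlo p is used
#' when exact computation is infeasible; the method actually used is
#' reported.
#'
#' @param table survey data frame.
#' @param factor_field name of the demographic column.
#' @param response_field name of the response column
#'   (e.g. `"perceived_change_10y"`).
#' @param level_cap maximum number of factor levels handled by Fisher's
#'   exact test (default 4).
#' @param mc_draws Monte-Carlo replicates for large Fisher tables.
#' @param seed seed for the Monte-Carlo p-value.
#' @return list with `statistic` (`NA` for Fisher), `p_value`, `test_name`
#'   (`"fisher"` or `"kruskal-wallis"`), `method` (`"exact"`,
#'   `"monte-carlo"` or `"rank"`), `n_used`.
#' @examples
#' tab <- data.frame(patch_id = "p",
#'   gender = rep(c("male", "female"), each = 20),
#'   perceived_change_10y = rep(c("Decreased", "Increased"), 20))
#' test_association(tab, "gender", "perceived_change_10y")
#' @export
test_association <- function(table, factor_field, response_field,
                             level_cap = 4L, mc_draws = 1e5, seed = 1L) {
  if (!factor_field %in% names(table)) stopf("no column '%s'", factor_field)
  if (!response_field %in% names(table)) stopf("no column '%s'", response_field)
  cats <- response_categories()
  fac <- factor(table[[factor_field]])
  resp <- factor(table[[response_field]], levels = cats)
  keep <- !is.na(fac) & !is.na(resp)
  fac <- droplevels(fac[keep]); resp <- resp[keep]
  if (nlevels(fac) < 2) stopf("factor '%s' has fewer than 2 levels", factor_field)

  if (nlevels(fac) <= level_cap) {
    ct <- table(fac, droplevels(resp))
    ct <- ct[rowSums(ct) > 0, colSums(ct) > 0, drop = FALSE]
    if (any(dim(ct) < 2)) stopf("contingency table is degenerate")
    res <- tryCatch(
      list(p = stats::fisher.test(ct, workspace = 2e7)$p.value,
           method = "exact"),
      error = function(e) {
        p <- with_seed(seed,
          stats::fisher.test(ct, simulate.p.value = TRUE, B = mc_draws)$p.value)
        list(p = p, method = "monte-carlo")
      })
    list(statistic = NA_real_, p_value = res$p, test_name = "fisher",
         method = res$method, n_used = sum(ct))
  } else {
    ord <- c(Decreased = 1, `No change` = 2, Increased = 3)
    keep2 <- as.character(resp) %in% names(ord)
    fac2 <- droplevels(fac[keep2])
    if (nlevels(fac2) < 2 || length(fac2) == 0) {
      stopf("not enough directional responses for a rank test")
    }
    score <- ord[as.character(resp[keep2])]
    kw <- stats::kruskal.test(score, fac2)
    list(statistic = unname(kw$statistic), p_value = kw$p.value,
         test_name = "kruskal-wallis", method = "rank",
         n_used = length(score))
  }
}

#' Association grid over several demographic factors
#'
#' Convenience wrapper running [test_association()] for each factor against
#' each recall period, returning the factor x test x p grid that
#' accompanies survey summaries.
#'
#' @param table survey data frame.
#' @param factors character vector of demographic column names.
#' @param response_fields response columns to test (default both recall
#'   periods).
#' @inheritParams test_association
#' @return data frame `factor, response, test, method, statistic, p_value`.
#' @export
association_grid <- function(table, factors,
                             response_fields = c("perceived_change_5y",
                                                 "perceived_change_10y"),
                             level_cap = 4L, seed = 1L) {
  rows <- list()
  for (rf in response_fields) {
    for (f in factors) {
      res <- tryCatch(
        test_association(table, f, rf, level_cap = level_cap, seed = seed),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, response = rf, test = res$test_name,
        method = res$method, statistic = res$statistic,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(factor = character(0), response = character(0),
                      test = character(0), method = character(0),
                      statistic = numeric(0), p_value = numeric(0)))
  }
  do.call(rbind, rows)
}
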