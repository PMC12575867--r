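#' Stratified random sample of reference pixels
#'
#' Allocates reference points to map classes proportionally to class area
#' by largest-remainder apportionment, with a floor of one point per
#' nonempty class, then samples pixel locations without replacement within
#' each stratum. This mirrors the standard design for thematic-map accuracy
#' assessment where reference labels are later assigned by an independent
#' interpreter.
#'
#' @param map an [lc_raster()].
#' @param n_total total number of sample points; must be at least the
#'   number of nonempty classes.
#' @param seed integer seed for reproducible draws.
#' @return data frame `row, col, mapped_class` (class labels).
#' @export
stratified_sample <- function(map, n_total, seed = 1L) {
  labs <- map$scheme$labels
  counts <- tabulate(match(map$values, map$scheme$codes), nbins = length(labs))
  nonempty <- which(counts > 0)
  if (n_total < length(nonempty)) {
    stopf("n_total (%d) is below the number of nonempty classes (%d)",
          n_total, length(nonempty))
  }
  alloc <- integer(length(labs))
  alloc[nonempty] <- largest_remainder(counts[nonempty], n_total, minimum = 1L)
  with_seed(seed, {
    out <- lapply(nonempty, function(i) {
      idx <- which(map$values == map$scheme$codes[i])
      take <- idx[sample.int(length(idx), min(alloc[i], length(idx)))]
      data.frame(row = ((take - 1) %% nrow(map$values)) + 1,
                 col = ((take - 1) %/% nrow(map$values)) + 1,
                 mapped_class = labs[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# Largest-remainder (Hamilton) apportionment of n among weights, with an
# optional per-stratum floor.
largest_remainder <- function(weights, n, minimum = 0L) {
  quota <- n * weights / sum(weights)
  alloc <- pmax(floor(quota), minimum)
  rem <- n - sum(alloc)
  frac <- quota - floor(quota)
  if (rem > 0) {
    ord <- order(frac, weights, decreasing = TRUE)
    take <- ord[seq_len(rem)]
    alloc[take] <- alloc[take] + 1L
  } else if (rem < 0) {
    # floors pushed us over: pull back from the smallest remainders that
    # still sit above the floor
    ord <- order(frac, weights)
    for (i in ord) {
      if (rem == 0) break
      if (alloc[i] > minimum) {
        alloc[i] <- alloc[i] - 1L
        rem <- rem + 1L
      }
    }
  }
  as.integer(alloc)
}

#' Confusion matrix from mapped and reference labels
#'
#' @param mapped character vector of map labels, one per sample.
#' @param reference character vector of reference labels, same length.
#' @param labels the closed label set (defaults to the union observed).
#' @return an object of class `confusion_matrix`: integer matrix `counts`
#'   with rows = mapped class and columns = reference class, and `n_total`.
#' @export
confusion_from_refs <- function(mapped, reference, labels = NULL) {
  if (length(mapped) != length(reference)) {
    stopf("mapped and reference differ in length")
  }
  if (is.null(labels)) labels <- sort(unique(c(mapped, reference)))
  bad <- setdiff(unique(c(mapped, reference)), labels)
  if (length(bad) > 0) {
    stopf("labels outside the scheme: %s", paste(bad, collapse = ", "))
  }
  fm <- factor(mapped, levels = labels)
  fr <- factor(reference, levels = labels)
  counts <- unclass(table(fm, fr))
  dimnames(counts) <- list(mapped = labels, reference = labels)
  structure(list(counts = counts, n_total = length(mapped)),
            class = "confusion_matrix")
}

#' Overall, producer's and user's accuracy with binomial standard errors
#'
#' Overall accuracy is the trace over the total; producer's accuracy of a
#' class is its diagonal count over its reference (column) total, user's
#' accuracy over its mapped (row) total. Each standard error is the
#' binomial `sqrt(p (1 - p) / n)` with that metric's own denominator.
#' Classes with a zero marginal get `NA` (undefined), not 0. Simple
#' (non-area-weighted) estimators throughout.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `accuracy_report`: `overall` and `overall_se`
#'   plus a data frame `per_class` with columns `class`, `producers`,
#'   `producers_se`, `users`, `users_se`.
#' @examples
#' cm <- confusion_from_refs(c("a", "a", "b"), c("a", "b", "b"))
#' accuracy_metrics(cm)
#' @export
accuracy_metrics <- function(cm) {
  if (cm$n_total <= 0) stopf("empty confusion matrix")
  counts <- cm$counts
  diagv <- diag(counts)
  rowt <- rowSums(counts)
  colt <- colSums(counts)
  overall <- sum(diagv) / cm$n_total
  producers <- ifelse(colt > 0, diagv / colt, NA_real_)
  users <- ifelse(rowt > 0, diagv / rowt, NA_real_)
  binom_se <- function(p, n) ifelse(n > 0, sqrt(p * (1 - p) / n), NA_real_)
  structure(list(
    overall = overall,
    overall_se = binom_se(overall, cm$n_total),
    per_class = data.frame(
      class = rownames(counts),
      producers = unname(producers),
      producers_se = unname(binom_se(producers, colt)),
      users = unname(users),
      users_se = unname(binom_se(users, rowt)),
      stringsAsFactors = FALSE
    )
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Overall accuracy %.3f (SE %.4f)\n", x$overall, x$overall_se))
  print(transform(x$per_class,
                  producers = round(producers, 3), users = round(users, 3),
                  producers_se = round(producers_se, 4),
                  users_se = round(users_se, 4)), row.names = FALSE)
  invisible(x)
}

#' Write an accuracy report to CSV and JSON
#'
#' @param report an [accuracy_metrics()] result.
#' @param path_csv,path_json output paths; either may be `NULL` to skip.
#' @return the report, invisibly.
#' @export
write_accuracy_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    df <- rbind(
      data.frame(class = "overall", producers = report$overall,
                 producers_se = report$overall_se, users = report$overall,
                 users_se = report$overall_se, stringsAsFactors = FALSE),
      report$per_class
    )
    utils::write.csv(df, path_csv, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(overall = report$overall, overall_se = report$overall_se,
           per_class = report$per_class),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(report)
}
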