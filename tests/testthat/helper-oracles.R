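# Independent oracles and small generators shared across the suite.
# The oracles deliberately avoid the code paths they check: the crosstab
# oracle is a per-pixel double loop, the Fisher oracle a direct
# hypergeometric enumeration.

oracle_crosstab <- function(vals_a, vals_b, scheme, cell_area_ha) {
  K <- length(scheme$codes)
  m <- matrix(0, K, K, dimnames = list(scheme$labels, scheme$labels))
  for (i in seq_len(nrow(vals_a))) {
    for (j in seq_len(ncol(vals_a))) {
      ca <- vals_a[i, j]; cb <- vals_b[i, j]
      if (!is.na(ca) && !is.na(cb)) {
        ia <- match(ca, scheme$codes); ib <- match(cb, scheme$codes)
        m[ia, ib] <- m[ia, ib] + cell_area_ha
      }
    }
  }
  m
}

oracle_change_counts <- function(vals_a, vals_b, fcode) {
  counts <- c(`net deforestation` = 0, `net regrowth` = 0,
              `stable forest` = 0, `stable non-forest` = 0)
  for (i in seq_len(nrow(vals_a))) {
    for (j in seq_len(ncol(vals_a))) {
      ca <- vals_a[i, j]; cb <- vals_b[i, j]
      if (is.na(ca) || is.na(cb)) next
      k <- if (ca == fcode && cb != fcode) 1 else if (ca != fcode && cb == fcode) 2
        else if (ca == fcode) 3 else 4
      counts[k] <- counts[k] + 1
    }
  }
  counts
}

# Two-sided Fisher p for a 2x2 table by summing hypergeometric point
# probabilities no larger than the observed one.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  pobs <- stats::dhyper(a, c1, n - c1, r1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

kernel_power_oracle <- function(k, t) {
  Reduce(`%*%`, replicate(t, k, simplify = FALSE))
}

# Random co-registered map pair with some nodata, on the default scheme.
random_map_pair <- function(nr, nc, seed, p_na = 0.05) {
  sch <- default_scheme()
  set.seed(seed)
  mk <- function(epoch) {
    v <- matrix(sample(sch$codes, nr * nc, replace = TRUE), nr, nc)
    v[stats::runif(nr * nc) < p_na] <- NA_integer_
    lc_raster(v, epoch, cell_area_ha = 0.09, scheme = sch)
  }
  list(a = mk(2010), b = mk(2022))
}

# Survey table built directly from category counts for one patch.
table_from_counts <- function(counts, patch_id = "p", period = "10y") {
  resp <- rep(names(counts), counts)
  df <- data.frame(patch_id = patch_id, stringsAsFactors = FALSE,
                   row = seq_along(resp))
  df[[paste0("perceived_change_", period)]] <- resp
  df
}

balanced_direction_probs <- function(dec = 0.55, inc = 0.2, nc = 0.15) {
  v <- c(dec, inc, nc, 1 - dec - inc - nc)
  names(v) <- response_categories()
  list(`5y` = v, `10y` = v)
}
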