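#' Build an annual transition kernel from per-transition rates
#'
#' The landscape simulator moves each pixel through a first-order Markov
#' chain on the class codes. Rates are specified as annual probabilities of
#' moving from one class to another; the probability of staying put is the
#' remainder, so each row of the kernel sums to 1.
#'
#' @param scheme a [class_scheme()].
#' @param rates data frame with columns `from`, `to` (class labels) and
#'   `annual_rate` (probability per year). Omitted pairs get rate 0.
#' @return a K x K matrix with `dimnames` set to the scheme labels.
#' @examples
#' k <- transition_kernel(default_scheme(),
#'   data.frame(from = "forest", to = "cropland", annual_rate = 0.02))
#' rowSums(k)
#' @export
transition_kernel <- function(scheme, rates = NULL) {
  K <- length(scheme$labels)
  kern <- diag(K)
  dimnames(kern) <- list(scheme$labels, scheme$labels)
  if (!is.null(rates) && nrow(rates) > 0) {
    bad <- setdiff(unique(c(rates$from, rates$to)), scheme$labels)
    if (length(bad) > 0) {
      stopf("unknown class in transition rates: %s", paste(bad, collapse = ", "))
    }
    for (i in seq_len(nrow(rates))) {
      kern[rates$from[i], rates$to[i]] <- rates$annual_rate[i]
    }
    diag(kern) <- 0
    stay <- 1 - rowSums(kern)
    if (any(stay < -1e-9)) {
      stopf("annual departure rates from '%s' exceed 1",
            scheme$labels[which(stay < -1e-9)[1]])
    }
    diag(kern) <- pmax(stay, 0)
  }
  kern
}

#' Landscape simulation scenario
#'
#' Describes a synthetic multi-epoch categorical landscape: grid shape, cell
#' area, epoch years, initial class proportions, an annual Markov transition
#' kernel, and the expected clump size of the initial map. Epoch gaps are
#' handled by raising the annual kernel to the number of intervening years,
#' so a five-year interval applies the kernel power 5.
#'
#' @param grid_rows,grid_cols grid dimensions in pixels.
#' @param cell_area_ha area per pixel (ha); default 0.09 (a 30 m pixel).
#' @param epochs strictly increasing integer years, at least one.
#' @param initial_class_proportions named numeric vector over scheme labels
#'   (missing labels get 0); must sum to 1 within 1e-9.
#' @param kernel K x K annual transition matrix (rows sum to 1), e.g. from
#'   [transition_kernel()]. Must be square and match the scheme classes.
#' @param clump_size expected contiguous-patch size of the initial map, in
#'   pixels (>= 1). 1 reduces to i.i.d. pixels.
#' @param scheme a [class_scheme()].
#' @param seed integer seed governing all stochastic draws of the scenario.
#' @return an object of class `landscape_scenario`.
#' @export
landscape_scenario <- function(grid_rows, grid_cols, epochs,
                               initial_class_proportions,
                               kernel = transition_kernel(scheme),
                               clump_size = 8, cell_area_ha = 0.09,
                               scheme = default_scheme(), seed = 1L) {
  if (grid_rows < 1 || grid_cols < 1) stopf("grid dimensions must be positive")
  epochs <- as.numeric(epochs)
  if (length(epochs) < 1 || is.unsorted(epochs, strictly = TRUE)) {
    stopf("epochs must be strictly increasing")
  }
  props <- stats::setNames(numeric(length(scheme$labels)), scheme$labels)
  bad <- setdiff(names(initial_class_proportions), scheme$labels)
  if (length(bad) > 0) stopf("unknown class in proportions: %s", paste(bad, collapse = ", "))
  props[names(initial_class_proportions)] <- initial_class_proportions
  if (!sums_to_one(props)) stopf("initial class proportions must sum to 1")
  if (!is.matrix(kernel) || nrow(kernel) != ncol(kernel)) {
    stopf("transition kernel must be a square matrix")
  }
  if (nrow(kernel) != length(scheme$labels)) {
    stopf("kernel has %d classes but the scheme has %d",
          nrow(kernel), length(scheme$labels))
  }
  if (!is.null(rownames(kernel))) {
    bad <- setdiff(rownames(kernel), scheme$labels)
    if (length(bad) > 0) stopf("unknown class in kernel: %s", paste(bad, collapse = ", "))
    kernel <- kernel[scheme$labels, scheme$labels]
  }
  if (any(abs(rowSums(kernel) - 1) > 1e-9) || any(kernel < 0)) {
    stopf("each kernel row must be a probability vector summing to 1")
  }
  if (clump_size < 1) stopf("clump_size must be >= 1")
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         cell_area_ha = cell_area_ha, epochs = epochs,
         initial_class_proportions = props, kernel = kernel,
         clump_size = clump_size, scheme = scheme, seed = as.integer(seed)),
    class = "landscape_scenario"
  )
}

# Seeded region growing: scatter seeds (one per `clump_size` pixels), give
# each seed a class drawn from the target proportions, then accrete
# unassigned pixels onto a random assigned 4-neighbour, ring by ring.
# Proportions are matched in expectation; clumps have realistic irregular
# shapes rather than i.i.d. salt-and-pepper.
grow_clumped_map <- function(nr, nc, codes, props, clump_size) {
  n <- nr * nc
  n_seeds <- max(1L, as.integer(round(n / clump_size)))
  g <- rep(NA_integer_, n)
  seeds <- sample.int(n, n_seeds)
  g[seeds] <- sample(codes, n_seeds, replace = TRUE, prob = props)
  while (anyNA(g)) {
    gm <- matrix(g, nr, nc)
    up    <- rbind(gm[-1, , drop = FALSE], NA_integer_)
    down  <- rbind(NA_integer_, gm[-nr, , drop = FALSE])
    left  <- cbind(gm[, -1, drop = FALSE], NA_integer_)
    right <- cbind(NA_integer_, gm[, -nc, drop = FALSE])
    cand <- cbind(as.vector(up), as.vector(down), as.vector(left), as.vector(right))
    un <- which(is.na(g))
    cc <- cand[un, , drop = FALSE]
    picks <- apply(cc, 1L, function(r) {
      r <- r[!is.na(r)]
      if (length(r) == 0L) NA_integer_ else r[sample.int(length(r), 1L)]
    })
    g[un] <- picks
  }
  matrix(g, nr, nc)
}

# Integer matrix power by repeated multiplication (small K, small exponents).
kernel_power <- function(kern, years) {
  out <- diag(nrow(kern))
  dimnames(out) <- dimnames(kern)
  for (i in seq_len(years)) out <- out %*% kern
  out
}

# Class-conditional band reflectance means; SD is constant across bands.
# Chosen so forest has the highest NIR and NDVI, shrubland intermediate,
# built-up high SWIR (positive NDBI), and water high NDWI.
reflectance_profile <- function() {
  m <- rbind(
    forest               = c(0.03, 0.05, 0.04, 0.45, 0.12),
    shrubland            = c(0.04, 0.07, 0.08, 0.32, 0.18),
    cropland             = c(0.06, 0.10, 0.14, 0.28, 0.24),
    `built-up`           = c(0.12, 0.14, 0.16, 0.20, 0.30),
    wetland              = c(0.05, 0.08, 0.07, 0.25, 0.10),
    waterbody            = c(0.06, 0.07, 0.05, 0.03, 0.02),
    `sparse vegetation`  = c(0.08, 0.11, 0.13, 0.20, 0.26)
  )
  colnames(m) <- c("Blue", "Green", "Red", "NIR", "SWIR")
  list(means = m, sd = 0.02)
}

#' Simulate a multi-epoch classified landscape
#'
#' Draws the first epoch by clumped seeding that matches the scenario's
#' initial class proportions in expectation, then advances each pixel
#' independently through the annual Markov kernel raised to the inter-epoch
#' year gap. The same seed always yields bit-identical rasters.
#'
#' @param scenario a [landscape_scenario()].
#' @param reflectance if `TRUE`, also return one [spectral_stack()] per
#'   epoch, drawing band reflectances from class-conditional normal
#'   distributions (truncated to [0, 1]).
#' @return a list with `rasters` (list of [lc_raster()], one per epoch) and,
#'   when requested, `stacks` (list of [spectral_stack()]).
#' @examples
#' sc <- landscape_scenario(16, 16, epochs = c(2010, 2022),
#'   initial_class_proportions = c(forest = 0.7, cropland = 0.3),
#'   kernel = transition_kernel(default_scheme(),
#'     data.frame(from = "forest", to = "cropland", annual_rate = 0.02)),
#'   seed = 42)
#' maps <- simulate_landscape_series(sc)$rasters
#' @export
simulate_landscape_series <- function(scenario, reflectance = FALSE) {
  sch <- scenario$scheme
  with_seed(scenario$seed, {
    current <- grow_clumped_map(scenario$grid_rows, scenario$grid_cols,
                                sch$codes, scenario$initial_class_proportions,
                                scenario$clump_size)
    rasters <- vector("list", length(scenario$epochs))
    rasters[[1]] <- lc_raster(current, scenario$epochs[1],
                              scenario$cell_area_ha, sch)
    if (length(scenario$epochs) > 1) {
      for (e in 2:length(scenario$epochs)) {
        gap <- scenario$epochs[e] - scenario$epochs[e - 1]
        kg <- kernel_power(scenario$kernel, gap)
        nxt <- current
        for (i in seq_along(sch$codes)) {
          idx <- which(current == sch$codes[i])
          if (length(idx) > 0) {
            nxt[idx] <- sample(sch$codes, length(idx), replace = TRUE,
                               prob = kg[i, ])
          }
        }
        current <- nxt
        rasters[[e]] <- lc_raster(current, scenario$epochs[e],
                                  scenario$cell_area_ha, sch)
      }
    }
    out <- list(rasters = rasters)
    if (reflectance) {
      prof <- reflectance_profile()
      out$stacks <- lapply(rasters, function(r) {
        idx <- match(sch$labels[match(r$values, sch$codes)],
                     rownames(prof$means))
        bands <- lapply(colnames(prof$means), function(bn) {
          mu <- prof$means[idx, bn]
          b <- matrix(stats::rnorm(length(mu), mu, prof$sd),
                      nrow(r$values), ncol(r$values))
          pmin(pmax(b, 0), 1)
        })
        names(bands) <- colnames(prof$means)
        spectral_stack(bands, epoch = r$epoch)
      })
    }
    out
  })
}

#' Survey simulation scenario
#'
#' Describes a synthetic household survey for one forest patch: the number
#' of respondents, the target distribution of perceived-change responses per
#' recall period, a driver menu with citation probabilities, demographic
#' marginals, and optional demographic effects expressed as log-odds shifts
#' of the response distribution (applied on the multinomial-logit scale, so
#' shifted probabilities always remain a valid distribution).
#'
#' @param n_respondents number of survey rows to draw (>= 1).
#' @param patch_id patch label.
#' @param direction_probs named list with elements `"5y"` and `"10y"`, each
#'   a named probability vector over
#'   `c("Decreased", "Increased", "No change", "Don't know")` summing to 1.
#' @param driver_menu data frame with columns `label`,
#'   `valence` (one of `"positive"`, `"neutral"`, `"negative"`) and `prob`
#'   (independent citation probability per respondent), or `NULL`.
#' @param demographics named list of named probability vectors giving the
#'   marginal distribution of each demographic field; defaults cover gender,
#'   age class, education, community, residency class and marital status.
#' @param demographic_effects optional nested list
#'   `field -> level -> named numeric` of log-odds shifts added to
#'   `log(direction_probs)` before renormalisation; `NULL` means none.
#' @param household_size_lambda Poisson mean for household size (shifted by
#'   1 so sizes are >= 1).
#' @param seed integer seed.
#' @return an object of class `survey_scenario`.
#' @export
survey_scenario <- function(n_respondents, patch_id = "patch",
                            direction_probs,
                            driver_menu = NULL,
                            demographics = default_demographics(),
                            demographic_effects = NULL,
                            household_size_lambda = 5,
                            seed = 1L) {
  if (n_respondents < 1) stopf("n_respondents must be >= 1")
  cats <- response_categories()
  if (!all(c("5y", "10y") %in% names(direction_probs))) {
    stopf("direction_probs needs elements '5y' and '10y'")
  }
  for (p in names(direction_probs)) {
    v <- direction_probs[[p]]
    if (!setequal(names(v), cats)) {
      stopf("direction_probs$%s must be named over: %s", p,
            paste(cats, collapse = ", "))
    }
    if (any(v < 0) || !sums_to_one(v)) {
      stopf("direction_probs$%s must be a probability vector summing to 1", p)
    }
    direction_probs[[p]] <- v[cats]
  }
  if (!is.null(driver_menu)) {
    if (!all(c("label", "valence", "prob") %in% names(driver_menu))) {
      stopf("driver_menu needs columns label, valence, prob")
    }
    if (!all(driver_menu$valence %in% c("positive", "neutral", "negative"))) {
      stopf("driver valence must be positive, neutral or negative")
    }
    if (any(driver_menu$prob < 0 | driver_menu$prob > 1)) {
      stopf("driver citation probabilities must lie in [0, 1]")
    }
  }
  structure(
    list(n_respondents = as.integer(n_respondents), patch_id = patch_id,
         direction_probs = direction_probs, driver_menu = driver_menu,
         demographics = demographics,
         demographic_effects = demographic_effects,
         household_size_lambda = household_size_lambda,
         seed = as.integer(seed)),
    class = "survey_scenario"
  )
}

#' Canonical perceived-change response categories
#' @return character vector of the four categories.
#' @export
response_categories <- function() {
  c("Decreased", "Increased", "No change", "Don't know")
}

#' @describeIn survey_scenario default demographic marginals, loosely shaped
#'   on forest-adjacent West African communities: male-skewed respondents,
#'   middle-aged majority, mixed education, long residency.
#' @export
default_demographics <- function() {
  list(
    gender = c(male = 0.75, female = 0.25),
    age_class = c(`20-35` = 0.2, `35-50` = 0.35, `50-65` = 0.3, `>65` = 0.15),
    education = c(none = 0.3, primary = 0.25, secondary = 0.35, tertiary = 0.1),
    community = c(A = 0.25, B = 0.2, C = 0.2, D = 0.15, E = 0.1, F = 0.1),
    occupation = c(farming = 0.55, `crafts and trades` = 0.15,
                   `household roles` = 0.1, hunters = 0.05,
                   unemployed = 0.05, others = 0.1),
    residency_class = c(`<5` = 0.1, `5-10` = 0.1, `10-15` = 0.1,
                        `15-20` = 0.1, `>20` = 0.6),
    marital_status = c(married = 0.7, single = 0.15, widowed = 0.1,
                       divorced = 0.05)
  )
}

#' Simulate a household survey table
#'
#' Draws demographics from the scenario's marginal distributions, then draws
#' each respondent's perceived change per recall period from the target
#' response distribution, shifted on the log-odds scale by any demographic
#' effects. Drivers are cited independently with their menu probabilities.
#'
#' @param scenario a [survey_scenario()].
#' @return a data frame, one row per respondent, with columns
#'   `respondent_id`, `patch_id`, the demographic fields, `household_size`,
#'   `perceived_change_5y`, `perceived_change_10y`, `drivers_5y`,
#'   `drivers_10y` (semicolon-joined driver labels).
#' @examples
#' sc <- survey_scenario(50, direction_probs = list(
#'   `5y` = c(Decreased = 1, Increased = 0, `No change` = 0, `Don't know` = 0),
#'   `10y` = c(Decreased = 1, Increased = 0, `No change` = 0, `Don't know` = 0)))
#' tab <- simulate_survey(sc)
#' table(tab$perceived_change_10y)
#' @export
simulate_survey <- function(scenario) {
  n <- scenario$n_respondents
  cats <- response_categories()
  with_seed(scenario$seed, {
    demo <- lapply(scenario$demographics, function(p) {
      sample(names(p), n, replace = TRUE, prob = p)
    })
    tab <- data.frame(
      respondent_id = sprintf("%s_%04d", scenario$patch_id, seq_len(n)),
      patch_id = scenario$patch_id,
      stringsAsFactors = FALSE
    )
    for (f in names(demo)) tab[[f]] <- demo[[f]]
    tab$household_size <- 1L + stats::rpois(n, scenario$household_size_lambda - 1)

    for (period in c("5y", "10y")) {
      base_logit <- log(pmax(scenario$direction_probs[[period]], 1e-12))
      draws <- character(n)
      for (i in seq_len(n)) {
        lg <- base_logit
        if (!is.null(scenario$demographic_effects)) {
          for (f in names(scenario$demographic_effects)) {
            lv <- tab[[f]][i]
            shift <- scenario$demographic_effects[[f]][[lv]]
            if (!is.null(shift)) lg[names(shift)] <- lg[names(shift)] + shift
          }
        }
        p <- exp(lg - max(lg))
        draws[i] <- sample(cats, 1L, prob = p / sum(p))
      }
      tab[[paste0("perceived_change_", period)]] <- draws
    }

    for (period in c("5y", "10y")) {
      col <- paste0("drivers_", period)
      if (is.null(scenario$driver_menu)) {
        tab[[col]] <- ""
      } else {
        menu <- scenario$driver_menu
        cites <- matrix(stats::runif(n * nrow(menu)) < rep(menu$prob, each = n),
                        n, nrow(menu))
        tab[[col]] <- apply(cites, 1L, function(z) {
          paste(menu$label[z], collapse = ";")
        })
      }
    }
    tab
  })
}

#' Write a canonical three-patch fixture bundle
#'
#' Emits three small end-to-end scenarios with designed outcomes, each in
#' its own directory under `dir`: `full` (simulated forest decline plus 90%
#' "Decreased" responses, designed to classify as full convergence),
#' `dissonance` (a landscape whose forest area is held fixed while other
#' classes churn, paired with 95% "Decreased" responses), and `partial`
#' (decline with a 45/35 increase/decrease response split). Each directory
#' contains one text-grid raster per epoch (2010, 2015, 2020, 2022) with its
#' JSON sidecar and a `survey.csv`. Re-running with the same seed reproduces
#' every file byte for byte.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return named list of the three scenario directories, invisibly
#'   re-readable with [read_fixture_patch()].
#' @export
make_fixture_suite <- function(seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sch <- default_scheme()
  epochs <- c(2010, 2015, 2020, 2022)
  loss_kernel <- transition_kernel(sch, data.frame(
    from = c("forest", "shrubland"), to = c("cropland", "cropland"),
    annual_rate = c(0.03, 0.01)))
  churn_kernel <- transition_kernel(sch, data.frame(
    from = c("shrubland", "cropland"), to = c("cropland", "shrubland"),
    annual_rate = c(0.05, 0.05)))
  dp <- function(d, i, nc, dk) {
    v <- c(Decreased = d, Increased = i, `No change` = nc, `Don't know` = dk)
    list(`5y` = v, `10y` = v)
  }
  drivers <- data.frame(
    label = c("logging", "slash-and-burn agriculture", "bush fires",
              "population growth", "NTFP collection",
              "effective law enforcement", "forest regrowth",
              "nothing to report"),
    valence = c("negative", "negative", "negative", "negative", "negative",
                "positive", "positive", "neutral"),
    prob = c(0.5, 0.3, 0.25, 0.2, 0.15, 0.05, 0.05, 0.1)
  )
  specs <- list(
    full = list(
      land = landscape_scenario(48, 48, epochs,
        c(forest = 0.7, shrubland = 0.15, cropland = 0.15),
        kernel = loss_kernel, seed = seed),
      survey = survey_scenario(120, "full",
        dp(0.90, 0.03, 0.04, 0.03), driver_menu = drivers, seed = seed + 1L)
    ),
    dissonance = list(
      land = landscape_scenario(48, 48, epochs,
        c(forest = 0.75, shrubland = 0.1, cropland = 0.1, wetland = 0.05),
        kernel = churn_kernel, seed = seed + 2L),
      survey = survey_scenario(120, "dissonance",
        dp(0.95, 0.01, 0.02, 0.02), driver_menu = drivers, seed = seed + 3L)
    ),
    partial = list(
      land = landscape_scenario(48, 48, epochs,
        c(forest = 0.7, shrubland = 0.15, cropland = 0.15),
        kernel = loss_kernel, seed = seed + 4L),
      survey = survey_scenario(120, "partial",
        dp(0.35, 0.45, 0.12, 0.08), driver_menu = drivers, seed = seed + 5L)
    )
  )
  out <- list()
  for (nm in names(specs)) {
    pdir <- file.path(dir, nm)
    dir.create(pdir, showWarnings = FALSE)
    sim <- simulate_landscape_series(specs[[nm]]$land)
    for (r in sim$rasters) {
      write_lc_raster(r, file.path(pdir, sprintf("raster_%d.txt", as.integer(r$epoch))))
    }
    tab <- simulate_survey(specs[[nm]]$survey)
    utils::write.csv(tab, file.path(pdir, "survey.csv"), row.names = FALSE)
    out[[nm]] <- pdir
  }
  invisible(out)
}

#' Read one fixture patch directory back in
#'
#' @param pdir a patch directory written by [make_fixture_suite()].
#' @return list with `rasters` (epoch-ordered [lc_raster()]s) and `survey`
#'   (data frame).
#' @export
read_fixture_patch <- function(pdir) {
  grids <- sort(list.files(pdir, pattern = "^raster_\\d+\\.txt$",
                           full.names = TRUE))
  rasters <- lapply(grids, read_lc_raster)
  rasters <- rasters[order(vapply(rasters, function(r) r$epoch, numeric(1)))]
  survey <- utils::read.csv(file.path(pdir, "survey.csv"),
                            stringsAsFactors = FALSE)
  list(rasters = rasters, survey = survey)
}
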