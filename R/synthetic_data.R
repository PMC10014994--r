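#' Configure a synthetic community survey
#'
#' Describes the generating model of a quadrat survey: a species abundance
#' distribution (SAD) giving expected per-survey totals, an occupancy model
#' linking how many quadrats a species occupies to its abundance, a
#' life-form-specific cover model, and the sampling design (number and size of
#' quadrats, site extent, spatial placement). Defaults emulate the tropical
#' deciduous forest study design the package's fixtures come from: 29 species,
#' 54 randomly placed 100 m2 quadrats on a ~30.8 ha site, a lognormal SAD and
#' an abundance-linked occupancy fitted to the packaged structure table, and
#' per-life-form lognormal cover.
#'
#' @param n_species number of species.
#' @param n_units number of quadrats.
#' @param site_extent site width and height in metres (default ~555 m square,
#'   i.e. 30.8 ha).
#' @param unit_area quadrat area in m2.
#' @param sad list; `type` one of `"lognormal"` (`meanlog`, `sdlog`),
#'   `"geometric"` (`k`, `total`), `"equal"` (`total`), `"fixed"` (`values`,
#'   expected per-survey totals per species). Defaults to the lognormal MLE
#'   fit of the fixture's expected counts.
#' @param occupancy list; `type` `"logit_linear"` (`intercept`, `slope` on the
#'   logit of occupancy vs log expected abundance; defaults fitted to the
#'   fixture) or `"fixed"` (`p`, per-species occupancy probabilities).
#' @param cover_model list; `type` `"life_form"` (`params`: named list of
#'   `c(meanlog, sdlog)` per life form for per-individual cover in m2;
#'   defaults fitted to the fixtures) or `"fixed_species"` (`mean`: named
#'   per-species mean per-individual cover, `sdlog`: multiplicative noise).
#' @param spatial_mode list; `type` `"uniform_random"` or `"clustered"`
#'   (`n_parents`, `dispersion` in metres) controlling which quadrats a
#'   species occupies.
#' @param taxa optional taxon table to use verbatim (must have `n_species`
#'   rows); otherwise a synthetic taxon table is generated.
#' @param seed default seed for [generate_survey()].
#' @return list of class `community_config`.
#' @export
community_config <- function(n_species = 29,
                             n_units = 54,
                             site_extent = c(555, 555),
                             unit_area = 100,
                             sad = NULL,
                             occupancy = NULL,
                             cover_model = NULL,
                             spatial_mode = list(type = "uniform_random"),
                             taxa = NULL,
                             seed = NULL) {
  if (n_species < 1L || n_units < 1L || unit_area <= 0) {
    abort("n_species, n_units and unit_area must be positive")
  }
  side <- sqrt(unit_area)
  if (site_extent[1] < side || site_extent[2] < side ||
      prod(site_extent) < 2 * n_units * unit_area) {
    abort("site extent too small to place %d disjoint %.0f m2 quadrats",
          n_units, unit_area)
  }
  if (is.null(sad)) sad <- fitted_sad_defaults()
  if (is.null(occupancy)) occupancy <- fitted_occupancy_defaults()
  if (is.null(cover_model)) cover_model <- fitted_cover_defaults()
  if (!is.null(taxa) && nrow(taxa) != n_species) {
    abort("taxa must have exactly n_species = %d rows", n_species)
  }
  structure(list(n_species = as.integer(n_species),
                 n_units = as.integer(n_units),
                 site_extent = as.numeric(site_extent),
                 unit_area = as.numeric(unit_area),
                 sad = sad, occupancy = occupancy, cover_model = cover_model,
                 spatial_mode = spatial_mode, taxa = taxa, seed = seed),
            class = "community_config")
}

# expected per-survey counts implied by the fixture's ind/ha column on 0.54 ha
fixture_expected_counts <- function() {
  tab <- load_table2_structure()
  structure(tab$abundance_ind_ha * 0.54, names = tab$species_id)
}

fitted_sad_defaults <- function() {
  lc <- log(fixture_expected_counts())
  list(type = "lognormal", meanlog = mean(lc), sdlog = sd(lc))
}

fitted_occupancy_defaults <- function() {
  tab <- load_table2_structure()
  n <- fixture_expected_counts()
  p <- pmin(pmax(tab$sites / 54, 0.5 / 54), 1 - 0.5 / 54)
  fit <- stats::lm(stats::qlogis(p) ~ log(n))
  list(type = "logit_linear",
       intercept = unname(stats::coef(fit)[1L]),
       slope = unname(stats::coef(fit)[2L]))
}

fitted_cover_defaults <- function() {
  tab <- load_table2_structure()
  taxa <- load_table1_taxa()
  per_ind <- tab$dominance_m2_ha / tab$abundance_ind_ha  # m2 per individual
  lf <- taxa$life_form[match(tab$species_id, taxa$species_id)]
  params <- lapply(split(log(per_ind), lf), function(v) {
    c(meanlog = mean(v), sdlog = if (length(v) > 1L) sd(v) else 0.5)
  })
  # any life form absent from the fit falls back to the overall fit
  fallback <- c(meanlog = mean(log(per_ind)), sdlog = sd(log(per_ind)))
  for (f in setdiff(life_forms(), names(params))) params[[f]] <- fallback
  list(type = "life_form", params = params)
}

#' Study-calibrated generator preset
#'
#' A [community_config()] whose expected per-species totals, occupancy
#' probabilities and per-individual cover equal the values implied by the
#' packaged structure table (29 species over 54 quadrats of 100 m2 on a
#' 30.8 ha site), with the packaged taxon table. Replicates drawn from this
#' preset reproduce the fixture's relative-abundance ranking up to sampling
#' noise.
#'
#' @param seed default seed passed through to [generate_survey()].
#' @return a `community_config`.
#' @export
raboso_config <- function(seed = NULL) {
  tab <- load_table2_structure()
  taxa <- load_table1_taxa()
  taxa <- taxa[match(tab$species_id, taxa$species_id), , drop = FALSE]
  community_config(
    n_species = nrow(tab),
    n_units = 54,
    site_extent = c(555, 555),
    unit_area = 100,
    sad = list(type = "fixed", values = fixture_expected_counts()),
    occupancy = list(type = "fixed", p = pmin(tab$sites / 54, 1)),
    cover_model = list(type = "fixed_species",
                       mean = structure(tab$dominance_m2_ha /
                                          tab$abundance_ind_ha,
                                        names = tab$species_id),
                       sdlog = 0.3),
    spatial_mode = list(type = "uniform_random"),
    taxa = taxa,
    seed = seed)
}

#' Generate a synthetic quadrat survey
#'
#' Realises one survey from a [community_config()]: quadrats are placed at
#' random without overlap; each species' total count is Poisson around its SAD
#' expectation; occupied quadrats are drawn from the occupancy model (with
#' spatial clustering if configured); individuals are spread over the occupied
#' quadrats by multinomial allocation; per-individual cover areas are drawn
#' from the cover model. Deterministic given the seed.
#'
#' @param config a [community_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `dataset` (a validated [survey_dataset()]) and `truth`
#'   (the exact SAD expectations and draws, true SAD shares, true pooled H of
#'   the expectations, occupancy probabilities, and the expected per-quadrat
#'   species profile).
#' @export
generate_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "community_config"))
  if (is.null(seed)) abort("a seed is required (argument or config$seed)")
  with_seed(seed, generate_survey_impl(config, seed))
}

generate_survey_impl <- function(config, seed) {
  ns <- config$n_species
  nu <- config$n_units
  taxa <- if (is.null(config$taxa)) synth_taxa(ns) else config$taxa
  units <- place_units(nu, config$site_extent, config$unit_area)

  lambda <- draw_sad(config$sad, ns)
  names(lambda) <- taxa$species_id
  p_occ <- occupancy_probs(config$occupancy, lambda, nu)

  obs_list <- vector("list", ns)
  for (i in seq_len(ns)) {
    n_i <- rpois(1L, lambda[[i]])
    if (n_i == 0L) next
    w <- unit_weights(config$spatial_mode, units, config$site_extent)
    k <- max(1L, min(rbinom(1L, nu, p_occ[[i]]), n_i))
    occ <- if (k == nu) seq_len(nu) else sample.int(nu, k, prob = w)
    counts <- as.vector(rmultinom(1L, n_i, rep(1, k)))
    keep <- counts > 0L
    if (!any(keep)) next
    covers <- draw_covers(config$cover_model, taxa, i, counts[keep])
    obs_list[[i]] <- data.frame(unit_id = units$unit_id[occ[keep]],
                                species_id = taxa$species_id[[i]],
                                count = counts[keep],
                                cover_m2 = covers,
                                crown_d1_m = NA_real_, crown_d2_m = NA_real_,
                                stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, obs_list[!vapply(obs_list, is.null, logical(1))])
  if (is.null(obs)) {
    obs <- data.frame(unit_id = character(), species_id = character(),
                      count = numeric(), cover_m2 = numeric(),
                      crown_d1_m = numeric(), crown_d2_m = numeric(),
                      stringsAsFactors = FALSE)
  }
  dataset <- survey_dataset(units, obs, taxa)
  truth <- list(seed = as.integer(seed),
                lambda = lambda,
                shares = lambda / sum(lambda),
                true_pooled_h = shannon(lambda),
                occupancy = p_occ,
                expected_unit_profile = lambda / nu,
                n_obs = nrow(dataset$observations),
                total_count = sum(dataset$observations$count))
  list(dataset = dataset, truth = truth)
}

synth_taxa <- function(ns) {
  # life-form mix follows the study community (13:9:4:2:1 over 29 species)
  lf <- sample(life_forms(), ns, replace = TRUE,
               prob = c(13, 9, 4, 2, 1) / 29)
  genus <- sprintf("Genus%02d", seq_len(ns))
  data.frame(species_id = sprintf("sp%02d", seq_len(ns)),
             scientific_name = paste(genus, "synthetica"),
             common_name = sprintf("synthetic species %d", seq_len(ns)),
             genus = genus,
             family = sprintf("Family%02d", ceiling(seq_len(ns) / 3)),
             life_form = lf,
             stringsAsFactors = FALSE)
}

place_units <- function(nu, extent, unit_area) {
  side <- sqrt(unit_area)
  half <- side / 2
  xs <- numeric(nu); ys <- numeric(nu)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 1000L * nu
  while (placed < nu) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort("could not place %d disjoint quadrats in a %.0f x %.0f m site",
            nu, extent[1], extent[2])
    }
    x <- runif(1L, half, extent[1] - half)
    y <- runif(1L, half, extent[2] - half)
    if (placed == 0L ||
        all(pmax(abs(xs[seq_len(placed)] - x),
                 abs(ys[seq_len(placed)] - y)) >= side)) {
      placed <- placed + 1L
      xs[placed] <- x
      ys[placed] <- y
    }
  }
  data.frame(unit_id = sprintf("q%02d", seq_len(nu)), x = xs, y = ys,
             area_m2 = unit_area, stringsAsFactors = FALSE)
}

draw_sad <- function(sad, ns) {
  switch(sad$type,
    lognormal = rlnorm(ns, sad$meanlog, sad$sdlog),
    geometric = {
      w <- sad$k * (1 - sad$k)^(seq_len(ns) - 1L)
      sad$total * w / sum(w)
    },
    equal = rep(sad$total / ns, ns),
    fixed = {
      if (length(sad$values) != ns) abort("sad$values must have n_species entries")
      as.numeric(sad$values)
    },
    abort("unknown SAD type '%s'", sad$type))
}

occupancy_probs <- function(occupancy, lambda, nu) {
  p <- switch(occupancy$type,
    logit_linear = stats::plogis(occupancy$intercept +
                                   occupancy$slope * log(pmax(lambda, 1e-9))),
    fixed = rep_len(as.numeric(occupancy$p), length(lambda)),
    abort("unknown occupancy type '%s'", occupancy$type))
  pmin(pmax(p, 1 / nu), 1)
}

unit_weights <- function(spatial_mode, units, extent) {
  if (spatial_mode$type == "uniform_random") return(rep(1, nrow(units)))
  if (spatial_mode$type != "clustered") {
    abort("unknown spatial mode '%s'", spatial_mode$type)
  }
  np <- spatial_mode$n_parents
  disp <- spatial_mode$dispersion
  pxy <- cbind(runif(np, 0, extent[1]), runif(np, 0, extent[2]))
  d2 <- vapply(seq_len(nrow(units)), function(u) {
    min((units$x[u] - pxy[, 1L])^2 + (units$y[u] - pxy[, 2L])^2)
  }, numeric(1))
  exp(-d2 / (2 * disp^2)) + 1e-9
}

draw_covers <- function(cover_model, taxa, i, counts) {
  if (cover_model$type == "life_form") {
    par <- cover_model$params[[taxa$life_form[[i]]]]
    meanlog <- par[["meanlog"]]; sdlog <- par[["sdlog"]]
  } else if (cover_model$type == "fixed_species") {
    m <- cover_model$mean[[taxa$species_id[[i]]]]
    sdlog <- cover_model$sdlog
    meanlog <- log(m) - sdlog^2 / 2  # mean-preserving multiplicative noise
  } else {
    abort("unknown cover model type '%s'", cover_model$type)
  }
  vapply(counts, function(k) sum(rlnorm(k, meanlog, sdlog)), numeric(1))
}

#' Compare a synthetic survey against its generating truth
#'
#' Single-replicate recovery metrics: error of the pooled Shannon index
#' against the H of the true SAD expectations, and bias/RMSE of the observed
#' relative-abundance shares against the true SAD shares (percentage points).
#'
#' @param dataset the `dataset` element returned by [generate_survey()].
#' @param truth the matching `truth` element.
#' @return list with `pooled_h_obs`, `pooled_h_true`, `pooled_h_error`,
#'   `ar_bias_pp`, `ar_rmse_pp`.
#' @export
truth_recovery_report <- function(dataset, truth) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (nrow(dataset$observations) != truth$n_obs ||
      sum(dataset$observations$count) != truth$total_count) {
    abort("dataset does not match the supplied truth record")
  }
  counts <- species_totals(dataset, dataset$observations$count)
  counts <- counts[names(truth$shares)]
  obs_shares <- counts / sum(counts)
  pooled <- shannon(as.numeric(counts))
  err <- 100 * (obs_shares - truth$shares)
  list(pooled_h_obs = pooled,
       pooled_h_true = truth$true_pooled_h,
       pooled_h_error = pooled - truth$true_pooled_h,
       ar_bias_pp = mean(err),
       ar_rmse_pp = sqrt(mean(err^2)))
}

#' Replicated recovery and bootstrap-coverage experiment
#'
#' Generates `n_reps` independent surveys from one configuration and measures
#' (i) bias and RMSE of the pooled Shannon index against the per-replicate
#' truth, and (ii) empirical coverage of the bootstrap confidence interval for
#' the mean per-unit H. The population mean per-unit H (the coverage target)
#' is estimated by Monte Carlo from `truth_reps` additional replicates drawn
#' on a disjoint seed stream.
#'
#' @param config a [community_config()].
#' @param n_reps number of evaluation replicates (default 200).
#' @param B,alpha bootstrap settings (defaults 1000, 0.05).
#' @param seed base integer seed; replicate seeds are derived from it.
#' @param truth_reps replicates used for the Monte-Carlo truth (default 200).
#' @return list with `coverage`, `n_reps`, `truth_mean_h`, `mean_ci_width`,
#'   `pooled_h_bias`, `pooled_h_rmse`.
#' @export
replicate_recovery <- function(config, n_reps = 200, B = 1000, alpha = 0.05,
                               seed, truth_reps = 200) {
  if (missing(seed)) abort("a base seed is required")
  mean_unit_h <- function(s) {
    g <- generate_survey(config, seed = s)
    h <- suppressWarnings(per_unit_diversity(g$dataset))
    list(h = h$per_unit$H, g = g)
  }
  truth_h <- vapply(seq_len(truth_reps), function(j) {
    mean(mean_unit_h(seed + 500000L + j)$h)
  }, numeric(1))
  truth_mean_h <- mean(truth_h)

  covered <- logical(n_reps)
  widths <- numeric(n_reps)
  ph_err <- numeric(n_reps)
  for (j in seq_len(n_reps)) {
    rep_j <- mean_unit_h(seed + j)
    ci <- bootstrap_mean_ci(rep_j$h, B = B, alpha = alpha,
                            seed = seed + 250000L + j)
    covered[j] <- ci$ci_low <= truth_mean_h && truth_mean_h <= ci$ci_high
    widths[j] <- ci$width
    ph_err[j] <- truth_recovery_report(rep_j$g$dataset,
                                       rep_j$g$truth)$pooled_h_error
  }
  list(coverage = mean(covered), n_reps = n_reps,
       truth_mean_h = truth_mean_h, mean_ci_width = mean(widths),
       pooled_h_bias = mean(ph_err), pooled_h_rmse = sqrt(mean(ph_err^2)))
}
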