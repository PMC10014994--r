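test_that("the generator is deterministic given a seed and always validates", {
  cfg <- small_config()
  a <- generate_survey(cfg, seed = 5)
  b <- generate_survey(cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$dataset, generate_survey(cfg, seed = 6)$dataset))
  expect_s3_class(a$dataset, "survey_dataset")  # constructor validated it

  # a generated survey survives a CSV round trip unchanged
  tmp <- withr_like_tempdir()
  p <- file.path(tmp, c("u.csv", "o.csv", "t.csv"))
  write_survey(a$dataset, p[1], p[2], p[3])
  expect_equal(read_survey(p[1], p[2], p[3]), a$dataset)
})

test_that("degenerate communities hit their analytic limits", {
  # one species: every unit is a monoculture, IVI concentrates fully
  cfg1 <- community_config(n_species = 1, n_units = 6,
                           site_extent = c(150, 150),
                           sad = list(type = "equal", total = 300),
                           occupancy = list(type = "fixed", p = 1),
                           spatial_mode = list(type = "uniform_random"))
  g1 <- generate_survey(cfg1, seed = 3)
  div1 <- suppressWarnings(per_unit_diversity(g1$dataset))
  expect_true(all(div1$per_unit$H == 0))
  expect_equal(ivi_table(g1$dataset)$ivi, 100)

  # equal SAD with full occupancy: pooled H approaches ln(n_species)
  cfg_eq <- community_config(n_species = 12, n_units = 20,
                             site_extent = c(300, 300),
                             sad = list(type = "equal", total = 4000),
                             occupancy = list(type = "fixed", p = 1),
                             spatial_mode = list(type = "uniform_random"))
  g <- generate_survey(cfg_eq, seed = 11)
  expect_equal(g$truth$true_pooled_h, log(12), tolerance = 1e-12)
  div <- suppressWarnings(per_unit_diversity(g$dataset))
  expect_lt(abs(div$pooled_h - log(12)), 0.02)
  expect_true(all(div$per_unit$H <= log(12) + 1e-12))
})

test_that("site-calibrated preset reproduces the fixture's abundance structure", {
  tab <- load_table2_structure()
  target_ar <- relative_shares(tab$abundance_ind_ha)
  names(target_ar) <- tab$species_id
  top5 <- tab$species_id[1:5]
  seeds <- c(2, 9, 23, 31, 44, 57, 68, 75)
  ar_by_seed <- sapply(seeds, function(s) {
    g <- generate_survey(raboso_config(), seed = s)
    expect_equal(nrow(g$dataset$units), 54)
    expect_equal(nrow(g$dataset$taxa), 29)
    expect_equal(unique(g$dataset$units$area_m2), 100)
    ivi <- ivi_table(g$dataset)
    # the dominant succulent keeps its rank in every replicate
    expect_equal(ivi$species_id[which.max(ivi$AR)], "opuntia_streptacantha")
    structure(ivi$AR, names = ivi$species_id)[top5]
  })
  # calibration: mean AR across seeds tracks the fixture's shares
  expect_lt(max(abs(rowMeans(ar_by_seed) - target_ar[top5])), 2)
})

test_that("evener abundance distributions raise mean per-unit diversity", {
  mean_h <- function(sdlog, seed) {
    cfg <- community_config(n_species = 10, n_units = 15,
                            site_extent = c(250, 250),
                            sad = list(type = "lognormal", meanlog = 3,
                                       sdlog = sdlog),
                            occupancy = list(type = "fixed", p = 0.8),
                            spatial_mode = list(type = "uniform_random"))
    g <- generate_survey(cfg, seed = seed)
    mean(suppressWarnings(per_unit_diversity(g$dataset))$per_unit$H)
  }
  seeds <- 1:20
  h_uneven <- vapply(seeds, function(s) mean_h(2.0, s), numeric(1))
  h_mid <- vapply(seeds, function(s) mean_h(1.0, s), numeric(1))
  h_even <- vapply(seeds, function(s) mean_h(0.1, s), numeric(1))
  expect_lt(mean(h_uneven), mean(h_mid))
  expect_lt(mean(h_mid), mean(h_even))
  wt <- stats::wilcox.test(h_uneven, h_even, paired = TRUE,
                           alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("truth recovery reports errors against the generating model", {
  g <- generate_survey(small_config(), seed = 17)
  rep1 <- truth_recovery_report(g$dataset, g$truth)
  expect_true(is.finite(rep1$pooled_h_error))
  expect_gte(rep1$ar_rmse_pp, 0)
  expect_equal(rep1$pooled_h_obs - rep1$pooled_h_true, rep1$pooled_h_error)

  other <- generate_survey(small_config(), seed = 18)
  expect_error(truth_recovery_report(g$dataset, other$truth),
               "does not match")
})

test_that("pooled H from equal-SAD replicates is nearly unbiased", {
  cfg <- community_config(n_species = 29, n_units = 54,
                          site_extent = c(555, 555),
                          sad = list(type = "equal", total = 968),
                          occupancy = list(type = "fixed", p = 0.6),
                          spatial_mode = list(type = "uniform_random"))
  errs <- vapply(1:60, function(s) {
    g <- generate_survey(cfg, seed = 3000 + s)
    truth_recovery_report(g$dataset, g$truth)$pooled_h_error
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("clustered placement concentrates a species in fewer, nearby units", {
  cfg <- community_config(n_species = 4, n_units = 40,
                          site_extent = c(600, 600),
                          sad = list(type = "equal", total = 800),
                          occupancy = list(type = "fixed", p = 0.3),
                          spatial_mode = list(type = "clustered",
                                              n_parents = 2, dispersion = 60))
  g <- generate_survey(cfg, seed = 9)
  expect_s3_class(g$dataset, "survey_dataset")
  expect_gt(nrow(g$dataset$observations), 0)

  # occupied units are spatially closer together than the full design
  units <- g$dataset$units
  obs <- g$dataset$observations
  sp <- names(which.max(table(obs$species_id)))
  occ <- units[units$unit_id %in% obs$unit_id[obs$species_id == sp], ]
  mean_d <- function(df) mean(dist(cbind(df$x, df$y)))
  expect_lt(mean_d(occ), mean_d(units))
})

test_that("infeasible configurations are rejected", {
  expect_error(community_config(n_units = 54, site_extent = c(50, 50)),
               "too small")
  expect_error(generate_survey(small_config()), "seed")
})
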