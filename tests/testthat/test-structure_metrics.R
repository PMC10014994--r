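test_that("crown area treats the mean of two crosswise diameters as a circle", {
  expect_equal(crown_area(2, 2), pi)
  expect_equal(crown_area(3, 5), pi * 4)
  expect_error(crown_area(0, 2), "positive")
  expect_error(crown_area(2, -1), "positive")
})

test_that("absolute abundance, site counts and dominance follow their definitions", {
  ds <- tiny_dataset()  # 3 units of 100 m2 -> 0.03 ha
  a <- absolute_abundance(ds)
  expect_equal(unname(a["sp_a"]), 7 / 0.03)
  expect_equal(unname(a["sp_b"]), 3 / 0.03)

  sc <- site_counts(ds)
  expect_equal(sc$sites[sc$species_id == "sp_a"], 2)
  expect_equal(sc$frequency[sc$species_id == "sp_c"], 2 / 3)

  d <- absolute_dominance(ds)
  # sp_a: 12 m2 explicit + 2 individuals of crown diameter 2 -> 2 * pi
  expect_equal(unname(d["sp_a"]), (12 + 2 * pi) / 0.03)
  expect_equal(unname(d["sp_c"]), (30 + 8) / 0.03)

  # a species in the taxon list but never observed scores zero abundance
  extra <- rbind(tiny_taxa(),
                 data.frame(species_id = "sp_d", scientific_name = "Delta dura",
                            common_name = "delta", genus = "Delta",
                            family = "Famtwo", life_form = "climber"))
  ds2 <- survey_dataset(tiny_units(), ds$observations, extra)
  expect_equal(unname(absolute_abundance(ds2)["sp_d"]), 0)

  # zero-cover seedling contributes to abundance but not dominance
  ds3 <- survey_dataset(tiny_units(),
                        rbind(ds$observations, obs_row("u3", "sp_a", 2, 0)),
                        tiny_taxa())
  expect_equal(unname(absolute_abundance(ds3)["sp_a"]), 9 / 0.03)
  expect_equal(unname(absolute_dominance(ds3)["sp_a"]), (12 + 2 * pi) / 0.03)
})

test_that("relative shares normalise to 100 and reject degenerate input", {
  expect_equal(relative_shares(5), 100)
  expect_equal(sum(relative_shares(c(3, 1, 6))), 100)
  expect_error(relative_shares(c(0, 0)), "zero")
  expect_error(relative_shares(c(1, -1)), "nonnegative")
})

test_that("ivi table matches hand-computed shares on the published structure", {
  tab <- load_table2_structure()
  taxa <- load_table1_taxa()
  ivi <- ivi_table(tab, taxa = taxa)

  expect_equal(ivi$scientific_name[1], "Opuntia streptacantha")
  row_op <- ivi[ivi$species_id == "opuntia_streptacantha", ]
  expect_equal(row_op$AR, 609 / 1794 * 100)
  expect_equal(row_op$FR, 49 / 343 * 100)
  expect_equal(row_op$ivi_raw, row_op$AR + row_op$FR + row_op$DR)
  expect_equal(row_op$ivi, row_op$ivi_raw / 3)

  # printed relative columns recovered within the rounding tolerance
  printed_ar <- c(opuntia_streptacantha = 34.0, ipomoea_wolcottiana = 4.1,
                  bursera_copallifera = 0.8, echinocactus_platyacanthus = 8.3)
  printed_fr <- c(opuntia_streptacantha = 14.3, ipomoea_wolcottiana = 8.7,
                  bursera_copallifera = 2.3)
  printed_dr <- c(ipomoea_wolcottiana = 20.2, ceiba_aesculifolia = 17.7)
  for (sp in names(printed_ar)) {
    expect_lt(abs(ivi$AR[ivi$species_id == sp] - printed_ar[[sp]]), 0.1 + 1e-9)
  }
  for (sp in names(printed_fr)) {
    expect_lt(abs(ivi$FR[ivi$species_id == sp] - printed_fr[[sp]]), 0.1 + 1e-9)
  }
  for (sp in names(printed_dr)) {
    expect_lt(abs(ivi$DR[ivi$species_id == sp] - printed_dr[[sp]]), 0.1 + 1e-9)
  }
})

test_that("ivi from a raw dataset equals ivi from its aggregated absolute table", {
  ds <- tiny_dataset()
  from_ds <- ivi_table(ds)
  abs_tab <- data.frame(species_id = ds$taxa$species_id,
                        abundance_ind_ha = as.numeric(absolute_abundance(ds)),
                        sites = site_counts(ds)$sites,
                        dominance_m2_ha = as.numeric(absolute_dominance(ds)))
  from_tab <- ivi_table(abs_tab, taxa = ds$taxa, n_units = nrow(ds$units))
  expect_identical(as.data.frame(from_ds), as.data.frame(from_tab))
})

test_that("relative columns sum to 100 and are invariant to rescaling areas", {
  for (s in 1:6) {
    g <- generate_survey(small_config(), seed = s)
    ivi <- ivi_table(g$dataset)
    for (col in c("AR", "FR", "DR", "ivi")) {
      expect_equal(sum(ivi[[col]]), 100, tolerance = 1e-9)
    }
    expect_equal(sum(ivi$ivi_raw), 300, tolerance = 1e-9)

    scaled_units <- g$dataset$units
    scaled_units$area_m2 <- scaled_units$area_m2 * 7
    ds2 <- survey_dataset(scaled_units, g$dataset$observations,
                          g$dataset$taxa)
    ivi2 <- ivi_table(ds2)
    expect_equal(ivi2$AR, ivi$AR)
    expect_equal(ivi2$FR, ivi$FR)
    expect_equal(ivi2$DR, ivi$DR)
    expect_equal(ivi2$ivi, ivi$ivi)
    expect_equal(ivi2$A, ivi$A / 7)
    expect_equal(ivi2$D, ivi$D / 7)
  }
})

test_that("single-species community takes the whole importance value", {
  ds <- survey_dataset(tiny_units(), obs_row("u1", "sp_a", 4, 10),
                       tiny_taxa()[1, ])
  ivi <- ivi_table(ds)
  expect_equal(ivi$ivi_raw, 300)
  expect_equal(ivi$ivi, 100)
})

test_that("family aggregation reproduces the published family totals", {
  ivi <- ivi_table(load_table2_structure(), taxa = load_table1_taxa())
  fam <- family_ivi(ivi, load_table1_taxa())
  expect_equal(fam$ivi[fam$family == "Burseraceae"], 8.8)
  expect_equal(fam$family[1], "Fabaceae")
  expect_equal(sum(fam$n_species), 29)

  # full-precision aggregation still sums to 100 over families
  fam_full <- family_ivi(ivi, load_table1_taxa(), digits = NULL)
  expect_equal(sum(fam_full$ivi), 100, tolerance = 1e-9)

  # all species in one family -> 100%
  taxa1 <- load_table1_taxa()
  taxa1$family <- "OneFam"
  expect_equal(family_ivi(ivi, taxa1, digits = NULL)$ivi, 100,
               tolerance = 1e-9)

  expect_error(family_ivi(ivi, load_table1_taxa()[-1, ]), "missing")
})
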