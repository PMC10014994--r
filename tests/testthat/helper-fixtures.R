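# small in-code fixtures shared across test files

tiny_taxa <- function() {
  data.frame(
    species_id = c("sp_a", "sp_b", "sp_c"),
    scientific_name = c("Alpha alba", "Beta brevis", "Gamma grandis"),
    common_name = c("alpha", "beta", "gamma"),
    genus = c("Alpha", "Beta", "Gamma"),
    family = c("Famone", "Famone", "Famtwo"),
    life_form = c("tree", "shrub", "succulent"),
    stringsAsFactors = FALSE)
}

tiny_units <- function(n = 3, area = 100) {
  data.frame(unit_id = sprintf("u%d", seq_len(n)),
             x = seq_len(n) * 50, y = rep(10, n), area_m2 = area,
             stringsAsFactors = FALSE)
}

obs_row <- function(unit, sp, count, cover = NA, d1 = NA, d2 = NA) {
  data.frame(unit_id = unit, species_id = sp, count = count,
             cover_m2 = cover, crown_d1_m = d1, crown_d2_m = d2,
             stringsAsFactors = FALSE)
}

tiny_dataset <- function() {
  obs <- rbind(obs_row("u1", "sp_a", 5, cover = 12),
               obs_row("u1", "sp_b", 3, cover = 4),
               obs_row("u2", "sp_a", 2, d1 = 2, d2 = 2),
               obs_row("u2", "sp_c", 1, cover = 30),
               obs_row("u3", "sp_c", 4, cover = 8))
  survey_dataset(tiny_units(), obs, tiny_taxa())
}

# any 54-vector with exactly the requested sample mean and sd
surrogate_sample <- function(n = 54, target_mean = 1.44759,
                             target_sd = 0.422139, seed = 1) {
  v <- vegstruct:::with_seed(seed, rnorm(n))
  (v - mean(v)) / sd(v) * target_sd + target_mean
}

withr_like_tempdir <- function() {
  d <- tempfile("vegstruct-test-")
  dir.create(d)
  d
}

# small fast generator configuration for property loops
small_config <- function(n_species = 8, n_units = 12) {
  community_config(
    n_species = n_species, n_units = n_units,
    site_extent = c(200, 200), unit_area = 100,
    sad = list(type = "lognormal", meanlog = 3, sdlog = 1),
    occupancy = list(type = "logit_linear", intercept = -2, slope = 0.5),
    spatial_mode = list(type = "uniform_random"))
}
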