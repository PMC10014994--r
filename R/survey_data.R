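#' Assemble and validate a quadrat survey dataset
#'
#' Bundles the three tables of a quadrat vegetation survey — sampling units,
#' per-unit species observations, and the taxon table — into a validated
#' `survey_dataset` object, the input of every analysis stage.
#'
#' Validation enforces: unique unit ids with positive quadrat areas; integer
#' counts of at least 1; every observation carrying a cover area and/or a pair
#' of crown diameters; and referential integrity of observation unit and
#' species ids. Duplicate `(unit_id, species_id)` observation rows are summed
#' (counts add, resolved cover areas add) with a warning — field sheets
#' commonly split tallies. A genus that is not the first token of the
#' scientific name raises a warning, not an error.
#'
#' @param units data.frame with columns `unit_id`, `x`, `y`, `area_m2`
#'   (planar metres / square metres; any projected CRS).
#' @param observations data.frame with columns `unit_id`, `species_id`,
#'   `count`, `cover_m2`, `crown_d1_m`, `crown_d2_m` (the last three may be
#'   `NA` row-wise, subject to the cover-or-diameters rule).
#' @param taxa data.frame with columns `species_id`, `scientific_name`,
#'   `common_name`, `genus`, `family`, `life_form`.
#' @return an object of class `survey_dataset`: a list with elements `units`,
#'   `observations`, `taxa`.
#' @seealso [read_survey()], [write_survey()], [ivi_table()],
#'   [per_unit_diversity()]
#' @export
survey_dataset <- function(units, observations, taxa) {
  units <- as.data.frame(units)
  observations <- as.data.frame(observations)
  taxa <- as.data.frame(taxa)

  check_columns(units, c("unit_id", "x", "y", "area_m2"), "units")
  check_columns(observations,
                c("unit_id", "species_id", "count", "cover_m2",
                  "crown_d1_m", "crown_d2_m"), "observations")
  check_columns(taxa,
                c("species_id", "scientific_name", "common_name", "genus",
                  "family", "life_form"), "taxa")

  units$unit_id <- as.character(units$unit_id)
  taxa$species_id <- as.character(taxa$species_id)
  observations$unit_id <- as.character(observations$unit_id)
  observations$species_id <- as.character(observations$species_id)
  for (col in c("count", "cover_m2", "crown_d1_m", "crown_d2_m")) {
    observations[[col]] <- as.numeric(observations[[col]])
  }

  if (anyDuplicated(units$unit_id)) {
    abort("units: duplicated unit_id: %s",
          paste(unique(units$unit_id[duplicated(units$unit_id)]),
                collapse = ", "))
  }
  if (any(!is.finite(units$area_m2)) || any(units$area_m2 <= 0)) {
    abort("units: area_m2 must be positive and finite")
  }
  if (anyDuplicated(taxa$species_id)) {
    abort("taxa: duplicated species_id: %s",
          paste(unique(taxa$species_id[duplicated(taxa$species_id)]),
                collapse = ", "))
  }
  bad_lf <- setdiff(unique(taxa$life_form), life_forms())
  if (length(bad_lf) > 0L) {
    abort("taxa: unknown life_form value(s): %s", paste(bad_lf, collapse = ", "))
  }
  first_token <- sub("\\s.*$", "", taxa$scientific_name)
  off <- taxa$genus != first_token
  if (any(off)) {
    warning(sprintf("taxa: genus does not match first token of scientific_name for: %s",
                    paste(taxa$species_id[off], collapse = ", ")),
            call. = FALSE)
  }

  if (nrow(observations) > 0L) {
    unknown_u <- setdiff(observations$unit_id, units$unit_id)
    if (length(unknown_u) > 0L) {
      abort("observations reference unknown unit_id(s): %s",
            paste(unknown_u, collapse = ", "))
    }
    unknown_s <- setdiff(observations$species_id, taxa$species_id)
    if (length(unknown_s) > 0L) {
      abort("observations reference unknown species_id(s): %s",
            paste(unknown_s, collapse = ", "))
    }
    if (any(!is.finite(observations$count)) ||
        any(observations$count < 1) ||
        any(observations$count != round(observations$count))) {
      abort("observations: count must be an integer >= 1 in every row")
    }
    has_cover <- !is.na(observations$cover_m2)
    has_diam <- !is.na(observations$crown_d1_m) & !is.na(observations$crown_d2_m)
    if (any(!has_cover & !has_diam)) {
      bad <- which(!has_cover & !has_diam)
      abort("observations: row(s) %s have neither cover_m2 nor both crown diameters",
            paste(bad, collapse = ", "))
    }
    if (any(has_cover & observations$cover_m2 < 0)) {
      abort("observations: cover_m2 must be >= 0")
    }
    observations <- aggregate_observations(observations)
  }

  # deterministic row order regardless of input ordering
  units <- units[order(units$unit_id), , drop = FALSE]
  taxa <- taxa[order(taxa$species_id), , drop = FALSE]
  if (nrow(observations) > 0L) {
    observations <- observations[order(observations$unit_id,
                                       observations$species_id), , drop = FALSE]
  }
  rownames(units) <- rownames(taxa) <- rownames(observations) <- NULL

  structure(list(units = units, observations = observations, taxa = taxa),
            class = "survey_dataset")
}

life_forms <- function() {
  c("tree", "shrub", "succulent", "acaulescent_rosette", "climber")
}

# sum duplicate (unit, species) rows: counts add, resolved covers add;
# merged rows lose their crown diameters (cover already resolved)
aggregate_observations <- function(obs) {
  key <- paste(obs$unit_id, obs$species_id, sep = "\r")
  if (!anyDuplicated(key)) return(obs)
  warning("duplicate (unit_id, species_id) observation rows summed",
          call. = FALSE)
  dup_keys <- unique(key[duplicated(key)])
  keep <- obs[!(key %in% dup_keys), , drop = FALSE]
  merged <- lapply(dup_keys, function(k) {
    g <- obs[key == k, , drop = FALSE]
    data.frame(unit_id = g$unit_id[[1L]],
               species_id = g$species_id[[1L]],
               count = sum(g$count),
               cover_m2 = sum(vapply(seq_len(nrow(g)), function(i)
                 resolve_cover_row(g[i, ]), numeric(1))),
               crown_d1_m = NA_real_, crown_d2_m = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- rbind(keep, do.call(rbind, merged))
  rownames(out) <- NULL
  out
}

# one observation row -> cover area in m2 (explicit cover wins over diameters)
resolve_cover_row <- function(row) {
  if (!is.na(row$cover_m2)) return(row$cover_m2)
  row$count * crown_area(row$crown_d1_m, row$crown_d2_m)
}

# vectorised cover resolution over an observation table
resolved_covers <- function(obs) {
  covers <- obs$cover_m2
  need <- is.na(covers)
  if (any(need)) {
    covers[need] <- obs$count[need] *
      crown_area(obs$crown_d1_m[need], obs$crown_d2_m[need])
  }
  covers
}

#' Read a survey from its three CSV files
#'
#' CSV dialect: UTF-8, comma-separated, headers exactly
#' `unit_id,x,y,area_m2`, `unit_id,species_id,count,cover_m2,crown_d1_m,crown_d2_m`
#' and `species_id,scientific_name,common_name,genus,family,life_form`.
#' A missing required column is a format error naming the column; unknown
#' unit/species references are referential errors listing the offenders.
#'
#' @param units_path,observations_path,taxa_path paths to the three CSVs.
#' @return a validated [survey_dataset()].
#' @export
read_survey <- function(units_path, observations_path, taxa_path) {
  for (p in c(units_path, observations_path, taxa_path)) {
    if (!file.exists(p)) abort("file not found: %s", p)
  }
  units <- read.csv(units_path, stringsAsFactors = FALSE)
  observations <- read.csv(observations_path, stringsAsFactors = FALSE,
                           colClasses = c(unit_id = "character",
                                          species_id = "character"))
  taxa <- read.csv(taxa_path, stringsAsFactors = FALSE)
  survey_dataset(units, observations, taxa)
}

#' Write a survey to the three-CSV interchange format
#'
#' Emits the same dialect [read_survey()] consumes, so read-write-read
#' round-trips to an identical dataset.
#'
#' @param dataset a [survey_dataset()].
#' @param units_path,observations_path,taxa_path output paths.
#' @return invisibly, the dataset.
#' @export
write_survey <- function(dataset, units_path, observations_path, taxa_path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  write.csv(dataset$units, units_path, row.names = FALSE, quote = FALSE)
  write.csv(dataset$observations, observations_path, row.names = FALSE,
            quote = FALSE)
  write.csv(dataset$taxa, taxa_path, row.names = FALSE, quote = FALSE)
  invisible(dataset)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("survey_dataset: %d sampling units (%.2f ha), %d taxa, %d observations\n",
              nrow(x$units), sampled_area_ha(x), nrow(x$taxa),
              nrow(x$observations)))
  invisible(x)
}

#' Total sampled area in hectares
#'
#' @param dataset a [survey_dataset()].
#' @return sum of quadrat areas, in ha.
#' @export
sampled_area_ha <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  sum(dataset$units$area_m2) / 1e4
}

#' Summarise a taxon table
#'
#' Counts of distinct species, genera and families, plus per-family species
#' and genus tallies (sorted by species count descending, then family name).
#'
#' @param taxa a taxon table data.frame (or a [survey_dataset()], whose `taxa`
#'   element is used).
#' @return a list with `n_species`, `n_genera`, `n_families`, and `per_family`
#'   (data.frame `family`, `n_species`, `n_genera`).
#' @export
taxon_summary <- function(taxa) {
  if (inherits(taxa, "survey_dataset")) taxa <- taxa$taxa
  if (nrow(taxa) == 0L) abort("taxon table is empty")
  per_family <- do.call(rbind, lapply(split(taxa, taxa$family), function(g) {
    data.frame(family = g$family[[1L]], n_species = length(unique(g$species_id)),
               n_genera = length(unique(g$genus)), stringsAsFactors = FALSE)
  }))
  per_family <- per_family[order(-per_family$n_species, per_family$family), ,
                           drop = FALSE]
  rownames(per_family) <- NULL
  list(n_species = length(unique(taxa$species_id)),
       n_genera = length(unique(taxa$genus)),
       n_families = length(unique(taxa$family)),
       per_family = per_family)
}

#' Packaged taxon-table fixture
#'
#' The 29-species taxon list of a tropical deciduous forest community in the
#' upper Balsas watershed (Puebla, Mexico) surveyed under copal-resin
#' extraction pressure: 11 families, 21 genera, five life forms. Species ids
#' use the canonical (alphabetical-list) spellings; the companion structure
#' table's variant spellings are normalised to these.
#'
#' @return taxon table data.frame (29 rows).
#' @export
load_table1_taxa <- function() {
  read.csv(system.file("extdata", "table1_taxa.csv", package = "vegstruct",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Packaged structure-table fixture (absolute columns)
#'
#' Per-species absolute structure of the same community: abundance in
#' individuals per hectare, number of occupied sampling units (of 54), and
#' canopy-cover dominance in m2 per hectare. Only the absolute columns are
#' stored; relative shares and the Importance Value Index are always
#' recomputed (see [ivi_table()]). The printed per-species abundances are
#' rounded, so the column sums to 1794 rather than the published total of
#' 1793, and the dominance column sums to 4557.7 against a published 4557.8;
#' the sites column sums exactly to 343.
#'
#' @return data.frame with columns `species_id`, `abundance_ind_ha`, `sites`,
#'   `dominance_m2_ha` (29 rows, descending IVI order).
#' @export
load_table2_structure <- function() {
  read.csv(system.file("extdata", "table2_structure.csv",
                       package = "vegstruct", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
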