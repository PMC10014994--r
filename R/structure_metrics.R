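#' Crown area from two crosswise diameter measurements
#'
#' The canopy of a tree is treated as a circle whose diameter is the mean of
#' two crosswise tape measurements: area = pi * ((d1 + d2) / 4)^2.
#'
#' @param d1,d2 crown diameters in metres (vectorised).
#' @return crown area in m2.
#' @export
#' @examples
#' crown_area(2, 2)   # pi
#' crown_area(3, 5)   # pi * 4
crown_area <- function(d1, d2) {
  if (any(!is.finite(d1)) || any(!is.finite(d2)) || any(d1 <= 0) || any(d2 <= 0)) {
    abort("crown diameters must be positive and finite")
  }
  pi * ((d1 + d2) / 4)^2
}

#' Per-species absolute abundance (individuals per hectare)
#'
#' A_i = N_i / S with N_i the species' total individual count across all
#' sampling units and S the total sampled area in hectares. Species present in
#' the taxon table but never observed get 0.
#'
#' @param dataset a [survey_dataset()].
#' @return named numeric vector (one entry per taxon, taxon-table order).
#' @export
absolute_abundance <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  s_ha <- sampled_area_ha(dataset)
  if (s_ha <= 0) abort("total sampled area must be positive")
  species_totals(dataset, dataset$observations$count) / s_ha
}

#' Per-species site counts and occupancy frequency
#'
#' P_i is the number of distinct sampling units in which species i occurs;
#' the absolute frequency is the occupancy fraction F_i = P_i / NS with NS the
#' number of sampling units.
#'
#' @param dataset a [survey_dataset()].
#' @return data.frame with columns `species_id`, `sites` (P_i), `frequency`
#'   (F_i in [0, 1]).
#' @export
site_counts <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  ns <- nrow(dataset$units)
  if (ns < 1L) abort("dataset has no sampling units")
  # observations are aggregated, so each row is one (unit, species) presence
  p <- species_totals(dataset, rep(1, nrow(dataset$observations)))
  data.frame(species_id = names(p), sites = as.integer(p),
             frequency = as.numeric(p) / ns, stringsAsFactors = FALSE)
}

#' Per-species absolute dominance (canopy cover, m2 per hectare)
#'
#' D_i = (total cover area of species i) / S(ha). An observation's cover is
#' its `cover_m2` when present, otherwise `count * crown_area(d1, d2)`
#' (explicit cover takes precedence when both are recorded).
#'
#' @param dataset a [survey_dataset()].
#' @return named numeric vector (one entry per taxon).
#' @export
absolute_dominance <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  s_ha <- sampled_area_ha(dataset)
  if (s_ha <= 0) abort("total sampled area must be positive")
  species_totals(dataset, resolved_covers(dataset$observations)) / s_ha
}

# sum a per-observation quantity by species over the full taxon list
species_totals <- function(dataset, values) {
  out <- structure(numeric(nrow(dataset$taxa)),
                   names = dataset$taxa$species_id)
  if (nrow(dataset$observations) > 0L) {
    agg <- tapply(values, dataset$observations$species_id, sum)
    out[names(agg)] <- agg
  }
  out
}

#' Relative shares of a nonnegative measure, in percent
#'
#' value_i / sum(values) * 100. Used identically for relative abundance,
#' frequency and dominance: the 1/S and 1/NS denominators of the absolute
#' measures cancel in the share, so shares of raw N_i, P_i and total cover are
#' the same as shares of A_i, F_i and D_i.
#'
#' @param values nonnegative numeric vector, at least one entry > 0.
#' @return vector summing to 100.
#' @export
relative_shares <- function(values) {
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("values must be finite and nonnegative")
  }
  total <- sum(values)
  if (total <= 0) abort("all values are zero; shares are undefined")
  values / total * 100
}

#' Importance Value Index table
#'
#' Builds the per-species community structure table: absolute abundance `A`
#' (ind/ha), relative abundance `AR` (%), occupancy frequency `F` and relative
#' frequency `FR` (%), cover dominance `D` (m2/ha) and relative dominance `DR`
#' (%), the raw Importance Value Index `ivi_raw = AR + FR + DR` (sums to 300
#' over species) and the normalised `ivi = ivi_raw / 3` (sums to 100, the
#' convention used when the index is reported as a percentage). Rows are
#' sorted by `ivi` descending, ties broken alphabetically by scientific name
#' (or species id when no taxa are supplied).
#'
#' @param x a [survey_dataset()], or a data.frame of absolute columns
#'   `species_id`, `abundance_ind_ha`, `sites`, `dominance_m2_ha` (the format
#'   of [load_table2_structure()]).
#' @param taxa optional taxon table used for scientific names (taken from the
#'   dataset when `x` is a `survey_dataset`).
#' @param n_units number of sampling units NS, used only to report the
#'   occupancy fraction `F` when `x` is an absolute table; shares are
#'   unaffected. Default 54.
#' @return data.frame of class `ivi_table` with one row per species.
#' @export
ivi_table <- function(x, taxa = NULL, n_units = 54) {
  if (inherits(x, "survey_dataset")) {
    taxa <- x$taxa
    abs_tab <- data.frame(
      species_id = x$taxa$species_id,
      abundance_ind_ha = as.numeric(absolute_abundance(x)),
      sites = site_counts(x)$sites,
      dominance_m2_ha = as.numeric(absolute_dominance(x)),
      stringsAsFactors = FALSE)
    n_units <- nrow(x$units)
  } else {
    abs_tab <- as.data.frame(x)
    check_columns(abs_tab, c("species_id", "abundance_ind_ha", "sites",
                             "dominance_m2_ha"), "absolute structure table")
  }
  if (!is.null(taxa)) {
    unmapped <- setdiff(abs_tab$species_id, taxa$species_id)
    if (length(unmapped) > 0L) {
      abort("species missing from taxon table: %s",
            paste(unmapped, collapse = ", "))
    }
    sci <- taxa$scientific_name[match(abs_tab$species_id, taxa$species_id)]
  } else {
    sci <- abs_tab$species_id
  }
  out <- data.frame(
    species_id = abs_tab$species_id,
    scientific_name = sci,
    A = abs_tab$abundance_ind_ha,
    AR = relative_shares(abs_tab$abundance_ind_ha),
    F = abs_tab$sites / n_units,
    FR = relative_shares(abs_tab$sites),
    D = abs_tab$dominance_m2_ha,
    DR = relative_shares(abs_tab$dominance_m2_ha),
    stringsAsFactors = FALSE)
  out$ivi_raw <- out$AR + out$FR + out$DR
  out$ivi <- out$ivi_raw / 3
  out <- out[order(-out$ivi, out$scientific_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ivi_table", "data.frame")
  out
}

#' Family-level Importance Value Index
#'
#' Sums the normalised per-species IVI within each botanical family. By
#' default the species values are first rounded to the table's reporting
#' precision (1 decimal place), so the family totals are exactly what a reader
#' obtains by summing the published species table; pass `digits = NULL` for
#' full-precision aggregation.
#'
#' @param rows an [ivi_table()].
#' @param taxa taxon table mapping every species to a family.
#' @param digits rounding applied to species `ivi` before summation
#'   (default 1); `NULL` for no rounding.
#' @return data.frame `family`, `n_species`, `ivi`, sorted by `ivi` descending
#'   then family name.
#' @export
family_ivi <- function(rows, taxa, digits = 1) {
  unmapped <- setdiff(rows$species_id, taxa$species_id)
  if (length(unmapped) > 0L) {
    abort("species missing from taxon table: %s",
          paste(unmapped, collapse = ", "))
  }
  fam <- taxa$family[match(rows$species_id, taxa$species_id)]
  v <- if (is.null(digits)) rows$ivi else round(rows$ivi, digits)
  agg <- tapply(v, fam, sum)
  cnt <- tapply(v, fam, length)
  out <- data.frame(family = names(agg), n_species = as.integer(cnt),
                    ivi = as.numeric(agg), stringsAsFactors = FALSE)
  out <- out[order(-out$ivi, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
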