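#' Shannon diversity index (natural log)
#'
#' H = -sum(p_i * ln(p_i)) with p_i = n_i / N the proportion of individuals
#' belonging to species i. Zero counts are excluded (0 * ln 0 := 0). H is 0
#' for a monoculture and reaches ln(richness) when all species are equally
#' abundant.
#'
#' @param counts nonnegative individual counts per species; at least one > 0.
#' @return H in nats.
#' @export
#' @examples
#' shannon(c(5, 5, 5, 5))  # log(4)
#' shannon(c(1, 1, 2))     # 1.0397...
shannon <- function(counts) {
  if (length(counts) == 0L || any(!is.finite(counts)) || any(counts < 0)) {
    abort("counts must be a nonempty vector of finite nonnegative numbers")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) abort("all counts are zero; H is undefined")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Classify a Shannon index value
#'
#' Standard interpretation bands for natural-log Shannon values in vegetation
#' communities: low diversity up to 1.35, medium diversity above 1.35 and up
#' to 3.5, high diversity above 3.5 (continuous cut points).
#'
#' @param h Shannon index value(s) in nats, >= 0.
#' @return character vector in {"low", "medium", "high"}.
#' @export
classify_diversity <- function(h) {
  if (any(!is.finite(h)) || any(h < 0)) abort("H must be finite and >= 0")
  ifelse(h <= 1.35, "low", ifelse(h <= 3.5, "medium", "high"))
}

#' Richness/equitability decomposition of a Shannon value
#'
#' For an observed H over r species: the effective species number e_H = e^H
#' is how many equally abundant species would produce the observed index; the
#' horizontal deviation a = r - e^H counts species short of maximum
#' equitability; the vertical deviation b = ln(r) - H is the diversity the
#' community fails to realise relative to its equiabundant potential
#' H_max = ln(r). Both deviations are zero exactly at maximum equitability.
#'
#' @param h Shannon index in nats, 0 <= h <= ln(r) (up to rounding slack).
#' @param r species richness, >= 1.
#' @return list with `e_h`, `a`, `b`.
#' @export
equitability_decomposition <- function(h, r) {
  if (!is.finite(r) || r < 1 || r != round(r)) {
    abort("r must be a positive integer richness")
  }
  if (!is.finite(h) || h < 0) abort("H must be finite and >= 0")
  if (h > log(r) + 1e-9) {
    abort("H = %.6f exceeds ln(r) = %.6f: impossible index for r = %d species",
          h, log(r), as.integer(r))
  }
  e_h <- exp(h)
  list(e_h = e_h, a = r - e_h, b = log(r) - h)
}

#' Per-unit Shannon diversity and community summary
#'
#' Computes the Shannon index of every sampling unit from that unit's species
#' counts (all life forms pooled), summary statistics over units (mean, sample
#' sd, min, max), the pooled index over the summed counts of all units, and
#' the richness/equitability decomposition of the mean per-unit H against the
#' total species richness r.
#'
#' Units with zero individuals are assigned H = 0 and flagged with a warning;
#' with `drop_empty_units = TRUE` they are excluded from the per-unit table
#' and all summaries instead.
#'
#' @param dataset a [survey_dataset()] with at least one observation.
#' @param drop_empty_units drop units without individuals rather than scoring
#'   them H = 0 (default FALSE).
#' @return object of class `diversity_result`: list with `per_unit`
#'   (data.frame `unit_id`, `x`, `y`, `richness`, `H`), `h_average`, `h_sd`,
#'   `h_min`, `h_max`, `pooled_h`, `r`, `e_h`, `a`, `b`, `class_label`,
#'   `n_units_used`, `n_empty_units`.
#' @export
per_unit_diversity <- function(dataset, drop_empty_units = FALSE) {
  stopifnot(inherits(dataset, "survey_dataset"))
  obs <- dataset$observations
  if (nrow(obs) == 0L) abort("dataset has no observations; H is undefined")

  per_unit <- dataset$units[, c("unit_id", "x", "y")]
  groups <- split(obs, factor(obs$unit_id, levels = per_unit$unit_id))
  per_unit$richness <- vapply(groups, nrow, integer(1))
  per_unit$H <- vapply(groups, function(g) {
    if (nrow(g) == 0L) 0 else shannon(g$count)
  }, numeric(1))
  empty <- per_unit$richness == 0L
  if (any(empty)) {
    if (drop_empty_units) {
      per_unit <- per_unit[!empty, , drop = FALSE]
    } else {
      warning(sprintf("%d unit(s) without individuals scored H = 0: %s",
                      sum(empty),
                      paste(per_unit$unit_id[empty], collapse = ", ")),
              call. = FALSE)
    }
  }
  rownames(per_unit) <- NULL

  pooled_counts <- tapply(obs$count, obs$species_id, sum)
  r <- length(pooled_counts)
  h_avg <- mean(per_unit$H)
  dec <- equitability_decomposition(h_avg, r)

  structure(list(
    per_unit = per_unit,
    h_average = h_avg,
    h_sd = if (nrow(per_unit) > 1L) sd(per_unit$H) else 0,
    h_min = min(per_unit$H),
    h_max = max(per_unit$H),
    pooled_h = shannon(as.numeric(pooled_counts)),
    r = r,
    e_h = dec$e_h,
    a = dec$a,
    b = dec$b,
    class_label = classify_diversity(h_avg),
    n_units_used = nrow(per_unit),
    n_empty_units = sum(empty)
  ), class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Shannon diversity over %d sampling units\n", x$n_units_used))
  cat(sprintf("  H average %.5f (sd %.5f), min %.5f, max %.5f  [%s diversity]\n",
              x$h_average, x$h_sd, x$h_min, x$h_max, x$class_label))
  cat(sprintf("  pooled H %.5f over r = %d species; e^H = %.3f, a = %.3f, b = %.3f\n",
              x$pooled_h, x$r, x$e_h, x$a, x$b))
  invisible(x)
}
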