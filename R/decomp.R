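# Community-weighted mean size and its partition into intraspecific and
# interspecific (species turnover) components.
#
# For each period the community mean including both sources of change weights
# every individual observation by w_obs = w_spe / m_spe, where w_spe is the
# species' relative abundance in the counted assemblage and m_spe the number
# of measured cysts of that species in that period. The community mean
# excluding intraspecific change replaces each species' per-period mean by a
# fixed cross-period species mean, weighted by the same per-period abundance
# weights, so it moves only when composition moves. The difference of
# differences is the intraspecific contribution — an exact additive identity.

#' Per-species assemblage weights for one period
#'
#' `w_spe = count_spe / sum(counts)` over the included species. Weights are
#' renormalised over `included_species`, so taxa outside the measured set
#' (rare or unidentifiable cysts) simply drop out of the community.
#'
#' @param assemblage Count tibble as from [read_assemblage()].
#' @param period Period label to extract.
#' @param included_species Character vector of species to keep (default: all
#'   species present for the period).
#' @return A tibble `species`, `period`, `weight` with weights summing to 1.
#' @export
species_weights <- function(assemblage, period,
                            included_species = NULL) {
  a <- assemblage[assemblage$period == period, ]
  if (is.null(included_species)) included_species <- unique(a$species)
  missing <- setdiff(included_species, a$species)
  if (length(missing) > 0) {
    ps_stop(sprintf("no assemblage count for species '%s' in period '%s'",
                    missing[1], period), "paleosize_missing_species_error")
  }
  a <- a[a$species %in% included_species, ]
  total <- sum(a$count)
  if (total == 0) {
    ps_stop(sprintf("assemblage counts for period '%s' sum to zero", period),
            "paleosize_degenerate_error")
  }
  tibble::tibble(species = a$species, period = period, weight = a$count / total)
}

#' Per-observation weights
#'
#' Spreads each species' assemblage weight evenly over its measured cysts:
#' `w_obs = w_spe / m_spe` with `m_spe` the number of observations of that
#' species. Observation weights sum to 1. A species that carries weight but
#' has no measurements is dropped with a warning and the remaining weights
#' renormalised; an observation whose species has no weight is an error.
#'
#' @param observations Observation tibble for one period.
#' @param weights Tibble from [species_weights()] for the same period.
#' @return `observations` with a `weight` column appended.
#' @export
observation_weights <- function(observations, weights) {
  unweighted <- setdiff(unique(observations$species), weights$species)
  if (length(unweighted) > 0) {
    ps_stop(sprintf("observations of species '%s' have no assemblage weight",
                    unweighted[1]), "paleosize_missing_species_error")
  }
  m <- table(observations$species)
  unobserved <- setdiff(weights$species, names(m))
  if (length(unobserved) > 0) {
    warning(sprintf("species with assemblage weight but no observations excluded: %s",
                    paste(unobserved, collapse = ", ")),
            call. = FALSE)
    weights <- weights[!weights$species %in% unobserved, ]
    weights$weight <- weights$weight / sum(weights$weight)
  }
  w_spe <- setNames(weights$weight, weights$species)
  out <- observations
  out$weight <- unname(w_spe[out$species]) / as.numeric(m[out$species])
  out
}

.community_row <- function(period, level, values, weights, n_obs, correct = TRUE) {
  s <- weighted_sample(values, weights, n_obs)
  # a single-value community has a mean but no dispersion
  sd_w <- if (n_obs >= 2) wtd_sd(s, correct) else NA_real_
  tibble::tibble(period = period, level = level,
                 mean = wtd_mean(s), sd = sd_w,
                 se = if (is.na(sd_w)) NA_real_ else wtd_se(sd_w, n_obs),
                 n_obs = as.integer(n_obs))
}

#' Community-weighted mean including intraspecific change
#'
#' The abundance-weighted mean of all individual diameter observations of one
#' period, with observation weights from [observation_weights()]. Its SD and
#' SE use the number of measured cysts as the effective sample size.
#'
#' @param observations Observation tibble (may contain several periods; only
#'   `period` rows are used).
#' @param assemblage Count tibble.
#' @param period Period label.
#' @param included_species Species set over which weights are renormalised
#'   (default: species present in both tables for this period).
#' @param correct Weighted-SD small-sample correction, see [wtd_sd()].
#' @return A one-row tibble `period`, `level` (`"intra+inter"`), `mean`,
#'   `sd`, `se`, `n_obs`.
#' @export
community_mean_intra_inter <- function(observations, assemblage, period,
                                       included_species = NULL, correct = TRUE) {
  obs <- observations[observations$period == period, ]
  if (nrow(obs) < 2) {
    ps_stop(sprintf("need at least 2 observations in period '%s'", period),
            "paleosize_insufficient_data_error")
  }
  if (is.null(included_species)) {
    included_species <- intersect(unique(obs$species),
                                  assemblage$species[assemblage$period == period])
  }
  obs <- obs[obs$species %in% included_species, ]
  w <- species_weights(assemblage, period, included_species)
  obs <- observation_weights(obs, w)
  .community_row(period, "intra+inter", obs$diameter, obs$weight, nrow(obs), correct)
}

#' Cross-period pooled species means
#'
#' The fixed species trait value used by the interspecific community mean:
#' by default the arithmetic mean of all of a species' observations pooled
#' over both periods (so period sample sizes act as weights). The alternative
#' `"period_mean"` averages the two per-period means with equal weight.
#'
#' @param observations Observation tibble covering both periods.
#' @param species Species to compute (default: all present).
#' @param pooling `"pooled"` (default) or `"period_mean"`.
#' @return A named numeric vector of species means (μm).
#' @export
species_pooled_means <- function(observations, species = NULL,
                                 pooling = c("pooled", "period_mean")) {
  pooling <- match.arg(pooling)
  if (is.null(species)) species <- unique(observations$species)
  vapply(setNames(species, species), function(sp) {
    obs <- observations[observations$species == sp, ]
    if (nrow(obs) == 0) {
      ps_stop(sprintf("no observations for species '%s'", sp),
              "paleosize_missing_species_error")
    }
    switch(pooling,
      pooled = mean(obs$diameter),
      period_mean = mean(tapply(obs$diameter, obs$period, mean))
    )
  }, numeric(1))
}

#' Community-weighted mean excluding intraspecific change
#'
#' Weighted mean of fixed species trait values (cross-period species means,
#' or literature midpoints) under one period's abundance weights. Because the
#' trait values are fixed, this mean changes between periods only through
#' composition. SD and SE use the number of species as the effective sample
#' size.
#'
#' @param species_means Named numeric vector, species -> trait value (μm).
#' @param weights Tibble from [species_weights()].
#' @param level Level tag for the output row (default `"inter"`).
#' @param correct See [wtd_sd()].
#' @return A one-row tibble like [community_mean_intra_inter()].
#' @export
community_mean_inter <- function(species_means, weights, level = "inter",
                                 correct = TRUE) {
  missing <- setdiff(weights$species, names(species_means))
  if (length(missing) > 0) {
    ps_stop(sprintf("no species mean for '%s'", missing[1]),
            "paleosize_missing_species_error")
  }
  vals <- species_means[weights$species]
  .community_row(weights$period[1], level, vals, weights$weight,
                 nrow(weights), correct)
}

#' Partition community mean size change into intra- and interspecific parts
#'
#' Computes, for a reference and a comparison period, the community-weighted
#' mean with and without intraspecific change and partitions the total change
#' \eqn{\Delta\bar{x}_{intra+inter} = \bar{x}_{cmp} - \bar{x}_{ref}} into an
#' interspecific part (difference of the fixed-trait means) and an
#' intraspecific remainder. The identity
#' `delta_intra + delta_inter == delta_total` holds exactly by construction.
#'
#' @param observations Observation tibble covering both periods.
#' @param assemblage Count tibble covering both periods.
#' @param ref_period,cmp_period Period labels; deltas are comparison minus
#'   reference (cold minus warm in the motivating study).
#' @param pooling Species-mean convention, see [species_pooled_means()].
#' @param correct See [wtd_sd()].
#' @return A list with `community` (4-row tibble of community means) and
#'   `decomposition` (one-row tibble: `delta_total`, `delta_inter`,
#'   `delta_intra`, `fraction_intra`, `fraction_inter`; fractions are `NA`
#'   when `delta_total` is 0).
#' @export
#' @examples
#' cfg <- default_config()
#' obs <- generate_observations(cfg, seed = 1)
#' asm <- generate_assemblage(cfg)
#' decompose_size_change(obs, asm, "warm", "cold")$decomposition
decompose_size_change <- function(observations, assemblage,
                                  ref_period, cmp_period,
                                  pooling = c("pooled", "period_mean"),
                                  correct = TRUE) {
  pooling <- match.arg(pooling)
  included <- intersect(unique(observations$species), unique(assemblage$species))
  if (length(included) == 0) {
    ps_stop("no species shared between observation and assemblage tables",
            "paleosize_missing_species_error")
  }
  obs <- observations[observations$species %in% included, ]
  pooled <- species_pooled_means(obs, included, pooling)
  rows <- list()
  inter_means <- numeric(2)
  total_means <- numeric(2)
  periods <- c(ref_period, cmp_period)
  for (i in 1:2) {
    p <- periods[i]
    w <- species_weights(assemblage, p, included)
    tot <- community_mean_intra_inter(obs, assemblage, p, included, correct)
    int <- community_mean_inter(pooled, w, "inter", correct)
    total_means[i] <- tot$mean
    inter_means[i] <- int$mean
    rows <- c(rows, list(tot, int))
  }
  decomp <- decompose_from_means(total_means[1], total_means[2],
                                 inter_means[1], inter_means[2])
  list(community = dplyr::bind_rows(rows), decomposition = decomp)
}

#' Decomposition arithmetic from four community means
#'
#' The partition applied directly to already-computed community means — for
#' instance the community rows of a published summary table.
#'
#' @param total_ref,total_cmp Community means including intraspecific change
#'   for the reference and comparison periods (μm).
#' @param inter_ref,inter_cmp Community means excluding intraspecific change
#'   (μm).
#' @return A one-row tibble: `delta_total`, `delta_inter`, `delta_intra`,
#'   `fraction_intra`, `fraction_inter`.
#' @export
#' @examples
#' decompose_from_means(31.80, 36.24, 33.30, 34.53)
decompose_from_means <- function(total_ref, total_cmp, inter_ref, inter_cmp) {
  delta_total <- total_cmp - total_ref
  delta_inter <- inter_cmp - inter_ref
  delta_intra <- delta_total - delta_inter
  if (delta_total == 0) {
    f_intra <- NA_real_
    f_inter <- NA_real_
  } else {
    f_intra <- delta_intra / delta_total
    f_inter <- delta_inter / delta_total
  }
  tibble::tibble(delta_total = delta_total, delta_inter = delta_inter,
                 delta_intra = delta_intra,
                 fraction_intra = f_intra, fraction_inter = f_inter)
}

#' Percent change in linear dimension
#'
#' `100 * (cmp - ref) / ref`, e.g. the percent change of a mean diameter.
#'
#' @param mean_ref,mean_cmp Reference and comparison means (μm); `mean_ref`
#'   must be positive.
#' @return Percent change (positive = increase).
#' @export
#' @examples
#' linear_change_percent(34.08, 37.96)  # about 11.4
linear_change_percent <- function(mean_ref, mean_cmp) {
  stopifnot(mean_ref > 0)
  100 * (mean_cmp - mean_ref) / mean_ref
}

#' Percent change in sphere volume implied by a diameter change
#'
#' Treats the cyst as a sphere (\eqn{V = \frac{4}{3}\pi r^3}); the
#' radius-vs-diameter distinction cancels in the ratio, so the volume change
#' is `100 * ((cmp/ref)^3 - 1)`.
#'
#' @inheritParams linear_change_percent
#' @return Percent change in volume.
#' @export
#' @examples
#' volume_change_percent(34.08, 37.96)  # about 38
volume_change_percent <- function(mean_ref, mean_cmp) {
  stopifnot(mean_ref > 0)
  100 * ((mean_cmp / mean_ref)^3 - 1)
}
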