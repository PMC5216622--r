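# Seeded generator of synthetic observation and assemblage tables emulating a
# six-species, two-period Arctic dinoflagellate cyst study. Stands in for the
# motivating study's raw measurements, which were never deposited: per-species
# SDs and measurement counts follow the published summary table; assemblage
# fractions follow the published dominant-species percentages, with the
# remainder split over the three minor species proportionally to measured n
# (a declared fixture convention — the true minor fractions are unpublished).

#' Default synthetic-study configuration
#'
#' Returns the bundled study fixture: six dinoflagellate cyst species
#' (*Brigantedinium simplex*, *Islandinium minutum*, *Islandinium? cezare*,
#' *Pentapharsodinium dalei*, *Spiniferites elongatus*, *Spiniferites
#' ramosus*) in two climate periods (`"warm"`, a medieval warm interval, and
#' `"cold"`, the Little Ice Age). Per species and period it carries the mean
#' and SD of cyst diameter (μm), the number of cysts measured (448 in total),
#' and the species' relative abundance in the counted assemblage. Assemblage
#' totals are 613 counted cysts in the warm period and 680 in the cold period.
#'
#' Dominant-species abundance fractions are fixed
#' (*I. minutum* 0.50 warm / 0.65 cold, *P. dalei* 0.20 / 0.08,
#' *I.? cezare* 0.04 / 0.06); the remainder of each period is allocated to the
#' three minor species proportionally to their measured n and the six
#' fractions renormalised to sum to 1. Unidentifiable and rare cysts ("Other",
#' roughly a fifth of the raw assemblage) are excluded and weights
#' renormalised over the six measured species, so community weights always
#' sum to 1 over the cysts the analysis covers.
#'
#' @return An object of class `synth_config`: a list with elements `specs`
#'   (tibble with columns `species`, `period`, `mean`, `sd`, `n_measured`,
#'   `assemblage_fraction`) and `assemblage_total` (named integer vector,
#'   one total per period).
#' @seealso [generate_observations()], [generate_assemblage()]
#' @export
#' @examples
#' cfg <- default_config()
#' sum(cfg$specs$n_measured)  # 448 measured cysts
default_config <- function() {
  specs <- tibble::tribble(
    ~species,                  ~period, ~mean,  ~sd,  ~n_measured,
    "Brigantedinium simplex",  "warm",  47.75,  5.75, 30L,
    "Brigantedinium simplex",  "cold",  51.68,  7.28, 30L,
    "Islandinium minutum",     "warm",  34.08,  4.35, 52L,
    "Islandinium minutum",     "cold",  37.96,  4.34, 51L,
    "Islandinium? cezare",     "warm",  24.55,  3.39, 34L,
    "Islandinium? cezare",     "cold",  26.89,  5.54, 55L,
    "Pentapharsodinium dalei", "warm",  25.85,  3.30, 57L,
    "Pentapharsodinium dalei", "cold",  27.31,  2.71, 55L,
    "Spiniferites elongatus",  "warm",  39.65,  4.22, 27L,
    "Spiniferites elongatus",  "cold",  39.17,  4.41, 21L,
    "Spiniferites ramosus",    "warm",  37.33,  3.59, 19L,
    "Spiniferites ramosus",    "cold",  36.84,  4.01, 17L
  )
  fixed <- list(
    warm = c("Islandinium minutum" = 0.50, "Pentapharsodinium dalei" = 0.20,
             "Islandinium? cezare" = 0.04),
    cold = c("Islandinium minutum" = 0.65, "Pentapharsodinium dalei" = 0.08,
             "Islandinium? cezare" = 0.06)
  )
  specs$assemblage_fraction <- NA_real_
  for (p in c("warm", "cold")) {
    in_p <- specs$period == p
    fx <- fixed[[p]]
    frac <- setNames(rep(NA_real_, sum(in_p)), specs$species[in_p])
    frac[names(fx)] <- fx
    minor <- is.na(frac)
    n_minor <- specs$n_measured[in_p][minor]
    frac[minor] <- (1 - sum(fx)) * n_minor / sum(n_minor)
    frac <- frac / sum(frac)
    specs$assemblage_fraction[in_p] <- unname(frac)
  }
  new_synth_config(specs, c(warm = 613L, cold = 680L))
}

#' Build a synthetic-study configuration
#'
#' @param specs Tibble with columns `species`, `period`, `mean` (μm, > 0),
#'   `sd` (μm, >= 0), `n_measured` (>= 1) and `assemblage_fraction`
#'   (fractions must sum to 1 within each period).
#' @param assemblage_total Named integer vector of total counted cysts per
#'   period.
#' @return A `synth_config` object.
#' @export
new_synth_config <- function(specs, assemblage_total) {
  stopifnot(all(c("species", "period", "mean", "sd", "n_measured",
                  "assemblage_fraction") %in% names(specs)))
  if (any(specs$mean <= 0) || any(specs$sd < 0) || any(specs$n_measured < 1)) {
    ps_stop("specs require mean > 0, sd >= 0, n_measured >= 1",
            "paleosize_validation_error")
  }
  key <- paste(specs$species, specs$period, sep = "\r")
  if (anyDuplicated(key)) {
    ps_stop("duplicate (species, period) in specs", "paleosize_duplicate_error")
  }
  for (p in unique(specs$period)) {
    s <- sum(specs$assemblage_fraction[specs$period == p])
    if (abs(s - 1) > 1e-9) {
      ps_stop(sprintf("assemblage fractions for period '%s' sum to %.12f, not 1", p, s),
              "paleosize_validation_error")
    }
    if (!p %in% names(assemblage_total)) {
      ps_stop(sprintf("no assemblage total for period '%s'", p),
              "paleosize_validation_error")
    }
  }
  structure(list(specs = tibble::as_tibble(specs),
                 assemblage_total = assemblage_total),
            class = "synth_config")
}

# One substream seed per (species, period), derived from the master seed in
# sorted key order so the draw for a given species-period does not depend on
# row order in `specs`.
.substream_seeds <- function(specs, seed) {
  key <- paste(specs$species, specs$period, sep = "\r")
  ord <- order(key)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, nrow(specs))
  sub[order(ord)]  # back to specs row order
}

#' Generate synthetic diameter observations
#'
#' For each (species, period) spec, draws exactly `n_measured` diameters from
#' a normal distribution with the spec's mean and SD, truncated below at
#' 0.1 μm. Truncation only guards the positivity invariant; at realistic cyst
#' sizes (means 20–50 μm, SDs 3–7 μm) it is numerically irrelevant. Each
#' (species, period) uses its own substream derived from `seed` in sorted key
#' order, so draws are independent of record order and of each other.
#'
#' @param config A `synth_config`, e.g. [default_config()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble of observations (`species`, `period`, `diameter`), valid
#'   input for the analysis functions and [write_observations()].
#' @export
#' @examples
#' obs <- generate_observations(default_config(), seed = 1)
#' nrow(obs)  # 448
generate_observations <- function(config, seed) {
  stopifnot(inherits(config, "synth_config"))
  specs <- config$specs
  subs <- .substream_seeds(specs, seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  pieces <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    set.seed(subs[i])
    n <- specs$n_measured[i]
    if (specs$sd[i] == 0) {
      d <- rep(specs$mean[i], n)
    } else {
      d <- rnorm(n, specs$mean[i], specs$sd[i])
      # truncate below at 0.1 μm by redrawing (essentially never triggered)
      while (any(bad <- d < 0.1)) {
        d[bad] <- rnorm(sum(bad), specs$mean[i], specs$sd[i])
      }
    }
    pieces[[i]] <- tibble::tibble(species = specs$species[i],
                                  period = specs$period[i], diameter = d)
  }
  dplyr::bind_rows(pieces)
}

#' Generate a synthetic assemblage count table
#'
#' Converts each period's assemblage fractions into integer counts by
#' largest-remainder apportionment: each species starts at
#' `floor(fraction * total)` and the remaining units go to the species with
#' the largest fractional parts. Counts therefore sum exactly to the
#' configured per-period total and every count is within one cyst of its
#' exact value `fraction * total`. Deterministic (no random draws).
#'
#' @inheritParams generate_observations
#' @return A tibble of counts (`species`, `period`, `count`).
#' @export
generate_assemblage <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  specs <- config$specs
  pieces <- lapply(unique(specs$period), function(p) {
    s <- specs[specs$period == p, ]
    total <- config$assemblage_total[[p]]
    exact <- s$assemblage_fraction * total
    cnt <- floor(exact)
    short <- total - sum(cnt)
    if (short > 0) {
      # award leftover units by largest fractional part, larger species first
      give <- order(exact - cnt, s$assemblage_fraction, decreasing = TRUE)[seq_len(short)]
      cnt[give] <- cnt[give] + 1
    }
    tibble::tibble(species = s$species, period = p, count = as.integer(cnt))
  })
  dplyr::bind_rows(pieces)
}
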