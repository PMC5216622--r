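# Literature size-range conversion, midpoints and measured-vs-literature
# comparison. Integer rounding is half-away-from-zero throughout (so 50.5 ->
# 51 and 34.5 -> 35), matching how taxonomic keys print derived ranges;
# banker's rounding would disagree on exact halves.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert length and width ranges to a diameter range
#'
#' For taxa whose keys report cyst length and width rather than a diameter,
#' the diameter range is the endpoint-wise average:
#' `d_min = round((l_min + w_min)/2)`, `d_max = round((l_max + w_max)/2)`,
#' rounding half away from zero.
#'
#' @param length_range,width_range Numeric pairs `c(min, max)` in μm.
#' @return Integer pair `c(min, max)` (μm).
#' @export
#' @examples
#' lw_to_diameter(c(40, 59), c(26, 42))  # c(33, 51)
lw_to_diameter <- function(length_range, width_range) {
  stopifnot(length(length_range) == 2, length(width_range) == 2,
            length_range[1] <= length_range[2],
            width_range[1] <= width_range[2])
  as.integer(round_half_away((length_range + width_range) / 2))
}

#' Midpoint of a size range
#'
#' The value in the middle of a literature size range,
#' `round((min + max)/2)` half away from zero, used as the species' fixed
#' trait value in literature-based community means.
#'
#' @param range Numeric pair `c(min, max)`, `min <= max`.
#' @return The (integer-rounded) midpoint (μm).
#' @export
#' @examples
#' range_midpoint(c(29, 54))  # 42
range_midpoint <- function(range) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  round_half_away((range[1] + range[2]) / 2)
}

# diameter range of a literature entry row, deriving it from length/width
# when the key reports no diameter
.entry_diameter_range <- function(entry) {
  if (!is.na(entry$diameter_min)) {
    c(entry$diameter_min, entry$diameter_max)
  } else {
    lw_to_diameter(c(entry$length_min, entry$length_max),
                   c(entry$width_min, entry$width_max))
  }
}

#' Compare measured sizes of one species against its literature range
#'
#' Flags, by strict inequality, whether the measured mean falls outside the
#' literature diameter range and whether the measured size range extends
#' beyond it on either side.
#'
#' @param species Species label.
#' @param measured_mean Measured mean diameter (μm).
#' @param measured_range Numeric pair: total measured size range (μm).
#' @param entry One-row literature tibble for the species (a row of
#'   [read_literature()] output).
#' @return A one-row tibble: `species`, `measured_mean`, `measured_min`,
#'   `measured_max`, `lit_min`, `lit_max`, `midpoint`, and logical flags
#'   `mean_below_range`, `mean_above_range`, `measured_extends_below`,
#'   `measured_extends_above`.
#' @export
compare_species <- function(species, measured_mean, measured_range, entry) {
  dr <- .entry_diameter_range(entry)
  tibble::tibble(
    species = species,
    measured_mean = measured_mean,
    measured_min = measured_range[1], measured_max = measured_range[2],
    lit_min = dr[1], lit_max = dr[2],
    midpoint = range_midpoint(dr),
    mean_below_range = measured_mean < dr[1],
    mean_above_range = measured_mean > dr[2],
    measured_extends_below = measured_range[1] < dr[1],
    measured_extends_above = measured_range[2] > dr[2]
  )
}

#' Literature-based interspecific community mean
#'
#' The community mean excluding intraspecific change, evaluated with
#' literature midpoints as the fixed species trait values and the same
#' per-period assemblage weights as the measured interspecific mean.
#'
#' @param entries Literature tibble from [read_literature()] covering every
#'   weighted species.
#' @param weights Tibble from [species_weights()].
#' @param correct See [wtd_sd()].
#' @return A one-row community-mean tibble with level `"inter-literature"`.
#' @export
literature_community_mean <- function(entries, weights, correct = TRUE) {
  mids <- vapply(seq_len(nrow(entries)), function(i) {
    range_midpoint(.entry_diameter_range(entries[i, ]))
  }, numeric(1))
  names(mids) <- entries$species
  community_mean_inter(mids, weights, level = "inter-literature", correct)
}
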