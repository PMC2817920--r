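# Polarity classification on the solvent D/V ladder.
#
# D/V (Debye/Angstrom^3) is used as a solubility proxy: a complex is expected
# to dissolve in solvents of comparable D/V. The packaged ladder runs from
# water (0.090) through the alcohols down to hexane (0.00).

# band boundaries interpolate the verbal anchors used with the ladder:
# ~0.005 low-polarity solvents, 0.04-0.045 methanol/ethanol territory,
# 0.090 water
DEFAULT_POLARITY_BANDS <- c(nonpolar = 0.005, low_polarity = 0.02,
                            alcohol_range = 0.06)

band_of <- function(dv, bands = DEFAULT_POLARITY_BANDS) {
  bands <- sort(bands)
  dplyr::case_when(
    dv >= bands[3] ~ "water-like",
    dv >= bands[2] ~ "alcohol-range",
    dv >= bands[1] ~ "low-polarity",
    TRUE ~ "nonpolar"
  )
}

POLARITY_BAND_LEVELS <- c("nonpolar", "low-polarity", "alcohol-range",
                          "water-like")

#' Classify polarity against the solvent ladder
#'
#' Maps each D/V ratio to its nearest reference solvent (minimizing
#' `|dv - solvent dv|`; ties resolve to the more polar solvent) and to a
#' polarity band: `"water-like"` (>= 0.06), `"alcohol-range"` (0.02-0.06),
#' `"low-polarity"` (0.005-0.02) or `"nonpolar"` (< 0.005). Band boundaries
#' are configurable.
#'
#' @param dv_ratio Numeric vector of D/V ratios (Debye/Angstrom^3), >= 0.
#' @param ladder Solvent reference tibble (default [solvent_ladder()]),
#'   with columns `name` and `dv`.
#' @param bands Three ascending band boundaries
#'   (default `c(0.005, 0.02, 0.06)`).
#' @return A tibble with columns `dv`, `nearest_solvent`, `band`.
#' @export
#' @examples
#' classify_polarity(c(0.090, 0.0405, 0))
classify_polarity <- function(dv_ratio, ladder = solvent_ladder(),
                              bands = DEFAULT_POLARITY_BANDS) {
  if (any(is.na(dv_ratio) | dv_ratio < 0)) {
    abort_asf("dv_ratio must be non-negative.", "asfscreen_domain_error")
  }
  if (nrow(ladder) == 0) {
    abort_asf("The solvent ladder is empty.", "asfscreen_domain_error")
  }
  # ladder sorted descending by dv: on ties, the first (more polar) wins
  ladder <- dplyr::arrange(ladder, dplyr::desc(.data$dv))
  nearest <- purrr::map_chr(dv_ratio, function(v) {
    ladder$name[which.min(abs(ladder$dv - v))]
  })
  tibble(
    dv = dv_ratio,
    nearest_solvent = nearest,
    band = factor(band_of(dv_ratio, bands), levels = POLARITY_BAND_LEVELS)
  )
}

#' Polarity range of a complex ensemble
#'
#' The span of D/V ratios across an ensemble of candidate complexes of one
#' ligand. A ligand whose iron complexes reach different polarity bands by
#' shifting which donors bind the metal is flagged *polarity adaptive* --
#' the two-band criterion is this package's operationalization of that
#' notion, as no quantitative criterion is established.
#'
#' @param results An `asf_results` tibble (or any tibble with a `dv` column)
#'   with at least two rows.
#' @param bands Band boundaries passed to [classify_polarity()].
#' @return A one-row tibble: `min_dv`, `max_dv`, `span`, `min_band`,
#'   `max_band`, `adaptive`.
#' @export
#' @examples
#' polarity_range(score_complexes(load_fixture("table5")))
polarity_range <- function(results, bands = DEFAULT_POLARITY_BANDS) {
  dv <- results$dv
  if (length(dv) < 2) {
    abort_asf("polarity_range needs at least two complexes.",
              "asfscreen_domain_error")
  }
  lo <- min(dv)
  hi <- max(dv)
  lo_band <- band_of(lo, bands)
  hi_band <- band_of(hi, bands)
  tibble(
    min_dv = lo, max_dv = hi, span = hi - lo,
    min_band = lo_band, max_band = hi_band,
    adaptive = lo_band != hi_band
  )
}

#' Hydration increments between dry and aqua ensembles
#'
#' Componentwise differences (wet minus dry) between two group summaries,
#' e.g. an Fe-ligand ensemble and its Fe-ligand-H2O counterpart. The area
#' and volume increments are also expressed as multiples of a single water
#' molecule's surface area (36.4 Angstrom^2) and volume (19.4 Angstrom^3):
#' an aqua ligand entering the inner sphere should add about one water's
#' worth of each.
#'
#' @param summary_dry,summary_wet One-row group summaries
#'   (see [summarize_group()] or `load_fixture("table8")` rows).
#' @param water_area,water_volume Reference surface area and volume of one
#'   water molecule.
#' @return A one-row tibble with `d_area_A2`, `d_volume_A3`,
#'   `d_dipole_debye`, `d_energy_J`, `water_equiv_area`, `water_equiv_volume`.
#' @export
#' @examples
#' t8 <- load_fixture("table8")
#' hydration_increment(t8[t8$species == "Fe-Disco", ],
#'                     t8[t8$species == "Fe-Disco_H2O", ])
hydration_increment <- function(summary_dry, summary_wet,
                                water_area = 36.4, water_volume = 19.4) {
  if (nrow(summary_dry) == 0 || nrow(summary_wet) == 0) {
    abort_asf("Both summaries must be non-empty.", "asfscreen_domain_error")
  }
  d_area <- summary_wet$area_A2 - summary_dry$area_A2
  d_vol <- summary_wet$volume_A3 - summary_dry$volume_A3
  tibble(
    d_area_A2 = d_area,
    d_volume_A3 = d_vol,
    d_dipole_debye = summary_wet$dipole_debye - summary_dry$dipole_debye,
    d_energy_J = summary_wet$energy_J - summary_dry$energy_J,
    water_equiv_area = d_area / water_area,
    water_equiv_volume = d_vol / water_volume
  )
}
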