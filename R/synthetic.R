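# Synthetic and mock descriptor providers.
#
# These stand in for the semi-empirical quantum-chemistry stage that
# produces descriptors for real complexes: generate_descriptors() draws
# stochastic descriptor tables whose marginal ranges match the packaged
# reference tables, and mock_descriptors() derives deterministic
# pseudo-descriptors from shell geometry. Both are declared non-physical
# plumbing: they give the scoring, filtering and ranking machinery
# structured, reproducible inputs, nothing more.

#' Synthetic descriptor generator configuration
#'
#' Defaults reflect the spreads of the packaged reference tables: bond
#' lengths 1.85-2.80 Angstrom, dipole moments 7-37 Debye, energies around
#' 1.2e6 J (sd 6e5), and an aqua-ligand dipole shift of +4.97 Debye -- the
#' reported difference between the hydrated (13.36 D) and dry (8.39 D)
#' discodermolide ensemble means.
#'
#' @param seed Integer seed (mandatory; generation is reproducible).
#' @param n_complexes Number of records to draw.
#' @param bond_length_range,dipole_range,volume_range,area_range,molar_mass_range
#'   Low/high bounds for uniform draws.
#' @param energy_mean,energy_sd Normal energy distribution (truncated at 0
#'   unless `negative_energy_fraction` > 0).
#' @param aqua_fraction Fraction of records carrying an aqua ligand.
#' @param aqua_dipole_shift Added to the dipole of aqua records (Debye).
#' @param negative_energy_fraction Fraction of records whose energy sign is
#'   flipped negative (default 0).
#' @return A validated config list of class `asf_synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_complexes = 100,
                             bond_length_range = c(1.85, 2.80),
                             dipole_range = c(7, 37),
                             energy_mean = 1.2e6,
                             energy_sd = 6e5,
                             volume_range = c(640, 1570),
                             area_range = c(650, 1590),
                             molar_mass_range = c(600, 1600),
                             aqua_fraction = 0.5,
                             aqua_dipole_shift = 4.97,
                             negative_energy_fraction = 0) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed)) {
    abort_asf("A numeric seed is mandatory for synthetic generation.",
              "asfscreen_config_error")
  }
  ranges <- list(bond_length_range = bond_length_range,
                 dipole_range = dipole_range,
                 volume_range = volume_range,
                 area_range = area_range,
                 molar_mass_range = molar_mass_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2] || r[1] <= 0) {
      abort_asf(paste0(nm, " must be an ordered positive (low, high) pair."),
                "asfscreen_config_error")
    }
  }
  if (aqua_fraction < 0 || aqua_fraction > 1) {
    abort_asf("aqua_fraction must lie in [0, 1].", "asfscreen_config_error")
  }
  if (n_complexes < 1) {
    abort_asf("n_complexes must be >= 1.", "asfscreen_config_error")
  }
  structure(
    c(list(seed = as.integer(seed), n_complexes = as.integer(n_complexes)),
      ranges,
      list(energy_mean = energy_mean, energy_sd = energy_sd,
           aqua_fraction = aqua_fraction,
           aqua_dipole_shift = aqua_dipole_shift,
           negative_energy_fraction = negative_energy_fraction)),
    class = "asf_synthetic_config"
  )
}

#' Generate a synthetic descriptor table
#'
#' Draws `n_complexes` descriptor records reproducibly from the seed: bond
#' lengths i.i.d. uniform within range, dipole moments uniform within range
#' (plus the aqua shift for aqua records), energies normal truncated at
#' zero, charge +1 throughout. Aqua records replace one donor with the
#' reserved `"H2O"` label.
#'
#' @param config An [synthetic_config()] object.
#' @return A descriptor tibble in the canonical schema (plus `has_aqua`,
#'   `incomplete`), directly consumable by [score_complexes()].
#' @export
#' @examples
#' generate_descriptors(synthetic_config(seed = 1, n_complexes = 5))
generate_descriptors <- function(config) {
  stopifnot(inherits(config, "asf_synthetic_config"))
  n <- config$n_complexes
  withr::with_seed(config$seed, {
    n_aqua <- round(n * config$aqua_fraction)
    has_aqua <- rep(FALSE, n)
    if (n_aqua > 0) has_aqua[sample.int(n, n_aqua)] <- TRUE

    runi <- function(r) stats::runif(n, r[1], r[2])
    dist_mat <- matrix(stats::runif(6 * n, config$bond_length_range[1],
                                    config$bond_length_range[2]),
                       nrow = n, ncol = 6)
    dipole <- runi(config$dipole_range) +
      ifelse(has_aqua, config$aqua_dipole_shift, 0)

    # truncated-normal energies by rejection; the truncated tail is small
    # for the default mean/sd so this converges immediately
    energy <- stats::rnorm(n, config$energy_mean, config$energy_sd)
    while (any(bad <- energy <= 0)) {
      energy[bad] <- stats::rnorm(sum(bad), config$energy_mean,
                                  config$energy_sd)
    }
    if (config$negative_energy_fraction > 0) {
      n_neg <- round(n * config$negative_energy_fraction)
      if (n_neg > 0) {
        flip <- sample.int(n, n_neg)
        energy[flip] <- -energy[flip]
      }
    }

    donor_pool <- c(paste0("O", 1:10), paste0("N", 1:4))
    donors <- purrr::map_chr(seq_len(n), function(i) {
      k <- if (has_aqua[i]) 5 else 6
      picked <- sort(sample(donor_pool, k))
      join_donors(c(picked, if (has_aqua[i]) "H2O"))
    })

    out <- tibble(
      complex_id = sprintf("syn-%04d", seq_len(n)),
      donors = donors,
      dipole_debye = dipole
    )
    for (j in 1:6) out[[paste0("d", j)]] <- dist_mat[, j]
    out$area_A2 <- runi(config$area_range)
    out$volume_A3 <- runi(config$volume_range)
    out$molar_mass <- runi(config$molar_mass_range)
    out$energy_J <- energy
    out$charge <- 1
    out$incomplete <- FALSE
    out$has_aqua <- has_aqua
    out
  })
}

#' Deterministic mock descriptors from shell geometry
#'
#' Derives pseudo-descriptors for enumerated shells from donor coordinates
#' alone, with a pseudo-iron placed at the donor centroid:
#'
#' * bond distances: donor-to-centroid distances, clipped to 1.85-3.2
#'   Angstrom; an aqua ligand contributes a fixed idealized 2.1 Angstrom
#'   bond and no dipole contribution;
#' * dipole: 5 Debye times the magnitude of the vector sum of unit
#'   centroid-to-donor vectors (zero for a symmetric shell);
#' * energy: 1e6 times the mean squared deviation of the bond distances
#'   from 2.1 Angstrom (zero for an ideal shell, strictly increasing as a
#'   donor is displaced);
#' * area/volume: sphere through the farthest donor plus 1.4 Angstrom
#'   padding.
#'
#' The functional forms are non-physical test plumbing; identical inputs
#' give identical outputs.
#'
#' @param shells A tibble from [enumerate_shells()] (or one row of it).
#' @param donors A donor tibble from [identify_donors()] with coordinates.
#' @return A descriptor tibble with one row per shell.
#' @export
#' @examples
#' donors <- identify_donors(asf_fixture_path("toy9donors_synthetic.sdf"))
#' shells <- enumerate_shells(donors, include_aqua = TRUE)
#' mock_descriptors(head(shells, 3), donors)
mock_descriptors <- function(shells, donors) {
  if (!all(c("label", "x", "y", "z") %in% names(donors))) {
    abort_asf("donors must carry label and x/y/z coordinates.",
              "asfscreen_geometry_error")
  }
  one <- function(donor_string, has_aqua) {
    labels <- split_donors(donor_string)[[1]]
    labels <- setdiff(labels, "H2O")
    idx <- match(labels, donors$label)
    if (any(is.na(idx))) {
      abort_asf(paste0("Shell donor(s) missing from structure: ",
                       paste(labels[is.na(idx)], collapse = ", ")),
                "asfscreen_geometry_error")
    }
    pos <- as.matrix(donors[idx, c("x", "y", "z")])
    if (any(!is.finite(pos))) {
      abort_asf("Shell donors lack finite coordinates.",
                "asfscreen_geometry_error")
    }
    centroid <- colMeans(pos)
    rel <- sweep(pos, 2, centroid)
    raw_dist <- sqrt(rowSums(rel^2))
    dist <- pmin(pmax(raw_dist, 1.85), 3.2)
    if (has_aqua) dist <- c(dist, 2.1)
    unit <- rel / pmax(raw_dist, .Machine$double.eps)
    dipole <- 5 * sqrt(sum(colSums(unit)^2))
    energy <- 1e6 * mean((dist - 2.1)^2)
    r <- max(raw_dist) + 1.4
    row <- tibble(
      complex_id = paste0("mock-", gsub(";", "-", donor_string)),
      donors = donor_string,
      dipole_debye = dipole
    )
    for (j in 1:6) row[[paste0("d", j)]] <- dist[j]
    row$area_A2 <- 4 * pi * r^2
    row$volume_A3 <- 4 / 3 * pi * r^3
    row$molar_mass <- 100 * length(labels) + if (has_aqua) 18 else 0
    row$energy_J <- energy
    row$charge <- 1
    row$incomplete <- FALSE
    row$has_aqua <- has_aqua
    row
  }
  purrr::map2_dfr(shells$donors, shells$has_aqua, one)
}
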