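# The aqueous stability factor (ASF) scoring core.
#
# ASF = E * L / (D * Z), in J*m/Debye, where E is the complex energy (J),
# L the average coordination bond length (converted Angstrom -> meters),
# D the dipole moment (Debye) and Z the complex charge. Smaller (or
# negative) ASF marks a complex expected to be more stable and more
# water-soluble.

ANGSTROM_TO_M <- 1e-10

#' Average coordination bond length
#'
#' Arithmetic mean of the Fe--O/Fe--N/Fe--OH2 bond distances. No rounding is
#' applied; `NA` entries (an incomplete record) are dropped.
#'
#' @param bond_distances Numeric vector of positive bond lengths (Angstrom).
#' @return The mean bond length in Angstrom.
#' @export
#' @examples
#' average_bond_length(c(1.957, 2.485, 1.964, 2.456, 2.184, 2.253))
average_bond_length <- function(bond_distances) {
  d <- bond_distances[!is.na(bond_distances)]
  if (length(d) == 0) {
    abort_asf("bond_distances must contain at least one value.",
              "asfscreen_domain_error")
  }
  if (any(d <= 0)) {
    abort_asf("bond_distances must all be positive.", "asfscreen_domain_error")
  }
  mean(d)
}

#' Compute the aqueous stability factor
#'
#' `ASF = E * L / (D * Z)` with the average bond length `L` converted from
#' Angstrom to meters, giving J*m/Debye. The sign of the score follows
#' `sign(E) * sign(Z)`: a negative complex energy (a bound, stabilized
#' complex) yields a negative, i.e. best-ranked, score. All arguments are
#' vectorized.
#'
#' @param energy Complex energy in J (on the scale of the descriptor source).
#' @param abl Average bond length in Angstrom.
#' @param dipole Dipole moment in Debye; must be positive.
#' @param charge Complex charge (signed integer, typically +1); must be
#'   non-zero.
#' @param complex_id Optional label(s) used in error messages.
#' @return ASF in J*m/Debye.
#' @export
#' @examples
#' compute_asf(1073380.93, 2.2165, 11.17, 1) # 2.1299e-05
compute_asf <- function(energy, abl, dipole, charge = 1, complex_id = NULL) {
  who <- function(i) {
    if (is.null(complex_id)) paste0("element ", i) else complex_id[[i]]
  }
  if (any(bad <- !is.na(dipole) & dipole <= 0)) {
    abort_asf(paste0("Dipole moment must be positive to compute ASF (",
                     who(which(bad)[1]), ")."),
              "asfscreen_division_error")
  }
  if (any(bad <- !is.na(charge) & charge == 0)) {
    abort_asf(paste0("Charge must be non-zero to compute ASF (",
                     who(which(bad)[1]), ")."),
              "asfscreen_domain_error")
  }
  if (any(bad <- !is.na(abl) & abl <= 0)) {
    abort_asf(paste0("Average bond length must be positive (",
                     who(which(bad)[1]), ")."),
              "asfscreen_domain_error")
  }
  energy * (abl * ANGSTROM_TO_M) / (dipole * charge)
}

#' Dipole-to-volume ratio
#'
#' `D/V` in Debye/Angstrom^3, the polarity proxy matched against the solvent
#' ladder: water sits at 0.090, hexane at 0.00.
#'
#' @param dipole Dipole moment in Debye.
#' @param volume Molecular volume in Angstrom^3; must be positive.
#' @return D/V in Debye/Angstrom^3.
#' @export
#' @examples
#' compute_dv(1.74, 19.24) # water, ~0.090
compute_dv <- function(dipole, volume) {
  if (any(!is.na(volume) & volume <= 0)) {
    abort_asf("Volume must be positive to compute D/V.",
              "asfscreen_domain_error")
  }
  dipole / volume
}

#' Covalency filter configuration
#'
#' Complexes with an average coordination bond length above
#' `max_average_bond_length` are discarded outright, and any single bond
#' longer than `max_single_bond_length` is taken as close to lacking
#' covalency, discarding the complex as well. Either rule can be disabled.
#'
#' @param max_average_bond_length Threshold on the mean bond length
#'   (Angstrom; default 2.7).
#' @param max_single_bond_length Threshold on any single bond
#'   (Angstrom; default 2.9).
#' @param enforce_average,enforce_single Enable/disable each rule.
#' @return A filter-config list used by [apply_filters()] and
#'   [score_complexes()].
#' @export
asf_filter_config <- function(max_average_bond_length = 2.7,
                              max_single_bond_length = 2.9,
                              enforce_average = TRUE,
                              enforce_single = TRUE) {
  if (max_average_bond_length <= 0 || max_single_bond_length <= 0) {
    abort_asf("Filter thresholds must be positive.", "asfscreen_config_error")
  }
  structure(
    list(
      max_average_bond_length = max_average_bond_length,
      max_single_bond_length = max_single_bond_length,
      enforce_average = isTRUE(enforce_average),
      enforce_single = isTRUE(enforce_single)
    ),
    class = "asf_filter_config"
  )
}

#' Apply the covalency filters to descriptor records
#'
#' Appends a `passed` flag and a `filter_reasons` column (";"-joined rule
#' identifiers, `""` when passing). Reasons: `"abl_gt_max"` when the mean
#' bond length strictly exceeds the average-bond threshold, `"bond_gt_max"`
#' when any single bond strictly exceeds the single-bond threshold; both may
#' co-occur. Filtering never errors on valid descriptors.
#'
#' @param descriptors A descriptor tibble (see [read_descriptor_table()]).
#' @param config A [asf_filter_config()].
#' @return The input tibble with `passed` and `filter_reasons` appended.
#' @export
apply_filters <- function(descriptors, config = asf_filter_config()) {
  stopifnot(inherits(config, "asf_filter_config"))
  dist_mat <- as.matrix(descriptors[DISTANCE_COLUMNS])
  abl <- apply(dist_mat, 1, function(d) mean(d, na.rm = TRUE))
  max_single <- apply(dist_mat, 1, function(d) max(d, na.rm = TRUE))
  reasons <- purrr::map2_chr(abl, max_single, function(a, m) {
    r <- character()
    if (config$enforce_average && a > config$max_average_bond_length) {
      r <- c(r, "abl_gt_max")
    }
    if (config$enforce_single && m > config$max_single_bond_length) {
      r <- c(r, "bond_gt_max")
    }
    paste(r, collapse = ";")
  })
  descriptors$passed <- reasons == ""
  descriptors$filter_reasons <- reasons
  descriptors
}

#' Score complexes by the aqueous stability factor
#'
#' Computes, for each descriptor record, the average bond length, the ASF,
#' the D/V ratio and the covalency-filter verdict. The ASF is computed for
#' filtered-out complexes too (the verdict is recorded separately), so
#' published tables that contain rule-violating rows can be replicated.
#'
#' @param descriptors A descriptor tibble.
#' @param config A [asf_filter_config()].
#' @param charge Optional charge override; defaults to each record's
#'   `charge` column.
#' @return A tibble of class `asf_results` with columns `complex_id`,
#'   `donors`, `has_aqua`, `asf` (J*m/Debye), `abl_A`, `dv`, `passed`,
#'   `filter_reasons`, plus the descriptor columns used.
#' @export
#' @examples
#' score_complexes(load_fixture("table2"))
score_complexes <- function(descriptors, config = asf_filter_config(),
                            charge = NULL) {
  if (nrow(descriptors) == 0) {
    out <- tibble(complex_id = character(), donors = character(),
                  has_aqua = logical(), asf = double(), abl_A = double(),
                  dv = double(), passed = logical(),
                  filter_reasons = character())
    class(out) <- c("asf_results", class(out))
    return(out)
  }
  x <- apply_filters(descriptors, config)
  dist_mat <- as.matrix(x[DISTANCE_COLUMNS])
  x$abl_A <- apply(dist_mat, 1, function(d) mean(d, na.rm = TRUE))
  z <- if (is.null(charge)) x$charge else charge
  x$asf <- compute_asf(x$energy_J, x$abl_A, x$dipole_debye, z,
                       complex_id = x$complex_id)
  x$dv <- compute_dv(x$dipole_debye, x$volume_A3)
  if (!"has_aqua" %in% names(x)) {
    x$has_aqua <- purrr::map_lgl(split_donors(x$donors),
                                 function(d) "H2O" %in% d)
  }
  front <- c("complex_id", "donors", "has_aqua", "asf", "abl_A", "dv",
             "passed", "filter_reasons")
  out <- x[, c(front, setdiff(names(x), front))]
  class(out) <- c("asf_results", class(out))
  out
}

#' Rank scored complexes
#'
#' The smaller the ASF, the more likely the complex is to be stable with a
#' physiological solubility, so ranking is ascending. The default `"signed"`
#' policy places negative scores (negative complex energy, i.e. a stabilized
#' complex) first; `"magnitude"` ranks by `|ASF|` instead. Ties are broken
#' lexicographically by `complex_id`. Complexes failing the covalency
#' filters are excluded unless `include_filtered = TRUE`.
#'
#' @param results An `asf_results` tibble from [score_complexes()].
#' @param k Number of top complexes to return (default: all).
#' @param policy `"signed"` (default) or `"magnitude"`.
#' @param include_filtered Keep complexes that failed the filters.
#' @return The ranked tibble with a `rank` column prepended.
#' @export
rank_complexes <- function(results, k = Inf,
                           policy = c("signed", "magnitude"),
                           include_filtered = FALSE) {
  policy <- tryCatch(rlang::arg_match(policy), error = function(e) {
    abort_asf(paste0("Unknown ranking policy '", policy[1],
                     "'; use \"signed\" or \"magnitude\"."),
              "asfscreen_config_error")
  })
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    abort_asf("k must be a number >= 1.", "asfscreen_config_error")
  }
  out <- results
  if (!include_filtered && "passed" %in% names(out)) {
    out <- dplyr::filter(out, .data$passed)
  }
  key <- if (policy == "signed") out$asf else abs(out$asf)
  out <- out[order(key, out$complex_id, method = "radix"), , drop = FALSE]
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  if (is.finite(k)) out <- dplyr::slice_head(out, n = as.integer(k))
  out
}

#' Summarize a group of complexes
#'
#' Group averages in the shape of the per-species summary table: mean area,
#' volume, dipole moment, D/V, average bond length and energy, together with
#' the best (minimum signed) and mean ASF, and the group size.
#'
#' @param x A descriptor tibble or an `asf_results` tibble; descriptors are
#'   scored on the fly with `config`.
#' @param label Species label for the group.
#' @param config Filter configuration used when `x` still needs scoring.
#' @return A one-row tibble with columns `species`, `area_A2`, `volume_A3`,
#'   `dipole_debye`, `dv`, `abl_A`, `energy_J`, `asf_best`, `asf_mean`, `n`.
#' @export
#' @examples
#' summarize_group(load_fixture("table2"), "Fe-Disco-top10")
summarize_group <- function(x, label, config = asf_filter_config()) {
  if (nrow(x) == 0) {
    abort_asf("Cannot summarize an empty group.", "asfscreen_domain_error")
  }
  if (!"asf" %in% names(x)) {
    x <- score_complexes(x, config)
  }
  tibble(
    species = label,
    area_A2 = mean(x$area_A2),
    volume_A3 = mean(x$volume_A3),
    dipole_debye = mean(x$dipole_debye),
    dv = mean(x$dv),
    abl_A = mean(x$abl_A),
    energy_J = mean(x$energy_J),
    asf_best = min(x$asf),
    asf_mean = mean(x$asf),
    n = nrow(x)
  )
}

#' Replicate a packaged reference table
#'
#' Rescores one of the packaged descriptor tables (`"table2"` ...
#' `"table7"`) and compares the recomputed average bond length, D/V ratio
#' and ASF with the printed columns. Rows whose printed average bond length
#' disagrees with the mean of their own printed distances by more than
#' `abl_tol` are flagged (`abl_consistent = FALSE`) and their ASF is
#' recomputed from the *printed* average instead, since the scoring formula
#' was evidently applied to that value; three such internal inconsistencies
#' are known in the halichondrin tables.
#'
#' @param table_name One of `"table2"` ... `"table7"`, or a descriptor tibble
#'   carrying `printed_abl`, `printed_dv`, `printed_asf` columns.
#' @param abl_tol,dv_tol Absolute agreement tolerances for the printed
#'   average bond length and D/V columns (default 5e-4, the rounding implied
#'   by the printed precision).
#' @param asf_rel_tol Relative tolerance for the printed ASF column
#'   (default 1%, covering 2-5 printed significant figures).
#' @return A tibble with recomputed values (`abl_A`, `dv`, `asf`), printed
#'   values, per-row absolute/relative deviations, and consistency flags
#'   `abl_consistent`, `dv_consistent`, `asf_consistent`, `complete`.
#' @export
#' @examples
#' replicate_table("table2")
replicate_table <- function(table_name, abl_tol = 5e-4, dv_tol = 5e-4,
                            asf_rel_tol = 0.01) {
  x <- if (is.data.frame(table_name)) table_name else load_fixture(table_name)
  needed <- c("printed_abl", "printed_dv", "printed_asf")
  if (!all(needed %in% names(x))) {
    abort_asf("Replication needs printed_abl, printed_dv, printed_asf columns.",
              "asfscreen_schema_error")
  }
  scored <- score_complexes(x)
  eps <- 1e-12  # keep deviations sitting exactly on the tolerance inside it
  scored$abl_dev <- abs(scored$abl_A - scored$printed_abl)
  scored$abl_consistent <- scored$abl_dev <= abl_tol + eps
  scored$dv_dev <- abs(scored$dv - scored$printed_dv)
  scored$dv_consistent <- scored$dv_dev <= dv_tol + eps
  scored$complete <- !scored$incomplete
  # where the printed ABL disagrees with the printed distances, replicate
  # the printed ASF from the printed ABL
  abl_used <- ifelse(scored$abl_consistent, scored$abl_A, scored$printed_abl)
  scored$asf_replicated <- compute_asf(scored$energy_J, abl_used,
                                       scored$dipole_debye, scored$charge,
                                       complex_id = scored$complex_id)
  scored$asf_rel_dev <- abs(scored$asf_replicated - scored$printed_asf) /
    abs(scored$printed_asf)
  scored$asf_consistent <- scored$asf_rel_dev <= asf_rel_tol
  scored
}
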