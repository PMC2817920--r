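# Reading and writing descriptor and activity tables.
#
# Canonical descriptor schema (CSV header):
#   complex_id,donors,dipole_debye,d1,d2,d3,d4,d5,d6,area_A2,volume_A3,
#   molar_mass,energy_J,charge
# Donor labels are ";"-joined free strings ("O1;O2;...;N1"); "H2O" is the
# reserved label for an aqua ligand occupying one coordination site.

DESCRIPTOR_COLUMNS <- c(
  "complex_id", "donors", "dipole_debye",
  paste0("d", 1:6),
  "area_A2", "volume_A3", "molar_mass", "energy_J", "charge"
)

DISTANCE_COLUMNS <- paste0("d", 1:6)

abort_asf <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "asfscreen_error"), ...)
}

#' Read a descriptor table
#'
#' Reads a CSV/TSV table of per-complex physical descriptors: dipole moment
#' (Debye), the six Fe--O/Fe--N/Fe--OH2 coordination bond distances (Angstrom),
#' surface area (Angstrom^2), volume (Angstrom^3), molar mass (g/mol), complex
#' energy (J, on the scale of the semi-empirical output it came from), and
#' complex charge. Bond distances may be supplied either as six numeric
#' columns `d1`...`d6` or as a single comma-joined `distances` column.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @param strict If `TRUE` (default) every record must carry six bond
#'   distances. If `FALSE`, records with five distances are retained and
#'   flagged in the `incomplete` column (some published tables print only
#'   five distances for a six-coordinate complex).
#' @return A tibble with the canonical descriptor columns plus `has_aqua`
#'   (the donor set contains the reserved `"H2O"` label) and `incomplete`.
#'   Extra columns in the input are preserved.
#' @export
#' @examples
#' path <- asf_fixture_path("table2.csv")
#' read_descriptor_table(path)
read_descriptor_table <- function(path, dialect = c("csv", "tsv"),
                                  strict = TRUE) {
  dialect <- rlang::arg_match(dialect)
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)

  if ("distances" %in% names(raw) && !all(DISTANCE_COLUMNS %in% names(raw))) {
    parts <- stringr::str_split(raw$distances, ",\\s*")
    for (i in 1:6) {
      raw[[paste0("d", i)]] <- purrr::map_chr(parts, function(p) {
        if (length(p) >= i) p[[i]] else NA_character_
      })
    }
    raw$distances <- NULL
  }

  missing_cols <- setdiff(DESCRIPTOR_COLUMNS, names(raw))
  # d6 may be legitimately absent only as empty cells, never as a column,
  # so every canonical column must be present.
  if (length(missing_cols) > 0) {
    abort_asf(
      paste0("Descriptor table is missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      "asfscreen_schema_error"
    )
  }

  numeric_cols <- setdiff(DESCRIPTOR_COLUMNS, c("complex_id", "donors"))
  out <- raw
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & out[[col]] != "" & is.na(parsed))
    if (length(bad) > 0) {
      abort_asf(
        paste0("Column '", col, "' has unparseable numeric value(s) in row(s) ",
               paste(bad, collapse = ", "), " (e.g. \"", out[[col]][bad[1]],
               "\"); refusing to coerce silently."),
        "asfscreen_parse_error"
      )
    }
    out[[col]] <- parsed
  }
  # Any remaining extra column that looks numeric is parsed too.
  for (col in setdiff(names(out), DESCRIPTOR_COLUMNS)) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    if (!all(is.na(parsed) & !is.na(out[[col]]) & out[[col]] != "")) {
      ok <- is.na(out[[col]]) | out[[col]] == "" | !is.na(parsed)
      if (all(ok)) out[[col]] <- parsed
    }
  }

  dist_mat <- as.matrix(out[DISTANCE_COLUMNS])
  n_dist <- rowSums(!is.na(dist_mat))
  if (any(n_dist < 5)) {
    abort_asf(
      paste0("Row(s) ", paste(which(n_dist < 5), collapse = ", "),
             " have fewer than 5 bond distances."),
      "asfscreen_record_error"
    )
  }
  if (strict && any(n_dist < 6)) {
    abort_asf(
      paste0("Row(s) ", paste(which(n_dist < 6), collapse = ", "),
             " have fewer than 6 bond distances; re-read with strict = FALSE ",
             "to retain them flagged as incomplete."),
      "asfscreen_record_error"
    )
  }

  out <- as_tibble(out)
  out$incomplete <- n_dist < 6
  out$has_aqua <- purrr::map_lgl(split_donors(out$donors), function(d) "H2O" %in% d)
  validate_descriptors(out)
  out
}

#' Write a descriptor table
#'
#' Inverse of [read_descriptor_table()]: writes the canonical descriptor
#' schema (plus any extra columns) so that reading the file back reproduces
#' the input field-by-field.
#'
#' @param x A descriptor tibble.
#' @param path Output file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- rlang::arg_match(dialect)
  missing_cols <- setdiff(DESCRIPTOR_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    abort_asf(
      paste0("Cannot write descriptor table; missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      "asfscreen_schema_error"
    )
  }
  extras <- setdiff(names(x), c(DESCRIPTOR_COLUMNS, "incomplete", "has_aqua"))
  out <- x[, c(DESCRIPTOR_COLUMNS, extras)]
  writer <- if (dialect == "csv") readr::write_csv else readr::write_tsv
  writer(out, path, progress = FALSE)
  invisible(path)
}

#' Read an activity table
#'
#' Reads a two-column CSV (`sample_id,gi50`) of growth-inhibition activity
#' values, e.g. GI50 concentrations from the NCI 60-cell-line screen.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `sample_id` (character) and `gi50` (numeric).
#' @export
read_activity_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    gi50 = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(c("sample_id", "gi50"), names(out))
  if (length(missing_cols) > 0) {
    abort_asf(
      paste0("Activity table is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      "asfscreen_schema_error"
    )
  }
  if (any(!is.finite(out$gi50) | out$gi50 <= 0)) {
    abort_asf("All gi50 values must be positive (their logarithm is taken).",
              "asfscreen_record_error")
  }
  out
}

split_donors <- function(donors) {
  stringr::str_split(donors, ";\\s*")
}

join_donors <- function(labels) {
  paste(labels, collapse = ";")
}

validate_descriptors <- function(x) {
  check <- function(cond, msg) {
    bad <- which(!cond)
    if (length(bad) > 0) {
      abort_asf(paste0(msg, " (row(s) ", paste(bad, collapse = ", "), ")."),
                "asfscreen_record_error")
    }
  }
  check(!is.na(x$dipole_debye) & x$dipole_debye >= 0,
        "dipole_debye must be non-negative")
  check(!is.na(x$volume_A3) & x$volume_A3 > 0, "volume_A3 must be positive")
  check(!is.na(x$area_A2) & x$area_A2 > 0, "area_A2 must be positive")
  dist_mat <- as.matrix(x[DISTANCE_COLUMNS])
  check(apply(dist_mat, 1, function(d) all(is.na(d) | d > 0)),
        "bond distances must be positive")
  invisible(x)
}
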