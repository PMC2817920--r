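# Donor-atom identification and octahedral coordination-shell enumeration.
#
# Iron is assumed six-coordinate (octahedral). A candidate shell is either
# six O/N donors from the ligand, or five ligand donors plus one aqua ligand
# occupying the sixth site.

#' Identify O/N donor atoms in a molecular structure
#'
#' Parses an SDF/MOL V2000 file (via \pkg{ChemmineR}) and returns every
#' oxygen and nitrogen atom as a candidate iron-binding donor. Labels are
#' assigned per element in file atom order (`"O1"`, `"O2"`, ..., `"N1"`, ...),
#' matching the convention of numbering a structure's heteroatoms by element.
#' A user-supplied label map can override this numbering to match a published
#' figure.
#'
#' @param structure Path to an SDF or MOL file, or a `ChemmineR::SDFset`.
#' @param label_map Optional relabeling: a named character vector mapping
#'   0-based atom indices to labels (e.g. `c("0" = "O3")`), or the path to a
#'   JSON file holding such a mapping.
#' @return A tibble with columns `atom_index` (0-based index into the
#'   structure), `element` (`"O"` or `"N"`), `label`, and coordinates
#'   `x`, `y`, `z` in Angstrom. A structure with no O or N atoms yields an
#'   empty tibble.
#' @export
#' @examples
#' donors <- identify_donors(asf_fixture_path("toy9donors_synthetic.sdf"))
#' donors
identify_donors <- function(structure, label_map = NULL) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort_asf("Package 'ChemmineR' is required to parse SDF/MOL structures.",
              "asfscreen_dependency_error")
  }
  if (is.character(structure)) {
    if (!file.exists(structure)) {
      abort_asf(paste0("Structure file not found: ", structure),
                "asfscreen_format_error")
    }
    sdf <- tryCatch(ChemmineR::read.SDFset(structure),
                    error = function(e) {
                      abort_asf(paste0("Cannot parse structure file '",
                                       structure, "': ", conditionMessage(e)),
                                "asfscreen_format_error")
                    })
  } else {
    sdf <- structure
  }
  ab <- ChemmineR::atomblock(sdf[[1]])
  elements <- sub("_.*$", "", rownames(ab))

  keep <- which(elements %in% c("O", "N"))
  out <- tibble(
    atom_index = keep - 1L,
    element = elements[keep],
    x = unname(ab[keep, 1]),
    y = unname(ab[keep, 2]),
    z = unname(ab[keep, 3])
  )
  # per-element counters in file atom order
  out$label <- paste0(out$element,
                      stats::ave(seq_along(keep), out$element, FUN = seq_along))

  if (!is.null(label_map)) {
    if (is.character(label_map) && length(label_map) == 1 &&
        file.exists(label_map)) {
      lm_list <- jsonlite::read_json(label_map, simplifyVector = TRUE)
      label_map <- unlist(lm_list)
    }
    idx <- match(as.character(out$atom_index), names(label_map))
    hit <- !is.na(idx)
    out$label[hit] <- unname(label_map[idx[hit]])
  }
  if (anyDuplicated(out$label)) {
    abort_asf("Donor labels must be unique within a molecule.",
              "asfscreen_record_error")
  }
  out[, c("atom_index", "element", "label", "x", "y", "z")]
}

#' Enumerate candidate octahedral coordination shells
#'
#' Builds every candidate six-coordinate shell over a donor set: all
#' 6-donor subsets, and (with `include_aqua = TRUE`) additionally all
#' 5-donor subsets completed by an aqua ligand on the sixth site. Output
#' order is deterministic: shells are listed lexicographically by their
#' sorted donor labels, six-donor shells first.
#'
#' @param donors A tibble from [identify_donors()], or a character vector of
#'   donor labels.
#' @param include_aqua Also enumerate five-donor + water shells.
#' @param max_span Optional geometry prefilter: maximum allowed pairwise
#'   donor-donor distance (Angstrom) within a shell. All six donors of an
#'   octahedron with bonds below ~2.9 Angstrom fit in a sphere of diameter
#'   ~5.8 Angstrom; `8.0` is a permissive bound. Requires donor coordinates.
#' @return A tibble with columns `shell_id`, `donors` (";"-joined sorted
#'   labels), `has_aqua`, `n_donors`.
#' @export
#' @examples
#' enumerate_shells(paste0("O", 1:8))
enumerate_shells <- function(donors, include_aqua = FALSE, max_span = NULL) {
  if (is.data.frame(donors)) {
    labels <- donors$label
    coords <- if (all(c("x", "y", "z") %in% names(donors))) {
      as.matrix(donors[, c("x", "y", "z")])
    }
  } else {
    labels <- as.character(donors)
    coords <- NULL
  }
  if (anyDuplicated(labels)) {
    abort_asf("Donor labels must be unique.", "asfscreen_record_error")
  }
  n <- length(labels)
  needed <- if (include_aqua) 5L else 6L
  if (n < needed) {
    abort_asf(
      paste0("Need at least ", needed, " donors to enumerate shells; got ",
             n, "."),
      "asfscreen_capacity_error"
    )
  }
  ord <- order(labels, method = "radix")
  labels <- labels[ord]
  if (!is.null(coords)) coords <- coords[ord, , drop = FALSE]

  subsets_of <- function(k) {
    if (n < k) return(list())
    cols <- utils::combn(n, k)
    lapply(seq_len(ncol(cols)), function(j) cols[, j])
  }

  build <- function(idx_list, aqua) {
    if (length(idx_list) == 0) return(NULL)
    keep <- rep(TRUE, length(idx_list))
    if (!is.null(max_span)) {
      if (is.null(coords)) {
        abort_asf("Geometry prefilter requires donor coordinates.",
                  "asfscreen_geometry_error")
      }
      keep <- purrr::map_lgl(idx_list, function(idx) {
        d <- stats::dist(coords[idx, , drop = FALSE])
        length(d) == 0 || max(d) <= max_span
      })
    }
    idx_list <- idx_list[keep]
    if (length(idx_list) == 0) return(NULL)
    tibble(
      donors = purrr::map_chr(idx_list, function(idx) join_donors(labels[idx])),
      has_aqua = aqua,
      n_donors = if (aqua) 5L else 6L
    )
  }

  six <- build(subsets_of(6L), aqua = FALSE)
  five <- if (include_aqua) build(subsets_of(5L), aqua = TRUE)
  out <- dplyr::bind_rows(six, five)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(donors = character(), has_aqua = logical(),
                  n_donors = integer())
  }
  out <- out %>%
    dplyr::arrange(.data$has_aqua, .data$donors) %>%
    dplyr::mutate(shell_id = dplyr::row_number(), .before = 1)
  out
}

#' Cap the number of shells per coordination mode
#'
#' A combinatorial enumeration over a donor-rich ligand easily exceeds the
#' roughly fifty structures per mode that are practical to push through a
#' quantum-chemistry stage, so the candidate list is capped explicitly.
#' `"first"` keeps the lexicographically first shells per mode;
#' `"random"` draws a reproducible seeded sample per mode.
#'
#' @param shells A tibble from [enumerate_shells()].
#' @param max_count Maximum number of shells retained per mode
#'   (six-donor and aqua shells are capped independently).
#' @param rule `"first"` (default) or `"random"`.
#' @param seed Integer seed; mandatory when `rule = "random"`.
#' @return The capped shells tibble, in enumeration order.
#' @export
cap_shells <- function(shells, max_count = 50, rule = c("first", "random"),
                       seed = NULL) {
  rule <- rlang::arg_match(rule)
  if (!is.numeric(max_count) || max_count < 1) {
    abort_asf("max_count must be a positive number.",
              "asfscreen_config_error")
  }
  if (rule == "random" && is.null(seed)) {
    abort_asf("Random shell selection requires an explicit seed.",
              "asfscreen_config_error")
  }
  pick <- function(group) {
    if (nrow(group) <= max_count) return(group)
    if (rule == "first") {
      group[seq_len(max_count), , drop = FALSE]
    } else {
      idx <- withr::with_seed(seed, sample(nrow(group), max_count))
      group[sort(idx), , drop = FALSE]
    }
  }
  shells %>%
    dplyr::group_by(.data$has_aqua) %>%
    dplyr::group_modify(function(g, key) pick(g)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$shell_id)
}

#' Count staggered-rotamer conformations
#'
#' A backbone with `n` freely rotating single bonds, each with three
#' staggered rotamers, has up to `3^n` conformations. Computed in exact
#' integer arithmetic: the result is returned as a numeric when it is
#' exactly representable as a double (n <= 33) and as a decimal string
#' otherwise, so no precision is lost up to n = 40 and beyond.
#'
#' @param n_rotatable_bonds Non-negative integer count of rotatable bonds.
#' @return `3^n`, numeric for n <= 33, character for larger n.
#' @export
#' @examples
#' count_conformers(15) # 14348907
count_conformers <- function(n_rotatable_bonds) {
  n <- n_rotatable_bonds
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n != floor(n) || n < 0) {
    abort_asf("n_rotatable_bonds must be a single non-negative integer.",
              "asfscreen_domain_error")
  }
  # little-endian base-10 digit vector, schoolbook multiply by 3
  digits <- c(1L)
  if (n > 0) {
    for (i in seq_len(n)) {
      prod <- digits * 3L
      carry <- 0L
      for (j in seq_along(prod)) {
        v <- prod[j] + carry
        prod[j] <- v %% 10L
        carry <- v %/% 10L
      }
      while (carry > 0L) {
        prod <- c(prod, carry %% 10L)
        carry <- carry %/% 10L
      }
      digits <- prod
    }
  }
  s <- paste(rev(digits), collapse = "")
  if (n <= 33) as.numeric(s) else s
}
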