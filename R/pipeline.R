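# End-to-end screening pipeline: descriptors in (table, fixture, structure
# + mock, or synthetic), scored/ranked/polarity-classified results out,
# with optional activity correlation and a run manifest.

#' Run the full ASF screening pipeline
#'
#' Wires the package's stages together: obtain descriptors, apply the
#' covalency filters and score, rank, summarize, classify polarity, and
#' optionally fit a descriptor trend and correlate against activity data.
#'
#' `config` is a flat named list (or the path to a JSON/YAML file holding
#' one) with exactly one descriptor source among:
#'
#' * `descriptor_table`: path to a CSV/TSV descriptor table;
#' * `fixture`: name of a packaged table (`"table2"` ... `"table7"`);
#' * `structure`: path to an SDF/MOL file -- shells are enumerated over its
#'   O/N donors (`aqua`, `cap`, `seed`, `max_span` control the enumeration)
#'   and scored from deterministic mock descriptors;
#' * `synthetic`: a list of [synthetic_config()] arguments (needs `seed`).
#'
#' Optional entries: `max_abl` (2.7), `max_bond` (2.9), `charge` (records'
#' own charge), `rank_k` (10), `policy` (`"signed"`), `include_filtered`
#' (FALSE), `aqua` (FALSE), `cap` (50), `seed`, `max_span`, `bands`,
#' `group_label`, `activity_table` (path), `out_dir`.
#'
#' When `out_dir` is set, the stage outputs are written there:
#' `results.csv`, `summary.csv`, `polarity.json`, `trends.json` (when
#' activity data were given) and `manifest.json` (config hash, seed,
#' package version, per-stage counts).
#'
#' @param config Named list or path to a JSON/YAML config file.
#' @return A list of class `asf_pipeline_result` with elements
#'   `descriptors`, `results`, `ranked`, `summary`, `polarity`,
#'   `correlation` (or `NULL`), `log`, `manifest`.
#' @export
#' @examples
#' run_asf_pipeline(list(fixture = "table2", rank_k = 5))
run_asf_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  if (!is.list(config)) {
    abort_asf("config must be a named list or the path to a config file.",
              "asfscreen_config_error")
  }
  defaults <- list(max_abl = 2.7, max_bond = 2.9, charge = NULL,
                   rank_k = 10, policy = "signed", include_filtered = FALSE,
                   aqua = FALSE, cap = 50, seed = NULL, max_span = NULL,
                   group_label = "complexes", out_dir = NULL)
  config <- utils::modifyList(defaults, config)

  sources <- intersect(c("descriptor_table", "fixture", "structure",
                         "synthetic"), names(config))
  if (length(sources) != 1) {
    abort_asf(paste0("Pipeline stage 'input': config must name exactly one ",
                     "descriptor source (descriptor_table, fixture, ",
                     "structure, or synthetic); found ", length(sources), "."),
              "asfscreen_config_error")
  }

  log <- list()
  descriptors <- switch(
    sources,
    descriptor_table = read_descriptor_table(config$descriptor_table,
                                             strict = FALSE),
    fixture = load_fixture(config$fixture),
    structure = {
      donors <- identify_donors(config$structure,
                                label_map = config$label_map)
      shells <- enumerate_shells(donors, include_aqua = isTRUE(config$aqua),
                                 max_span = config$max_span)
      log$shells_enumerated <- nrow(shells)
      shells <- cap_shells(shells, max_count = config$cap,
                           rule = if (is.null(config$seed)) "first" else "random",
                           seed = config$seed)
      log$shells_after_cap <- nrow(shells)
      mock_descriptors(shells, donors)
    },
    synthetic = {
      syn <- config$synthetic
      generate_descriptors(do.call(synthetic_config, syn))
    }
  )
  log$descriptors <- nrow(descriptors)

  fc <- asf_filter_config(max_average_bond_length = config$max_abl,
                          max_single_bond_length = config$max_bond)
  results <- score_complexes(descriptors, fc, charge = config$charge)
  log$filtered_out <- sum(!results$passed)
  log$filter_reasons <- table(results$filter_reasons[!results$passed])

  ranked <- rank_complexes(results, k = config$rank_k,
                           policy = config$policy,
                           include_filtered = isTRUE(config$include_filtered))
  log$ranked <- nrow(ranked)

  summary <- summarize_group(results, config$group_label, fc)
  bands <- if (is.null(config$bands)) DEFAULT_POLARITY_BANDS
           else sort(unlist(config$bands))
  polarity <- list(
    classification = classify_polarity(results$dv, bands = bands),
    range = polarity_range(results, bands = bands)
  )

  correlation <- NULL
  if (!is.null(config$activity_table)) {
    activity <- read_activity_table(config$activity_table)
    correlation <- sorted_log_correlation(results$asf, activity$gi50)
  }

  manifest <- list(
    package = "asfscreen",
    version = as.character(utils::packageVersion("asfscreen")),
    config_hash = rlang::hash(config[sort(names(config))]),
    seed = config$seed %||% config$synthetic$seed,
    source = sources,
    counts = log[c("descriptors", "filtered_out", "ranked")]
  )

  out <- structure(
    list(descriptors = descriptors, results = results, ranked = ranked,
         summary = summary, polarity = polarity, correlation = correlation,
         log = log, manifest = manifest),
    class = "asf_pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort_asf(paste0("Pipeline stage 'config': file not found: ", path),
              "asfscreen_config_error")
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_asf("Package 'yaml' is required to read YAML configs.",
                "asfscreen_dependency_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res_out <- res$results
  res_out$rank <- res$ranked$rank[match(res_out$complex_id,
                                        res$ranked$complex_id)]
  readr::write_csv(res_out, file.path(out_dir, "results.csv"),
                   progress = FALSE)
  readr::write_csv(res$summary, file.path(out_dir, "summary.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(range = res$polarity$range,
         classification = res$polarity$classification),
    file.path(out_dir, "polarity.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  if (!is.null(res$correlation)) {
    cor <- res$correlation
    jsonlite::write_json(
      list(family = cor$fit$family,
           coefficients = as.list(cor$fit$coefficients),
           r_squared = cor$fit$r_squared,
           n = cor$n_pairs,
           warnings = cor$warnings),
      file.path(out_dir, "trends.json"), auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.asf_pipeline_result <- function(x, ...) {
  cat("<asf_pipeline_result>\n")
  cat("  descriptors: ", nrow(x$descriptors), "\n", sep = "")
  cat("  filtered out: ", x$log$filtered_out, "\n", sep = "")
  cat("  ranked: ", nrow(x$ranked), " (best ASF ",
      format(x$ranked$asf[1], digits = 4), ")\n", sep = "")
  cat("  polarity: ", as.character(x$polarity$range$min_band), " to ",
      as.character(x$polarity$range$max_band),
      if (x$polarity$range$adaptive) " (polarity adaptive)", "\n", sep = "")
  invisible(x)
}
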