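#' Write a simulated dataset as TSV files
#'
#' Writes wide probe-by-sample matrices (`two_color_log2ratio.tsv`,
#' `two_color_uniform.tsv`, `one_color_signal.tsv`,
#' `one_color_background.tsv`, `one_color_uniform.tsv`) plus `design.tsv`,
#' `probes.tsv`, `truth.tsv`, `truth_effects.tsv` and `artifacts.tsv`.
#' Missing values are written as empty fields.
#'
#' @param sim An `mghi_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  if (!inherits(sim, "mghi_sim")) abort("`sim` must be an mghi_sim object")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name), na = "", progress = FALSE)
  }
  wide <- function(long, value) {
    long %>%
      select("probe_id", "sample_id", all_of(value)) %>%
      tidyr::pivot_wider(names_from = "sample_id", values_from = all_of(value)) %>%
      arrange(.data$probe_id)
  }
  w(wide(sim$two_color, "log2_ratio"), "two_color_log2ratio.tsv")
  w(wide(sim$two_color, "uniform"), "two_color_uniform.tsv")
  w(wide(sim$one_color, "signal"), "one_color_signal.tsv")
  w(wide(sim$one_color, "background"), "one_color_background.tsv")
  w(wide(sim$one_color, "uniform"), "one_color_uniform.tsv")
  w(sim$design, "design.tsv")
  w(sim$probes, "probes.tsv")
  w(sim$truth, "truth.tsv")
  w(sim$truth_effects, "truth_effects.tsv")
  w(sim$artifacts, "artifacts.tsv")
  cfg <- sim$config
  cfg$probes_per_gene <- as.list(cfg$probes_per_gene)
  cfg$class_proportions <- as.list(cfg$class_proportions)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated dataset written by [write_sim_data()]
#'
#' @param dir Directory holding the TSV files.
#' @return An `mghi_sim` object.
#' @export
read_sim_data <- function(dir) {
  need <- c("two_color_log2ratio.tsv", "two_color_uniform.tsv",
            "one_color_signal.tsv", "one_color_background.tsv",
            "one_color_uniform.tsv", "design.tsv", "probes.tsv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      abort(sprintf("input file missing or unreadable: %s",
                    file.path(dir, f)))
    }
  }
  r <- function(name, types = NULL) {
    readr::read_tsv(file.path(dir, name), col_types = types,
                    progress = FALSE)
  }
  design <- r("design.tsv", readr::cols(.default = readr::col_character(),
                                        replicate = readr::col_integer()))
  if (!all(c("sample_id", "experiment", "condition", "timepoint",
             "replicate", "channel") %in% names(design))) {
    abort(sprintf("corrupt design file: %s", file.path(dir, "design.tsv")))
  }
  long <- function(name, value, col_type) {
    r(name, readr::cols(probe_id = readr::col_character(),
                        .default = col_type)) %>%
      tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                          values_to = value)
  }
  two_color <- long("two_color_log2ratio.tsv", "log2_ratio",
                    readr::col_double()) %>%
    inner_join(long("two_color_uniform.tsv", "uniform",
                    readr::col_logical()),
               by = c("probe_id", "sample_id")) %>%
    inner_join(design %>%
                 filter(.data$channel == "log2ratio") %>%
                 mutate(contrast = c(Mg_vs_Ctrl = "mg",
                                     MgHI_vs_HI = "mghi_hi",
                                     HI_vs_Ctrl = "hi")[.data$condition]) %>%
                 select("sample_id", "contrast", "timepoint", "replicate"),
               by = "sample_id")
  one_color <- long("one_color_signal.tsv", "signal", readr::col_double()) %>%
    inner_join(long("one_color_background.tsv", "background",
                    readr::col_double()),
               by = c("probe_id", "sample_id")) %>%
    inner_join(long("one_color_uniform.tsv", "uniform",
                    readr::col_logical()),
               by = c("probe_id", "sample_id")) %>%
    inner_join(design %>%
                 filter(.data$channel %in% c("Cy3", "Cy5")) %>%
                 select("sample_id", "experiment", "condition", "timepoint",
                        "replicate"),
               by = "sample_id")
  probes <- r("probes.tsv", readr::cols(.default = readr::col_character()))

  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    r("truth.tsv", readr::cols(.default = readr::col_character()))
  } else NULL
  te_path <- file.path(dir, "truth_effects.tsv")
  truth_effects <- if (file.exists(te_path)) {
    r("truth_effects.tsv",
      readr::cols(.default = readr::col_character(),
                  true_log2_effect = readr::col_double()))
  } else NULL
  art_path <- file.path(dir, "artifacts.tsv")
  artifacts <- if (file.exists(art_path)) {
    r("artifacts.tsv", readr::cols(.default = readr::col_character()))
  } else NULL
  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path)) {
    raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    raw$probes_per_gene <- unlist(raw$probes_per_gene)
    raw$class_proportions <- unlist(raw$class_proportions)
    do.call(sim_config, raw[setdiff(names(raw), character())])
  } else NULL

  structure(list(two_color = two_color %>%
                   select("probe_id", "contrast", "timepoint", "replicate",
                          "sample_id", "log2_ratio", "uniform"),
                 one_color = one_color %>%
                   select("probe_id", "experiment", "condition", "timepoint",
                          "replicate", "sample_id", "signal", "background",
                          "uniform"),
                 design = design, probes = probes, truth = truth,
                 truth_effects = truth_effects, artifacts = artifacts,
                 config = config),
            class = "mghi_sim")
}

#' Write all pipeline outputs as TSV/JSON files
#'
#' One TSV per directional list, plus the classification, probe and gene
#' statistics, Venn counts, tallies, amplitude and summary tables, and the
#' run manifest as JSON.
#'
#' @param result An `mghi_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  if (!inherits(result, "mghi_result")) {
    abort("`result` must come from run_pipeline()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name), na = "", progress = FALSE)
  }
  for (nm in names(result$lists)) {
    w(as_tibble(result$lists[[nm]]), sprintf("list_%s.tsv", nm))
  }
  w(result$classification, "classification.tsv")
  w(result$stats, "probe_stats.tsv")
  w(result$gene_stats, "gene_stats.tsv")
  w(result$venn, "venn_counts.tsv")
  w(result$tallies, "direction_tallies.tsv")
  w(result$amplitudes, "amplitudes.tsv")
  w(result$summary, "summary.tsv")
  manifest <- result$manifest
  manifest$config <- if (!is.null(manifest$config)) {
    unclass(manifest$config)
  } else NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
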