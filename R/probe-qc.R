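#' Filter probes on spot uniformity and detection above background
#'
#' Operates on a long spot table (one row per probe x sample). Filtering is
#' cell-wise, where a cell is a probe crossed with the grouping columns
#' present in the table (any of `contrast`, `experiment`, `condition`,
#' `timepoint`): differential calls are extracted per timepoint, so a probe
#' unusable in one cell can still support calls elsewhere.
#'
#' A cell is removed when any of its spots carries a non-uniformity flag.
#' For one-color tables (a `background` column is present) a cell is
#' additionally removed unless its signal is strictly above
#' `detection_factor` times the local background in at least `min_detected`
#' samples; boundary equality fails. Two-color ratio tables are filtered on
#' uniformity only.
#'
#' @param spots Long tibble with columns `probe_id`, `sample_id`, `uniform`,
#'   plus `signal` and `background` for one-color data and any grouping
#'   columns.
#' @param detection_factor Multiple of background a signal must exceed.
#' @param min_detected Minimum number of detected samples per cell.
#'
#' @return The retained spots. The removal log (one row per dropped cell,
#'   with a `reason`) is attached as attribute `"qc_report"`; see
#'   [qc_report()].
#' @export
filter_probes <- function(spots, detection_factor = 2, min_detected = 2) {
  assert_cols(spots, c("probe_id", "sample_id", "uniform"), "spots")
  assert_scalar_number(detection_factor, "detection_factor", min = 1e-12)
  assert_scalar_number(min_detected, "min_detected", min = 1)
  one_color <- "background" %in% names(spots)
  if (one_color) {
    assert_cols(spots, "signal", "spots")
    if (anyNA(spots$background)) {
      abort("one-color input has missing `background` values")
    }
  }
  group_cols <- intersect(c("contrast", "experiment", "condition", "timepoint"),
                          names(spots))
  cell_cols <- c("probe_id", group_cols)

  cells <- spots %>%
    group_by(across(all_of(cell_cols))) %>%
    summarise(
      n_nonuniform = sum(!.data$uniform),
      n_detected = if (one_color) {
        sum(.data$signal > .env$detection_factor * .data$background)
      } else NA_integer_,
      .groups = "drop") %>%
    mutate(reason = case_when(
      .data$n_nonuniform > 0 ~ "non_uniform",
      one_color & .data$n_detected < .env$min_detected ~ "below_detection",
      .default = NA_character_))

  removed <- cells %>%
    filter(!is.na(.data$reason)) %>%
    select(all_of(cell_cols), "reason")
  kept <- spots %>%
    anti_join(removed, by = cell_cols)
  attr(kept, "qc_report") <- removed
  kept
}

#' Retrieve the removal log of a QC step
#'
#' @param x A table returned by [filter_probes()].
#' @return Tibble of removed cells with their reason, or counts of excluded
#'   probes for [exclude_nongene_probes()] output.
#' @export
qc_report <- function(x) {
  attr(x, "qc_report") %||% tibble()
}

#' Keep only probes annotated to validated gene symbols
#'
#' Probes annotated as Riken clones or array controls are excluded; only
#' probes with `status == "gene"` are carried forward, with their gene symbol
#' joined in. Every probe must have an annotation row.
#'
#' @param spots Long spot table with a `probe_id` column.
#' @param annotation Tibble with `probe_id`, `gene_symbol`, `status`.
#'
#' @return `spots` restricted to gene probes, with `gene_symbol` attached.
#'   Counts of excluded probes by status are available via [qc_report()].
#' @export
exclude_nongene_probes <- function(spots, annotation) {
  assert_cols(spots, "probe_id", "spots")
  assert_cols(annotation, c("probe_id", "gene_symbol", "status"), "annotation")
  unknown <- setdiff(unique(spots$probe_id), annotation$probe_id)
  if (length(unknown) > 0) {
    abort(sprintf("probe(s) without annotation row: %s%s",
                  paste(utils::head(unknown, 5), collapse = ", "),
                  if (length(unknown) > 5) ", ..." else ""))
  }
  ann <- annotation %>% distinct(.data$probe_id, .data$gene_symbol, .data$status)
  joined <- spots %>% inner_join(ann, by = "probe_id")
  kept <- joined %>% filter(.data$status == "gene") %>% select(-"status")
  excluded <- joined %>%
    filter(.data$status != "gene") %>%
    distinct(.data$probe_id, .data$status) %>%
    count(.data$status, name = "n_probes")
  if (nrow(kept) == 0) {
    warn("no gene-annotated probes remain after exclusion")
  }
  attr(kept, "qc_report") <- excluded
  kept
}

#' Resolve multiple probes per gene, flagging splice conflicts
#'
#' For every gene x contrast x timepoint the probe with the largest absolute
#' mean log2 ratio represents the gene (ties broken by lexicographically
#' smallest probe id). When two probes of one gene are both called at the
#' same timepoint in opposite directions the gene is flagged
#' `splice_conflict` and both direction-bearing probes are retained, so the
#' gene appears in both the induced and the repressed list.
#'
#' @param stats Probe-level statistics with columns `probe_id`,
#'   `gene_symbol`, `contrast`, `timepoint`, `mean_log2_ratio`, `direction`,
#'   `called` (as from [call_differential()]).
#'
#' @return Gene-level statistics: the representative row(s) per gene x
#'   contrast x timepoint with `chosen_probe`, `n_probes` and
#'   `splice_conflict` columns.
#' @export
resolve_multiprobe <- function(stats) {
  assert_cols(stats, c("probe_id", "gene_symbol", "contrast", "timepoint",
                       "mean_log2_ratio", "direction", "called"), "stats")
  ranked <- stats %>%
    group_by(.data$gene_symbol, .data$contrast, .data$timepoint) %>%
    arrange(desc(abs(.data$mean_log2_ratio)), .data$probe_id,
            .by_group = TRUE) %>%
    mutate(
      n_probes = n(),
      splice_conflict = any(.data$called & .data$direction == "induced") &&
        any(.data$called & .data$direction == "repressed"),
      .rank = row_number()) %>%
    ungroup()

  primary <- ranked %>% filter(.data$.rank == 1)
  # best called probe of the direction opposite to the representative
  secondary <- ranked %>%
    filter(.data$splice_conflict, .data$called) %>%
    inner_join(primary %>%
                 select("gene_symbol", "contrast", "timepoint",
                        primary_direction = "direction"),
               by = c("gene_symbol", "contrast", "timepoint")) %>%
    filter(.data$direction != .data$primary_direction) %>%
    group_by(.data$gene_symbol, .data$contrast, .data$timepoint) %>%
    slice_head(n = 1) %>%
    ungroup() %>%
    select(-"primary_direction")

  bind_rows(primary, secondary) %>%
    mutate(chosen_probe = .data$probe_id) %>%
    select(-".rank") %>%
    arrange(.data$gene_symbol, .data$contrast, .data$timepoint,
            desc(abs(.data$mean_log2_ratio)))
}
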